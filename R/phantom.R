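#' Parameters of the synthetic multi-modal phantom cohort
#'
#' The phantom stands in for a clinical thigh-MRI cohort: per subject, three
#' co-registered modality volumes (T1WI-, T2WI- and STIR-like) over the same
#' anatomy — a cylindrical "thigh" of muscle containing a "bone" cylinder
#' and a single ellipsoidal tumor — plus exact voxel ground truth.  Native
#' spacing is anisotropic (large slice gap, finer in-plane) so the
#' resampling stage is genuinely exercised.
#'
#' The modality contrast table encodes the clinical signal behaviour the
#' segmentation model exploits: the tumor is hypointense relative to muscle
#' in the T1-like modality and hyperintense in the T2- and STIR-like
#' modalities.  A table violating that ordering is rejected.
#'
#' The tumor is elongated along the slice axis and its centre is drawn from
#' the central third of that axis; its slice-axis semi-axis is inflated, if
#' needed, so that after 1 mm resampling every one of the central
#' `ensure_box_slices` scan planes has a nonempty tumor cross-section.  That
#' guarantees the downstream contract that every retained slice carries a
#' marker box (a deliberate idealization relative to clinical tumors).
#'
#' @param n_subjects number of subjects.
#' @param volume_shape native grid (slices, rows, cols).
#' @param spacing native voxel size in mm (slice gap, row, col).
#' @param tumor_radius_range range (mm) of the in-plane tumor semi-axes.
#' @param tumor_halflength_range range (mm) of the slice-axis semi-axis
#'   (inflated when needed for the central-slice guarantee).
#' @param contrast data.frame with one row per modality (T1WI, T2WI, STIR)
#'   and columns `background`, `muscle`, `bone`, `tumor`, `noise_sd`
#'   (arbitrary signal units).
#' @param ensure_box_slices width (in 1 mm resampled slices) of the central
#'   band on which a tumor cross-section is guaranteed (default 64).
#' @param seed master RNG seed for the cohort.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(n_subjects = 45L,
                           volume_shape = c(16L, 160L, 160L),
                           spacing = c(6, 1.6, 1.6),
                           tumor_radius_range = c(15, 30),
                           tumor_halflength_range = c(36, 44),
                           contrast = default_contrast(),
                           ensure_box_slices = 64L,
                           seed = 1L) {
  stopifnot(n_subjects >= 0, length(volume_shape) == 3L, all(volume_shape >= 2),
            length(spacing) == 3L, all(spacing > 0),
            length(tumor_radius_range) == 2L,
            tumor_radius_range[1] > 0,
            diff(tumor_radius_range) >= 0,
            length(tumor_halflength_range) == 2L,
            diff(tumor_halflength_range) >= 0)
  contrast <- validate_contrast(contrast)
  structure(list(n_subjects = as.integer(n_subjects),
                 volume_shape = as.integer(volume_shape),
                 spacing = as.numeric(spacing),
                 tumor_radius_range = as.numeric(tumor_radius_range),
                 tumor_halflength_range = as.numeric(tumor_halflength_range),
                 contrast = contrast,
                 ensure_box_slices = as.integer(ensure_box_slices),
                 seed = as.integer(seed)),
            class = "phantom_params")
}

#' Default modality contrast table for the phantom
#'
#' Signal means in arbitrary units: tumor darker than muscle on the T1-like
#' modality, brighter than muscle on the T2- and STIR-like modalities;
#' moderate additive Gaussian noise.
#' @return data.frame with rows T1WI, T2WI, STIR.
#' @export
default_contrast <- function() {
  data.frame(
    modality   = c("T1WI", "T2WI", "STIR"),
    background = c(10, 10, 10),
    muscle     = c(400, 300, 250),
    bone       = c(550, 220, 180),
    tumor      = c(220, 620, 520),
    noise_sd   = c(20, 20, 20),
    stringsAsFactors = FALSE
  )
}

validate_contrast <- function(contrast) {
  need <- c("modality", "background", "muscle", "bone", "tumor", "noise_sd")
  if (!is.data.frame(contrast) || !all(need %in% names(contrast)))
    stop("phantom_params: contrast table needs columns ",
         paste(need, collapse = ", "))
  rownames(contrast) <- contrast$modality
  if (!all(.modalities %in% contrast$modality))
    stop("phantom_params: contrast table must cover T1WI, T2WI, STIR")
  contrast <- contrast[.modalities, ]
  if (any(contrast$noise_sd < 0))
    stop("phantom_params: noise_sd must be >= 0")
  if (contrast["T1WI", "tumor"] >= contrast["T1WI", "muscle"])
    stop("phantom_params: T1WI tumor mean must be below muscle mean ",
         "(tumor is hypointense on T1)")
  for (m in c("T2WI", "STIR"))
    if (contrast[m, "tumor"] <= contrast[m, "muscle"])
      stop("phantom_params: ", m, " tumor mean must exceed muscle mean ",
           "(tumor is hyperintense on T2/STIR)")
  contrast
}

# Deterministic per-subject seed below 2^31, derived from the master seed.
subject_seed <- function(master, index) {
  as.integer((as.numeric(master) * 1000003 + 7919 * as.numeric(index)) %% 2147483629)
}

#' Generate one synthetic subject
#'
#' Builds the three modality volumes for one subject: tissue geometry is
#' sampled once (shared by all modalities), per-modality means come from the
#' contrast table, and independent Gaussian noise is added per voxel.  The
#' returned mask is the exact voxelization of the analytic tumor ellipsoid
#' (voxel centres inside the ellipsoid), and per-slice boxes are the tight
#' bounding rectangles of the mask's nonempty cross-sections on the native
#' grid.  Fully deterministic given `params` and `subj_seed`.
#'
#' @param params a [phantom_params()].
#' @param subj_seed integer RNG seed for this subject.
#' @return list with `volumes` (named list of three [volume_grid()]s),
#'   `mask` (native-grid 0/1 array), `boxes` (data.frame slice, x_min, y_min,
#'   x_max, y_max; 0-based native slice index, nonempty slices only) and
#'   `geometry` (the sampled analytic parameters, in mm).
#' @export
generate_subject <- function(params, subj_seed) {
  stopifnot(inherits(params, "phantom_params"))
  d <- params$volume_shape; sp <- params$spacing
  ext <- (d - 1) * sp                      # physical extent per axis, mm
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(subj_seed))

  # thigh + bone geometry (deterministic given the grid)
  cy <- ext[2] / 2; cx <- ext[3] / 2
  thigh_r <- 0.40 * min(ext[2], ext[3])
  bone_r <- 0.15 * thigh_r
  bone_c <- c(cy, cx + 0.25 * thigh_r)

  # tumor: centre in the central third of the slice axis; slice-axis
  # semi-axis inflated so the central resampled band keeps a cross-section
  az <- stats::runif(1, params$tumor_halflength_range[1],
                     params$tumor_halflength_range[2])
  cz <- stats::runif(1, ext[1] / 3, 2 * ext[1] / 3)
  L1 <- round(ext[1]) + 1                                   # 1 mm slice count
  band <- central_slice_index(L1, min(params$ensure_box_slices, L1))
  az <- max(az, (max(band) - cz) + 3, (cz - min(band)) + 3)
  ay <- stats::runif(1, params$tumor_radius_range[1], params$tumor_radius_range[2])
  ax <- stats::runif(1, params$tumor_radius_range[1], params$tumor_radius_range[2])

  # in-plane placement: inside muscle, clear of the bone
  r_in <- max(ay, ax)
  ok <- FALSE
  for (try in 1:200) {
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- sqrt(stats::runif(1)) * max(thigh_r - r_in - 2, 0)
    tc <- c(cy + rad * sin(ang), cx + rad * cos(ang))
    if (sqrt(sum((tc - bone_c)^2)) >= bone_r + r_in + 2) { ok <- TRUE; break }
  }
  if (!ok) stop("generate_subject: could not place tumor inside muscle; ",
                "tumor_radius_range too large for this geometry")

  z <- (seq_len(d[1]) - 1) * sp[1]
  y <- (seq_len(d[2]) - 1) * sp[2]
  x <- (seq_len(d[3]) - 1) * sp[3]

  # in-plane tissue label (row x col): 0 bg, 1 muscle, 2 bone
  dy2 <- outer((y - cy)^2, rep(1, d[3]))
  dx2 <- outer(rep(1, d[2]), (x - cx)^2)
  plane <- matrix(0L, d[2], d[3])
  plane[dy2 + dx2 <= thigh_r^2] <- 1L
  bdy2 <- outer((y - bone_c[1])^2, rep(1, d[3]))
  bdx2 <- outer(rep(1, d[2]), (x - bone_c[2])^2)
  plane[bdy2 + bdx2 <= bone_r^2] <- 2L

  # tumor voxelization: voxel centres inside the analytic ellipsoid
  ty2 <- outer(((y - tc[1]) / ay)^2, rep(1, d[3]))
  tx2 <- outer(rep(1, d[2]), ((x - tc[2]) / ax)^2)
  # (placement guarantees the ellipsoid stays inside the muscle in-plane,
  #  so the mask is literally the ellipsoid interior at voxel centres)
  mask <- array(0L, d)
  tissue <- array(0L, d)
  for (s in seq_len(d[1])) {
    tz2 <- ((z[s] - cz) / az)^2
    msl <- (tz2 + ty2 + tx2 <= 1)
    mask[s, , ] <- msl * 1L
    lab <- plane
    lab[msl] <- 3L
    tissue[s, , ] <- lab
  }

  means <- params$contrast
  volumes <- list()
  for (m in .modalities) {
    mu <- c(means[m, "background"], means[m, "muscle"],
            means[m, "bone"], means[m, "tumor"])[tissue + 1L]
    noise <- if (means[m, "noise_sd"] > 0)
      stats::rnorm(length(mu), 0, means[m, "noise_sd"]) else 0
    volumes[[m]] <- volume_grid(array(mu + noise, d), sp,
                                origin_note = paste0("phantom:", m))
  }

  list(volumes = volumes, mask = mask,
       boxes = mask_boxes(mask),
       geometry = list(tumor_center = c(cz, tc), tumor_semiaxes = c(az, ay, ax),
                       thigh_center = c(cy, cx), thigh_radius = thigh_r,
                       bone_center = bone_c, bone_radius = bone_r))
}

# Tight bounding rectangles (0-based, half-open) of each nonempty slice of a
# binary volume.
mask_boxes <- function(mask) {
  rows <- lapply(seq_len(dim(mask)[1]), function(s) {
    sl <- mask[s, , ]
    if (!any(sl > 0)) return(NULL)
    rr <- range(which(rowSums(sl) > 0))  # rows = y
    cc <- range(which(colSums(sl) > 0))  # cols = x
    data.frame(slice = s - 1L, x_min = cc[1] - 1L, y_min = rr[1] - 1L,
               x_max = cc[2], y_max = rr[2])
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(slice = integer(), x_min = integer(), y_min = integer(),
                      x_max = integer(), y_max = integer())
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a phantom cohort on disk
#'
#' Writes `n_subjects` independent subjects under `out_dir`: per subject a
#' directory with the three modality volumes and the native ground-truth
#' mask as NIfTI, plus a box CSV on the resampled annotation grid (the mask
#' is resampled to `target_spacing` / `plane_size` with nearest-neighbour
#' interpolation and per-slice tight boxes are taken from it — the same grid
#' the preprocessing stage and clinical annotations use).  Per-subject seeds
#' are derived deterministically from the master seed and recorded in the
#' returned manifest, so two cohorts with the same parameters are identical.
#'
#' @param params a [phantom_params()].
#' @param out_dir output directory.
#' @param target_spacing,plane_size annotation grid (defaults 1 mm, 512^2),
#'   matching [build_dataset()]'s defaults.
#' @return data.frame manifest: subject id, seed, volume/mask/box paths.
#' @export
generate_cohort <- function(params, out_dir,
                            target_spacing = c(1, 1, 1),
                            plane_size = c(512, 512)) {
  stopifnot(inherits(params, "phantom_params"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", params$n_subjects)
  for (i in seq_len(params$n_subjects)) {
    id <- sprintf("subj%03d", i)
    sdir <- file.path(out_dir, id)
    dir.create(sdir, showWarnings = FALSE)
    seed_i <- subject_seed(params$seed, i)
    subj <- generate_subject(params, seed_i)
    paths <- list()
    for (m in .modalities) {
      paths[[m]] <- file.path(sdir, paste0(m, ".nii.gz"))
      write_volume(subj$volumes[[m]], paths[[m]], datatype = "float")
    }
    mask_path <- file.path(sdir, "mask_native.nii.gz")
    write_volume(volume_grid(subj$mask * 1.0, params$spacing,
                             origin_note = "phantom:mask"), mask_path,
                 datatype = "uint8")
    rmask <- resample_volume(volume_grid(subj$mask * 1.0, params$spacing),
                             target_spacing, plane_size, "nearest")
    boxes <- mask_boxes(round(rmask$data))
    boxes <- cbind(patient = id, boxes)
    box_path <- file.path(sdir, "boxes.csv")
    utils::write.csv(boxes, box_path, row.names = FALSE)
    rows[[i]] <- data.frame(patient = id, seed = seed_i,
                            path_T1WI = paths$T1WI, path_T2WI = paths$T2WI,
                            path_STIR = paths$STIR, path_mask = mask_path,
                            path_boxes = box_path, stringsAsFactors = FALSE)
  }
  manifest <- if (params$n_subjects > 0) do.call(rbind, rows) else
    data.frame(patient = character(), seed = integer(),
               path_T1WI = character(), path_T2WI = character(),
               path_STIR = character(), path_mask = character(),
               path_boxes = character(), stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  manifest
}

#' Load a phantom cohort as [build_dataset()] input
#'
#' @param cohort_manifest data.frame from [generate_cohort()] (or its
#'   `cohort.csv` read back).
#' @return list of patient records (`id`, `volumes`, `boxes`).
#' @export
load_cohort <- function(cohort_manifest) {
  lapply(seq_len(nrow(cohort_manifest)), function(i) {
    row <- cohort_manifest[i, ]
    vols <- lapply(c(T1WI = row$path_T1WI, T2WI = row$path_T2WI,
                     STIR = row$path_STIR), read_volume, format = "nifti")
    list(id = row$patient, volumes = vols,
         boxes = utils::read.csv(row$path_boxes, stringsAsFactors = FALSE))
  })
}
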