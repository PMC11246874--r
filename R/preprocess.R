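#' Rectangular tumor annotation
#'
#' A box annotation marks the sarcoma region on one scan plane with an
#' axis-aligned rectangle, recorded by its upper-left and lower-right
#' corners.  Coordinates are 0-based and half-open: the box covers pixel
#' columns `[x_min, x_max)` and rows `[y_min, y_max)`, with x = column and
#' y = row.  One box is shared by all modalities of the same scan plane.
#'
#' @param x_min,y_min,x_max,y_max integer pixel bounds, `0 <= min < max`.
#' @param applies_to optional patient/plane identifier string.
#' @return An object of class `box_annotation`.
#' @export
box_annotation <- function(x_min, y_min, x_max, y_max, applies_to = "") {
  v <- vapply(list(x_min, y_min, x_max, y_max), function(z) {
    z <- as.numeric(z)
    if (length(z) != 1 || !is.finite(z) || z != round(z))
      stop("box_annotation: corners must be single integers")
    z
  }, 0)
  if (v[1] < 0 || v[2] < 0 || v[1] >= v[3] || v[2] >= v[4])
    stop("box_annotation: need 0 <= x_min < x_max and 0 <= y_min < y_max")
  structure(list(x_min = v[1], y_min = v[2], x_max = v[3], y_max = v[4],
                 applies_to = as.character(applies_to)[1]),
            class = "box_annotation")
}

#' @export
print.box_annotation <- function(x, ...) {
  cat(sprintf("<box_annotation> [%d,%d) x [%d,%d) (x=col, y=row, half-open)%s\n",
              x$x_min, x$x_max, x$y_min, x$y_max,
              if (nzchar(x$applies_to)) paste0(" @", x$applies_to) else ""))
  invisible(x)
}

#' Trimmed min-max normalization of one slice
#'
#' Rescales a scan plane to \[0, 1\] using a min-max transform that is robust
#' to intensity outliers: the brightest and darkest 5% of pixels are
#' discarded and the bounds are taken from the remaining 90%, i.e.
#' `S_min` = 5th percentile and `S_max` = 95th percentile of the slice.
#' The output is `clip((S - S_min) / (S_max - S_min), 0, 1)`, so pixels at
#' the percentile bounds map to exactly 0 and 1 and trimmed outliers are
#' clipped into the interval.  Percentiles use the linear-interpolation
#' convention (R's `quantile()` type 7).
#'
#' The transform is invariant under positive affine rescaling of the input
#' (`a*S + b`, `a > 0`), which is what makes per-slice normalization
#' comparable across scanners and shooting parameters.
#'
#' @param slice 2D numeric array of raw signal intensities.
#' @return list with `data` (normalized 2D array) and `record` (list with
#'   `s_min`, `s_max`), the normalization bounds actually used.
#' @export
trimmed_minmax_normalize <- function(slice) {
  if (!is.matrix(slice) && !(is.array(slice) && length(dim(slice)) == 2L))
    stop("trimmed_minmax_normalize: 'slice' must be 2D")
  if (!all(is.finite(slice)))
    stop("trimmed_minmax_normalize: non-finite intensities")
  q <- percentile_linear(as.vector(slice), c(0.05, 0.95))
  s_min <- q[1]; s_max <- q[2]
  if (s_max <= s_min)
    stop("trimmed_minmax_normalize: degenerate slice (5th and 95th percentile coincide)")
  out <- (slice - s_min) / (s_max - s_min)
  out[out < 0] <- 0
  out[out > 1] <- 1
  list(data = out, record = list(s_min = s_min, s_max = s_max))
}

# Linear-interpolation percentiles (identical to quantile(..., type = 7))
# via partial sorting: only the needed order statistics are selected, which
# matters on 512 x 512 planes.
percentile_linear <- function(x, probs) {
  n <- length(x)
  h <- (n - 1) * probs + 1
  lo <- floor(h); hi <- ceiling(h)
  s <- sort(x, partial = unique(c(lo, hi)))
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

#' Convert a box annotation to a binary mask
#'
#' The ground-truth segmentation target is the filled rectangle of the
#' marker box: 1 on `[y_min, y_max) x [x_min, x_max)`, 0 elsewhere.
#'
#' @param box a [box_annotation()].
#' @param shape length-2 (rows, cols) of the target plane.
#' @return Integer 2D matrix of 0/1.
#' @export
box_to_mask <- function(box, shape) {
  stopifnot(inherits(box, "box_annotation"))
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L)
  if (box$x_max > shape[2] || box$y_max > shape[1])
    stop("box_to_mask: box exceeds plane of ", shape[1], "x", shape[2])
  m <- matrix(0L, shape[1], shape[2])
  m[(box$y_min + 1):box$y_max, (box$x_min + 1):box$x_max] <- 1L
  m
}

#' Crop a fixed window around a tumor box
#'
#' Places a `crop x crop` window centred on the box centre, then translates
#' it the minimum distance needed to lie entirely inside the image, so the
#' crop always contains the whole marker box and never reads outside the
#' original plane.  The returned annotation is the same box re-expressed in
#' crop-local coordinates.
#'
#' @param image 2D array, at least `crop x crop`.
#' @param box a [box_annotation()] in image coordinates; must fit in the window.
#' @param crop window side length in pixels (default 256).
#' @return list with `data` (`crop x crop` array), `box` (shifted
#'   [box_annotation()]), and `offset` (length-2 c(row0, col0), the 0-based
#'   image coordinates of the window's upper-left corner).
#' @export
crop_around_box <- function(image, box, crop = 256L) {
  stopifnot(inherits(box, "box_annotation"))
  crop <- as.integer(crop)
  d <- dim(image)
  if (is.null(d) || length(d) != 2L) stop("crop_around_box: 'image' must be 2D")
  if (d[1] < crop || d[2] < crop)
    stop("crop_around_box: image smaller than crop window")
  if ((box$x_max - box$x_min) > crop || (box$y_max - box$y_min) > crop)
    stop("crop_around_box: box larger than crop window",
         if (nzchar(box$applies_to)) paste0(" (", box$applies_to, ")") else "")
  col0 <- floor((box$x_min + box$x_max - crop) / 2)
  row0 <- floor((box$y_min + box$y_max - crop) / 2)
  col0 <- min(max(col0, 0), d[2] - crop)
  row0 <- min(max(row0, 0), d[1] - crop)
  out <- image[(row0 + 1):(row0 + crop), (col0 + 1):(col0 + crop), drop = FALSE]
  list(
    data = out,
    box = box_annotation(box$x_min - col0, box$y_min - row0,
                         box$x_max - col0, box$y_max - row0,
                         applies_to = box$applies_to),
    offset = c(row0, col0)
  )
}

#' Extract the central slices of a sequence
#'
#' Keeps the `n` scan planes in the middle of the slice axis: slices
#' `[floor((L - n)/2), floor((L - n)/2) + n)` in 0-based indexing.  Applying
#' this with the same `L` to every modality of a patient selects the same
#' physical planes.
#'
#' @param volume 3D array (slices x rows x cols).
#' @param n number of central slices to keep (default 64).
#' @return 3D array `n x rows x cols`.
#' @export
central_slices <- function(volume, n = 64L) {
  d <- dim(volume)
  if (is.null(d) || length(d) != 3L) stop("central_slices: 'volume' must be 3D")
  n <- as.integer(n)
  if (d[1] < n)
    stop("central_slices: volume has ", d[1], " slices, need >= ", n)
  lo <- floor((d[1] - n) / 2)
  volume[(lo + 1):(lo + n), , , drop = FALSE]
}

# 0-based indices selected by central_slices for a length-L axis
central_slice_index <- function(L, n) {
  lo <- floor((L - n) / 2)
  seq.int(lo, lo + n - 1)
}

.modalities <- c("T1WI", "T2WI", "STIR")

#' Build an aligned multi-modal training dataset
#'
#' Runs the full preprocessing pipeline over a cohort: each modality volume
#' is resampled to the target grid (1 mm, 512 x 512 plane), every retained
#' scan plane is intensity-normalized with [trimmed_minmax_normalize()], the
#' 64 central slices are selected, and each is cropped to 256 x 256 around
#' its (modality-shared) marker box.  Per patient and modality one NIfTI
#' stack of shape `n_slices x crop x crop` is written, plus one rectangle
#' ground-truth mask stack, and a manifest row per (patient, slice) records
#' the three modality paths, the mask path and the crop-local box.
#'
#' Boxes are interpreted on the resampled `plane_size` grid (the grid the
#' clinical annotations are made on), one per retained scan plane; a missing
#' box for a retained slice is an annotation error.
#'
#' @param patients list; each element a list with `id` (string), `volumes`
#'   (named list of [volume_grid()]s with names T1WI, T2WI, STIR), and
#'   `boxes` (data.frame with columns slice, x_min, y_min, x_max, y_max;
#'   `slice` 0-based on the resampled grid).
#' @param out_dir output directory (created if needed).
#' @param target_spacing,plane_size resampling target (defaults 1 mm, 512^2).
#' @param crop crop window side (default 256).
#' @param n_slices central slices per patient (default 64).
#' @param strict if `TRUE` (default) any per-patient failure aborts; if
#'   `FALSE` the offending patient is skipped with a warning.
#' @param compress write gzipped NIfTI stacks (default `TRUE`); `FALSE`
#'   trades disk space for speed on large cohorts.
#' @return A `dataset_manifest`: data.frame of slice records with attributes
#'   `params` (the pipeline parameters) and `path` (the manifest CSV).
#' @export
build_dataset <- function(patients, out_dir,
                          target_spacing = c(1, 1, 1),
                          plane_size = c(512, 512),
                          crop = 256L, n_slices = 64L,
                          strict = TRUE, compress = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  crop <- as.integer(crop); n_slices <- as.integer(n_slices)
  rows <- list()
  for (p in patients) {
    rec <- tryCatch(
      build_one_patient(p, out_dir, target_spacing, plane_size, crop, n_slices,
                        compress),
      error = function(e) e
    )
    if (inherits(rec, "error")) {
      if (strict) stop("build_dataset: patient '", p$id, "': ",
                       conditionMessage(rec), call. = FALSE)
      warning("build_dataset: skipping patient '", p$id, "': ",
              conditionMessage(rec), call. = FALSE)
      next
    }
    rows[[length(rows) + 1]] <- rec
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else empty_manifest()
  params <- list(target_spacing = target_spacing, plane_size = plane_size,
                 crop = crop, n_slices = n_slices,
                 modalities = .modalities,
                 box_dialect = "0-based, half-open, x=col, y=row, crop-local")
  path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  jsonlite::write_json(params, file.path(out_dir, "manifest_params.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(manifest, params = params, path = path,
            class = c("dataset_manifest", class(manifest)))
}

empty_manifest <- function() {
  data.frame(patient = character(), slice = integer(), stack_index = integer(),
             path_T1WI = character(), path_T2WI = character(),
             path_STIR = character(), path_mask = character(),
             x_min = integer(), y_min = integer(),
             x_max = integer(), y_max = integer(),
             split = character(), stringsAsFactors = FALSE)
}

build_one_patient <- function(p, out_dir, target_spacing, plane_size,
                              crop, n_slices, compress = TRUE) {
  ext <- if (compress) ".nii.gz" else ".nii"
  if (is.null(p$id) || !nzchar(p$id)) stop("patient without id")
  missing_mod <- setdiff(.modalities, names(p$volumes))
  if (length(missing_mod))
    stop("missing modalities: ", paste(missing_mod, collapse = ", "))
  # resample without plane standardization; the symmetric crop/pad to
  # plane_size is applied per retained slice below (same arithmetic as
  # crop_pad_plane, without materializing full padded volumes)
  res <- lapply(.modalities, function(m)
    resample_volume(p$volumes[[m]], target_spacing, NULL, "linear"))
  names(res) <- .modalities
  dres <- unique(t(vapply(res, function(v) dim(v$data), c(0, 0, 0))))
  if (nrow(dres) != 1) stop("modalities resample to different grids")
  L <- dres[1, 1]
  if (L < n_slices)
    stop("resampled volume has ", L, " slices, need >= ", n_slices)
  r2 <- crop_pad_ranges(dres[1, 2], plane_size[1])
  r3 <- crop_pad_ranges(dres[1, 3], plane_size[2])
  idx <- central_slice_index(L, n_slices)       # 0-based resampled indices

  boxes <- p$boxes
  need <- setdiff(c("slice", "x_min", "y_min", "x_max", "y_max"), names(boxes))
  if (length(need)) stop("box table missing columns: ", paste(need, collapse = ", "))

  stacks <- lapply(.modalities, function(m) array(0, c(n_slices, crop, crop)))
  names(stacks) <- .modalities
  mask_stack <- array(0, c(n_slices, crop, crop))
  out_rows <- empty_manifest()[0, ]

  recs <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    s <- idx[k]
    b <- boxes[boxes$slice == s, , drop = FALSE]
    if (nrow(b) != 1)
      stop("slice ", s, ": expected exactly one box, found ", nrow(b))
    box <- box_annotation(b$x_min, b$y_min, b$x_max, b$y_max,
                          applies_to = paste0(p$id, "/slice", s))
    shifted <- NULL
    for (m in .modalities) {
      sl <- matrix(0, plane_size[1], plane_size[2])
      sl[r2$dst, r3$dst] <- res[[m]]$data[s + 1, r2$src, r3$src]
      # percentiles over the full standardized plane, affine transform +
      # clip applied on the crop window only (identical result, less work)
      q <- percentile_linear(as.vector(sl), c(0.05, 0.95))
      if (q[2] <= q[1])
        stop("slice ", s, " (", m, "): degenerate intensity distribution")
      cr <- crop_around_box(sl, box, crop)
      nrm <- (cr$data - q[1]) / (q[2] - q[1])
      nrm[nrm < 0] <- 0; nrm[nrm > 1] <- 1
      stacks[[m]][k, , ] <- nrm
      shifted <- cr$box        # identical across modalities (same box)
    }
    mask_stack[k, , ] <- box_to_mask(shifted, c(crop, crop))
    recs[[k]] <- data.frame(patient = p$id, slice = s, stack_index = k,
                            x_min = shifted$x_min, y_min = shifted$y_min,
                            x_max = shifted$x_max, y_max = shifted$y_max,
                            stringsAsFactors = FALSE)
  }

  pdir <- file.path(out_dir, p$id)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (m in .modalities) {
    paths[[m]] <- file.path(pdir, paste0(m, ext))
    write_volume(volume_grid(stacks[[m]], target_spacing,
                             origin_note = paste0(p$id, ":", m)), paths[[m]],
                 datatype = "float")
  }
  mask_path <- file.path(pdir, paste0("mask", ext))
  write_volume(volume_grid(mask_stack, target_spacing,
                           origin_note = paste0(p$id, ":mask")), mask_path,
               datatype = "uint8")

  out <- do.call(rbind, recs)
  out$path_T1WI <- paths$T1WI; out$path_T2WI <- paths$T2WI
  out$path_STIR <- paths$STIR; out$path_mask <- mask_path
  out$split <- ""
  out[, names(empty_manifest())]
}

#' Read a dataset manifest written by [build_dataset()]
#'
#' @param path path to a manifest CSV (its params sidecar is read from the
#'   same directory when present).
#' @return A `dataset_manifest` data.frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  m$split[is.na(m$split)] <- ""
  pj <- file.path(dirname(path), "manifest_params.json")
  params <- if (file.exists(pj)) jsonlite::read_json(pj, simplifyVector = TRUE) else NULL
  structure(m, params = params, path = path,
            class = c("dataset_manifest", class(m)))
}

# Load the slice stack for one manifest row: list of M modality matrices
# (crop x crop) plus the binary mask.  A tiny cache avoids re-reading the
# same NIfTI stack for consecutive rows of one patient.
load_slice <- function(row, cache = NULL) {
  get_stack <- function(path) {
    if (!is.null(cache)) {
      if (!is.null(cache[[path]])) return(cache[[path]])
      v <- read_volume(path, "nifti")$data
      cache[[path]] <- v
      return(v)
    }
    read_volume(path, "nifti")$data
  }
  k <- row$stack_index
  mods <- lapply(c(row$path_T1WI, row$path_T2WI, row$path_STIR),
                 function(p) get_stack(p)[k, , ])
  mask <- get_stack(row$path_mask)[k, , ]
  list(modalities = mods, mask = round(mask))
}
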