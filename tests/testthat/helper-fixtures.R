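# Shared fixtures, built once per test run.

# Small phantom cohort pushed through the full preprocessing pipeline.
# Native geometry is deliberately small (the resampled grid is still the
# standard 1 mm / 512 plane / 256 crop); regenerated lazily and cached.
tiny_cohort_env <- new.env()
tiny_dataset <- function(n_subjects = 2, seed = 11) {
  key <- paste0("ds_", n_subjects, "_", seed)
  if (is.null(tiny_cohort_env[[key]])) {
    pp <- phantom_params(n_subjects = n_subjects,
                         volume_shape = c(10, 80, 80),
                         spacing = c(8, 3, 3), seed = seed)
    coh <- generate_cohort(pp, file.path(tempdir(), paste0("coh", key)))
    man <- build_dataset(load_cohort(coh),
                         file.path(tempdir(), paste0("ds", key)),
                         compress = FALSE)
    tiny_cohort_env[[key]] <- list(params = pp, cohort = coh, manifest = man)
  }
  tiny_cohort_env[[key]]
}

# n preprocessed (modality-stack, mask) training samples from the fixture
tiny_slices <- function(n = 8, n_subjects = 2, seed = 11) {
  ds <- tiny_dataset(n_subjects, seed)
  man <- ds$manifest
  rows <- man[round(seq(1, nrow(man), length.out = n)), ]
  sarcoseg:::load_manifest_slices(rows)
}

# Fake manifest with patients only (for split logic tests; no files needed)
fake_manifest <- function(n_patients, slices_per_patient = 4) {
  ids <- sprintf("p%03d", seq_len(n_patients))
  m <- expand.grid(slice = seq_len(slices_per_patient) - 1L, patient = ids,
                   stringsAsFactors = FALSE)[, c("patient", "slice")]
  m$split <- ""
  m
}

# Minimal explicit-VR little-endian DICOM slice writer (synthetic headers),
# independent of the package's reader.
write_synth_dicom <- function(path, rows, cols, z, pixel_spacing = c(1, 1),
                              data = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  elem_str <- function(group, el, vr, s) {
    if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
    u16(group); u16(el); writeChar(vr, con, eos = NULL); u16(nchar(s))
    writeChar(s, con, eos = NULL)
  }
  elem_us <- function(group, el, v) {
    u16(group); u16(el); writeChar("US", con, eos = NULL); u16(2); u16(v)
  }
  elem_str(0x0018, 0x0050, "DS", "1")
  elem_str(0x0020, 0x0032, "DS", sprintf("0\\0\\%g", z))
  elem_us(0x0028, 0x0010, rows)
  elem_us(0x0028, 0x0011, cols)
  elem_str(0x0028, 0x0030, "DS",
           sprintf("%g\\%g", pixel_spacing[1], pixel_spacing[2]))
  elem_us(0x0028, 0x0100, 16)
  elem_us(0x0028, 0x0103, 0)
  if (is.null(data)) data <- matrix(0L, rows, cols)
  px <- as.integer(t(data))            # DICOM pixel order is row-major
  u16(0x7fe0); u16(0x0010); writeChar("OW", con, eos = NULL); u16(0)
  writeBin(as.integer(2 * length(px)), con, size = 4, endian = "little")
  writeBin(px, con, size = 2, endian = "little")
  invisible(path)
}

write_synth_series <- function(dir, zs, rows = 4, cols = 4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(zs)) {
    data <- matrix(as.integer(i * 100 + seq_len(rows * cols)), rows, cols)
    write_synth_dicom(file.path(dir, sprintf("slice%02d.dcm", i)),
                      rows, cols, zs[i], data = data)
  }
  dir
}
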