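# Minimal DICOM series reader: uncompressed explicit-VR little-endian,
# single-frame MR-style slices.  Covers exactly the header subset the
# pipeline needs (geometry + raw pixels); anything else in a file is walked
# over and ignored.  Compressed transfer syntaxes and implicit VR are out of
# scope and rejected up front.

# VRs whose explicit length field is 4 bytes after 2 reserved bytes
.dcm_long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

.dcm_u16 <- function(raw, off) {
  as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
}
.dcm_u32 <- function(raw, off) {
  as.numeric(raw[off + 1]) + 256 * as.numeric(raw[off + 2]) +
    65536 * as.numeric(raw[off + 3]) + 16777216 * as.numeric(raw[off + 4])
}

# Parse one DICOM file; returns the tag subset used by read_dicom_series.
parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    stop("dicom: missing DICM magic in ", path)
  off <- 132L
  out <- list()
  n <- length(raw)
  while (off + 8 <= n) {
    group <- .dcm_u16(raw, off); elem <- .dcm_u16(raw, off + 2L)
    vr <- rawToChar(raw[(off + 5L):(off + 6L)])
    if (grepl("^[A-Z]{2}$", vr)) {
      if (vr %in% .dcm_long_vrs) {
        len <- .dcm_u32(raw, off + 8L); hdr <- 12L
      } else {
        len <- .dcm_u16(raw, off + 6L); hdr <- 8L
      }
    } else stop("dicom: implicit-VR or corrupt element in ", path)
    if (len == 4294967295) stop("dicom: undefined-length element unsupported in ", path)
    body_off <- off + hdr
    if (body_off + len > n) stop("dicom: truncated element in ", path)
    key <- sprintf("%04x,%04x", group, elem)
    body <- raw[seq_len(len) + body_off]
    if (key %in% c("0028,0010", "0028,0011", "0028,0100", "0028,0103")) {
      out[[key]] <- .dcm_u16(body, 0L)
    } else if (key %in% c("0028,0030", "0018,0050", "0020,0032", "0020,1041")) {
      out[[key]] <- as.numeric(strsplit(trimws(rawToChar(body)), "\\\\")[[1]])
    } else if (key == "7fe0,0010") {
      out[["pixeldata"]] <- body
      out[["pixelvr"]] <- vr
    }
    off <- body_off + len
  }
  out
}

# Read every *.dcm file in `dir` as one series and assemble a volume_grid.
read_dicom_series <- function(dir) {
  if (!dir.exists(dir)) stop("read_volume: no such directory: ", dir)
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) < 2) stop("read_volume: need >= 2 DICOM slices in ", dir)
  hdrs <- lapply(files, parse_dicom_file)

  need <- c("0028,0010", "0028,0011", "0028,0030", "0020,0032")
  for (i in seq_along(hdrs))
    for (k in need)
      if (is.null(hdrs[[i]][[k]]))
        stop("dicom: tag (", k, ") missing in ", files[i])

  rows <- vapply(hdrs, `[[`, 0L, "0028,0010")
  cols <- vapply(hdrs, `[[`, 0L, "0028,0011")
  if (length(unique(rows)) > 1 || length(unique(cols)) > 1)
    stop("dicom: inconsistent matrix sizes across series")
  ps <- hdrs[[1]][["0028,0030"]]

  zpos <- vapply(hdrs, function(h) h[["0020,0032"]][3], 0)
  ord <- order(zpos)
  files <- files[ord]; hdrs <- hdrs[ord]; zpos <- zpos[ord]
  gaps <- diff(zpos)
  if (any(gaps <= 0))
    stop("dicom: duplicate slice positions in series")
  if ((max(gaps) - min(gaps)) > 1e-3 * median(gaps)) {
    bad <- which(abs(gaps - median(gaps)) > 1e-3 * median(gaps))
    stop("dicom: non-uniform slice spacing (missing slice?) between ",
         paste(sprintf("'%s' and '%s' (gap %.4g mm)",
                       basename(files[bad]), basename(files[bad + 1]),
                       gaps[bad]), collapse = "; "))
  }

  slices <- lapply(seq_along(files), function(i) {
    h <- hdrs[[i]]
    bits <- h[["0028,0100"]] %||% 16L
    if (bits != 16L) stop("dicom: only 16-bit pixel data supported: ", files[i])
    signed <- isTRUE(h[["0028,0103"]] == 1L)
    px <- readBin(h[["pixeldata"]], "integer", n = length(h[["pixeldata"]]) / 2,
                  size = 2, signed = signed, endian = "little")
    if (length(px) != rows[1] * cols[1])
      stop("dicom: pixel count mismatch in ", files[i])
    t(matrix(px, nrow = cols[1]))   # DICOM pixel order is row-major
  })
  data <- array(0, dim = c(length(slices), rows[1], cols[1]))
  for (i in seq_along(slices)) data[i, , ] <- slices[[i]]
  volume_grid(data, spacing = c(median(gaps), ps[1], ps[2]),
              origin_note = paste0("dicom:", dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
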