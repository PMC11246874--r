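test_that("trimmed normalization pins the 5th/95th percentile bounds", {
  # explicit 100-value list: brute-force the linear-interpolation percentile
  x <- matrix(0:99, 10, 10)
  brute <- function(v, p) {           # independent of the package path
    v <- sort(v); n <- length(v); h <- (n - 1) * p + 1
    v[floor(h)] + (h - floor(h)) * (v[ceiling(h)] - v[floor(h)])
  }
  expect_equal(brute(0:99, 0.05), 4.95)
  expect_equal(brute(0:99, 0.95), 94.05)
  r <- trimmed_minmax_normalize(x)
  expect_equal(r$record$s_min, 4.95)
  expect_equal(r$record$s_max, 94.05)
  expect_equal(r$data[x == 50][1], (50 - 4.95) / (94.05 - 4.95))
})

test_that("percentile helper agrees with quantile(type = 7)", {
  set.seed(10)
  for (i in 1:25) {
    v <- rnorm(sample(10:500, 1))
    p <- sort(runif(2))
    expect_equal(sarcoseg:::percentile_linear(v, p),
                 unname(quantile(v, p, type = 7)), tolerance = 1e-12)
  }
})

test_that("normalization clips to [0,1] and hits both endpoints with heavy
           tails", {
  set.seed(11)
  x <- matrix(rnorm(400), 20, 20)
  r <- trimmed_minmax_normalize(x)
  expect_true(all(r$data >= 0 & r$data <= 1))
  expect_equal(min(r$data), 0)   # >= 5% of pixels at each tail get clipped
  expect_equal(max(r$data), 1)
  expect_error(trimmed_minmax_normalize(matrix(7, 5, 5)), "degenerate")
})

test_that("normalization is invariant under positive affine rescaling", {
  set.seed(12)
  for (i in 1:20) {
    x <- matrix(rnorm(256, sd = runif(1, 0.1, 50)), 16, 16)
    a <- runif(1, 0.01, 100); b <- runif(1, -500, 500)
    r1 <- trimmed_minmax_normalize(x)$data
    r2 <- trimmed_minmax_normalize(a * x + b)$data
    expect_equal(r1, r2, tolerance = 1e-6)
  }
})

test_that("box_to_mask fills exactly the half-open rectangle", {
  full <- box_to_mask(box_annotation(0, 0, 512, 512), c(512, 512))
  expect_true(all(full == 1))
  m <- box_to_mask(box_annotation(10, 20, 12, 25), c(64, 64))
  expect_equal(sum(m), 2 * 5)
  set.seed(13)
  for (i in 1:20) {
    x0 <- sample(0:20, 1); x1 <- x0 + sample(1:10, 1)
    y0 <- sample(0:20, 1); y1 <- y0 + sample(1:10, 1)
    m <- box_to_mask(box_annotation(x0, y0, x1, y1), c(32, 32))
    ref <- matrix(0L, 32, 32)
    for (r in 1:32) for (c in 1:32)
      if (r - 1 >= y0 && r - 1 < y1 && c - 1 >= x0 && c - 1 < x1)
        ref[r, c] <- 1L
    expect_identical(m, ref)
  }
  expect_error(box_to_mask(box_annotation(0, 0, 40, 40), c(32, 32)), "exceeds")
  expect_error(box_annotation(5, 5, 5, 9), "x_min < x_max")
})

test_that("crop_around_box centres, clamps and preserves box content", {
  img <- matrix(rnorm(512 * 512), 512, 512)
  cr <- crop_around_box(img, box_annotation(200, 200, 312, 312), 256)
  expect_equal(cr$offset, c(128, 128))
  b <- cr$box
  expect_equal(c(b$x_min, b$y_min, b$x_max, b$y_max), c(72, 72, 184, 184))
  expect_identical(cr$data[(b$y_min + 1):b$y_max, (b$x_min + 1):b$x_max],
                   img[201:312, 201:312])

  corner <- crop_around_box(img, box_annotation(0, 0, 50, 50), 256)
  expect_equal(corner$offset, c(0, 0))
  expect_equal(corner$box$x_min, 0)
  expect_identical(corner$data, img[1:256, 1:256])

  expect_error(crop_around_box(img, box_annotation(0, 0, 300, 40), 256),
               "larger than crop")
})

test_that("crop preserves tumor pixels for random valid boxes", {
  set.seed(14)
  img <- matrix(rnorm(300 * 300), 300, 300)
  for (i in 1:50) {
    w <- sample(1:128, 1); h <- sample(1:128, 1)
    x0 <- sample(0:(300 - w), 1); y0 <- sample(0:(300 - h), 1)
    box <- box_annotation(x0, y0, x0 + w, y0 + h)
    cr <- crop_around_box(img, box, 128)
    expect_true(all(cr$offset >= 0) && all(cr$offset + 128 <= 300))
    b <- cr$box
    expect_identical(cr$data[(b$y_min + 1):b$y_max, (b$x_min + 1):b$x_max],
                     img[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w)])
  }
})

test_that("central_slices keeps the middle band", {
  v <- array(seq_len(64 * 2 * 2), c(64, 2, 2))
  expect_identical(central_slices(v, 64), v)
  v81 <- array(seq_len(81 * 2 * 2), c(81, 2, 2))
  out <- central_slices(v81, 64)
  expect_identical(out, v81[9:72, , , drop = FALSE])  # 0-based [8, 72)
  expect_error(central_slices(array(0, c(10, 2, 2)), 64), "slices")
})

test_that("build_dataset produces an aligned manifest with 64 slices per
           patient and shared masks", {
  ds <- tiny_dataset(2)
  man <- ds$manifest
  expect_equal(nrow(man), 2 * 64)
  expect_setequal(unique(man$patient), c("subj001", "subj002"))
  expect_true(all(file.exists(man$path_T1WI)))
  expect_true(all(man$x_max - man$x_min > 0))

  # cross-modality alignment: identical shapes, identical rectangle mask
  row <- man[40, ]
  sl <- sarcoseg:::load_slice(row)
  expect_equal(length(sl$modalities), 3)
  for (m in sl$modalities) expect_equal(dim(m), c(256, 256))
  bx <- box_annotation(row$x_min, row$y_min, row$x_max, row$y_max)
  expect_equal(sl$mask, box_to_mask(bx, c(256, 256)) * 1.0)
  expect_true(all(vapply(sl$modalities, function(m)
    min(m) >= 0 && max(m) <= 1, TRUE)))

  # manifest round-trips through its CSV
  back <- read_manifest(attr(man, "path"))
  expect_equal(nrow(back), nrow(man))
  expect_equal(back$x_min, man$x_min)
})

test_that("build_dataset reports missing modalities with the patient id", {
  ds <- tiny_dataset(2)
  pats <- load_cohort(ds$cohort)
  pats[[1]]$volumes$STIR <- NULL
  expect_error(build_dataset(pats[1], tempfile()), "subj001")
  expect_error(build_dataset(pats[1], tempfile()), "STIR")
  expect_warning(
    man <- build_dataset(pats, tempfile(), strict = FALSE, compress = FALSE),
    "skipping")
  expect_equal(unique(man$patient), "subj002")
})
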