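gauss_raster <- function(n, cx, cy, sx, sy, amp = 1000) {
  x <- 0:(n - 1); y <- 0:(n - 1)
  amp * exp(-outer((y - cy)^2 / (2 * sy^2), (x - cx)^2 / (2 * sx^2), "+"))
}

test_that("mask_area is pixel count times squared pixel size", {
  m <- new_mask(matrix(c(rep(TRUE, 100), rep(FALSE, 44)), 12, 12))
  expect_equal(mask_area(m, 0.5), 25)
  expect_equal(mask_area(new_mask(matrix(FALSE, 4, 4)), 0.5), 0)
  set.seed(1)
  r <- matrix(runif(256) < 0.4, 16, 16)
  expect_equal(mask_area(new_mask(r), 0.5), sum(r) * 0.25)
})

test_that("intensity-weighted ellipse axes match analytic Gaussian spots", {
  # single pixel: point mass, zero axes
  m1 <- matrix(FALSE, 9, 9); m1[5, 5] <- TRUE
  mm <- intensity_moments(matrix(1, 9, 9), new_mask(m1), 0.5)
  expect_equal(mm$minor_axis, 0)
  expect_equal(mm$major_axis, 0)

  # isotropic sigma = 2 px, pixel 0.5 um: axes = 4*2*0.5 = 4 um
  g <- gauss_raster(41, 20, 20, 2, 2)
  mi <- intensity_moments(g, full_mask(41), 0.5)
  expect_equal(mi$minor_axis, 4, tolerance = 0.05)
  expect_equal(mi$major_axis, 4, tolerance = 0.05)

  # anisotropic sigma_x = 4, sigma_y = 1: axis ratio ~ 4
  ga <- gauss_raster(61, 30, 30, 4, 1)
  ma <- intensity_moments(ga, full_mask(61), 0.5)
  expect_equal(ma$major_axis / ma$minor_axis, 4, tolerance = 0.10)

  # zero in-mask intensity: flagged invalid, no exception
  z <- intensity_moments(matrix(0, 5, 5), full_mask(5), 0.5)
  expect_false(z$valid)
  expect_true(is.na(z$minor_axis))
})

test_that("axes agree with a dense eigendecomposition oracle", {
  set.seed(99)
  for (i in 1:50) {
    ch <- matrix(runif(100, 0.1, 10), 10, 10)
    mask <- matrix(runif(100) < 0.6, 10, 10)
    if (sum(mask) < 3) next
    m <- intensity_moments(ch, new_mask(mask), 0.5)
    idx <- which(mask)
    w <- ch[idx]
    yy <- (idx - 1) %% 10; xx <- (idx - 1) %/% 10
    cx <- sum(w * xx) / sum(w); cy <- sum(w * yy) / sum(w)
    cov <- matrix(c(sum(w * (xx - cx)^2), sum(w * (xx - cx) * (yy - cy)),
                    sum(w * (xx - cx) * (yy - cy)), sum(w * (yy - cy)^2)),
                  2, 2) / sum(w)
    ev <- eigen(cov, symmetric = TRUE)$values
    expect_equal(m$major_axis, 4 * sqrt(ev[1]) * 0.5, tolerance = 1e-9)
    expect_equal(m$minor_axis, 4 * sqrt(max(ev[2], 0)) * 0.5,
                 tolerance = 1e-9)
  }
})

test_that("aspect ratio distinguishes disks from bars", {
  d <- disk_raster(41, 20, 20, 14)
  expect_gte(aspect_ratio(new_mask(d$truth)), 0.95)
  bar <- matrix(FALSE, 25, 25); bar[12, 3:22] <- TRUE
  expect_lte(aspect_ratio(new_mask(bar)), 0.15)
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(aspect_ratio(new_mask(single)), 1)
})

test_that("gradient RMS is zero on constants, decreases under blur, matches a convolution oracle", {
  expect_equal(gradient_rms(matrix(5, 10, 10), full_mask(10)), 0)

  d <- disk_raster(41, 20, 20, 10, amp = 200)$raster
  blurred <- EBImage::gblur(d, sigma = 3)
  m <- full_mask(41)
  expect_lt(gradient_rms(blurred, m), gradient_rms(d, m))

  # checkerboard vs a direct edge-replicated Sobel convolution
  cb <- matrix(rep(c(0, 1), 41)[1:64], 8, 8) * 10
  pad <- rbind(cb[1, ], cb, cb[8, ]); pad <- cbind(pad[, 1], pad, pad[, 8])
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # d/dx (columns)
  ky <- t(kx)
  conv <- function(k) {
    out <- matrix(0, 8, 8)
    for (i in 1:8) for (j in 1:8) {
      out[i, j] <- sum(pad[i:(i + 2), j:(j + 2)] * k)
    }
    out
  }
  mag <- sqrt(conv(kx)^2 + conv(ky)^2)
  expect_equal(gradient_rms(cb, full_mask(8)), sqrt(mean(mag^2)),
               tolerance = 1e-9)
})

test_that("brightfield contrast is brightness-invariant", {
  expect_equal(bf_contrast(matrix(3, 6, 6), full_mask(6)), 0)
  set.seed(3)
  ch <- matrix(runif(100, 50, 150), 10, 10)
  m <- new_mask(matrix(runif(100) < 0.8, 10, 10))
  expect_equal(bf_contrast(ch, m), bf_contrast(ch * 10, m), tolerance = 1e-12)
})

test_that("bright detail intensity isolates small bright spots", {
  m <- full_mask(21)
  expect_equal(bright_detail_intensity(matrix(8, 21, 21), m, 3), 0)
  spot <- matrix(0, 21, 21); spot[11, 11] <- 500
  expect_equal(bright_detail_intensity(spot, m, 3), 500, tolerance = 1e-9)
  # a wide smooth Gaussian passes through the opening almost unchanged
  wide <- gauss_raster(41, 20, 20, 8, 8, amp = 100)
  bdi <- bright_detail_intensity(wide, full_mask(41), 3)
  expect_lt(bdi, 0.05 * sum(wide))
})

test_that("PulSA triplet follows the projected-pulse definition", {
  # single bright column
  one <- matrix(0, 10, 10); one[, 4] <- 50
  p <- pulsa_triplet(one, full_mask(10), 0.5)
  expect_equal(p$width, 0.5)
  expect_equal(p$height, 500)
  expect_equal(p$area, 500)

  # two separated narrow puncta: only above-half-max columns count
  two <- matrix(0, 20, 20); two[10, 5] <- 100; two[10, 15] <- 100
  p2 <- pulsa_triplet(two, full_mask(20), 0.5)
  expect_equal(p2$width, 2 * 0.5)   # the two peak columns, not the span

  # direct profile oracle on a random raster
  set.seed(8)
  ch <- matrix(runif(144, 0, 9), 12, 12)
  mask <- new_mask(matrix(runif(144) < 0.7, 12, 12))
  prof <- colSums(ch * mask$raster)
  po <- pulsa_triplet(ch, mask, 0.5)
  expect_equal(po$area, sum(prof))
  expect_equal(po$height, max(prof))
  expect_equal(po$width, sum(prof >= max(prof) / 2) * 0.5)
})

test_that("features are translation invariant and intensity-scale equivariant", {
  # noise-free analytic cell so constant padding is an exact translation
  set.seed(21)
  golgi <- Reduce(`+`, lapply(1:5, function(i) {
    gauss_raster(64, 26 + runif(1, -4, 4), 30 + runif(1, -4, 4), 1.4, 1.4,
                 amp = runif(1, 300, 600))
  }))
  bf <- 100 + 300 * disk_raster(64, 30, 30, 15)$truth
  dna <- gauss_raster(64, 30, 30, 4, 4, amp = 250) +
    gauss_raster(64, 28, 32, 1.2, 1.2, amp = 400)
  base <- cell_record("b", list(BF = bf * 1.0, GOLGI = golgi, DNA = dna), 0.5)
  shift <- function(m, dy, dx) {
    out <- matrix(min(m), nrow(m), ncol(m))
    out[(1 + dy):nrow(m), (1 + dx):ncol(m)] <-
      m[1:(nrow(m) - dy), 1:(ncol(m) - dx)]
    out
  }
  shifted <- cell_record("s", lapply(base$channels, shift, dy = 3, dx = 2),
                         base$pixel_size)
  f0 <- compute_features(list(base))
  f1 <- compute_features(list(shifted))
  for (col in c("golgi_t60_area", "golgi_t60_minor_axis_intensity",
                "bf_aspect_ratio", "dna_bdi_r3")) {
    expect_equal(f1[[col]], f0[[col]], tolerance = 1e-3, label = col)
  }
  # intensity scaling: equivariant and invariant features
  g <- base$channels$GOLGI
  obj <- object_mask(g, keep = "all")
  t60 <- threshold_mask(obj, g, 60)
  m0 <- intensity_moments(g, t60, 0.5)
  m2 <- intensity_moments(3 * g, t60, 0.5)
  expect_equal(m2$total_intensity, 3 * m0$total_intensity)
  expect_equal(m2$minor_axis, m0$minor_axis, tolerance = 1e-12)
  p0 <- pulsa_triplet(g, obj, 0.5); p2 <- pulsa_triplet(3 * g, obj, 0.5)
  expect_equal(p2$area, 3 * p0$area)
  expect_equal(p2$height, 3 * p0$height)
})

test_that("the feature table is order-stable and self-consistent", {
  pop <- sample_population(get_preset("exemplars"), n = 6, seed = 31)
  ft <- compute_features(pop$cells)
  expect_equal(nrow(ft), 6)
  expect_identical(ft$cell_id, pop$truth$cell_id)
  expect_true(all(is.finite(as.matrix(ft[, c("golgi_t60_area", "bf_area",
                                             "dna_total_intensity")]))))

  # permuting input cells permutes rows identically
  perm <- c(4, 1, 6, 2, 5, 3)
  ftp <- compute_features(pop$cells[perm])
  expect_equal(as.data.frame(ftp), as.data.frame(ft[perm, ]),
               ignore_attr = TRUE)

  # standalone ops reproduce table values
  cell <- pop$cells[[3]]
  g <- cell$channels$GOLGI
  t60 <- threshold_mask(object_mask(g, keep = "all"), g, 60)
  expect_equal(ft$golgi_t60_area[3], mask_area(t60, cell$pixel_size))
  expect_equal(ft$golgi_t60_minor_axis_intensity[3],
               intensity_moments(g, t60, cell$pixel_size)$minor_axis)
  bf <- cell$channels$BF
  expect_equal(ft$bf_gradient_rms[3], gradient_rms(bf, object_mask(bf)))
})
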