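test_that("Otsu splits a two-level image between the levels", {
  px <- matrix(c(rep(10L, 128L), rep(200L, 128L)), 16L, 16L)
  out <- binarize_otsu(px)
  expect_gt(out$threshold, 10)
  expect_lt(out$threshold, 200)
  expect_identical(out$mask, px > 10L)
  expect_error(binarize_otsu(matrix(5L, 8L, 8L)), "constant")
})

test_that("Otsu equals the exhaustive between-class-variance argmax", {
  set.seed(31)
  for (i in 1:10) {
    px <- matrix(sample.int(256L, 1024L, replace = TRUE) - 1L, 32L, 32L)
    expect_equal(binarize_otsu(px)$threshold, oracle_otsu_threshold(px))
  }
})

test_that("Otsu threshold is shift-equivariant", {
  set.seed(32)
  px <- matrix(sample.int(200L, 1024L, replace = TRUE), 32L, 32L)
  t0 <- binarize_otsu(px)$threshold
  for (k in c(-30L, 17L, 1000L))
    expect_equal(binarize_otsu(px + k)$threshold, t0 + k)
})

test_that("contour extraction counts components and measures them", {
  m <- matrix(FALSE, 64L, 64L)
  m[10:19, 10:19] <- TRUE                      # filled 10x10 square
  cts <- extract_contours(m, 1)
  expect_length(cts, 1L)
  expect_equal(cts[[1]]$area_px, 100L)
  expect_equal(cts[[1]]$area_cm2, 100 * 0.01)

  m[40:49, 40:49] <- TRUE                      # second disjoint square
  expect_length(extract_contours(m, 1), 2L)
  expect_length(extract_contours(matrix(FALSE, 8L, 8L), 1), 0L)
})

test_that("contour components are 8-connected and holes are filled", {
  m <- matrix(FALSE, 16L, 16L)
  m[3, 3] <- TRUE; m[4, 4] <- TRUE             # diagonal touch: one contour
  expect_length(extract_contours(m, 1), 1L)

  ring <- disk_mask(41L, 41L, c(21, 21), 12) & !disk_mask(41L, 41L, c(21, 21), 6)
  cts <- extract_contours(ring, 1)
  expect_length(cts, 1L)
  expect_equal(cts[[1]]$area_px, sum(disk_mask(41L, 41L, c(21, 21), 12)))
})

test_that("disk contour area and Feret match brute-force geometry", {
  m <- disk_mask(101L, 101L, c(51, 51), 40)
  ct <- extract_contours(m, 1)[[1]]
  expect_lt(abs(ct$area_px - pi * 40^2) / (pi * 40^2), 0.02)
  feret <- max_feret_diameter(ct) * 10          # back to px (spacing 1 mm)
  expect_lt(abs(feret - 80), 2)
  expect_equal(feret, oracle_max_pairwise(ct$boundary_px))
})

test_that("max Feret equals the exhaustive pairwise maximum on random blobs", {
  set.seed(33)
  for (i in 1:5) {
    ctr <- c(26, 26) + sample(-3:3, 2L, replace = TRUE)
    blob <- disk_mask(51L, 51L, ctr, runif(1, 6, 14)) |
      disk_mask(51L, 51L, ctr + sample(-5:5, 2L, replace = TRUE),
                runif(1, 4, 10))
    cts <- extract_contours(blob, 1)
    ct <- cts[[which.max(vapply(cts, function(x) x$area_px, numeric(1)))]]
    expect_equal(max_feret_diameter(ct) * 10,
                 oracle_max_pairwise(ct$boundary_px))
  }
  # axis-aligned 30x40 rectangle: diagonal via Pythagoras
  m <- matrix(FALSE, 64L, 64L)
  m[11:40, 11:50] <- TRUE
  expect_equal(max_feret_diameter(extract_contours(m, 1)[[1]]) * 10,
               sqrt(29^2 + 39^2))
  # degenerate single pixel
  m1 <- matrix(FALSE, 8L, 8L); m1[4, 4] <- TRUE
  expect_equal(max_feret_diameter(extract_contours(m1, 1)[[1]]), 0)
})

test_that("the prior filter applies both conditions with the stated bounds", {
  mk <- function(size_cm, area_cm2) {
    ct <- structure(list(max_size_cm = size_cm, area_cm2 = area_cm2),
                    class = "ct_contour")
    ct
  }
  b <- prior_bounds()
  keep <- function(ct) length(filter_candidates(list(ct), b)) == 1L
  expect_true(keep(mk(3, 4)))                  # inside both windows
  expect_false(keep(mk(1.5, 4)))               # below size floor
  expect_false(keep(mk(2, 4)))                 # strict low: 2 cm excluded
  expect_true(keep(mk(5, 4)))                  # inclusive high
  expect_false(keep(mk(5.01, 4)))
  expect_false(keep(mk(3, 0.8)))               # vessel-area floor
  expect_false(keep(mk(3, 1)))                 # strict low on area
  expect_true(keep(mk(3, 6.25 * pi)))          # inclusive area cap
  expect_false(keep(mk(3, 6.25 * pi + 0.01)))
})

test_that("the prior filter is a pure, idempotent, order-preserving filter", {
  set.seed(34)
  cts <- lapply(1:20, function(i)
    structure(list(max_size_cm = runif(1, 0, 8),
                   area_cm2 = runif(1, 0, 25)), class = "ct_contour"))
  out <- filter_candidates(cts)
  expect_true(all(vapply(out, function(ct)
    any(vapply(cts, identical, logical(1), ct)), logical(1))))
  expect_identical(filter_candidates(out), out)  # idempotent
  idx <- vapply(out, function(o)
    which(vapply(cts, identical, logical(1), o))[1], integer(1))
  expect_true(all(diff(idx) > 0))                # order preserved
})

test_that("centroids match symmetry and exhaustive pixel moments", {
  sq <- matrix(FALSE, 32L, 32L); sq[11:21, 11:21] <- TRUE
  expect_equal(unname(contour_centroid(contour_from_mask(sq))), c(16, 16))

  dk <- disk_mask(201L, 301L, c(100, 200), 30)
  expect_equal(unname(contour_centroid(contour_from_mask(dk))), c(100, 200),
               tolerance = 1e-6)

  L <- matrix(FALSE, 40L, 40L)                  # L-shape
  L[5:30, 5:12] <- TRUE; L[24:30, 5:28] <- TRUE
  ct <- contour_from_mask(L)
  pix <- which(L, arr.ind = TRUE)
  expect_equal(unname(contour_centroid(ct)),
               c(mean(pix[, 1]), mean(pix[, 2])))
  # centroid lies inside the bounding box of the region
  expect_true(contour_centroid(ct)[1] >= min(pix[, 1]) &&
              contour_centroid(ct)[1] <= max(pix[, 1]))
})
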