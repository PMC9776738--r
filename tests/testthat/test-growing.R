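test_that("initial threshold is the stated fraction of the intensity range", {
  expect_equal(compute_initial_threshold(matrix(c(0L, 250L), 2L, 2L)), 50)
  expect_equal(compute_initial_threshold(matrix(c(100L, 1100L), 4L, 4L)), 200)
  expect_warning(t0 <- compute_initial_threshold(matrix(7L, 4L, 4L)),
                 "constant")
  expect_equal(t0, 0)
})

test_that("region growing matches the fixpoint flood-fill oracle", {
  set.seed(51)
  for (i in 1:20) {
    img <- matrix(sample.int(64L, 32L * 32L, replace = TRUE), 32L, 32L)
    seed <- c(sample.int(32L, 1L), sample.int(32L, 1L))
    thr <- runif(1, 0, 20)
    conn <- sample(c(4L, 8L), 1L)
    rg <- grow_region(img, seed, thr, conn)
    expect_identical(rg$mask, oracle_flood_fill(img, seed, thr, conn))
  }
})

test_that("growing covers a uniform image and honours degenerate cases", {
  img <- matrix(42L, 20L, 30L)
  expect_equal(grow_region(img, c(5L, 5L), 0)$area_px, 600L)
  img2 <- matrix(0L, 10L, 10L); img2[5, 5] <- 99L
  rg <- grow_region(img2, c(5L, 5L), 0)       # unique seed intensity
  expect_equal(rg$area_px, 1L)
  expect_true(rg$mask[5, 5])
  expect_error(grow_region(img2, c(0L, 5L), 1), "bounds")
})

test_that("a contrasted disk is recovered exactly and the base stays fixed", {
  img <- matrix(50L, 64L, 64L)
  dk <- disk_mask(64L, 64L, c(32, 32), 12)
  img[dk] <- 200L
  rg <- grow_region(img, c(32L, 32L), 30, spacing_mm = 1)
  expect_identical(rg$mask, dk)
  expect_equal(rg$base_intensity, 200L)
  expect_equal(rg$area_px, sum(dk))
  # every mask pixel satisfies the similarity test against the seed
  expect_true(all(abs(img[rg$mask] - rg$base_intensity) <= rg$threshold))
  expect_lt(abs(rg$max_size_cm * 10 - 24), 2)
})

test_that("the grown mask is monotone in the threshold", {
  set.seed(52)
  img <- matrix(sample.int(100L, 32L * 32L, replace = TRUE), 32L, 32L)
  seed <- c(16L, 16L)
  prev <- grow_region(img, seed, 0)$mask
  for (thr in c(5, 12, 25, 60, 99)) {
    cur <- grow_region(img, seed, thr)$mask
    expect_true(all(cur[prev]))               # superset of the smaller
    prev <- cur
  }
})

test_that("threshold update uses the circle of radius L = max dist + margin", {
  img <- matrix(50L, 101L, 101L)
  dk <- disk_mask(101L, 101L, c(51, 51), 10)
  img[dk] <- 200L
  rg <- grow_region(img, c(51L, 51L), 30)
  thr <- update_threshold(img, c(51L, 51L), rg, frac = 0.2, margin_px = 6)
  expect_equal(attr(thr, "radius_px"), 10 + 6)
  expect_equal(as.numeric(thr), 0.2 * 150)    # 50..200 inside the circle

  # ROI membership equals the exhaustive per-pixel distance check
  L <- attr(thr, "radius_px")
  img2 <- matrix(seq(40L, 240L, length.out = 101L * 101L), 101L, 101L)
  storage.mode(img2) <- "integer"
  d <- sqrt(outer((1:101 - 51)^2, (1:101 - 51)^2, "+"))
  vals <- img2[d <= L]
  thr2 <- update_threshold(img2, c(51L, 51L), rg, 0.2, 6)
  expect_equal(as.numeric(thr2), 0.2 * (max(vals) - min(vals)))
})

test_that("an empty previous region falls back to the initial threshold", {
  img <- matrix(sample.int(100L, 64L), 8L, 8L)
  empty <- structure(list(area_px = 0L,
                          boundary_px = matrix(numeric(0), 0L, 2L)),
                     class = "grown_region")
  thr <- update_threshold(img, c(4L, 4L), empty)
  expect_true(isTRUE(attr(thr, "fallback")))
  expect_equal(as.numeric(thr), compute_initial_threshold(img))
})

test_that("credibility follows the predicted size or the circle area", {
  dk <- disk_mask(64L, 64L, c(32, 32), 10)
  ct <- contour_from_mask(dk, spacing_mm = 1)
  img <- matrix(0L, 64L, 64L); img[dk] <- 100L
  rg <- grow_region(img, c(32L, 32L), 50, spacing_mm = 1)

  p_ok <- growth_params(predicted_max_size_cm = 5)
  p_small <- growth_params(predicted_max_size_cm = 1.5)
  expect_true(check_credible(rg, ct, c(32L, 32L), p_ok))
  expect_false(check_credible(rg, ct, c(32L, 32L), p_small))

  # circle mode: a region equal to the filled contour is credible
  expect_true(check_credible(rg, ct, c(32L, 32L), growth_params()))
  # a region clearly beyond the circumscribed circle is abnormal
  big <- grow_region(matrix(0L, 64L, 64L), c(32L, 32L), 1)
  expect_false(check_credible(big, ct, c(32L, 32L), growth_params()))
})

test_that("regions equal to star-convex fixtures pass circle-mode checks", {
  set.seed(53)
  for (i in 1:10) {
    # random star-convex blob: radius varies smoothly with angle
    ctr <- c(41, 41)
    nharm <- 3L
    a <- runif(nharm, -0.25, 0.25); b <- runif(nharm, -0.25, 0.25)
    base_r <- runif(1, 10, 22)
    rg <- matrix(seq_len(81L), 81L, 81L)
    cg <- matrix(seq_len(81L), 81L, 81L, byrow = TRUE)
    th <- atan2(cg - ctr[2], rg - ctr[1])
    rad <- base_r * (1 + Reduce(`+`, lapply(seq_len(nharm), function(k)
      a[k] * cos(k * th) + b[k] * sin(k * th))))
    blob <- (rg - ctr[1])^2 + (cg - ctr[2])^2 <= pmax(rad, 2)^2
    ct <- contour_from_mask(blob)
    img <- matrix(0L, 81L, 81L); img[blob] <- 100L
    c1 <- as.integer(round(contour_centroid(ct)))
    if (!blob[c1[1], c1[2]]) next
    region <- grow_region(img, c1, 50)
    region$credible <- NA
    expect_true(check_credible(region, ct, c1, growth_params()))
  }
})

test_that("combination is the pixelwise union of credible regions only", {
  mk <- function(mask, credible) structure(
    list(mask = mask, area_px = sum(mask), credible = credible),
    class = "grown_region")
  a <- matrix(FALSE, 16L, 16L); a[2:5, 2:5] <- TRUE
  b <- matrix(FALSE, 16L, 16L); b[10:14, 10:14] <- TRUE
  set.seed(54)
  cmask <- random_mask(16L, 16L)

  one <- combine_regions(list(mk(a, TRUE)))
  expect_identical(one$mask, a)
  expect_equal(one$status, "ok")

  two <- combine_regions(list(mk(a, TRUE), mk(b, TRUE)))
  expect_equal(sum(two$mask), sum(a) + sum(b))  # disjoint union

  mixed <- combine_regions(list(mk(a, TRUE), mk(cmask, FALSE), mk(b, TRUE)))
  expect_identical(mixed$mask, a | b)           # pixelwise OR oracle
  expect_equal(mixed$n_credible, 2L)

  none <- combine_regions(list(mk(a, FALSE), mk(b, FALSE)))
  expect_equal(none$status, "all_abnormal")
  expect_equal(sum(none$mask), 0L)
  expect_null(none$boundary)
})
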