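# Independent brute-force oracles used to validate the package's own
# implementations.  These deliberately take the slow, obvious route.

# Shift a logical matrix by (dr, dc), padding with FALSE.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# Fixpoint flood fill by repeated whole-image sweeps: a pixel joins if
# it is eligible and any neighbor is already in.  Independent of the
# queue-based grower.
oracle_flood_fill <- function(image, seed, threshold, connectivity = 8L) {
  eligible <- abs(image - image[seed[1L], seed[2L]]) <= threshold
  vis <- matrix(FALSE, nrow(image), ncol(image))
  vis[seed[1L], seed[2L]] <- TRUE
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L)
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  repeat {
    nb <- Reduce(`|`, lapply(offs, function(o) shift_mat(vis, o[1L], o[2L])))
    new <- eligible & nb & !vis
    if (!any(new)) break
    vis <- vis | new
  }
  vis
}

# Exhaustive Otsu: per-candidate direct sums over the histogram bins,
# same binning convention as the implementation (n bins over
# [min, max]), first argmax.
oracle_otsu_threshold <- function(image, n_bins = 256L) {
  lo <- min(image); hi <- max(image)
  w <- (hi - lo) / n_bins
  idx <- pmin(floor((as.vector(image) - lo) / w) + 1L, n_bins)
  p <- tabulate(idx, nbins = n_bins) / length(image)
  mids <- lo + (seq_len(n_bins) - 0.5) * w
  best_k <- NA_integer_; best <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:k] * mids[1:k]) / w0
    mu1 <- sum(p[(k + 1L):n_bins] * mids[(k + 1L):n_bins]) / w1
    s <- w0 * w1 * (mu0 - mu1)^2
    if (s > best) { best <- s; best_k <- k }
  }
  lo + best_k * w
}

# O(n^2) maximum pairwise distance.
oracle_max_pairwise <- function(points) {
  n <- nrow(points)
  if (n < 2L) return(0)
  best <- 0
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt(sum((points[i, ] - points[j, ])^2))
    if (d > best) best <- d
  }
  best
}

# Even-odd ray-casting point-in-polygon (polygon as closed (row, col)
# ring).
oracle_point_in_polygon <- function(p, poly) {
  n <- nrow(poly) - 1L
  inside <- FALSE
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    if ((a[2L] > p[2L]) != (b[2L] > p[2L])) {
      x <- a[1L] + (p[2L] - a[2L]) / (b[2L] - a[2L]) * (b[1L] - a[1L])
      if (p[1L] < x) inside <- !inside
    }
  }
  inside
}

# Deterministic random binary mask.
random_mask <- function(nr, nc, p = 0.4) {
  matrix(runif(nr * nc) < p, nr, nc)
}

# Build a ct_contour from a logical mask the way extract_contours
# would, for constructing seeding fixtures directly.
contour_from_mask <- function(mask, spacing_mm = 1) {
  cts <- extract_contours(mask, spacing_mm)
  stopifnot(length(cts) == 1L)
  cts[[1L]]
}

# Filled-disk mask.
disk_mask <- function(nr, nc, ctr, radius) {
  rg <- matrix(seq_len(nr), nr, nc)
  cg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rg - ctr[1L])^2 + (cg - ctr[2L])^2 <= radius^2
}
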