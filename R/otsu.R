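#' Otsu binarization
#'
#' Picks the gray threshold that maximizes the between-class variance
#' of the image histogram, then marks every pixel strictly above it as
#' foreground.  The histogram uses `n_bins` equal-width bins spanning
#' the observed `[min, max]` range, which makes the threshold exactly
#' shift-equivariant: adding a constant to all pixels shifts the
#' threshold by that constant.
#'
#' Between-class variance at candidate threshold t is
#' \deqn{\sigma_b^2(t) = w_0(t)\, w_1(t)\, (\mu_0(t) - \mu_1(t))^2}
#' with class weights \eqn{w} and means \eqn{\mu} taken from the
#' histogram; ties are broken toward the smallest maximizing threshold.
#'
#' @param image numeric matrix with at least two distinct intensity
#'   levels.
#' @param n_bins number of histogram bins (256, matching 8-bit gray
#'   resolution; 16-bit slices are binned over their range).
#' @return list with `mask` (logical matrix, `pixel > threshold`) and
#'   `threshold` (gray value).
#' @export
binarize_otsu <- function(image, n_bins = 256L) {
  if (inherits(image, "ct_slice")) image <- image$pixels
  stopifnot(is.matrix(image), all(is.finite(image)))
  lo <- min(image); hi <- max(image)
  if (hi <= lo)
    stop("constant image: Otsu histogram is degenerate", call. = FALSE)
  # bin i covers [lo + (i-1)*w, lo + i*w); candidate thresholds are the
  # bin upper edges (splitting after bin i)
  w <- (hi - lo) / n_bins
  idx <- pmin(floor((as.vector(image) - lo) / w) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  p <- counts / sum(counts)
  mids <- lo + (seq_len(n_bins) - 0.5) * w
  w0 <- cumsum(p)
  mu_cum <- cumsum(p * mids)
  mu_tot <- mu_cum[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_tot * w0[valid] - mu_cum[valid])^2 /
    (w0[valid] * w1[valid])
  k <- which.max(sigma_b)          # first max = smallest threshold
  thr <- lo + k * w
  list(mask = image > thr, threshold = thr)
}
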