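#' Contrast-stretch parameters
#'
#' @param low_percentile,high_percentile clip fractions in `[0, 1]`,
#'   `low < high`.  Defaults (0.02, 0.98) saturate the brightest ~2% of
#'   pixels, suppressing isolated bright spots that would otherwise
#'   survive binarization as spurious tumor candidates.
#' @return list of class `preprocess_params`.
#' @export
preprocess_params <- function(low_percentile = 0.02, high_percentile = 0.98) {
  if (!(low_percentile >= 0 && low_percentile < high_percentile &&
        high_percentile <= 1))
    stop("need 0 <= low_percentile < high_percentile <= 1", call. = FALSE)
  structure(list(low_percentile = low_percentile,
                 high_percentile = high_percentile),
            class = "preprocess_params")
}

#' Percentile contrast stretch
#'
#' Linear stretch used only to sharpen the tumor for *localization*
#' (binarization and contour filtering); region growing itself always
#' operates on the original intensities.  Intensities at or below the
#' low percentile map to 0, at or above the high percentile to the
#' dtype maximum, linearly in between.
#'
#' A constant (zero-dynamic-range) slice is returned unchanged with a
#' warning.  Monotone: the stretch never reorders intensities.
#'
#' @param slice a [ct_slice()].
#' @param params a [preprocess_params()].
#' @return A `ct_slice` with stretched pixels; shape, spacing and bit
#'   depth unchanged.
#' @export
adjust_contrast <- function(slice, params = preprocess_params()) {
  stopifnot(inherits(slice, "ct_slice"))
  px <- slice$pixels
  lohi <- quantile(px, c(params$low_percentile, params$high_percentile),
                   names = FALSE, type = 7)
  if (diff(lohi) <= 0) {
    if (min(px) == max(px)) {
      warning("constant image: contrast adjustment skipped", call. = FALSE)
      return(slice)
    }
    # degenerate percentile window on a non-constant image: widen to
    # the full range rather than dividing by zero
    lohi <- range(px)
  }
  top <- 2^slice$bit_depth - 1
  out <- (px - lohi[1]) / (lohi[2] - lohi[1]) * top
  out <- round(pmin(pmax(out, 0), top))
  storage.mode(out) <- "integer"
  ct_slice(out, slice$spacing_mm, slice$source_path, slice$bit_depth)
}
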