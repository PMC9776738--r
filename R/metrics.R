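#' Pair of masks for evaluation
#'
#' @param x binary mask, the reference (expert/label) segmentation.
#' @param y binary mask, the method output; same shape as `x`.
#' @return list of class `eval_pair`.
#' @export
eval_pair <- function(x, y) {
  x <- as_binary_mask(x)
  y <- as_binary_mask(y)
  if (!identical(dim(x), dim(y)))
    stop("masks have different shapes", call. = FALSE)
  structure(list(x = x, y = y), class = "eval_pair")
}

as_eval_pair <- function(pair, y) {
  if (inherits(pair, "eval_pair")) return(pair)
  eval_pair(pair, y)
}

#' Dice coefficient
#'
#' Overlap agreement between two pixel sets,
#' `2 |x ∩ y| / (|x| + |y|)`, in `[0, 1]`.  Evaluating two empty masks
#' is an error: agreement of nothing with nothing is undefined here.
#'
#' @param pair an [eval_pair()], or the reference mask if `y` is given.
#' @param y optional method mask (two-mask calling form).
#' @return fraction in `[0, 1]`.
#' @export
dice <- function(pair, y = NULL) {
  p <- as_eval_pair(pair, y)
  nx <- sum(p$x); ny <- sum(p$y)
  if (nx + ny == 0L)
    stop("Dice is undefined for two empty masks", call. = FALSE)
  2 * sum(p$x & p$y) / (nx + ny)
}

#' Jaccard distance
#'
#' Dissimilarity between two pixel sets,
#' `(|x ∪ y| - |x ∩ y|) / |x ∪ y| = 1 - J(x, y)`, in `[0, 1]`.
#' Undefined (error) when both masks are empty.
#'
#' @inheritParams dice
#' @return fraction in `[0, 1]`.
#' @export
jaccard_distance <- function(pair, y = NULL) {
  p <- as_eval_pair(pair, y)
  un <- sum(p$x | p$y)
  if (un == 0L)
    stop("Jaccard distance is undefined for two empty masks", call. = FALSE)
  (un - sum(p$x & p$y)) / un
}
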