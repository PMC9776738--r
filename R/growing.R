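#' Region-growing parameters
#'
#' @param threshold_frac fraction of the reference intensity range used
#'   as the gray tolerance (0.2: the seed absorbs neighbors within 20%
#'   of the range of the whole image for p1, of the update circle for
#'   p2...p7).
#' @param margin_px margin added to the threshold-update circle radius,
#'   in pixels (6).
#' @param connectivity 4 or 8 (8 matches the 8-connected contour
#'   extraction).
#' @param predicted_max_size_cm optional clinician-supplied maximum
#'   tumor size; when given, credibility is judged against it instead
#'   of the circumscribed-circle area.
#' @param anchor_p1 if `TRUE`, every update circle is centered at p1;
#'   default chains through the previous seed's result.
#' @param roi_stat how the "gray threshold" of a reference area is
#'   measured: `"range"` (max - min, default), `"max"`, or `"otsu"`.
#' @return list of class `growth_params`.
#' @export
growth_params <- function(threshold_frac = 0.2, margin_px = 6,
                          connectivity = 8L, predicted_max_size_cm = NULL,
                          anchor_p1 = FALSE,
                          roi_stat = c("range", "max", "otsu")) {
  roi_stat <- match.arg(roi_stat)
  if (!(threshold_frac > 0 && threshold_frac < 1))
    stop("threshold_frac must be in (0, 1)", call. = FALSE)
  if (margin_px < 0) stop("margin_px must be >= 0", call. = FALSE)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  structure(list(threshold_frac = threshold_frac, margin_px = margin_px,
                 connectivity = as.integer(connectivity),
                 predicted_max_size_cm = predicted_max_size_cm,
                 anchor_p1 = isTRUE(anchor_p1), roi_stat = roi_stat),
            class = "growth_params")
}

roi_gray_threshold <- function(values, roi_stat) {
  switch(roi_stat,
         range = max(values) - min(values),
         max = max(values),
         otsu = if (max(values) > min(values))
           binarize_otsu(matrix(values, nrow = 1L))$threshold else 0)
}

#' Initial gray tolerance: a fraction of the image intensity range
#'
#' The tolerance used when the first seed (p1) grows:
#' `frac * (max(image) - min(image))`.  A constant image yields
#' tolerance 0 with a warning.
#'
#' @param image numeric matrix (the original, non-preprocessed slice).
#' @param frac fraction of the range (0.2).
#' @param roi_stat see [growth_params()].
#' @return gray tolerance (same units as `image`).
#' @export
compute_initial_threshold <- function(image, frac = 0.2,
                                      roi_stat = "range") {
  if (inherits(image, "ct_slice")) image <- image$pixels
  stopifnot(is.matrix(image))
  if (max(image) == min(image)) {
    warning("constant image: zero gray tolerance", call. = FALSE)
    return(0)
  }
  frac * roi_gray_threshold(as.vector(image), roi_stat)
}

#' Queue-based region growing from one seed
#'
#' Breadth-first growth: the seed's intensity is saved as the base
#' value, and a neighboring pixel q joins the region iff
#' `|I(q) - base| <= threshold`.  Newly added pixels are queued and
#' their neighbors checked in turn, until no new growth points appear.
#' The visited set is the grown region; its outermost pixels form the
#' region boundary.  The base value stays fixed at the seed intensity
#' throughout (not a running mean), so the accepted set is exactly one
#' connected component of the eligibility predicate — which makes the
#' result monotone in the threshold.
#'
#' @param image numeric matrix of gray intensities.
#' @param seed integer `c(row, col)` inside the image.
#' @param threshold gray tolerance (>= 0).
#' @param connectivity 4 or 8.
#' @param spacing_mm optional; when supplied the region's maximum size
#'   is also reported in cm.
#' @return object of class `grown_region`: `seed`, `base_intensity`,
#'   `threshold`, `mask`, `area_px`, `boundary_px`, `max_size_cm`
#'   (`NA` without spacing), `credible` (`NA` until checked).
#' @export
grow_region <- function(image, seed, threshold, connectivity = 8L,
                        spacing_mm = NULL) {
  if (inherits(image, "ct_slice")) {
    if (is.null(spacing_mm)) spacing_mm <- image$spacing_mm
    image <- image$pixels
  }
  stopifnot(is.matrix(image), threshold >= 0)
  nr <- nrow(image); nc <- ncol(image)
  seed <- as.integer(round(seed))
  if (length(seed) < 2L || seed[1L] < 1L || seed[1L] > nr ||
      seed[2L] < 1L || seed[2L] > nc)
    stop("seed point is outside the image bounds", call. = FALSE)
  base <- image[seed[1L], seed[2L]]
  eligible <- abs(image - base) <= threshold
  offs <- if (connectivity == 8L)
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  else list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))

  visited <- matrix(FALSE, nr, nc)
  start <- (seed[2L] - 1L) * nr + seed[1L]
  visited[start] <- TRUE
  frontier <- start
  while (length(frontier) > 0L) {
    fr <- ((frontier - 1L) %% nr) + 1L
    fc <- ((frontier - 1L) %/% nr) + 1L
    nbrs <- integer(0L)
    for (off in offs) {
      ok <- fr + off[1L] >= 1L & fr + off[1L] <= nr &
            fc + off[2L] >= 1L & fc + off[2L] <= nc
      if (any(ok))
        nbrs <- c(nbrs, frontier[ok] + off[1L] + off[2L] * nr)
    }
    nbrs <- unique(nbrs)
    nbrs <- nbrs[eligible[nbrs] & !visited[nbrs]]
    visited[nbrs] <- TRUE
    frontier <- nbrs
  }
  bnd <- which(mask_boundary(visited))
  bpts <- cbind(row = ((bnd - 1L) %% nr) + 1L,
                col = ((bnd - 1L) %/% nr) + 1L)
  structure(
    list(seed = seed, base_intensity = base, threshold = threshold,
         mask = visited, area_px = sum(visited), boundary_px = bpts,
         max_size_cm = if (is.null(spacing_mm)) NA_real_ else
           feret_px(bpts) * spacing_mm / 10,
         credible = NA),
    class = "grown_region")
}

#' @export
print.grown_region <- function(x, ...) {
  cat(sprintf(
    "<grown_region> seed (%d, %d), base %g, tol %.3g, %d px%s%s\n",
    x$seed[1L], x$seed[2L], x$base_intensity, x$threshold, x$area_px,
    if (is.na(x$max_size_cm)) "" else sprintf(", %.2f cm", x$max_size_cm),
    if (is.na(x$credible)) "" else
      if (x$credible) ", credible" else ", abnormal"))
  invisible(x)
}

#' Automatic threshold update from the previous seed's result
#'
#' A circle of radius L is drawn around the previous seed, where L is
#' the maximum distance from that seed to its grown tumor boundary plus
#' `margin_px`; the next seed's gray tolerance is `frac` times the gray
#' threshold (intensity range) inside that circle.  Localizing the
#' reference area to the tumor neighborhood adapts the tolerance to
#' local contrast instead of the whole slice.
#'
#' @param image numeric matrix (original intensities).
#' @param prev_seed the previous seed `c(row, col)`.
#' @param prev_region the previous seed's `grown_region`.
#' @param frac fraction of the circle's intensity range (0.2).
#' @param margin_px circle-radius margin in pixels (6).
#' @param roi_stat see [growth_params()].
#' @return gray tolerance, with attribute `radius_px` = L.  An empty
#'   previous region falls back to [compute_initial_threshold()]
#'   (attribute `fallback = TRUE`).
#' @export
update_threshold <- function(image, prev_seed, prev_region, frac = 0.2,
                             margin_px = 6, roi_stat = "range") {
  if (inherits(image, "ct_slice")) image <- image$pixels
  stopifnot(is.matrix(image))
  if (is.null(prev_region) || prev_region$area_px == 0L ||
      nrow(prev_region$boundary_px) == 0L) {
    thr <- compute_initial_threshold(image, frac, roi_stat)
    attr(thr, "fallback") <- TRUE
    return(thr)
  }
  b <- prev_region$boundary_px
  L <- sqrt(max((b[, 1L] - prev_seed[1L])^2 + (b[, 2L] - prev_seed[2L])^2)) +
    margin_px
  nr <- nrow(image); nc <- ncol(image)
  rr <- seq_len(nr) - prev_seed[1L]
  cc <- seq_len(nc) - prev_seed[2L]
  in_circle <- outer(rr^2, cc^2, "+") <= L^2
  vals <- image[in_circle]
  if (max(vals) == min(vals)) {
    warning("constant intensities inside the update circle: zero tolerance",
            call. = FALSE)
    thr <- 0
  } else {
    thr <- frac * roi_gray_threshold(vals, roi_stat)
  }
  attr(thr, "radius_px") <- L
  thr
}

#' Growth-restriction credibility check
#'
#' Guards against leakage of the grown region out of the tumor.  With a
#' predicted maximum tumor size, a result is credible iff its maximum
#' size does not exceed the prediction.  Without one, the longest
#' distance r from the centroid C to the target contour D is taken as
#' the radius of a circle: a result whose pixel area exceeds the circle
#' area `pi * r^2` is abnormal.
#'
#' @param region a `grown_region`.
#' @param contour_d the target contour (`ct_contour`).
#' @param c the centroid seed `c(row, col)`.
#' @param params a [growth_params()].
#' @return `TRUE` (credible) or `FALSE` (abnormal).
#' @export
check_credible <- function(region, contour_d, c, params = growth_params()) {
  stopifnot(inherits(region, "grown_region"))
  if (!is.null(params$predicted_max_size_cm)) {
    if (is.na(region$max_size_cm))
      stop("predicted-size credibility needs the region's size in cm; ",
           "grow with `spacing_mm`", call. = FALSE)
    return(region$max_size_cm <= params$predicted_max_size_cm)
  }
  stopifnot(inherits(contour_d, "ct_contour"))
  b <- contour_d$boundary_px
  # +0.5: distances run between pixel centers, but pixel areas count
  # whole unit squares, which extend half a pixel beyond the boundary
  # centers; without the correction a region identical to a filled
  # disk D narrowly fails its own circumscribed circle.
  r <- sqrt(max((b[, 1L] - c[1L])^2 + (b[, 2L] - c[2L])^2)) + 0.5
  region$area_px <= pi * r^2
}

#' Combine the credible grown regions
#'
#' Pixelwise union of the masks of all regions whose credibility flag
#' is `TRUE`; abnormal regions contribute nothing.  If no region is
#' credible the combination fails explicitly (status
#' `"all_abnormal"`, empty mask) — there is no silent fallback.
#'
#' @param regions list of `grown_region`s with `credible` set.
#' @return list with `mask`, `boundary` (ordered closed polygon or
#'   `NULL`), `status` (`"ok"` or `"all_abnormal"`), `n_credible`.
#' @export
combine_regions <- function(regions) {
  stopifnot(length(regions) >= 1L)
  cred <- vapply(regions, function(r) isTRUE(r$credible), logical(1L))
  shape <- dim(regions[[1L]]$mask)
  mask <- matrix(FALSE, shape[1L], shape[2L])
  for (r in regions[cred]) mask <- mask | r$mask
  if (!any(cred))
    return(list(mask = mask, boundary = NULL, status = "all_abnormal",
                n_credible = 0L))
  list(mask = mask, boundary = trace_polygon(mask), status = "ok",
       n_credible = sum(cred))
}
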