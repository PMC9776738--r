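#' Automatic lung tumor segmentation on one CT slice
#'
#' The full workflow: contrast-adjust the slice (localization only),
#' binarize with Otsu, extract contours, filter them by the physical
#' priors to find the target contour D, take its centroid as seed p1,
#' expand to p2...p7 by 60-degree sector centroids, then grow a region
#' from each seed — p1 with a tolerance of 20% of the whole-image
#' intensity range, each later seed with a tolerance recomputed inside
#' a circle around the previous seed's result.  Each grown region is
#' credibility-checked against the growth restrictions and the final
#' segmentation is the union of the credible regions.  Region growing
#' always operates on the original (non-preprocessed) intensities.
#'
#' When several contours survive the prior filter, each is segmented
#' independently; the largest-area candidate is marked primary.
#'
#' @param slice a [ct_slice()].
#' @param params a [growth_params()].
#' @param preproc a [preprocess_params()].
#' @param bounds a [prior_bounds()].
#' @param seed optional manual seed `c(row, col)`.  Bypasses
#'   localization (the fallback when no candidate passes the priors):
#'   a single region is grown from this point and judged credible
#'   against `predicted_max_size_cm` when available, otherwise
#'   accepted with a flag.
#' @param sector_offset_deg rotation of the seed-expansion dividing
#'   lines, degrees.
#' @return Object of class `tumor_segmentation`: `candidates` (list of
#'   `segmentation_result`), `primary` (index of the largest-area
#'   candidate), `spacing_mm`, `params`.  Each `segmentation_result`
#'   carries `regions` (the per-seed `grown_region`s with credibility
#'   set), `combined_mask`, `boundary`, `restriction_mode`, `status`,
#'   `contour`, `seeds`, `spacing_mm`, `flags`.
#' @section Errors: No surviving candidate raises a
#'   `priorgrow_localization_error` suggesting manual seeding; all
#'   regions abnormal in every candidate raises a
#'   `priorgrow_combination_error`.
#' @export
segment_tumor <- function(slice, params = growth_params(),
                          preproc = preprocess_params(),
                          bounds = prior_bounds(), seed = NULL,
                          sector_offset_deg = 0) {
  stopifnot(inherits(slice, "ct_slice"), inherits(params, "growth_params"))
  if (!is.null(seed)) return(segment_manual(slice, params, seed))

  pre <- adjust_contrast(slice, preproc)
  bw <- binarize_otsu(pre$pixels)
  contours <- extract_contours(bw$mask, slice$spacing_mm)
  cands <- filter_candidates(contours, bounds)
  if (length(cands) == 0L)
    stop(priorgrow_condition(
      "priorgrow_localization_error",
      paste0("no contour passes the prior size/area filter (",
             length(contours), " contours found); the tumor may lie ",
             "outside the (2, 5] cm window - supply a manual seed ",
             "point via `seed = c(row, col)`")))

  areas <- vapply(cands, function(ct) ct$area_px, numeric(1L))
  results <- lapply(cands, function(ct)
    segment_candidate(slice, ct, params, sector_offset_deg))
  if (all(vapply(results, function(r) r$status != "ok", logical(1L))))
    stop(priorgrow_condition(
      "priorgrow_combination_error",
      "every grown region failed its growth-restriction check ",
      "(all abnormal); no credible segmentation to combine"))
  structure(
    list(candidates = results, primary = which.max(areas),
         otsu_threshold = bw$threshold,
         spacing_mm = slice$spacing_mm, params = params),
    class = "tumor_segmentation")
}

segment_candidate <- function(slice, contour, params, sector_offset_deg) {
  img <- slice$pixels
  spacing <- slice$spacing_mm
  flags <- character(0L)
  c_frac <- contour_centroid(contour)
  p1 <- as.integer(round(c_frac))
  inside <- region_lookup(contour)
  if (!inside[p1[1L], p1[2L]]) {
    p1 <- nearest_region_pixel(contour$pixels, p1)
    flags <- c(flags, "centroid outside concave region; p1 moved to nearest interior pixel")
  }
  seeds <- expand_seeds(contour, p1, sector_offset_deg)
  flags <- c(flags, seeds$flags)
  pts <- seed_matrix(seeds)

  regions <- vector("list", nrow(pts))
  thr <- compute_initial_threshold(img, params$threshold_frac,
                                   params$roi_stat)
  for (k in seq_len(nrow(pts))) {
    if (k > 1L) {
      prev_k <- if (params$anchor_p1) 1L else k - 1L
      thr <- update_threshold(img, regions[[prev_k]]$seed,
                              regions[[prev_k]],
                              params$threshold_frac, params$margin_px,
                              params$roi_stat)
      if (isTRUE(attr(thr, "fallback")))
        flags <- c(flags, sprintf(
          "seed %d: previous region empty, initial threshold reused", k))
    }
    rg <- grow_region(img, pts[k, ], as.numeric(thr),
                      params$connectivity, spacing)
    rg$credible <- check_credible(rg, contour, p1, params)
    regions[[k]] <- rg
  }
  comb <- combine_regions(regions)
  structure(
    list(regions = regions, combined_mask = comb$mask,
         boundary = comb$boundary, status = comb$status,
         n_credible = comb$n_credible,
         restriction_mode = if (is.null(params$predicted_max_size_cm))
           "circle-area" else "predicted-size",
         contour = contour, seeds = seeds, spacing_mm = spacing,
         flags = flags),
    class = "segmentation_result")
}

segment_manual <- function(slice, params, seed) {
  img <- slice$pixels
  thr <- compute_initial_threshold(img, params$threshold_frac,
                                   params$roi_stat)
  rg <- grow_region(img, seed, thr, params$connectivity, slice$spacing_mm)
  flags <- "manual seed: localization bypassed"
  if (!is.null(params$predicted_max_size_cm)) {
    rg$credible <- rg$max_size_cm <= params$predicted_max_size_cm
    mode <- "predicted-size"
  } else {
    rg$credible <- TRUE
    mode <- "circle-area"
    flags <- c(flags,
               "no predicted size: growth restriction not applicable")
  }
  comb <- combine_regions(list(rg))
  if (comb$status != "ok")
    stop(priorgrow_condition(
      "priorgrow_combination_error",
      "the manually seeded region exceeds the predicted maximum size"))
  res <- structure(
    list(regions = list(rg), combined_mask = comb$mask,
         boundary = comb$boundary, status = comb$status,
         n_credible = comb$n_credible, restriction_mode = mode,
         contour = NULL, seeds = NULL, spacing_mm = slice$spacing_mm,
         flags = flags),
    class = "segmentation_result")
  structure(list(candidates = list(res), primary = 1L,
                 otsu_threshold = NA_real_,
                 spacing_mm = slice$spacing_mm, params = params),
            class = "tumor_segmentation")
}

priorgrow_condition <- function(class, ...) {
  structure(class = c(class, "error", "condition"),
            list(message = paste0(...), call = NULL))
}

#' Primary segmentation result of a run
#'
#' @param x a `tumor_segmentation`.
#' @return the primary candidate's `segmentation_result`.
#' @export
primary_result <- function(x) {
  stopifnot(inherits(x, "tumor_segmentation"))
  x$candidates[[x$primary]]
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %d/%d credible regions, combined %d px, %s mode, status %s\n",
    x$n_credible, length(x$regions), sum(x$combined_mask),
    x$restriction_mode, x$status))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.tumor_segmentation <- function(x, ...) {
  cat(sprintf("<tumor_segmentation> %d candidate(s), primary = %d\n",
              length(x$candidates), x$primary))
  for (i in seq_along(x$candidates)) {
    cat(sprintf(" [%d]%s ", i, if (i == x$primary) "*" else " "))
    print(x$candidates[[i]])
  }
  invisible(x)
}
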