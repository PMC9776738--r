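#' Seed expansion: from the centroid seed to a seven-seed ensemble
#'
#' Three dividing lines through the centroid `c`, at 60 degrees to one
#' another, partition the filled target region into six angular
#' sectors.  Each sector's pixel centroid becomes one additional seed
#' (p2...p7); the centroid seed itself is p1.  A sector centroid that
#' falls outside the region (possible for concave tumors) is replaced
#' by [fallback_seed()].  Every returned seed lies inside the region.
#'
#' Sector membership uses half-open angle intervals
#' `[theta, theta + 60)` measured from the image-row axis, so the six
#' sectors tile the region exactly.
#'
#' @param contour a `ct_contour` (the target contour D).
#' @param c seed point `c(row, col)`; defaults to the rounded region
#'   centroid.  Must lie inside the region.
#' @param sector_offset_deg rotation of the dividing lines, degrees.
#' @return object of class `seed_set`: `p1`, `extras` (up to 6 x 2
#'   integer matrix), `sector_angles` (the three line angles),
#'   `flags` (character; e.g. fallback replacements, empty sectors,
#'   degenerate regions).
#' @export
expand_seeds <- function(contour, c = NULL, sector_offset_deg = 0) {
  stopifnot(inherits(contour, "ct_contour"))
  inside <- region_lookup(contour)
  if (is.null(c)) {
    c <- round(contour_centroid(contour))
    if (!inside[c[1L], c[2L]])
      stop("region centroid falls outside the (concave) region; ",
           "supply an interior seed point `c`", call. = FALSE)
  }
  c <- as.integer(round(c))
  if (!inside[c[1L], c[2L]])
    stop("seed point c is not inside the target region", call. = FALSE)
  angles <- (sector_offset_deg + c(0, 60, 120)) %% 180
  flags <- character(0L)

  px <- contour$pixels
  if (nrow(px) < 7L) {
    extras <- matrix(rep(c, 6L), ncol = 2L, byrow = TRUE,
                     dimnames = list(NULL, c("row", "col")))
    return(structure(list(p1 = c, extras = extras, sector_angles = angles,
                          flags = "degenerate: region smaller than 7 px"),
                     class = "seed_set"))
  }

  sec <- sector_of(px, c, sector_offset_deg)
  taken <- matrix(c, ncol = 2L)
  extras <- NULL
  for (s in 1:6) {
    in_s <- sec == s
    if (!any(in_s)) {
      flags <- c(flags, sprintf("sector %d contains no region pixels", s))
      next
    }
    cand <- round(colMeans(px[in_s, , drop = FALSE]))
    if (!inside[cand[1L], cand[2L]]) {
      cand <- fallback_seed(contour, c,
                            sector_offset_deg + c((s - 1) * 60, s * 60))
      if (is.null(cand)) {
        flags <- c(flags, sprintf("sector %d: no usable fallback seed", s))
        next
      }
      flags <- c(flags, sprintf("sector %d centroid outside region: %s", s,
                                attr(cand, "note")))
    }
    cand <- as.integer(cand[1:2])
    if (any(taken[, 1L] == cand[1L] & taken[, 2L] == cand[2L])) {
      cand <- nearest_region_pixel(px, cand, exclude = taken)
      if (is.null(cand)) {
        flags <- c(flags, sprintf("sector %d seed duplicates exhausted", s))
        next
      }
      flags <- c(flags, sprintf("sector %d seed collided; moved", s))
    }
    taken <- rbind(taken, cand)
    extras <- rbind(extras, cand)
  }
  dimnames(extras) <- list(NULL, c("row", "col"))
  structure(list(p1 = c, extras = extras, sector_angles = angles,
                 flags = flags),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> p1 = (%d, %d), %d expansion seeds\n",
              x$p1[1L], x$p1[2L], nrow(x$extras)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# Sector index (1..6) of each point relative to c; angle 0 along the
# image-row axis, half-open 60-degree intervals.
sector_of <- function(points, c, offset_deg = 0) {
  dr <- points[, 1L] - c[1L]
  dc <- points[, 2L] - c[2L]
  theta <- (atan2(dc, dr) * 180 / pi - offset_deg) %% 360
  pmin(floor(theta / 60) + 1L, 6L)
}

#' Fallback seed for a sector whose centroid leaves the region
#'
#' Midpoint of the minimum-distance line from the centroid `c` to the
#' region boundary restricted to the offending sector.  If the midpoint
#' itself lies outside the region (deeply concave shapes), the nearest
#' region pixel to the midpoint is returned instead; the choice made is
#' recorded in the `"note"` attribute.
#'
#' @param contour a `ct_contour`.
#' @param c the centroid seed `c(row, col)`.
#' @param sector angular interval `c(lo_deg, hi_deg)` (half-open),
#'   measured from the image-row axis.
#' @return integer `c(row, col)` inside the region, or `NULL` if the
#'   sector holds no boundary pixels.
#' @export
fallback_seed <- function(contour, c, sector) {
  stopifnot(inherits(contour, "ct_contour"), length(sector) == 2L)
  b <- contour$boundary_px
  width <- (sector[2L] - sector[1L]) %% 360
  if (width == 0) width <- 360
  th <- (atan2(b[, 2L] - c[2L], b[, 1L] - c[1L]) * 180 / pi -
           sector[1L]) %% 360
  in_sec <- th < width
  if (!any(in_sec)) return(NULL)
  bs <- b[in_sec, , drop = FALSE]
  d2 <- (bs[, 1L] - c[1L])^2 + (bs[, 2L] - c[2L])^2
  nb <- bs[which.min(d2), ]
  mid <- as.integer(round((c[1:2] + nb) / 2))
  inside <- region_lookup(contour)
  if (inside[mid[1L], mid[2L]]) {
    attr(mid, "note") <- "midpoint of minimum-distance line"
    return(mid)
  }
  out <- nearest_region_pixel(contour$pixels, mid)
  attr(out, "note") <- "midpoint outside region; nearest interior pixel used"
  out
}

nearest_region_pixel <- function(pixels, p, exclude = NULL) {
  cand <- pixels
  if (!is.null(exclude)) {
    bad <- (cand[, 1L] * 1e6 + cand[, 2L]) %in%
      (exclude[, 1L] * 1e6 + exclude[, 2L])
    cand <- cand[!bad, , drop = FALSE]
  }
  if (nrow(cand) == 0L) return(NULL)
  d2 <- (cand[, 1L] - p[1L])^2 + (cand[, 2L] - p[2L])^2
  as.integer(cand[which.min(d2), ])
}

# All seeds of a seed_set as a (<=7) x 2 integer matrix, p1 first.
seed_matrix <- function(seeds) {
  rbind(matrix(seeds$p1, ncol = 2L), seeds$extras)
}
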