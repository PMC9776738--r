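#' Prior bounds on tumor size and area
#'
#' Physical admissibility window for tumor candidates, taken from the
#' TNM (8th edition) size cut-points: stages T1c through T2b span
#' maximum diameters in (2, 5] cm.  The area window (1, 6.25*pi] cm^2
#' pairs the circle area of a 5 cm diameter (upper bound) with a 1 cm^2
#' floor that screens out vessel-tree cross-sections.  Both conditions
#' are strict at the low end and inclusive at the high end.
#'
#' @param size_low_cm,size_high_cm maximum-diameter window in cm.
#' @param area_low_cm2,area_high_cm2 area window in cm^2.
#' @return list of class `prior_bounds`.
#' @export
prior_bounds <- function(size_low_cm = 2, size_high_cm = 5,
                         area_low_cm2 = 1, area_high_cm2 = 6.25 * pi) {
  if (!(size_low_cm < size_high_cm) || !(area_low_cm2 < area_high_cm2))
    stop("prior bounds must satisfy low < high", call. = FALSE)
  structure(list(size_low_cm = size_low_cm, size_high_cm = size_high_cm,
                 area_low_cm2 = area_low_cm2, area_high_cm2 = area_high_cm2),
            class = "prior_bounds")
}

# 8-connected component labeling.  EBImage::bwlabel is 4-connected, so
# components touching only diagonally are merged afterwards with a
# small union-find over adjacent label pairs.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (connectivity == 4L || n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  for (dc in c(-1L, 1L)) {   # diagonal neighbors (+1, dc)
    a <- lab[seq_len(nr - 1L), , drop = FALSE]
    b <- lab[2:nr, , drop = FALSE]
    if (dc == 1L) {
      a <- a[, seq_len(nc - 1L), drop = FALSE]
      b <- b[, 2:nc, drop = FALSE]
    } else {
      a <- a[, 2:nc, drop = FALSE]
      b <- b[, seq_len(nc - 1L), drop = FALSE]
    }
    sel <- a > 0L & b > 0L & a != b
    if (!any(sel)) next
    pairs <- unique(cbind(a[sel], b[sel]))
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
      if (ra != rb) parent[ra] <- rb
    }
  }
  root <- vapply(seq_len(n), find, integer(1L))
  newid <- match(root, unique(root))
  pos <- lab > 0L
  lab[pos] <- newid[lab[pos]]
  lab
}

# Boundary pixels of a binary region: region pixels with at least one
# 4-neighbor outside the region (image border counts as outside).
mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- function(dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    out[ok_r, ok_c] <- mask[rs[ok_r], cs[ok_c]]
    out
  }
  interior <- mask & pad(1L, 0L) & pad(-1L, 0L) & pad(0L, 1L) & pad(0L, -1L)
  mask & !interior
}

new_contour <- function(pixels, boundary_px, polygon, spacing_mm, shape) {
  area_px <- nrow(pixels)
  structure(
    list(polygon = polygon,
         pixels = pixels,
         boundary_px = boundary_px,
         area_px = area_px,
         area_cm2 = area_px * (spacing_mm / 10)^2,
         max_size_cm = feret_px(boundary_px) * spacing_mm / 10,
         spacing_mm = spacing_mm,
         shape = shape),
    class = "ct_contour")
}

#' @export
print.ct_contour <- function(x, ...) {
  cat(sprintf(
    "<ct_contour> area %d px (%.2f cm^2), max size %.2f cm, %d boundary pts\n",
    x$area_px, x$area_cm2, x$max_size_cm, nrow(x$boundary_px)))
  invisible(x)
}

#' Extract contours from a binary image
#'
#' One contour per 8-connected foreground component.  Holes are
#' ignored (filled) so that each contour describes the component's
#' outer boundary, and every contour carries its pixel area, physical
#' area and maximum size (Feret diameter) ready for prior filtering.
#'
#' @param binary logical or 0/1 matrix.
#' @param spacing_mm pixel spacing used for the physical measurements.
#' @return list of `ct_contour` objects (empty for an empty mask),
#'   ordered by label (raster order of first pixel).
#' @export
extract_contours <- function(binary, spacing_mm) {
  binary <- as_binary_mask(binary)
  stopifnot(is.numeric(spacing_mm), spacing_mm > 0)
  lab <- label_components(binary, 8L)
  n <- max(lab)
  if (n == 0L) return(list())
  lab <- matrix(as.integer(EBImage::fillHull(lab)), nrow(lab), ncol(lab))
  idx <- which(lab > 0L)
  by_lab <- split(idx, lab[idx])
  shape <- dim(binary)
  lapply(seq_len(n), function(i) {
    ii <- by_lab[[as.character(i)]]
    pr <- ((ii - 1L) %% shape[1]) + 1L
    pc <- ((ii - 1L) %/% shape[1]) + 1L
    # work on the cropped bounding box to keep per-component cost local
    r0 <- min(pr); c0 <- min(pc)
    sub <- matrix(FALSE, max(pr) - r0 + 1L, max(pc) - c0 + 1L)
    sub[cbind(pr - r0 + 1L, pc - c0 + 1L)] <- TRUE
    bsub <- which(mask_boundary(sub))
    bpts <- cbind(row = ((bsub - 1L) %% nrow(sub)) + r0,
                  col = ((bsub - 1L) %/% nrow(sub)) + c0)
    poly <- trace_polygon(sub, offset = c(r0 - 1L, c0 - 1L))
    new_contour(cbind(row = pr, col = pc), bpts, poly, spacing_mm, shape)
  })
}

# Ordered closed outer boundary of a single-component mask, 1-based
# (row, col).  EBImage::ocontour returns 0-based coordinates in the
# same (dim1, dim2) order.
trace_polygon <- function(mask, offset = c(0L, 0L)) {
  oc <- tryCatch(EBImage::ocontour(matrix(as.integer(mask),
                                          nrow(mask), ncol(mask))),
                 error = function(e) NULL)
  if (is.null(oc) || length(oc) == 0L) return(NULL)
  p <- oc[[which.max(vapply(oc, nrow, integer(1L)))]]
  p <- p + 1L
  poly <- cbind(row = p[, 1L] + offset[1L], col = p[, 2L] + offset[2L])
  if (nrow(poly) > 1L && !identical(poly[1L, ], poly[nrow(poly), ]))
    poly <- rbind(poly, poly[1L, , drop = FALSE])   # close the ring
  poly
}

# Maximum pairwise distance between points (n x 2 matrix), in pixels.
# Convex-hull reduction first; exact pairwise on the hull.
feret_px <- function(points) {
  if (is.null(points) || nrow(points) < 2L) return(0)
  pts <- unique(points)
  if (nrow(pts) < 2L) return(0)
  if (nrow(pts) > 3L) {
    h <- tryCatch(grDevices::chull(pts[, 2L], pts[, 1L]),
                  error = function(e) seq_len(nrow(pts)))
    if (length(h) >= 2L) pts <- pts[h, , drop = FALSE]
  }
  d <- dist(pts)
  max(d)
}

#' Maximum Feret diameter of a contour
#'
#' The longest straight-line (caliper) distance between two boundary
#' points, converted to centimetres via the contour's pixel spacing.
#' This is the "maximum size" used by the prior filter's condition on
#' tumor diameter.
#'
#' @param contour a `ct_contour`.
#' @return length in cm (0 for a degenerate single-point contour).
#' @export
max_feret_diameter <- function(contour) {
  stopifnot(inherits(contour, "ct_contour"))
  feret_px(contour$boundary_px) * contour$spacing_mm / 10
}

#' Filter tumor candidates by physical priors
#'
#' Keeps exactly the contours whose maximum size lies in
#' `(size_low_cm, size_high_cm]` *and* whose area lies in
#' `(area_low_cm2, area_high_cm2]` — a pure filter: the result is a
#' subset of the input in the original order, and filtering twice
#' equals filtering once.
#'
#' @param contours list of `ct_contour`.
#' @param bounds a [prior_bounds()].
#' @return list of the surviving `ct_contour`s (possibly empty).
#' @export
filter_candidates <- function(contours, bounds = prior_bounds()) {
  stopifnot(inherits(bounds, "prior_bounds"))
  keep <- vapply(contours, function(ct) {
    ct$max_size_cm > bounds$size_low_cm &&
      ct$max_size_cm <= bounds$size_high_cm &&
      ct$area_cm2 > bounds$area_low_cm2 &&
      ct$area_cm2 <= bounds$area_high_cm2
  }, logical(1L))
  contours[keep]
}

#' Centroid of a contour's filled region
#'
#' First-moment centroid over the filled pixel set (the standard
#' region centroid), returned as fractional `(row, col)` coordinates;
#' round to the nearest integer pixel for seeding.
#'
#' @param contour a `ct_contour` with positive area.
#' @return numeric `c(row, col)`.
#' @export
contour_centroid <- function(contour) {
  stopifnot(inherits(contour, "ct_contour"))
  if (contour$area_px <= 0L)
    stop("cannot take the centroid of a zero-area contour", call. = FALSE)
  c(row = mean(contour$pixels[, 1L]), col = mean(contour$pixels[, 2L]))
}

# Constant-time point-in-region lookup for a contour.
region_lookup <- function(contour) {
  m <- matrix(FALSE, contour$shape[1], contour$shape[2])
  m[contour$pixels] <- TRUE
  m
}
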