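#' CT slice container
#'
#' A `ct_slice` bundles a 2-D gray-level pixel matrix with the physical
#' pixel spacing needed to apply size priors stated in centimetres.
#' Intensities are kept exactly as stored in the source file; the
#' segmentation threshold rule is relative (a fraction of the intensity
#' range), so no calibration to Hounsfield units is required.
#'
#' @param pixels numeric or integer matrix of gray intensities
#'   (rows x cols).
#' @param spacing_mm isotropic pixel spacing in millimetres per pixel.
#' @param source_path provenance string (file of origin, or
#'   `"<synthetic>"`).
#' @param bit_depth integer bit depth of the source data (8 or 16 for
#'   raster formats; whatever `BitsStored` says for DICOM).
#'
#' @return An object of class `ct_slice` with fields `pixels`,
#'   `spacing_mm`, `source_path`, `bit_depth`.
#' @seealso [read_ct_slice()]
#' @export
ct_slice <- function(pixels, spacing_mm, source_path = "<memory>",
                     bit_depth = 8L) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("`pixels` contains non-finite intensities", call. = FALSE)
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L ||
      !is.finite(spacing_mm) || spacing_mm <= 0)
    stop("`spacing_mm` must be a single positive number", call. = FALSE)
  structure(
    list(pixels = pixels, spacing_mm = as.numeric(spacing_mm),
         source_path = as.character(source_path),
         bit_depth = as.integer(bit_depth)),
    class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %d x %d px, %.4g mm/px, %d-bit, range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_mm, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  cat("  source:", x$source_path, "\n")
  invisible(x)
}

#' Read a CT slice from DICOM, PNG or TIFF
#'
#' DICOM files carry their own `PixelSpacing`; raster formats (PNG,
#' TIFF) do not, so `spacing_override` is mandatory for them.
#' Intensities are returned at native bit depth, never rescaled: the
#' minimum/maximum of the returned matrix equal the stored file values.
#' Anisotropic DICOM spacing is reduced to the mean of the row/column
#' spacings with a warning.
#'
#' @param path path to a `.dcm`, `.png`, `.tif`/`.tiff` file.  Format is
#'   detected from the file content (DICM magic / PNG signature), with
#'   the extension as fallback.
#' @param spacing_override pixel spacing in mm/pixel.  Optional for
#'   DICOM (overrides the header), required for PNG/TIFF.
#' @return A [ct_slice()].
#' @export
read_ct_slice <- function(path, spacing_override = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read CT slice: file not found: ", path, call. = FALSE)
  if (!is.null(spacing_override)) {
    if (!is.numeric(spacing_override) || length(spacing_override) != 1L ||
        !is.finite(spacing_override) || spacing_override <= 0)
      stop("`spacing_override` must be a single positive number in mm/pixel",
           call. = FALSE)
  }
  fmt <- detect_image_format(path)
  if (fmt == "dicom") {
    dcm <- read_dicom_slice(path)
    spacing <- if (!is.null(spacing_override)) spacing_override else
      dcm$spacing_mm
    if (is.null(spacing))
      stop("DICOM file has no PixelSpacing; supply `spacing_override`",
           call. = FALSE)
    return(ct_slice(dcm$pixels, spacing, path, dcm$bit_depth))
  }
  if (is.null(spacing_override))
    stop("PNG/TIFF input carries no pixel spacing; ",
         "`spacing_override` (mm/pixel) is required", call. = FALSE)
  raw01 <- switch(fmt,
    png  = png::readPNG(path),
    tiff = tiff::readTIFF(path),
    stop("unsupported image format for ", path, call. = FALSE))
  if (length(dim(raw01)) == 3L) raw01 <- raw01[, , 1L]   # drop channels
  # readPNG/readTIFF normalize to [0,1] and drop the bit depth; recover
  # it: 8-bit data are exact multiples of 1/255.
  depth <- if (all(abs(raw01 * 255 - round(raw01 * 255)) < 1e-9)) 8L else 16L
  px <- round(raw01 * (2^depth - 1))
  storage.mode(px) <- "integer"
  ct_slice(px, spacing_override, path, depth)
}

detect_image_format <- function(path) {
  hdr <- readBin(path, "raw", n = 132L)
  if (length(hdr) >= 132L && rawToChar(hdr[129:132]) == "DICM")
    return("dicom")
  if (length(hdr) >= 8L &&
      identical(hdr[1:8], as.raw(c(0x89, 0x50, 0x4e, 0x47,
                                   0x0d, 0x0a, 0x1a, 0x0a))))
    return("png")
  if (length(hdr) >= 4L &&
      (identical(hdr[1:4], as.raw(c(0x49, 0x49, 0x2a, 0x00))) ||
       identical(hdr[1:4], as.raw(c(0x4d, 0x4d, 0x00, 0x2a)))))
    return("tiff")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         dcm = "dicom", png = "png", tif = "tiff", tiff = "tiff",
         stop("cannot identify image format of ", path, call. = FALSE))
}

#' Write a binary mask losslessly to PNG
#'
#' The round trip `write_mask()` then [read_mask()] is bit-exact for any
#' binary matrix.
#'
#' @param mask logical or 0/1 matrix.
#' @param path output `.png` path.
#' @param slice_shape optional `c(rows, cols)`; when given, `mask` must
#'   have exactly this shape (guards against writing a mask for the
#'   wrong slice).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, slice_shape = NULL) {
  mask <- as_binary_mask(mask)
  if (!is.null(slice_shape) && !identical(dim(mask), as.integer(slice_shape)))
    stop(sprintf("mask shape %d x %d does not match slice shape %d x %d",
                 nrow(mask), ncol(mask), slice_shape[1], slice_shape[2]),
         call. = FALSE)
  ok <- tryCatch({
    png::writePNG(mask * 1.0, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write mask to ", path, call. = FALSE)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#'
#' @param path PNG path; any strictly positive pixel is foreground.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    stop("cannot read mask: file not found: ", path, call. = FALSE)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m > 0
}

as_binary_mask <- function(mask) {
  if (!is.matrix(mask))
    stop("mask must be a matrix", call. = FALSE)
  if (is.logical(mask)) return(mask)
  u <- unique(as.vector(mask))
  if (!all(u %in% c(0, 1)))
    stop("mask must be binary (logical or 0/1)", call. = FALSE)
  mask > 0
}

#' Build a segmentation report
#'
#' Flattens a [segment_tumor()] result (one candidate) into the
#' serializable per-seed audit trail: seed coordinates, the gray
#' tolerance each seed grew with, grown area and maximum size, and the
#' credibility verdict.  When a ground-truth mask is supplied, Dice and
#' Jaccard distance of the combined mask are included.
#'
#' @param result a `segmentation_result` (one element of
#'   `segment_tumor()$candidates`).
#' @param truth optional ground-truth binary mask of the same shape.
#' @return list of class `segmentation_report`.
#' @export
build_report <- function(result, truth = NULL) {
  stopifnot(inherits(result, "segmentation_result"))
  entries <- lapply(result$regions, function(rg) {
    list(seed = as.integer(rg$seed),
         threshold = rg$threshold,
         area_px = as.integer(rg$area_px),
         max_size_px = rg$max_size_cm / result$spacing_mm * 10,
         credible = rg$credible)
  })
  rep <- list(
    per_seed_entries = entries,
    combined_area_px = as.integer(sum(result$combined_mask)),
    boundary_polygon = result$boundary,
    restriction_mode = result$restriction_mode,
    status = result$status)
  if (!is.null(truth)) {
    truth <- as_binary_mask(truth)
    if (!identical(dim(truth), dim(result$combined_mask)))
      stop("truth mask shape does not match segmentation", call. = FALSE)
    pr <- eval_pair(truth, result$combined_mask)
    rep$dice <- dice(pr)
    rep$jaccard_distance <- jaccard_distance(pr)
  }
  class(rep) <- "segmentation_report"
  rep
}

#' Serialize a segmentation report to JSON
#'
#' Every populated field is written; `dice` / `jaccard_distance` appear
#' only when the report was built with a ground-truth mask.  Numbers are
#' serialized at full precision so the file parses back to an equal
#' structure.
#'
#' @param report a `segmentation_report` from [build_report()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "segmentation_report"))
  x <- unclass(report)
  if (!is.null(x$boundary_polygon))
    x$boundary_polygon <- unname(apply(x$boundary_polygon, 1L, as.integer,
                                       simplify = FALSE))
  ok <- tryCatch({
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write report to ", path, call. = FALSE)
  invisible(path)
}
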