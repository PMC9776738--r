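# Minimal single-frame DICOM reader.
#
# Scope is deliberately narrow: Part-10 files (128-byte preamble +
# "DICM"), little-endian transfer syntaxes (implicit 1.2.840.10008.1.2
# or explicit 1.2.840.10008.1.2.1), one uncompressed monochrome frame,
# 8 or 16 bits allocated.  That covers the CT slices this package
# consumes; compressed syntaxes and multi-frame objects are rejected
# with a clear error.

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte
# length instead of a 2-byte length.
LONG_VRS <- c("OB", "OW", "OF", "OL", "OD", "SQ", "UT", "UC", "UR", "UN")

read_u16 <- function(buf, pos) {
  as.integer(buf[pos]) + 256L * as.integer(buf[pos + 1L])
}
read_u32 <- function(buf, pos) {
  # kept in double: 32-bit lengths can exceed .Machine$integer.max
  as.numeric(buf[pos]) + 256 * as.numeric(buf[pos + 1L]) +
    65536 * as.numeric(buf[pos + 2L]) + 16777216 * as.numeric(buf[pos + 3L])
}

# Returns list(pixels, spacing_mm or NULL, bit_depth).
read_dicom_slice <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 140L || rawToChar(buf[129:132]) != "DICM")
    stop("not a Part-10 DICOM file (missing DICM magic): ", path,
         call. = FALSE)
  pos <- 133L

  # File meta group (0002,xxxx) is always explicit little-endian.
  ts <- TS_EXPLICIT_LE
  repeat {
    if (pos + 7L > length(buf)) stop("truncated DICOM meta header",
                                     call. = FALSE)
    grp <- read_u16(buf, pos)
    if (grp != 2L) break
    el <- read_u16(buf, pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (vr %in% LONG_VRS) {
      len <- read_u32(buf, pos + 8L); hdr <- 12L
    } else {
      len <- read_u16(buf, pos + 6L); hdr <- 8L
    }
    if (el == 0x0010) {
      bytes <- buf[(pos + hdr):(pos + hdr + len - 1L)]
      ts <- trimws(rawToChar(bytes[bytes != as.raw(0L)]))
    }
    pos <- pos + hdr + as.integer(len)
  }
  explicit <- if (ts == TS_IMPLICIT_LE) FALSE
    else if (ts == TS_EXPLICIT_LE) TRUE
    else stop("unsupported DICOM transfer syntax: ", ts,
              " (only uncompressed little-endian is handled)",
              call. = FALSE)

  rows <- cols <- bits_alloc <- bits_stored <- NA_integer_
  pixel_rep <- 0L
  spacing <- NULL
  pixel_raw <- NULL
  while (pos + 7L <= length(buf)) {
    grp <- read_u16(buf, pos)
    el <- read_u16(buf, pos + 2L)
    if (explicit) {
      vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
      if (vr %in% LONG_VRS) {
        len <- read_u32(buf, pos + 8L); hdr <- 12L
      } else {
        len <- read_u16(buf, pos + 6L); hdr <- 8L
      }
    } else {
      len <- read_u32(buf, pos + 4L); hdr <- 8L
    }
    if (len == 4294967295) # undefined length => encapsulated/sequence
      stop("undefined-length DICOM element encountered; ",
           "compressed or sequence pixel data is not supported",
           call. = FALSE)
    val_at <- pos + hdr
    value <- function() buf[val_at:(val_at + as.integer(len) - 1L)]
    if (grp == 0x0028) {
      if (el == 0x0010) rows <- read_u16(buf, val_at)
      if (el == 0x0011) cols <- read_u16(buf, val_at)
      if (el == 0x0030) {
        parts <- strsplit(trimws(rawToChar(value())), "\\\\")[[1]]
        sp <- suppressWarnings(as.numeric(parts))
        sp <- sp[is.finite(sp)]
        if (length(sp) >= 1L) {
          if (length(sp) >= 2L && abs(sp[1] - sp[2]) > 1e-9)
            warning("anisotropic PixelSpacing ", sp[1], " x ", sp[2],
                    " mm; using the mean", call. = FALSE)
          spacing <- mean(sp[1:min(2L, length(sp))])
        }
      }
      if (el == 0x0100) bits_alloc <- read_u16(buf, val_at)
      if (el == 0x0101) bits_stored <- read_u16(buf, val_at)
      if (el == 0x0103) pixel_rep <- read_u16(buf, val_at)
    }
    if (grp == 0x7FE0 && el == 0x0010) {
      pixel_raw <- value()
      break
    }
    pos <- val_at + as.integer(len)
  }

  if (is.null(pixel_raw) || is.na(rows) || is.na(cols))
    stop("DICOM file lacks Rows/Columns/PixelData: ", path, call. = FALSE)
  if (is.na(bits_alloc)) bits_alloc <- 16L
  if (is.na(bits_stored)) bits_stored <- bits_alloc
  n <- rows * cols
  px <- if (bits_alloc == 8L) {
    as.integer(pixel_raw[seq_len(n)])
  } else if (bits_alloc == 16L) {
    v <- readBin(pixel_raw, "integer", n = n, size = 2L,
                 signed = pixel_rep == 1L, endian = "little")
    if (pixel_rep == 0L) v[v < 0] <- v[v < 0] + 65536L
    v
  } else stop("unsupported BitsAllocated: ", bits_alloc, call. = FALSE)
  # DICOM pixel data is row-major; R matrices are column-major.
  mat <- matrix(px, nrow = rows, ncol = cols, byrow = TRUE)
  list(pixels = mat, spacing_mm = spacing, bit_depth = as.integer(bits_stored))
}
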