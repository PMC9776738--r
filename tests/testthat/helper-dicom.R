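# Byte-level DICOM writer fixture, independent of the package's
# reader.  Emits minimal Part-10 files: 128-byte preamble, "DICM",
# a file-meta TransferSyntaxUID element, then Rows / Columns /
# PixelSpacing / BitsAllocated / BitsStored / PixelRepresentation /
# PixelData in either explicit or implicit little-endian VR.

u16le <- function(x) as.raw(c(x %% 256L, x %/% 256L))
u32le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                              (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

dcm_str <- function(s, pad = " ") {
  b <- charToRaw(s)
  if (length(b) %% 2L == 1L) b <- c(b, charToRaw(pad))
  b
}

# One dataset element.  vr = NULL writes implicit VR.
dcm_elem <- function(group, elem, vr, value) {
  tag <- c(u16le(group), u16le(elem))
  if (is.null(vr)) return(c(tag, u32le(length(value)), value))
  if (vr %in% c("OB", "OW"))
    c(tag, charToRaw(vr), as.raw(c(0L, 0L)), u32le(length(value)), value)
  else
    c(tag, charToRaw(vr), u16le(length(value)), value)
}

# pixels: integer matrix (row, col); written row-major, unsigned.
write_dicom_fixture <- function(path, pixels, spacing_mm = NULL,
                                bits = 16L, explicit = TRUE) {
  ts <- if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
  meta <- dcm_elem(0x0002L, 0x0010L, "UI", {
    b <- charToRaw(ts)
    if (length(b) %% 2L == 1L) b <- c(b, as.raw(0L))  # UI pads with NUL
    b
  })
  vr <- function(v) if (explicit) v else NULL
  body <- c(
    dcm_elem(0x0028L, 0x0010L, vr("US"), u16le(nrow(pixels))),
    dcm_elem(0x0028L, 0x0011L, vr("US"), u16le(ncol(pixels))))
  if (!is.null(spacing_mm)) {
    sp <- paste(format(spacing_mm), format(spacing_mm), sep = "\\")
    body <- c(body, dcm_elem(0x0028L, 0x0030L, vr("DS"), dcm_str(sp)))
  }
  body <- c(body,
    dcm_elem(0x0028L, 0x0100L, vr("US"), u16le(bits)),
    dcm_elem(0x0028L, 0x0101L, vr("US"), u16le(bits)),
    dcm_elem(0x0028L, 0x0103L, vr("US"), u16le(0L)))
  vals <- as.integer(t(pixels))          # row-major
  pix <- if (bits == 8L) as.raw(vals) else
    as.raw(as.vector(rbind(vals %% 256L, vals %/% 256L)))
  if (length(pix) %% 2L == 1L) pix <- c(pix, as.raw(0L))
  body <- c(body, dcm_elem(0x7FE0L, 0x0010L, vr("OW"), pix))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(rep(as.raw(0L), 128L), charToRaw("DICM"), meta, body), con)
  invisible(path)
}
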