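## Minimal baseline TIFF support: uncompressed, single-strip, grayscale,
## 8- or 16-bit, little-endian. No TIFF package exists in the dependency
## stack; this covers exactly the layout the image simulator emits and a
## plain subset of what microscopes export.

#' Write a matrix as a grayscale TIFF
#'
#' @param img numeric or integer matrix (row = y). Values are rounded and
#'   clamped to the sample range.
#' @param path output file.
#' @param bits 16 (default) or 8 bits per sample.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path, bits = 16) {
  .sn_assert(bits %in% c(8, 16), "bits must be 8 or 16")
  h <- nrow(img); w <- ncol(img)
  maxv <- 2^bits - 1
  v <- as.integer(pmin(pmax(round(img), 0), maxv))
  # row-major pixel order
  v <- as.vector(t(matrix(v, h, w)))
  n_entries <- 8L
  ifd_off <- 8L
  data_off <- ifd_off + 2L + n_entries * 12L + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off, con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3) {  # SHORT: left-justified in the 4-byte slot
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(n_entries, con, size = 2, endian = "little")
  entry(256, 4, 1, w)                    # ImageWidth
  entry(257, 4, 1, h)                    # ImageLength
  entry(258, 3, 1, bits)                 # BitsPerSample
  entry(259, 3, 1, 1)                    # Compression = none
  entry(262, 3, 1, 1)                    # Photometric = BlackIsZero
  entry(273, 4, 1, data_off)             # StripOffsets
  entry(278, 4, 1, h)                    # RowsPerStrip
  entry(279, 4, 1, w * h * bits / 8)     # StripByteCounts
  writeBin(0L, con, size = 4, endian = "little")  # next IFD
  writeBin(v, con, size = bits / 8, endian = "little")
  invisible(path)
}

#' Read a grayscale TIFF written by [write_tiff()] (baseline subset)
#'
#' @param path file path.
#' @return integer matrix (row = y).
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  .sn_assert(length(raw) > 8, "not a TIFF: file too small")
  le <- rawToChar(raw[1:2]) == "II"
  .sn_assert(le || rawToChar(raw[1:2]) == "MM", "not a TIFF")
  end <- if (le) "little" else "big"
  getint <- function(off, size) {
    readBin(raw[(off + 1):(off + size)], "integer", size = size,
            endian = end, signed = FALSE)
  }
  get32 <- function(off) {
    readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = end)
  }
  ifd <- get32(4)
  n <- getint(ifd, 2)
  tags <- list()
  for (i in seq_len(n)) {
    e <- ifd + 2 + (i - 1) * 12
    tag <- getint(e, 2); type <- getint(e + 2, 2)
    val <- if (type == 3) getint(e + 8, 2) else get32(e + 8)
    tags[[as.character(tag)]] <- val
  }
  w <- tags[["256"]]; h <- tags[["257"]]
  bits <- if (is.null(tags[["258"]])) 1 else tags[["258"]]
  comp <- if (is.null(tags[["259"]])) 1 else tags[["259"]]
  .sn_assert(comp == 1, "only uncompressed TIFF supported")
  .sn_assert(bits %in% c(8, 16), "only 8/16-bit grayscale supported")
  off <- tags[["273"]]
  npx <- w * h
  v <- readBin(raw[(off + 1):(off + npx * bits / 8)], "integer",
               n = npx, size = bits / 8, endian = end, signed = FALSE)
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a channel stack (channels + masks + region labels) as TIFFs
#'
#' One 16-bit intensity TIFF per channel, one 16-bit label TIFF per truth
#' mask (`<name>_mask.tif`), `regions.tif` when a region mask is present,
#' and `truth.json` with the per-object table.
#'
#' @param stack a `channel_stack` from [simulate_images()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_channel_stack <- function(stack, dir) {
  .sn_assert(inherits(stack, "channel_stack"),
             "stack must be a channel_stack")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in names(stack$channels))
    write_tiff(stack$channels[[ch]], file.path(dir, paste0(ch, ".tif")))
  for (ch in names(stack$masks))
    write_tiff(stack$masks[[ch]],
               file.path(dir, paste0(ch, "_mask.tif")))
  if (!is.null(stack$region_mask))
    write_tiff(stack$region_mask, file.path(dir, "regions.tif"))
  if (!is.null(attr(stack, "truth")))
    write_truth_json(stack, file.path(dir, "truth.json"))
  invisible(dir)
}
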