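#' Load a fluorescence micrograph as the GFP channel
#'
#' Reads an 8- or 16-bit PNG or TIFF, isolates the GFP signal channel and
#' normalizes to the 0--255 scale all thresholds are defined on:
#'
#' * RGB / RGBA inputs yield the **green channel only** (GFP-labeled cells are
#'   imaged in green); alpha channels are ignored.
#' * grayscale inputs pass through unchanged.
#' * 16-bit inputs are linearly rescaled by 255/65535 -- deliberately not
#'   percentile-stretched, since the 0--50 threshold sweep is meaningful only
#'   on a fixed absolute scale.
#'
#' The file format is detected from the magic bytes, not the extension. TIFF
#' support covers baseline uncompressed files (both byte orders, 8/16-bit,
#' grayscale and RGB(A), chunky layout).
#'
#' @param path path to a readable PNG or TIFF file.
#' @return An [intensity_image()].
#' @export
load_gfp_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("`path` must be a single file path", call. = FALSE)
  if (!file.exists(path))
    stop("cannot read image: no such file: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) >= 4L && identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
    load_png_gfp(path)
  } else if (length(magic) >= 4L &&
             (identical(magic[1:2], charToRaw("II")) ||
              identical(magic[1:2], charToRaw("MM")))) {
    load_tiff_gfp(path)
  } else {
    stop("unsupported image format (expected PNG or TIFF): ", path,
         call. = FALSE)
  }
}

load_png_gfp <- function(path) {
  px <- png::readPNG(path)  # normalized to [0, 1] for any source depth
  # source bit depth from the IHDR chunk (offset 24 of the file)
  hdr <- readBin(path, "raw", n = 25L)
  depth <- as.integer(hdr[25L])
  if (!depth %in% c(8L, 16L))
    stop("unsupported PNG bit depth ", depth, ": ", path, call. = FALSE)
  m <- extract_green(px, path)
  # x/255 * 255 and x/65535 * 255 both land within 1e-12 of the exact value;
  # snap so 8-bit sources are bit-exact integers again
  intensity_image(round(m * 255, 6L), depth)
}

load_tiff_gfp <- function(path) {
  tf <- read_tiff_baseline(path)
  m <- extract_green(tf$pixels, path)
  if (tf$bits == 16L) m <- m * (255 / 65535)
  intensity_image(round(m, 6L), tf$bits)
}

extract_green <- function(px, path) {
  if (is.matrix(px)) return(px)
  nc <- dim(px)[3L]
  if (nc == 2L) px[, , 1L]            # gray + alpha
  else if (nc %in% c(3L, 4L)) px[, , 2L]  # RGB(A): green channel
  else stop("unsupported channel layout (", nc, " channels): ", path,
            call. = FALSE)
}

#' Write an intensity image to PNG or TIFF
#'
#' Companion writer for phantoms and audit overlays. The format follows the
#' file extension (`.png`, `.tif`, `.tiff`). PNG output is 8-bit grayscale
#' (values rounded to the nearest integer); TIFF output is baseline
#' uncompressed grayscale at the requested bit depth, with 16-bit values
#' rescaled by 65535/255.
#'
#' @param image an [intensity_image()].
#' @param path destination path ending in `.png`, `.tif` or `.tiff`.
#' @param bits 8 or 16 (TIFF only; PNG is always written 8-bit).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 8L) {
  assert_image(image)
  ext <- tolower(tools::file_ext(path))
  m <- as_pixel_matrix(image)
  if (ext == "png") {
    png::writePNG(round(m) / 255, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    if (bits == 8L) write_tiff_baseline(round(m), path, bits = 8L)
    else if (bits == 16L) write_tiff_baseline(round(m * (65535 / 255)), path, bits = 16L)
    else stop("`bits` must be 8 or 16", call. = FALSE)
  } else {
    stop("unsupported output extension '.", ext, "' (use .png/.tif/.tiff)",
         call. = FALSE)
  }
  invisible(path)
}

# ---- minimal baseline TIFF codec -------------------------------------------
# Uncompressed striped TIFF only; enough for fluorescence stereomicroscope
# exports saved without compression. Both byte orders on read; little-endian
# single-strip chunky on write.

read_tiff_baseline <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("truncated TIFF: ", path, call. = FALSE)
  endian <- if (identical(raw[1:2], charToRaw("II"))) "little"
            else if (identical(raw[1:2], charToRaw("MM"))) "big"
            else stop("not a TIFF file: ", path, call. = FALSE)
  rd_u16 <- function(off, n = 1L)
    readBin(raw[(off + 1L):(off + 2L * n)], "integer", n = n, size = 2L,
            signed = FALSE, endian = endian)
  rd_u32 <- function(off, n = 1L) {
    v <- readBin(raw[(off + 1L):(off + 4L * n)], "integer", n = n, size = 4L,
                 endian = endian)
    ifelse(v < 0, v + 2^32, as.numeric(v))
  }
  if (rd_u16(2L) != 42L) stop("bad TIFF magic: ", path, call. = FALSE)
  ifd <- rd_u32(4L)
  n_entries <- rd_u16(ifd)
  tags <- list()
  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)
  for (i in seq_len(n_entries)) {
    off <- ifd + 2L + (i - 1L) * 12L
    tag <- rd_u16(off); typ <- rd_u16(off + 2L); cnt <- rd_u32(off + 4L)
    sz <- type_size[as.character(typ)]
    if (is.na(sz)) next
    val_off <- if (sz * cnt <= 4L) off + 8L else rd_u32(off + 8L)
    vals <- if (typ == 3L) rd_u16(val_off, cnt)
            else if (typ == 4L) rd_u32(val_off, cnt)
            else if (typ == 1L) as.integer(raw[(val_off + 1L):(val_off + cnt)])
            else NULL
    if (!is.null(vals)) tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default))
        stop("TIFF missing required tag ", tag, ": ", path, call. = FALSE)
      default
    } else v
  }
  w <- need(256L); h <- need(257L)
  bits <- need(258L, 8L); spp <- need(277L, 1L)
  comp <- need(259L, 1L)
  planar <- need(284L, 1L)
  if (comp != 1L)
    stop("unsupported TIFF compression (", comp,
         "); only uncompressed baseline TIFF is supported: ", path,
         call. = FALSE)
  if (planar != 1L)
    stop("unsupported TIFF planar configuration: ", path, call. = FALSE)
  if (length(unique(bits)) != 1L || !bits[1L] %in% c(8L, 16L))
    stop("unsupported TIFF bit depth (", paste(bits, collapse = "/"),
         "): ", path, call. = FALSE)
  bits <- bits[1L]
  if (spp > 4L)
    stop("unsupported channel layout (", spp, " channels): ", path,
         call. = FALSE)
  offs <- need(273L); cnts <- need(279L, rep(w * h * spp * bits / 8, 1L))
  data <- raw(0L)
  for (i in seq_along(offs))
    data <- c(data, raw[(offs[i] + 1L):(offs[i] + cnts[i])])
  n_px <- w * h * spp
  vals <- if (bits == 8L) as.integer(data[seq_len(n_px)])
          else readBin(data, "integer", n = n_px, size = 2L, signed = FALSE,
                       endian = endian)
  # chunky layout: samples interleaved within row-major pixel order
  if (spp == 1L) {
    px <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    px <- array(0, c(h, w, spp))
    for (s in seq_len(spp))
      px[, , s] <- matrix(vals[seq(s, n_px, by = spp)], nrow = h, ncol = w,
                          byrow = TRUE)
  }
  list(pixels = px, bits = as.integer(bits), samples = as.integer(spp))
}

write_tiff_baseline <- function(pixels, path, bits = 8L) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  h <- dim(pixels)[1L]; w <- dim(pixels)[2L]; spp <- dim(pixels)[3L]
  stopifnot(bits %in% c(8L, 16L), spp %in% c(1L, 3L))
  maxv <- 2^bits - 1
  if (min(pixels) < 0 || max(pixels) > maxv)
    stop("pixel values out of range for ", bits, "-bit TIFF", call. = FALSE)
  # interleave samples in row-major order
  flat <- integer(h * w * spp)
  for (s in seq_len(spp))
    flat[seq(s, length(flat), by = spp)] <- as.integer(t(pixels[, , s]))
  con <- file(path, "wb")
  on.exit(close(con))
  wr_u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wr_u32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  entry <- function(tag, typ, cnt, val) { wr_u16(tag); wr_u16(typ); wr_u32(cnt)
    if (typ == 3L && cnt == 1L) { wr_u16(val); wr_u16(0L) } else wr_u32(val) }
  n_entries <- 10L
  ifd_off <- 8L
  after_ifd <- ifd_off + 2L + n_entries * 12L + 4L
  bps_off <- after_ifd                       # external BitsPerSample (spp = 3)
  data_off <- if (spp == 3L) after_ifd + 6L else after_ifd
  n_bytes <- length(flat) * bits / 8
  writeBin(charToRaw("II"), con); wr_u16(42L); wr_u32(ifd_off)
  wr_u16(n_entries)
  entry(256L, 4L, 1L, w)
  entry(257L, 4L, 1L, h)
  if (spp == 1L) entry(258L, 3L, 1L, bits) else entry(258L, 3L, 3L, bps_off)
  entry(259L, 3L, 1L, 1L)                              # uncompressed
  entry(262L, 3L, 1L, if (spp == 3L) 2L else 1L)       # photometric
  entry(273L, 4L, 1L, data_off)
  entry(277L, 3L, 1L, spp)
  entry(278L, 4L, 1L, h)                               # one strip
  entry(279L, 4L, 1L, n_bytes)
  entry(284L, 3L, 1L, 1L)                              # chunky
  wr_u32(0L)                                           # no next IFD
  if (spp == 3L) { wr_u16(bits); wr_u16(bits); wr_u16(bits) }
  if (bits == 8L) writeBin(as.raw(flat), con)
  else writeBin(flat, con, size = 2L, endian = "little")
  invisible(path)
}
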