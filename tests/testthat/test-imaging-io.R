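test_that("intensity_image validates its invariants", {
  expect_s3_class(intensity_image(matrix(0, 1, 1)), "intensity_image")
  expect_error(intensity_image(matrix(-1, 2, 2)), "\\[0, 255\\]")
  expect_error(intensity_image(matrix(256, 2, 2)), "\\[0, 255\\]")
  expect_error(intensity_image(matrix(NA_real_, 2, 2)), "NA")
  expect_error(intensity_image(1:4), "matrix")
  expect_error(intensity_image(matrix(0, 2, 2), source_depth = 12), "8 or 16")
})

test_that("PNG loading extracts the green channel and passes grayscale through", {
  d <- withr::local_tempdir()
  # 8-bit RGB with green uniformly 128
  rgb <- array(0, c(5, 7, 3)); rgb[, , 2] <- 128 / 255; rgb[, , 1] <- 33 / 255
  f <- file.path(d, "rgb.png"); png::writePNG(rgb, f)
  img <- load_gfp_image(f)
  expect_true(all(img == 128))
  expect_equal(dim(img), c(5L, 7L))
  # RGBA: alpha ignored
  rgba <- array(runif(5 * 7 * 4), c(5, 7, 4))
  f2 <- file.path(d, "rgba.png"); png::writePNG(rgba, f2)
  expect_equal(as.vector(unclass(load_gfp_image(f2))),
               as.vector(round(round(rgba[, , 2] * 255) / 255 * 255, 6)))
  # grayscale passthrough
  g <- matrix(sample(0:255, 35), 5, 7)
  f3 <- file.path(d, "gray.png"); png::writePNG(g / 255, f3)
  expect_equal(as.vector(unclass(load_gfp_image(f3))), as.vector(g))
  expect_identical(attr(load_gfp_image(f3), "source_depth"), 8L)
})

test_that("16-bit inputs are linearly rescaled by 255/65535", {
  d <- withr::local_tempdir()
  v16 <- matrix(c(0L, 1000L, 32768L, 65535L), 2, 2)
  img0 <- intensity_image(v16 / 65535 * 255)  # bypass writer scaling
  f <- file.path(d, "g16.tif")
  xenoquant:::write_tiff_baseline(v16, f, bits = 16L)
  img <- load_gfp_image(f)
  expect_identical(attr(img, "source_depth"), 16L)
  expect_equal(max(img), 255)                       # 65535 -> 255 endpoint
  expect_equal(as.vector(unclass(img)),
               as.vector(round(v16 * 255 / 65535, 6)))
  # monotone: rescaling preserves pixel ordering
  set.seed(4)
  raw16 <- matrix(sample(0:65535, 100), 10, 10)
  xenoquant:::write_tiff_baseline(raw16, f, bits = 16L)
  expect_identical(order(as.vector(unclass(load_gfp_image(f)))),
                   order(as.vector(raw16)))
})

test_that("hand-assembled baseline TIFFs decode to the expected pixels", {
  # 2 x 3 grayscale, both byte orders, built byte-by-byte (independent of
  # the package writer)
  build_tiff <- function(path, endian) {
    con <- file(path, "wb"); on.exit(close(con))
    u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = endian)
    u32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = endian)
    writeBin(charToRaw(if (endian == "little") "II" else "MM"), con)
    u16(42L); u32(8L)
    u16(8L)  # entries
    ent <- function(tag, typ, cnt, val) { u16(tag); u16(typ); u32(cnt)
      if (typ == 3L) { u16(val); u16(0L) } else u32(val) }
    ent(256L, 4L, 1L, 3L)       # width 3
    ent(257L, 4L, 1L, 2L)       # height 2
    ent(258L, 3L, 1L, 8L)
    ent(259L, 3L, 1L, 1L)
    ent(262L, 3L, 1L, 1L)
    ent(273L, 4L, 1L, 110L)     # strip offset
    ent(278L, 4L, 1L, 2L)
    ent(279L, 4L, 1L, 6L)
    u32(0L)
    writeBin(raw(110L - 10L - 8L * 12L - 4L), con)  # pad to offset 110
    writeBin(as.raw(c(10L, 20L, 30L, 40L, 50L, 60L)), con)
  }
  d <- withr::local_tempdir()
  for (endian in c("little", "big")) {
    f <- file.path(d, paste0(endian, ".tif"))
    build_tiff(f, endian)
    img <- load_gfp_image(f)
    expect_equal(unclass(img),
                 matrix(c(10, 20, 30, 40, 50, 60), 2, 3, byrow = TRUE),
                 ignore_attr = TRUE, info = endian)
  }
})

test_that("TIFF writer roundtrips 8-bit gray and RGB through the reader", {
  d <- withr::local_tempdir()
  set.seed(11)
  m <- matrix(sample(0:255, 12 * 18, TRUE), 12, 18)
  f <- file.path(d, "g.tif")
  write_image(intensity_image(m), f)
  expect_equal(as.vector(unclass(load_gfp_image(f))), as.vector(m))
  # RGB: reader must return the green plane
  rgb <- array(sample(0:255, 6 * 5 * 3, TRUE), c(6, 5, 3))
  f2 <- file.path(d, "rgb.tif")
  xenoquant:::write_tiff_baseline(rgb, f2, bits = 8L)
  expect_equal(as.vector(unclass(load_gfp_image(f2))), as.vector(rgb[, , 2]))
})

test_that("loader errors name the path and reject unknown layouts", {
  expect_error(load_gfp_image("/nonexistent/embryo.png"),
               "/nonexistent/embryo.png")
  d <- withr::local_tempdir()
  junk <- file.path(d, "junk.png")
  writeBin(as.raw(1:32), junk)
  expect_error(load_gfp_image(junk), "unsupported image format")
})

test_that("crop_roi follows 0-based half-open extents and checks bounds", {
  m <- matrix(seq_len(100 * 100), 100, 100)
  m <- m / max(m) * 255
  img <- intensity_image(m)
  expect_equal(unclass(crop_roi(img, c(0, 0, 100, 100))), unclass(img),
               ignore_attr = TRUE)
  sub <- crop_roi(img, c(10, 20, 10, 15))
  expect_equal(dim(sub), c(10L, 15L))
  expect_equal(unclass(sub), m[11:20, 21:35], ignore_attr = TRUE)
  expect_error(crop_roi(img, c(95, 0, 10, 10)), "outside")
  expect_error(crop_roi(img, c(0, 0, 0, 10)), ">= 1")
})

test_that("load-then-crop commutes with cropping the in-memory array", {
  d <- withr::local_tempdir()
  set.seed(21)
  m <- matrix(sample(0:255, 40 * 30, TRUE), 40, 30)
  f <- file.path(d, "a.png")
  write_image(intensity_image(m), f)
  rect <- c(5, 8, 12, 9)
  a <- crop_roi(load_gfp_image(f), rect)
  b <- intensity_image(m[6:17, 9:17])
  expect_equal(unclass(a), unclass(b), ignore_attr = TRUE)
})
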