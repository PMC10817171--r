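test_that("DICOM write/read round-trips pixels and metadata bit-exactly", {
  set.seed(3)
  px <- matrix(sample.int(4000, 48 * 40, replace = TRUE) - 1L, 48, 40)
  img <- image2d(px + 0, "SPGR", tr = 5.2, te = 2.5, fa = 18,
                 pixel_spacing = c(0.977, 0.977))
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(img, f)
  back <- read_dicom_slice(f)
  expect_identical(back$pixels, img$pixels)
  expect_equal(back$tr, 5.2)
  expect_equal(back$te, 2.5)
  expect_equal(back$fa, 18)
  expect_identical(back$modality, "SPGR")
  expect_equal(back$pixel_spacing, c(0.977, 0.977))

  ir <- image2d(px + 0, "IR", tr = 7800, ti = 200)
  f2 <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(ir, f2)
  back2 <- read_dicom_slice(f2)
  expect_identical(back2$modality, "IR")
  expect_equal(back2$ti, 200)
})

test_that("rescale slope/intercept are applied on read", {
  # stored value 100 with slope 2, intercept -10 must read as pixel 190
  px <- matrix(190, 4, 4)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(image2d(px), f, rescale = c(2, -10))
  back <- read_dicom_slice(f)
  expect_identical(back$pixels, px)

  # independent byte-level check: the stored uint16s really are 100
  bytes <- readBin(f, "raw", file.info(f)$size)
  n <- length(bytes)
  pix <- bytes[(n - 31):n]  # 16 pixels * 2 bytes
  stored <- as.integer(pix[seq(1, 32, 2)]) + 256L * as.integer(pix[seq(2, 32, 2)])
  expect_identical(stored, rep(100L, 16))
})

test_that("degenerate DICOM inputs are rejected, not repaired", {
  f <- withr::local_tempfile(fileext = ".dcm")
  writeBin(as.raw(rep(0, 200)), f)
  expect_error(read_dicom_slice(f), "DICM")

  # a valid file with the PixelData element stripped
  g <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(image2d(matrix(1, 4, 4)), g)
  bytes <- readBin(g, "raw", file.info(g)$size)
  # PixelData tag (7FE0,0010) little endian: E0 7F 10 00
  tagpos <- which(bytes == as.raw(0xE0))
  tagpos <- tagpos[bytes[tagpos + 1] == as.raw(0x7F)][1]
  writeBin(bytes[1:(tagpos - 1)], g)
  expect_error(read_dicom_slice(g), "PixelData")

  # non-integer images are quantized with a warning on write
  h <- withr::local_tempfile(fileext = ".dcm")
  expect_warning(write_dicom(image2d(matrix(runif(16), 4, 4)), h),
                 "quantized")
})

test_that("window_minmax and dicom_to_jpeg produce 8-bit windowed output", {
  two <- matrix(0, 8, 8)
  two[, 5:8] <- 100
  w <- window_minmax(two)
  expect_setequal(unique(as.vector(w)), c(0L, 255L))
  expect_warning(wc <- window_minmax(matrix(7, 4, 4)), "constant")
  expect_true(all(wc == 0L))

  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(image2d(two), f)
  jp <- withr::local_tempfile(fileext = ".jpg")
  dicom_to_jpeg(f, jp)
  out <- jpeg::readJPEG(jp)
  expect_identical(dim(out)[1:2], c(8L, 8L))
  # two-level image maps to the window endpoints (JPEG quantization slack)
  vals <- as.vector(out) * 255
  expect_lt(max(abs(vals - ifelse(vals > 128, 255, 0))), 6)

  # 16-bit linear ramp 0..1020 -> 8-bit ramp 0..255 within JPEG tolerance
  ramp <- matrix(rep(seq(0, 1020, length.out = 256), each = 16), 16, 256)
  fr <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(image2d(round(ramp)), fr)
  jr <- withr::local_tempfile(fileext = ".jpg")
  dicom_to_jpeg(fr, jr)
  ramp_out <- jpeg::readJPEG(jr) * 255
  oracle <- window_minmax(round(ramp))
  expect_lt(max(abs(ramp_out - oracle)), 4)
})

test_that("measurement tables read, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  set.seed(17)
  df <- data.frame(subject = 1:23,
                   qT1_observer1 = round(runif(23, 1200, 2500), 1),
                   qT1_observer2 = round(runif(23, 1200, 2500), 1))
  write.csv(df, f, row.names = FALSE)
  tab <- suppressMessages(read_measurement_table(f))
  expect_s3_class(tab, "measurement_table")
  expect_equal(nrow(tab), 23)
  expect_equal(tab$value1, df$qT1_observer1)

  # write-then-read round trip
  g <- withr::local_tempfile(fileext = ".csv")
  write_measurement_table(tab, g)
  tab2 <- suppressMessages(read_measurement_table(g))
  expect_equal(tab2$value1, tab$value1)
  expect_equal(tab2$value2, tab$value2)

  # empty file
  e <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b", e)
  expect_error(suppressMessages(read_measurement_table(e)), "empty")

  # a negative value is rejected naming the row
  df$qT1_observer2[7] <- -5
  write.csv(df, f, row.names = FALSE)
  expect_error(suppressMessages(read_measurement_table(f)), "7")

  # unrecognised headers fall back to numeric columns with a warning
  h <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = c(1000, 1100, 1200), b = c(1010, 1090, 1210)), h,
            row.names = FALSE)
  expect_warning(tab3 <- suppressMessages(read_measurement_table(h)),
                 "numeric columns")
  expect_equal(nrow(tab3), 3)
})

test_that("ROI files validate and round-trip coordinates exactly", {
  roi <- list(
    seed = c(64, 64),
    polygons = list(
      whole = ellipse_polygon(c(63.5, 55), c(30, 22), 0.3, n = 12L)
    )
  )
  f <- withr::local_tempfile(fileext = ".json")
  write_roi_file(roi, f)
  back <- read_roi_file(f, shape = c(128, 128))
  expect_equal(back$seed, c(64, 64))
  expect_equal(back$polygons$whole$x, roi$polygons$whole$x)
  expect_equal(back$polygons$whole$y, roi$polygons$whole$y)

  two_vertex <- '{"polygons": {"p": {"x": [1, 2], "y": [3, 4]}}}'
  g <- withr::local_tempfile(fileext = ".json")
  writeLines(two_vertex, g)
  expect_error(read_roi_file(g), "at least 3")

  oob <- '{"seed": [500, 4], "polygons": {}}'
  writeLines(oob, g)
  expect_error(read_roi_file(g, shape = c(128, 128)), "outside")

  oob2 <- '{"polygons": {"p": {"x": [1, 200, 3], "y": [1, 2, 3]}}}'
  writeLines(oob2, g)
  expect_error(read_roi_file(g, shape = c(128, 128)), "out-of-bounds")
})

test_that("masks export as PNG", {
  m <- matrix(FALSE, 8, 8)
  m[3:5, 3:5] <- TRUE
  f <- withr::local_tempfile(fileext = ".png")
  write_mask_png(m, f)
  back <- png::readPNG(f)
  expect_equal(back, m * 1)
})
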