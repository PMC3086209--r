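test_that("TIFF write/read round-trips pixels, bit depth and calibration", {
  set.seed(42)
  cases <- list(
    list(px = matrix(sample(0:255, 60, TRUE), 6, 10), depth = 8L, pitch = NULL),
    list(px = matrix(sample(0:4095, 200, TRUE), 10, 20), depth = 12L, pitch = 0.305),
    list(px = matrix(sample(0:65535, 200, TRUE), 20, 10), depth = 16L, pitch = 1.11),
    list(px = matrix(4095L, 5, 7), depth = 16L, pitch = NULL),   # constant max-ish
    list(px = matrix(0L, 2, 2), depth = 8L, pitch = NULL)        # degenerate size
  )
  for (cs in cases) {
    img <- radiograph(cs$px, cs$depth, cs$pitch)
    tf <- withr::local_tempfile(fileext = ".tif")
    write_image(img, tf)
    back <- read_image(tf)
    expect_identical(back$pixels, img$pixels)
    expect_identical(back$bit_depth, img$bit_depth)
    if (is.null(cs$pitch)) {
      expect_null(back$pixel_pitch_um)
    } else {
      expect_equal(back$pixel_pitch_um, cs$pitch)
    }
  }
})

test_that("12-bit data in a 16-bit container is recognized", {
  px <- matrix(c(0L, 1000L, 4095L, 7L), 2, 2)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_image(radiograph(px, 12L), tf)
  expect_identical(read_image(tf)$bit_depth, 12L)           # via metadata tag
  expect_identical(read_image(tf, bit_depth = 12)$bit_depth, 12L)

  # without the tag, 16-bit storage stays 16-bit unless overridden
  write_image(radiograph(px, 16L), tf)
  expect_identical(read_image(tf)$bit_depth, 16L)
  expect_identical(read_image(tf, bit_depth = 12)$bit_depth, 12L)

  # override refused when values exceed the 12-bit range
  write_image(radiograph(matrix(c(5000L, 0L, 1L, 2L), 2, 2), 16L), tf)
  expect_error(read_image(tf, bit_depth = 12), class = "microrad_validation_error")
})

test_that("radiograph construction enforces its invariants", {
  expect_error(radiograph(matrix(0:3, 1, 4)), class = "microrad_validation_error")
  expect_error(radiograph(matrix(-1:2, 2, 2)), class = "microrad_validation_error")
  expect_error(radiograph(matrix(c(0, 0.5, 1, 2), 2, 2)),
               class = "microrad_validation_error")
  expect_error(radiograph(matrix(0:3, 2, 2), bit_depth = 10),
               class = "microrad_validation_error")
  expect_error(radiograph(matrix(c(0L, 256L, 1L, 2L), 2, 2), bit_depth = 8),
               class = "microrad_validation_error")
  # invariant violated after construction is caught before writing
  img <- radiograph(matrix(0:3, 2, 2), bit_depth = 12)
  img$pixels[1, 1] <- 5000L
  expect_error(write_image(img, tempfile(fileext = ".tif")),
               class = "microrad_validation_error")
})

test_that("I/O failures raise classed errors", {
  expect_error(read_image(file.path(tempdir(), "absent.tif")),
               class = "microrad_io_error")
  img <- radiograph(matrix(0:3, 2, 2), 8L)
  expect_error(write_image(img, file.path(tempdir(), "no-such-dir", "x.tif")),
               class = "microrad_io_error")
})

test_that("reader interoperates with tifffile and rejects unsupported variants", {
  # tifffile as independent oracle: R-written file read back by Python
  img <- radiograph(matrix(sample(0:4095, 3000, TRUE), 50, 60), 12L)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_image(img, tf)
  out <- system2("python", c("-c", shQuote(sprintf(
    "import tifffile; a = tifffile.imread('%s'); print(a.shape[0], a.shape[1], a.dtype, int(a.sum()))",
    tf
  ))), stdout = TRUE)
  expect_identical(out, sprintf("50 60 uint16 %d", sum(img$pixels)))

  # Python-written variants read by R: big-endian, multi-strip, tiled
  mk <- function(code) {
    f <- tempfile(fileext = ".tif")
    system2("python", c("-c", shQuote(sprintf(
      "import numpy, tifffile\na = (numpy.arange(64*96).reshape(64, 96) %% 4096).astype('uint16')\n%s",
      sprintf(code, f)
    ))))
    f
  }
  expected <- matrix((seq_len(64 * 96) - 1) %% 4096, 64, 96, byrow = TRUE)
  storage.mode(expected) <- "integer"
  for (code in c(
    "tifffile.imwrite('%s', a, compression=None, byteorder='>')",
    "tifffile.imwrite('%s', a, compression=None, rowsperstrip=10)",
    "tifffile.imwrite('%s', a, compression=None, tile=(32, 32))"
  )) {
    f <- mk(code)
    expect_identical(read_image(f)$pixels, expected)
    unlink(f)
  }

  # unsupported: RGB, float samples, compressed
  for (case in list(
    c("import numpy, tifffile; tifffile.imwrite('%s', numpy.zeros((8, 8, 3), dtype='uint8'), photometric='rgb')",
      "SamplesPerPixel"),
    c("import numpy, tifffile; tifffile.imwrite('%s', numpy.zeros((8, 8), dtype='float32'))",
      "SampleFormat"),
    c("import numpy, tifffile; tifffile.imwrite('%s', numpy.zeros((8, 8), dtype='uint16'), compression='zlib')",
      "Compression")
  )) {
    f <- tempfile(fileext = ".tif")
    system2("python", c("-c", shQuote(sprintf(case[1], f))))
    expect_error(read_image(f), case[2],
                 class = "microrad_unsupported_format_error")
    unlink(f)
  }
})

test_that("a full-size phantom frame respects the 12-bit range", {
  spec <- phantom_spec(rows = 1920, cols = 2560,
                       film = film_model(noise_sd = 41))
  img <- generate_tooth_pair(spec, seed = 7)$before
  expect_identical(dim(img$pixels), c(1920L, 2560L))
  expect_lte(max(img$pixels), 4095L)
  expect_gte(min(img$pixels), 0L)
})

test_that("profile CSV export/read round-trips", {
  p <- density_profile(c(101.25, 7.5, 42, 9.125), origin_px = 12,
                       um_per_pixel = 0.305)
  tf <- withr::local_tempfile(fileext = ".csv")
  export_profile_csv(p, tf)
  lines <- readLines(tf)
  expect_length(lines, 5L)  # header + 4 samples
  expect_identical(lines[1], "position_px,position_um,value")
  back <- read_profile_csv(tf)
  expect_equal(back$values, p$values, tolerance = 1e-9)
  expect_equal(profile_positions_um(back), profile_positions_um(p),
               tolerance = 1e-9)

  # uncalibrated: no position_um column
  p2 <- density_profile(c(1, 2, 3))
  export_profile_csv(p2, tf)
  expect_identical(readLines(tf)[1], "position_px,value")
  expect_null(read_profile_csv(tf)$um_per_pixel)
})

test_that("profile CSV reader is strict on schema, tolerant on extras", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), tf)
  expect_error(read_profile_csv(tf), class = "microrad_schema_error")
  writeLines(c("position_px,other", "0,1"), tf)
  expect_error(read_profile_csv(tf), "value",
               class = "microrad_schema_error")
  writeLines(c("position_px,value,extra_stuff", "0,5,9", "1,6,9"), tf)
  expect_warning(p <- read_profile_csv(tf), "extra_stuff")
  expect_equal(p$values, c(5, 6))
})
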