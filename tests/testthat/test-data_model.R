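test_that("field file names round-trip through the parser", {
  expect_equal(parse_field_filename("B03_f04_DAPI.tif"),
               list(well_id = "B03", field_index = 4L, channel = "DAPI"))
  expect_equal(parse_field_filename("P24_f09_gH2AX.tif"),
               list(well_id = "P24", field_index = 9L, channel = "gH2AX"))

  # parser is the exact inverse of the name builder across the plate
  wells <- as.vector(outer(LETTERS[1:16], sprintf("%02d", 1:24), paste0))
  set.seed(11)
  for (w in sample(wells, 40)) {
    for (f in c(1L, 9L)) for (ch in c("DAPI", "53BP1", "gH2AX")) {
      got <- parse_field_filename(field_filename(w, f, ch))
      expect_identical(got, list(well_id = w, field_index = f, channel = ch))
    }
  }
})

test_that("malformed field file names are rejected with the offending token", {
  expect_error(parse_field_filename("B3_field4.tif"), "B3")
  expect_error(parse_field_filename("Q01_f01_DAPI.tif"), "cannot parse")
  expect_error(parse_field_filename("B03_f04_FITC.tif"), "FITC")
  expect_error(parse_field_filename("B03_f00_DAPI.tif"), ">= 1")
})

test_that("integer TIFF images round-trip bit-exactly", {
  d <- withr::local_tempdir()
  img <- channel_image(matrix(500, 64, 64), "DAPI", well_id = "B03",
                       field_index = 4L)
  p <- write_channel_image(img, d)
  expect_identical(basename(p), "B03_f04_DAPI.tif")
  back <- read_channel_image(p)
  expect_identical(back$pixels, img$pixels)
  expect_identical(back$well_id, "B03")
  expect_identical(back$field_index, 4L)
  expect_identical(back$channel, "DAPI")

  # a noisy 16-bit-range image is also exact
  set.seed(1)
  px <- matrix(sample(0:65535, 32 * 32, replace = TRUE), 32, 32)
  img2 <- channel_image(px, "53BP1", well_id = "A01")
  back2 <- read_channel_image(write_channel_image(img2, d))
  expect_identical(back2$pixels, img2$pixels + 0)
})

test_that("float TIFF images round-trip at 32-bit float precision", {
  d <- withr::local_tempdir()
  set.seed(2)
  px <- matrix(runif(32 * 32, 0, 60000), 32, 32)
  img <- channel_image(px, "gH2AX", well_id = "C05")
  back <- read_channel_image(write_channel_image(img, d))
  expect_lt(max(abs(back$pixels - px) / pmax(px, 1)), 1e-6)
})

test_that("RGB and multi-plane TIFFs are rejected", {
  f_rgb <- withr::local_tempfile(pattern = "A01_f01_DAPI", fileext = ".tif")
  # build the file name the reader expects, with RGB content
  f_rgb <- file.path(dirname(f_rgb), "A01_f01_DAPI.tif")
  tiff::writeTIFF(array(0.5, c(8, 8, 3)), f_rgb)
  expect_error(read_channel_image(f_rgb), "RGB|multi-sample")

  f_multi <- file.path(dirname(f_rgb), "A02_f01_DAPI.tif")
  tiff::writeTIFF(list(matrix(0.1, 4, 4), matrix(0.2, 4, 4)), f_multi)
  expect_error(read_channel_image(f_multi), "multi-plane")
})

test_that("cell tables round-trip value-exactly through CSV", {
  d <- withr::local_tempdir()
  tab <- data.frame(
    cell_id = c("A01_f01_n001", "A01_f01_n002", "A01_f02_n001"),
    well_id = "A01", field_index = c(1L, 1L, 2L),
    nucleus_label = c(1L, 2L, 1L),
    centroid_row = c(10.25, 33.5, 7.125), centroid_col = c(5, 60.75, 80),
    nucleus_area_px = c(400L, 380L, 395L),
    mean_nuclear_DAPI = c(3000.5, 2987.25, 3012),
    mean_nuclear_53BP1 = c(101.5, 99.75, 100),
    mean_nuclear_gH2AX = c(305.125, 290, 310.5),
    sum_spot_53BP1 = c(25.0, 0, 12345.675),
    sum_spot_gH2AX = c(0, 0, 999.5),
    spot_count_53BP1 = c(2L, 0L, 5L), spot_count_gH2AX = c(0L, 0L, 1L),
    stringsAsFactors = FALSE)
  p <- file.path(d, "cells.csv")
  write_cell_table(tab, p)
  expect_identical(length(readLines(p)), 4L)  # header + 3 rows
  back <- read_cell_table(p)
  expect_equal(back, tab)
})

test_that("empty cell tables and schema violations are handled", {
  d <- withr::local_tempdir()
  p <- file.path(d, "empty.csv")
  write_cell_table(fociscreen:::empty_cell_table(), p)
  back <- read_cell_table(p)
  expect_identical(nrow(back), 0L)

  bad <- data.frame(cell_id = "x", well_id = "A01")
  expect_error(write_cell_table(bad, p), "field_index")
  writeLines("cell_id,well_id\nx,A01", p)
  expect_error(read_cell_table(p), "missing mandatory column")
})

test_that("plate layouts validate wells and round-trip through YAML", {
  lay <- plate_layout(list(
    B03 = sample_meta("D1", "JURKAT", "DMSO"),
    B04 = sample_meta("D1", "JURKAT", "ETP", 30, replicate = 2L)))
  d <- withr::local_tempdir()
  p <- file.path(d, "layout.yaml")
  write_plate_layout(lay, p)
  back <- read_plate_layout(p)
  expect_equal(as.data.frame(back), as.data.frame(lay))

  expect_error(plate_layout(list(Z01 = sample_meta())), "invalid 384-well id")
  expect_error(
    plate_layout(list(A01 = sample_meta(), A01 = sample_meta())),
    "duplicate")
  expect_error(sample_meta(treatment = "DMSO", treatment_dose_uM = 10),
               "unless treatment is ETP")
})
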