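test_that("sequence round-trips through both dialects", {
  set.seed(5)
  fr <- lapply(1:3, function(i) matrix(runif(20 * 15, 20, 40), 15, 20))
  sq <- thermal_sequence(fr, fps = 4, meta = list(site = "unitA"))

  tif <- withr::local_tempfile(fileext = ".tif")
  write_sequence(sq, tif, "tiff16")
  rt <- read_sequence(tif, "tiff16")
  expect_equal(length(rt), 3L)
  expect_equal(rt$fps, 4)
  expect_equal(rt$meta$site, "unitA")
  # 16-bit quantization step over a 20 K range
  step <- 20 / 65535
  expect_lt(step, 0.04)
  for (i in 1:3)
    expect_lt(max(abs(rt$frames[[i]]$values - fr[[i]])), step)
  expect_equal(vapply(rt$frames, `[[`, numeric(1), "timestamp"),
               vapply(sq$frames, `[[`, numeric(1), "timestamp"))

  dirp <- withr::local_tempdir()
  write_sequence(sq, file.path(dirp, "stack"), "csv_stack")
  rt2 <- read_sequence(file.path(dirp, "stack"), "csv_stack")
  for (i in 1:3)
    expect_identical(rt2$frames[[i]]$values, fr[[i]])
})

test_that("constant sequences survive the tiff16 round trip exactly", {
  sq <- thermal_sequence(list(matrix(30, 8, 9), matrix(30, 8, 9)), fps = 4)
  tif <- withr::local_tempfile(fileext = ".tif")
  write_sequence(sq, tif, "tiff16")
  rt <- read_sequence(tif, "tiff16")
  expect_identical(rt$frames[[1]]$values, matrix(30, 8, 9))
})

test_that("IO contract errors fire", {
  expect_error(write_sequence(list(), tempfile(), "tiff16"), "thermal_sequence")
  expect_error(read_sequence(tempfile("nope"), "tiff16"), "no such path")
  # a TIFF page without the dialect metadata is rejected
  sq <- thermal_sequence(list(matrix(1:6 + 0, 2, 3)), fps = 1)
  tif <- withr::local_tempfile(fileext = ".tif")
  write_sequence(sq, tif, "tiff16")
  raw <- readBin(tif, "raw", file.size(tif))
  # corrupt the JSON magic so scale/offset metadata is unrecognizable
  idx <- grepRaw("thermovitals-tiff16", raw)
  raw[idx:(idx + 3)] <- as.raw(88)
  writeBin(raw, tif)
  expect_error(read_sequence(tif, "tiff16"), "dialect error")
  # malformed sequence construction
  expect_error(thermal_sequence(list(), fps = 4), "at least one")
  expect_error(thermal_sequence(list(matrix(0, 2, 2), matrix(0, 3, 2)),
                                fps = 4), "inconsistent")
})

test_that("normalize_frame maps min/max to 0/1 and is affine-invariant", {
  set.seed(2)
  v <- matrix(runif(60, 20, 40), 6, 10)
  nv <- normalize_frame(v)
  expect_equal(range(nv), c(0, 1))
  expect_equal(normalize_frame(v)[v == max(v)], 1)
  # specific linear map: min 20, max 40 -> 30 maps to 0.5
  v2 <- matrix(c(20, 30, 40, 25), 2, 2)
  expect_equal(normalize_frame(v2)[2, 1], 0.5)
  # affine rescaling of temperatures leaves the result unchanged
  expect_equal(normalize_frame(3.7 * v + 11), nv)
  # constant frame: all zeros by convention
  expect_equal(normalize_frame(matrix(25, 4, 4)), matrix(0, 4, 4))
})

test_that("darknet labels parse, serialize and round-trip", {
  f <- withr::local_tempfile()
  writeLines("2 0.5 0.5 0.5 0.5", f)
  b <- parse_labels(f, 100, 100)
  expect_equal(b$label, "head")
  expect_equal(c(b$x_min, b$y_min, b$x_max, b$y_max), c(25, 25, 75, 75))

  writeLines(character(0), f)
  expect_equal(nrow(parse_labels(f, 100, 100)), 0L)

  # round trip to 6 decimals
  writeLines("1 0.100000 0.100000 0.400000 0.400000", f)
  b <- parse_labels(f, 382, 288)
  expect_equal(b$label, "chest")
  f2 <- withr::local_tempfile()
  serialize_labels(b, f2, 382, 288)
  expect_identical(readLines(f2), "1 0.100000 0.100000 0.400000 0.400000")

  writeLines("1 1.05 0.5 0.4 0.4", f)   # x_center > 1
  expect_error(parse_labels(f, 100, 100), "line 1")
  writeLines("7 0.5 0.5 0.1 0.1", f)
  expect_error(parse_labels(f, 100, 100), "class id")
})

test_that("crop obeys the half-open convention and clamps with a flag", {
  v <- matrix(seq_len(30 * 40), 30, 40)
  fr <- thermal_frame(v)
  whole <- crop(fr, bounding_box("chest", 0, 0, 40, 30))
  expect_equal(dim(whole), c(30, 40))
  expect_false(attr(whole, "clipped"))

  one <- crop(fr, bounding_box("head", 5, 7, 6, 8))
  expect_equal(dim(one), c(1, 1))
  expect_equal(one[1, 1], v[8, 6])

  ten <- crop(fr, bounding_box("chest", 10, 10, 20, 20))
  expect_equal(dim(ten), c(10, 10))

  clipped <- crop(fr, bounding_box("chest", 35, 25, 45, 35))
  expect_true(attr(clipped, "clipped"))
  expect_equal(dim(clipped), c(5, 5))
  expect_error(crop(fr, bounding_box("chest", 100, 100, 110, 110)),
               "intersect")
})

test_that("label tracks round-trip through a directory", {
  sc <- tiny_scene(seed = 3, duration = 2)
  d <- withr::local_tempdir()
  write_label_track(sc$truth$boxes, d, 140, 110)
  rt <- read_label_track(d, length(sc$truth$boxes), 140, 110)
  expect_equal(length(rt), length(sc$truth$boxes))
  b0 <- sc$truth$boxes[[4]]; b1 <- rt[[4]]
  expect_equal(b1$label, b0$label)
  expect_equal(b1$x_min, b0$x_min, tolerance = 1e-3)
  expect_equal(b1$y_max, b0$y_max, tolerance = 1e-3)
})
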