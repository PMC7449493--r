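test_that("metaimage round-trip preserves voxels bit for bit and geometry", {
  set.seed(11)
  v <- ct_volume(array(rnorm(4 * 5 * 6, -500, 300), c(4, 5, 6)),
                 spacing = c(2.5, 0.7, 0.7), origin = c(-10, 5.25, -200.5),
                 series_id = "rt")
  path <- file.path(withr::local_tempdir(), "rt.mhd")
  write_metaimage(v, path)
  v2 <- read_metaimage(path)
  expect_identical(v2$voxels, v$voxels)
  expect_lt(max(abs(v2$spacing - v$spacing)), 1e-9)
  expect_lt(max(abs(v2$origin - v$origin)), 1e-9)
  hdr <- readLines(path)
  expect_true(any(grepl("^NDims = 3$", hdr)))
  # ElementSpacing written x y z to 6 decimals
  sp <- hdr[grepl("^ElementSpacing", hdr)]
  expect_match(sp, "0\\.700000 0\\.700000 2\\.500000")
})

test_that("header fields are parsed in (x,y,z) order into (z,y,x) geometry", {
  dir <- withr::local_tempdir()
  raw <- file.path(dir, "fx.raw")
  con <- file(raw, "wb")
  writeBin(as.integer(seq_len(3 * 4 * 5) - 100), con, size = 2,
           endian = "little")
  close(con)
  writeLines(c("ObjectType = Image", "NDims = 3", "BinaryData = True",
               "BinaryDataByteOrderMSB = False", "DimSize = 3 4 5",
               "ElementSpacing = 0.7 0.7 2.5", "Offset = 1 2 3",
               "ElementType = MET_SHORT", "ElementDataFile = fx.raw"),
             file.path(dir, "fx.mhd"))
  v <- read_metaimage(file.path(dir, "fx.mhd"))
  expect_identical(dim(v$voxels), c(5L, 4L, 3L))
  expect_equal(v$spacing, c(2.5, 0.7, 0.7))
  expect_equal(v$origin, c(3, 2, 1))
  # x varies fastest in the raw block
  expect_equal(v$voxels[1, 1, ], c(1, 2, 3) - 100)
})

test_that("missing files and unsupported types raise classed errors", {
  dir <- withr::local_tempdir()
  expect_error(read_metaimage(file.path(dir, "nope.mhd")), "nope.mhd",
               class = "lungcad_io_error")
  writeLines(c("NDims = 3", "DimSize = 2 2 2", "ElementType = MET_SHORT",
               "ElementDataFile = absent.raw"), file.path(dir, "bad.mhd"))
  expect_error(read_metaimage(file.path(dir, "bad.mhd")), "absent.raw",
               class = "lungcad_io_error")
  writeLines(c("NDims = 3", "DimSize = 2 2 2", "ElementType = MET_WEIRD",
               "ElementDataFile = x.raw"), file.path(dir, "bad2.mhd"))
  expect_error(read_metaimage(file.path(dir, "bad2.mhd")),
               class = "lungcad_format_error")
})

test_that("isotropic resampling has the right shape, value and idempotence", {
  v <- ct_volume(array(7, c(10, 10, 10)), spacing = c(2, 2, 2))
  r <- resample_isotropic(v, 1)
  expect_identical(dim(r$voxels), c(20L, 20L, 20L))
  expect_true(all(r$voxels == 7))           # constant stays constant
  expect_equal(r$spacing, c(1, 1, 1))
  # idempotence once spacing equals target
  r2 <- resample_isotropic(r, 1)
  expect_lt(max(abs(r2$voxels - r$voxels)), 1e-6)
  expect_error(resample_isotropic(v, 0), "positive")
  expect_error(resample_isotropic(v, -1), "positive")
})

test_that("trilinear midpoints of a ramp equal neighbour means", {
  ramp <- array(rep(seq(0, 90, by = 10), each = 1), c(1, 1, 10))
  v <- ct_volume(ramp, spacing = c(1, 1, 1))
  r <- resample_isotropic(v, 0.5)
  # odd output indices sit midway between input samples
  mids <- r$voxels[1, 1, seq(2, 18, by = 2)]
  expected <- (seq(0, 80, by = 10) + seq(10, 90, by = 10)) / 2
  expect_lt(max(abs(mids - expected)), 1e-6)
})

test_that("resampling down and back reproduces a smooth volume within 5%", {
  g <- expand.grid(z = 1:12, y = 1:12, x = 1:12)
  smooth <- array(sin(g$z / 3) + cos(g$y / 4) + sin(g$x / 5), c(12, 12, 12))
  v <- ct_volume(smooth, spacing = c(1, 1, 1))
  back <- resample_isotropic(resample_isotropic(v, 0.5), 1)
  scale <- diff(range(smooth))
  expect_lt(max(abs(back$voxels - smooth)) / scale, 0.05)
})

test_that("intensity standardization follows the linear contract", {
  v <- ct_volume(array(c(0, 10), c(2, 1, 1)))
  s <- standardize_intensity(v, 5, 5)
  expect_equal(as.vector(s$voxels), c(-1, 1))
  expect_equal(standardize_intensity(v, 0, 1)$voxels, v$voxels)
  set.seed(4)
  v2 <- ct_volume(array(rnorm(1000, 30, 7), c(10, 10, 10)))
  st <- volume_stats(v2)
  z <- standardize_intensity(v2, st$mean, st$std)
  expect_lt(abs(mean(z$voxels)), 1e-6)
  expect_lt(abs(sqrt(mean(z$voxels^2)) - 1), 1e-6)
  expect_error(standardize_intensity(v, 0, 0), "positive")
})

test_that("world/voxel coordinate mapping round-trips to 1e-9 mm", {
  v <- ct_volume(array(0, c(4, 5, 6)), spacing = c(2.5, 0.7, 0.7),
                 origin = c(-100, 3, 7))
  set.seed(8)
  idx <- cbind(runif(20, 0, 3), runif(20, 0, 4), runif(20, 0, 5))
  w <- voxel_to_world(v, idx)
  expect_lt(max(abs(world_to_voxel(v, w) - idx)), 1e-9)
  expect_equal(as.vector(voxel_to_world(v, c(1, 1, 1))), c(-97.5, 3.7, 7.7))
})

test_that("patch extraction slices interiors exactly and pads corners", {
  set.seed(2)
  arr <- array(rnorm(30 * 40 * 50), c(30, 40, 50))
  v <- ct_volume(arr)
  p <- extract_patch(v, c(15, 20, 25), shape = c(8, 6, 4))
  expect_identical(dim(p$voxels), c(4L, 6L, 8L))  # stored (z,y,x)
  expect_identical(p$voxels,
                   arr[14:17, 18:23, 22:29])      # centre at floor(shape/2)
  # default shape is 40 x 40 x 26 (x,y,z)
  pd <- extract_patch(v, c(15, 20, 25))
  expect_identical(dim(pd$voxels), c(26L, 40L, 40L))
  # corner patch: pad count equals shape product minus in-grid overlap (loop oracle)
  small <- ct_volume(array(0, c(8, 8, 8)))
  pc <- extract_patch(small, c(0, 0, 0), shape = c(6, 6, 6), pad_value = -1000)
  n_pad_oracle <- 0
  for (k in -3:2) for (j in -3:2) for (i in -3:2)
    if (k < 0 || j < 0 || i < 0) n_pad_oracle <- n_pad_oracle + 1
  expect_equal(sum(pc$voxels == -1000), n_pad_oracle)
  expect_equal(sum(pc$voxels == 0), 6^3 - n_pad_oracle)
  expect_error(extract_patch(small, c(8, 0, 0)), "inside")
})

test_that("patches centred on every voxel cover the whole grid", {
  arr <- array(seq_len(4 * 5 * 6), c(4, 5, 6))
  v <- ct_volume(arr)
  covered <- array(FALSE, dim(arr))
  for (k in 0:3) for (j in 0:4) for (i in 0:5) {
    p <- extract_patch(v, c(k, j, i), shape = c(3, 3, 3), pad_value = NA)
    expect_equal(p$voxels[2, 2, 2], arr[k + 1, j + 1, i + 1])
    covered[k + 1, j + 1, i + 1] <- TRUE
  }
  expect_true(all(covered))
})

test_that("annotation CSVs read, validate, and report malformed lines", {
  dir <- withr::local_tempdir()
  good <- file.path(dir, "ann.csv")
  writeLines(c("seriesuid,coordX,coordY,coordZ,diameter_mm",
               "s1,1.5,2.5,3.5,8.0", "s1,-10,0,4,22.5", "s2,5,6,7,3.25"), good)
  ann <- read_annotations(good)
  expect_equal(nrow(ann), 3)
  expect_equal(ann$diameter_mm, c(8, 22.5, 3.25))
  expect_s3_class(ann, "tbl_df")

  empty <- file.path(dir, "empty.csv")
  writeLines("seriesuid,coordX,coordY,coordZ,diameter_mm", empty)
  expect_equal(nrow(read_annotations(empty)), 0)

  bad <- file.path(dir, "bad.csv")
  writeLines(c("seriesuid,coordX,coordY,coordZ,diameter_mm",
               "s1,1,2,3,4", "s1,1,2,3,abc"), bad)
  expect_error(read_annotations(bad), "3", class = "lungcad_format_error")

  miss <- file.path(dir, "miss.csv")
  writeLines(c("seriesuid,coordX,coordY,coordZ", "s1,1,2,3"), miss)
  expect_error(read_annotations(miss), "diameter_mm",
               class = "lungcad_format_error")
})
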