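test_that("MRC round-trip preserves grid, voxel size and statistics", {
  g <- array(rnorm(16^3), c(16, 16, 16))
  vol <- density_volume(g, 2.16)
  path <- withr::local_tempfile(fileext = ".mrc")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$grid, g, tolerance = 1e-6)  # float32 precision
  expect_equal(back$voxel_size_nm, 2.16, tolerance = 1e-6)

  # header fields: dims and pixel spacing in Angstrom
  con <- file(path, "rb")
  dims <- readBin(con, "integer", 3, size = 4, endian = "little")
  readBin(con, "integer", 4, size = 4, endian = "little")
  mxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  close(con)
  expect_identical(dims, rep(16L, 3))
  expect_equal(cella / mxyz, rep(21.6, 3), tolerance = 1e-5)
})

test_that("pixel size written at 5.4 Angstrom reads back identically", {
  vol <- density_volume(array(0, c(8, 8, 8)), 0.54)
  path <- withr::local_tempfile(fileext = ".mrc")
  write_volume(vol, path)
  expect_equal(read_volume(path)$voxel_size_nm, 0.54, tolerance = 1e-6)
})

test_that("all-zero volume writes zero statistics", {
  path <- withr::local_tempfile(fileext = ".mrc")
  write_volume(density_volume(array(0, c(8, 8, 8)), 1), path)
  con <- file(path, "rb")
  seek(con, 76)  # dmin, dmax, dmean
  stats <- readBin(con, "numeric", 3, size = 4, endian = "little")
  close(con)
  expect_equal(stats, c(0, 0, 0))
})

test_that("corrupt or unsupported MRC files raise informative errors", {
  path <- withr::local_tempfile(fileext = ".mrc")
  write_volume(density_volume(array(rnorm(8^3), c(8, 8, 8)), 1), path)
  # truncate the data block
  full <- readBin(path, "raw", file.info(path)$size)
  writeBin(full[1:(1024 + 100)], path)
  expect_error(read_volume(path), "truncated")
  expect_error(read_volume(file.path(tempdir(), "nope.mrc")), "not found")
  bad <- density_volume(array(c(NaN, rnorm(8^3 - 1)), c(8, 8, 8)), 1)
  expect_error(write_volume(bad, path), "non-finite")
})

test_that("particle table TSV round-trips field-for-field", {
  set.seed(1)
  tab <- data.frame(particle_id = sprintf("p%03d", 1:100),
                    diameter_nm = runif(100, 30, 130),
                    azimuth_deg = runif(100, 0, 360),
                    docked = sample(c(TRUE, FALSE), 100, TRUE),
                    note = sample(letters, 100, TRUE),  # unknown column
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(tab, path)
  back <- read_table(path)
  expect_equal(back, tab)
})

test_that("table validation catches schema problems", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("particle_id\tdiameter_nm", path)
  empty <- read_table(path)
  expect_identical(nrow(empty), 0L)
  dup <- data.frame(particle_id = c("a", "a"), diameter_nm = c(1, 2))
  expect_error(write_table(dup, path), "duplicate")
  bad <- data.frame(foo = 1)
  expect_error(validate_particle_table(bad), "particle_id")
  neg <- data.frame(particle_id = "a", diameter_nm = -1)
  expect_error(validate_particle_table(neg), "positive")
})
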