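# A tiny deterministic raster: 4 x 4 grid, 10-degree cells covering
# lat 0..40 / lon 0..40, SST decreasing northward, one land cell.
toy_raster <- function() {
  mean_l <- matrix(c(20, 20, 20, 20,
                     22, 22, 22, 22,
                     25, NA, 25, 25,
                     28, 28, 28, 28), 4, 4, byrow = TRUE)
  new_sst_raster(nrows = 4, ncols = 4, cellsize = 10, xll = 0, yll = 0,
                 nodata = -9999, min = mean_l - 2, mean = mean_l,
                 max = mean_l + 3)
}

test_that("ascii grid round trip preserves grid and values", {
  r <- toy_raster()
  fs <- replicate(3, tempfile(fileext = ".asc"))
  write_ascii_grid(r, fs[1], fs[2], fs[3])
  r2 <- read_ascii_grid(fs[1], fs[2], fs[3])
  expect_equal(r2$ncols, 4)
  expect_equal(r2$cellsize, 10)
  expect_equal(r2$mean, r$mean, tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(is.na(r2$mean[3, 2]))
})

test_that("mismatched headers and min > max cells are rejected", {
  r <- toy_raster()
  fs <- replicate(4, tempfile(fileext = ".asc"))
  write_ascii_grid(r, fs[1], fs[2], fs[3])
  smaller <- new_sst_raster(nrows = 4, ncols = 3, cellsize = 10, xll = 0,
                            yll = 0, nodata = -9999,
                            min = r$min[, 1:3], mean = r$mean[, 1:3],
                            max = r$max[, 1:3])
  write_ascii_grid(smaller, fs[4], fs[4], fs[4])
  expect_error(read_ascii_grid(fs[4], fs[2], fs[3]), "headers differ")

  bad_min <- r$max + 1
  expect_error(new_sst_raster(4, 4, 10, 0, 0, -9999, bad_min, r$mean,
                              r$max), "min <= mean <= max")
})

test_that("extraction returns the containing cell, searching past nodata", {
  r <- toy_raster()
  # center of row 4 (lat 0-10), col 1
  expect_equal(extract_sst(r, 5, 5), c(min = 26, mean = 28, max = 31))
  # nodata cell at lat 15, lon 15: the four valid neighbours are equidistant
  # and the row-major tie-break picks the northernmost one (mean 22)
  v <- extract_sst(r, 15, 15)
  expect_equal(unname(v["mean"]), 22)
  # outside grid
  expect_error(extract_sst(r, 55, 5), "outside grid")
  expect_error(extract_sst(r, 5, -5), "outside grid")
  # nodata everywhere within radius 0
  r0 <- r
  r0$min[] <- NA; r0$mean[] <- NA; r0$max[] <- NA
  expect_error(extract_sst(r0, 15, 15, radius = 1), "no valid SST cell")
})

test_that("per-species summaries follow the extreme-based definition", {
  r <- toy_raster()
  # single record at (5, 5): min 26, mean 28, max 31
  one <- data.frame(species = "s1", lat = 5, lon = 5, provenance = "dna")
  sm <- summarize_species(one, r)
  expect_equal(sm$max_C, 31)
  expect_equal(sm$mean_C, 28)
  expect_equal(sm$min_C, 26)
  expect_equal(sm$max_range_C, 5)
  expect_equal(sm$lat_range, 0)
  expect_equal(sm$lon_range, 0)

  # two records: extremes beat means, per the hand-computed example
  two <- data.frame(species = "s2", lat = c(5, 35), lon = c(5, 25),
                    provenance = "dna")
  sm2 <- summarize_species(two, r)
  # records give (26,28,31) and (18,20,23)
  expect_equal(sm2$max_C, 27)
  expect_equal(sm2$min_C, 22)
  expect_equal(sm2$max_range_C, 31 - 18)
  expect_gte(sm2$max_range_C, sm2$max_C - sm2$min_C)
  expect_equal(sm2$lat_range, 30)
  expect_equal(sm2$lon_range, 20)
})

test_that("adding a record never shrinks ranges", {
  r <- toy_raster()
  recs <- data.frame(species = "s", lat = c(5, 25), lon = c(5, 35),
                     provenance = "dna")
  base <- summarize_species(recs, r)
  more <- summarize_species(rbind(recs, data.frame(
    species = "s", lat = 35, lon = 15, provenance = "dna")), r)
  expect_gte(more$max_range_C, base$max_range_C)
  expect_gte(more$lat_range, base$lat_range)
  expect_gte(more$lon_range, base$lon_range)
})

test_that("extraction is deterministic and failed records are dropped", {
  r <- toy_raster()
  v1 <- extract_sst(r, 15, 15)
  v2 <- extract_sst(r, 15, 15)
  expect_identical(v1, v2)

  recs <- data.frame(species = c("ok", "gone"), lat = c(5, 85),
                     lon = c(5, 5), provenance = "dna")
  expect_warning(expect_warning(
    sm <- summarize_species(recs, r), "dropped"), "omitted")
  expect_equal(sm$species, "ok")
})

test_that("occurrence CSV reading validates coordinates and provenance", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("species,lat,lon,provenance", "sp1,10.5,-64.2,dna"), f)
  occ <- read_occurrences(f)
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$lon, -64.2)

  writeLines(c("species,lat,lon,provenance", "sp1,95,-64.2,dna"), f)
  expect_error(read_occurrences(f), "out-of-range.*2")

  writeLines(c("species,lat,lon", "sp1,10.5,-64.2"), f)
  expect_warning(occ2 <- read_occurrences(f), "provenance")
  expect_equal(occ2$provenance, "literature")

  writeLines(c("species,lat", "sp1,10.5"), f)
  expect_error(read_occurrences(f), "lacks column")

  writeLines(c("species,lat,lon", "sp1,abc,-64.2"), f)
  expect_error(suppressWarnings(read_occurrences(f)), "unparseable lat")
})

test_that("circular longitudinal range takes the minimal covering arc", {
  recs <- data.frame(species = "s", lat = c(5, 5), lon = c(-175, 175),
                     provenance = "dna")
  r <- simulate_sst_raster(nrows = 18, ncols = 36, cellsize = 10,
                           sigma = 0, seed = 1)
  raw <- summarize_species(recs, r)
  circ <- summarize_species(recs, r, circular_lon = TRUE)
  expect_equal(raw$lon_range, 350)
  expect_equal(circ$lon_range, 10)
})

test_that("the published ten-species table satisfies the extremes invariant", {
  tab <- dictyota_thermal_summary()
  expect_equal(nrow(tab), 10L)
  expect_true(all(tab$max_range_C >= tab$max_C - tab$min_C))
  expect_true(all(tab$min_C <= tab$mean_C & tab$mean_C <= tab$max_C))
})
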