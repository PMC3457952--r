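# Raster world: vegetation quality, breeding phenology, generators,
# patch filtering.

test_that("digestibility follows 0.7 + sqrt(fraction), capped at 1", {
  expect_equal(digestibility(0), 0.7)
  expect_equal(digestibility(1), 1.0)
  expect_equal(digestibility(0.04), 0.9)
  expect_error(digestibility(-0.1), "must be in")
  expect_error(digestibility(1.1), "must be in")
})

test_that("digestibility is monotone and bounded on [0, 1]", {
  f <- seq(0, 1, length.out = 101)
  d <- digestibility(f)
  expect_true(all(diff(d) >= 0))
  expect_true(all(d >= 0.7 & d <= 1.0))
})

test_that("vegetation cohort ledger tracks the new-green pool", {
  p <- voleParams()
  warm <- paramValues(p)[["V14"]] + 5
  cold <- paramValues(p)[["V14"]] - 5

  # equal growth from a bare start: everything is younger than 14 days
  st <- vegetationState(mature = 0)
  for (i in 1:14) st <- updateVegetation(st, warm, p)
  expect_equal(st$new_green_fraction, 1.0)
  expect_equal(st$digestibility, 1.0)

  # 20 growth days: 14 days' growth still counts as new out of 20
  st <- vegetationState(mature = 0)
  for (i in 1:20) st <- updateVegetation(st, warm, p)
  expect_equal(st$new_green_fraction, 14 / 20)

  # 15 cold days age every cohort out of the pool
  for (i in 1:15) st <- updateVegetation(st, cold, p)
  expect_equal(st$new_green_fraction, 0)
  expect_equal(st$digestibility, 0.7)
})

test_that("breeding window combines the 7-day rule with the V15 floor", {
  p <- voleParams()  # V14 = 3.552, V15 = 80, V11 = 230
  warm_all <- data.frame(doy = 1:365, temp_c = rep(10, 365))
  bw <- breedingWindow(warm_all, p)
  expect_equal(bw$start_day, 80)  # rule satisfied early, V15 binds
  expect_equal(bw$end_day, 230)

  cold_all <- data.frame(doy = 1:365, temp_c = rep(0, 365))
  expect_true(is.na(breedingWindow(cold_all, p)$start_day))

  late <- data.frame(doy = 1:365, temp_c = ifelse(1:365 >= 100, 10, 0))
  expect_equal(breedingWindow(late, p)$start_day, 106)
})

test_that("breeding start is monotone non-decreasing in V14", {
  set.seed(5)
  w <- syntheticWeather("finland_like", years = 1, seed = 11)
  w <- data.frame(doy = w$doy, temp_c = w$temp_c)
  starts <- sapply(c(1, 3.552, 6, 9), function(v14)
    breedingWindow(w, voleParams(V14 = v14))$start_day)
  starts[is.na(starts)] <- 400
  expect_true(all(diff(starts) >= 0))
})

test_that("landscape generators honour their contracts", {
  g1 <- generateLandscape("patches", dims = c(120, 120), n_patches = 1,
                          seed = 3, grass_area_m2 = 900)
  pt1 <- patchTable(g1, keep_all = TRUE)
  expect_equal(sum(pt1$class == "grassland_unmanaged"), 1)

  g16 <- generateLandscape("patches", dims = c(400, 400), n_patches = 16,
                           seed = 3, grass_area_m2 = 16 * 900)
  pt16 <- patchTable(g16, keep_all = TRUE)
  expect_equal(sum(pt16$class == "grassland_unmanaged"), 16)

  gm <- generateLandscape("trap_meadow", dims = c(500, 400))
  expect_equal(sum(gm@codes == 1), 500 * 400)  # exactly 500 x 400 grassland

  expect_error(generateLandscape("volcano"), "arg")
})

test_that("generators are reproducible for a fixed seed", {
  a <- generateLandscape("mosaic", dims = c(120, 100), seed = 9)
  b <- generateLandscape("mosaic", dims = c(120, 100), seed = 9)
  c <- generateLandscape("mosaic", dims = c(120, 100), seed = 10)
  expect_identical(a@codes, b@codes)
  expect_false(identical(a@codes, c@codes))
})

test_that("patch table applies the class-specific minimum areas", {
  cls <- voleHabitatClasses()
  m <- matrix(0L, 150, 200)
  m[1:25, 1:200] <- 6L     # field crop, 5,000 m2: below 1 ha
  m[40:79, 1:30] <- 5L     # linear feature, 1,200 m2: above 1,000 m2
  m[100:129, 1:30] <- 1L   # grassland, 900 m2: below 1,000 m2
  g <- habitatGrid(m, cls)
  pt <- patchTable(g)
  expect_false("field_crop" %in% pt$class)
  expect_true("linear_feature" %in% pt$class)
  expect_false("grassland_unmanaged" %in% pt$class)

  all_pt <- patchTable(g, keep_all = TRUE)
  expect_equal(sum(all_pt$area_m2), sum(m != 0))  # partition of habitat
})

test_that("cell count equals patch area and patches partition the grid", {
  g <- generateLandscape("patches", dims = c(80, 80), n_patches = 3,
                         seed = 2, grass_area_m2 = 3 * 400)
  expect_equal(sort(unique(as.vector(g@patches))),
               seq_len(max(g@patches)))
  pt <- patchTable(g, keep_all = TRUE)
  expect_equal(sum(pt$area_m2), sum(g@codes == 1))
})
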