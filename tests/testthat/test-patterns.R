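# Pattern statistics and pass/fail evaluation.

mkCounts <- function(doys, females, males)
  data.frame(doy = doys, females = females, males = males)

test_that("sex ratio is the mean of daily females-per-male", {
  cc <- mkCounts(75:105, rep(50, 31), rep(50, 31))
  expect_equal(sexRatio(cc, 90), 1.0)
  cc2 <- mkCounts(75:105, rep(78, 31), rep(40, 31))
  expect_equal(sexRatio(cc2, 90), 1.95)

  # linearly varying counts: mean of daily ratios, not ratio of sums
  f <- seq(40, 100, length.out = 31); m <- seq(100, 40, length.out = 31)
  cc3 <- mkCounts(75:105, f, m)
  expect_equal(sexRatio(cc3, 90), mean(f / m))
  expect_equal(sexRatio(cc3, 90, ratio_of_sums = TRUE), sum(f) / sum(m))

  expect_error(sexRatio(mkCounts(90, 5, 0), 90), "zero males")
  expect_error(sexRatio(cc, 300), "window")
})

test_that("female density averages the window and divides by area", {
  cc <- mkCounts(185:215, rep(300, 31), rep(1, 31))
  expect_equal(femaleDensity(cc, area_ha = 4, day = 200), 75)
  cc0 <- mkCounts(185:215, rep(0, 31), rep(1, 31))
  expect_equal(femaleDensity(cc0, area_ha = 4), 0)
  f <- rpois(31, 100)
  expect_equal(femaleDensity(mkCounts(185:215, f, 1), 2), mean(f) / 2)
  expect_error(femaleDensity(cc, 0), "positive")
})

test_that("age-structure fit is the mean summed squared difference", {
  target <- matrix(0.25, 5, 4)
  model <- matrix(10, 5, 4)
  expect_equal(ageStructureFit(model, target), 0)

  model2 <- rbind(c(0.6, 0.4), matrix(0.5, 4, 2))
  target2 <- matrix(0.5, 5, 2)
  expect_equal(ageStructureFit(model2 * 100, target2), 0.004)

  empty <- model; empty[2, ] <- 0
  expect_warning(f <- ageStructureFit(empty, target), "no animals")
  expect_equal(f, 0)
  expect_error(ageStructureFit(model, target * 2), "sum to 1")
})

test_that("age-structure fit is zero iff exact, positive otherwise", {
  set.seed(9)
  for (i in 1:10) {
    p <- matrix(rgamma(20, 2), 5, 4)
    p <- p / rowSums(p)
    expect_equal(ageStructureFit(p * 50, p), 0)
    q <- p + matrix(runif(20, 0, 0.05), 5, 4)
    q <- q / rowSums(q)
    if (!isTRUE(all.equal(p, q)))
      expect_gt(ageStructureFit(q * 50, p), 0)
  }
})

test_that("habitat-density deviation is total absolute ln difference", {
  tt <- expand.grid(habitat = c("a", "b"), season = c("sp", "su"),
                    stringsAsFactors = FALSE)
  tt$density <- c(20, 40, 60, 80)
  mm <- tt
  fit <- habitatDensityFit(mm, tt)
  expect_equal(fit$total, 0)
  expect_true(fit$pass)

  mm2 <- tt; mm2$density[1] <- tt$density[1] * exp(1)
  expect_equal(habitatDensityFit(mm2, tt)$total, 1.0)

  # 22 observations each off by half an ln unit: 11.0 total, a failure
  t22 <- data.frame(habitat = paste0("h", 1:22), season = "sp",
                    density = 30)
  m22 <- t22; m22$density <- 30 * exp(0.5)
  f22 <- habitatDensityFit(m22, t22)
  expect_equal(f22$total, 11.0)
  expect_false(f22$pass)

  expect_error(habitatDensityFit(mm[-1, ], tt), "lacks observation")
})

test_that("the lumped low-density category contributes asymmetrically", {
  tt <- data.frame(habitat = "h", season = "sp", density = 5)  # < 9: lumped
  expect_equal(habitatDensityFit(data.frame(habitat = "h", season = "sp",
                                            density = 7), tt)$total, 0)
  expect_equal(habitatDensityFit(data.frame(habitat = "h", season = "sp",
                                            density = 18), tt)$total,
               log(2))
})

test_that("habitat fit is invariant to a common scale factor", {
  set.seed(10)
  tt <- data.frame(habitat = paste0("h", 1:8), season = "su",
                   density = runif(8, 10, 120), lumped = FALSE)
  mm <- tt; mm$density <- mm$density * exp(rnorm(8, 0, 0.4))
  f1 <- habitatDensityFit(mm, tt)$total
  mm2 <- mm; mm2$density <- mm2$density * 3.7
  tt2 <- tt; tt2$density <- tt2$density * 3.7
  expect_equal(habitatDensityFit(mm2, tt2)$total, f1)
})

test_that("cycle metrics: amplitude, period, degenerate inputs", {
  cm <- cycleMetrics(c(100, 500, 2008.6, 700, 150, 300, 1400, 2000, 600,
                       120))
  expect_equal(cm$amplitude, log(2008.6 / 100), tolerance = 1e-10)

  flat <- cycleMetrics(rep(500, 12))
  expect_equal(flat$amplitude, 0)
  expect_true(is.na(flat$period_years))
  expect_equal(flat$regime, 3L)

  saw <- cycleMetrics(rep(c(1, 2, 3, 4, 5), 5))
  expect_equal(saw$period_years, 5)

  zero <- cycleMetrics(c(0, 10, 100, 10, 0, 10))
  expect_true(zero$min_clamped)
  expect_equal(zero$amplitude, log(100))
})

test_that("cycle amplitude is scale invariant", {
  set.seed(11)
  x <- exp(cumsum(rnorm(20, 0, 0.5))) * 100
  expect_equal(cycleMetrics(x * 13)$amplitude, cycleMetrics(x)$amplitude)
})

test_that("pattern-set evaluation applies the printed tolerances", {
  st <- list(sex_ratio_day90 = 1.021, sex_ratio_day200 = 1.95 * 0.987,
             female_density_ha = 75 * 1.004)
  rep1 <- evaluatePatternSet(st, 1)
  r90 <- rep1[rep1$criterion == "sex_ratio_day90", ]
  expect_false(r90$pass)        # 2.1% exceeds the 2% line...
  expect_true(r90$marginal)     # ...but only marginally
  expect_true(rep1$pass[rep1$criterion == "sex_ratio_day200"])
  expect_true(rep1$pass[rep1$criterion == "female_density_ha"])

  rep2 <- evaluatePatternSet(list(total = 11, pass = FALSE), 2)
  expect_false(attr(rep2, "pass"))

  st3 <- list(philopatry_pct = c(male = 1.0, female = 0.3),
              mean_step_m = c(male = 11.8, female = 8.6),
              mean_max_m = c(male = 41.9, female = 22.2),
              natal_far_pct = c(male = 13, female = 13),
              natal_near_pct = c(male = 70, female = 70))
  rep3 <- evaluatePatternSet(st3, 3)
  expect_true(all(rep3$pass[grep("philopatry", rep3$criterion)]))

  regs <- list(list(regime = 1L), list(regime = 2L), list(regime = 3L))
  rep4 <- evaluatePatternSet(regs, 4)
  expect_true(attr(rep4, "pass"))
  regs2 <- list(list(regime = 2L), list(regime = 2L), list(regime = 3L))
  expect_false(attr(evaluatePatternSet(regs2, 4), "pass"))
})

test_that("statistics match brute-force recomputation from daily rows", {
  sim <- cachedSim("mini", function() runVoleSim(miniBlock(), seed = 1))
  cc <- simCounts(sim, postBurnIn = TRUE)
  w <- cc[abs(cc$doy - 90) <= 15 & cc$males > 0, ]
  expect_equal(sexRatio(cc, 90), mean(w$females / w$males))
  w2 <- cc[abs(cc$doy - 200) <= 15, ]
  expect_equal(femaleDensity(cc, 1, day = 200), mean(w2$females))
})
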