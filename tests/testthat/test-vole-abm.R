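# Agent-level behavioural rules and whole-scheduler invariants.

test_that("eviction needs same sex, >50% overlap and the V8 age gap", {
  expect_true(canEvict(100, 60, 0.6, TRUE))
  expect_false(canEvict(100, 80, 0.6, TRUE))   # gap 20 < 30
  expect_false(canEvict(100, 20, 0.4, TRUE))   # overlap at most 50%
  expect_false(canEvict(100, 20, 0.9, FALSE))  # different sex
})

test_that("a female chooses the nearest covering male, ties by id", {
  males <- data.frame(id = c(2L, 7L), x = c(5, 9), y = c(0, 0),
                      radius = c(9, 23))
  expect_equal(chooseMate(c(0, 0), males), 2L)
  expect_equal(chooseMate(c(0, 0), males[0, ]), NA_integer_)
  far <- data.frame(id = 1L, x = 50, y = 50, radius = 9)
  expect_equal(chooseMate(c(0, 0), far), NA_integer_)
  tied <- data.frame(id = c(9L, 3L), x = c(5, -5), y = c(0, 0),
                     radius = c(9, 9))
  expect_equal(chooseMate(c(0, 0), tied), 3L)
})

test_that("maturation is at V1/V2 and idempotent", {
  expect_equal(maturationStage(29, "male"), "juvenile")
  expect_equal(maturationStage(30, "male"), "adult")
  expect_equal(maturationStage(22, "female"), "juvenile")
  expect_equal(maturationStage(23, "female"), "adult")
  expect_equal(maturationStage(200, "female"), "adult")
})

test_that("survival under V10 alone matches the closed form", {
  p <- voleParams()
  n <- 1e5
  set.seed(1)
  alive <- rep(TRUE, n)
  for (d in 1:365) {
    idx <- which(alive)
    alive[idx] <- dailyMortality(age = rep(1, length(idx)),
                                 lifespan = rep(1e6, length(idx)),
                                 dispersed_today = FALSE, params = p)
  }
  expected <- (1 - 0.0025)^365
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(alive) - expected), 3 * se)
})

test_that("dispersal-day mortality combines hazards multiplicatively", {
  p <- voleParams()
  n <- 2e5
  set.seed(2)
  dead <- !dailyMortality(age = rep(1, n), lifespan = rep(1e6, n),
                          dispersed_today = TRUE, params = p)
  expected <- 1 - (1 - 0.0025) * (1 - 0.055)  # 0.0573625
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(dead) - expected), 3 * se)
  # beyond-lifespan death is deterministic
  expect_false(any(dailyMortality(age = 100, lifespan = 99)))
})

test_that("density threshold scales with the squared radius ratio", {
  expect_false(densityEffectsActive(3, "female"))
  expect_true(densityEffectsActive(4, "female"))
  # male threshold 4 * (9/8)^2 ~ 5.06: a count of 4 is below it
  expect_false(densityEffectsActive(4, "male"))
  expect_true(densityEffectsActive(6, "male"))
})

test_that("male restlessness fires at rate V12 only without females", {
  set.seed(3)
  expect_true(all(!maleRestlessness(2, n = 1000)))
  moves <- maleRestlessness(0, n = 2e4)
  se <- sqrt(0.0505 * (1 - 0.0505) / 2e4)
  expect_lt(abs(mean(moves) - 0.0505), 3 * se)
  expect_true(all(!maleRestlessness(0, n = 500, params = voleParams(V12 = 0))))
})

test_that("infanticide success declines with litter age", {
  set.seed(4)
  expect_true(all(replicate(50, infanticideAttempt(0))))   # age 0: certain
  expect_error(infanticideAttempt(14), "weaned")
  p0 <- voleParams(V17 = 0)
  expect_true(all(!replicate(50, infanticideAttempt(5, p0))))
})

test_that("territory acceptability scans radii against quality x V3", {
  q07 <- matrix(0.7, 60, 60)
  r <- territoryAcceptable(c(30, 30), "female", q07)
  expect_true(r$acceptable)
  expect_equal(r$radius, 8)  # 0.7 * 2.1 = 1.47 >= 1 at the minimum radius

  q02 <- matrix(0.2, 60, 60)
  expect_false(territoryAcceptable(c(30, 30), "male", q02)$acceptable)
  q0 <- matrix(0, 60, 60)
  expect_false(territoryAcceptable(c(30, 30), "female", q0)$acceptable)

  # the density rule vetoes an otherwise acceptable radius
  r2 <- territoryAcceptable(c(30, 30), "female", q07,
                            local_counts = function(r) 10)
  expect_false(r2$acceptable)
})

test_that("lifespans are ~N(15, 3) months, truncated at one day", {
  set.seed(6)
  ls <- drawLifespan(2e4)
  expect_true(all(ls >= 1))
  expect_lt(abs(mean(ls) - 15 * 30.44), 3 * 3 * 30.44 / sqrt(2e4))
})

test_that("litter sizes are truncated-Poisson with the configured mean", {
  set.seed(7)
  l <- drawLitterSize(2e4)
  expect_true(all(l >= 1))
  expect_lt(abs(mean(l) - mean(pmax(1, rpois(2e4, 5)))), 0.1)
})

test_that("same seed gives a bit-identical trajectory", {
  sc <- miniBlock()
  a <- runVoleSim(sc, voleParams(), seed = 11)
  b <- runVoleSim(sc, voleParams(), seed = 11)
  c <- runVoleSim(sc, voleParams(), seed = 12)
  expect_identical(simCounts(a), simCounts(b))
  expect_identical(simEvents(a), simEvents(b))
  expect_false(identical(simCounts(a)$total, simCounts(c)$total))
})

test_that("counts are non-negative and internally consistent", {
  sim <- cachedSim("mini", function() runVoleSim(miniBlock(), seed = 1))
  cc <- simCounts(sim)
  expect_true(all(cc[, c("adult_m", "adult_f", "juv_m", "juv_f")] >= 0))
  expect_equal(cc$total, cc$adult_m + cc$adult_f + cc$juv_m + cc$juv_f)
  expect_true(all(cc$females <= cc$females_all))
})

test_that("sex assignment at birth is an even coin", {
  sim <- cachedSim("mini3y", function()
    runVoleSim(miniBlock(years = 3, burnIn = 1, blockSide = 120), seed = 2))
  ev <- simEvents(sim)
  bm <- sum(ev$births_m); bf <- sum(ev$births_f)
  n <- bm + bf
  expect_gt(n, 1000)
  expect_gt(binom.test(bm, n, 0.5)$p.value, 0.01)
})

test_that("no weaned litter appears before start + gestation + weaning", {
  sim <- cachedSim("mini3y", function()
    runVoleSim(miniBlock(years = 3, burnIn = 1, blockSide = 120), seed = 2))
  ev <- simEvents(sim)
  ev$year <- (ev$day - 1) %/% 365 + 1
  ev$doy <- (ev$day - 1) %% 365 + 1
  bw <- simMeta(sim)$breedingWindow
  for (yr in 2:3) {  # year 1 inherits initial unsettled founders
    born <- ev$doy[ev$year == yr & (ev$births_m + ev$births_f) > 0]
    if (length(born))
      expect_gte(min(born), bw$start_day[yr] + 21 + 14)
  }
})

test_that("with hazards off, voles die only of old age", {
  p <- voleParams(V9 = 0, V10 = 0)
  sim <- runVoleSim(miniBlock(), p, seed = 3)
  ev <- simEvents(sim)
  expect_equal(sum(ev$deaths_background), 0)
  expect_equal(sum(ev$deaths_dispersal_m + ev$deaths_dispersal_f), 0)
  expect_equal(sum(ev$deaths_predation), 0)
  expect_gt(sum(ev$deaths_lifespan), 0)
})
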