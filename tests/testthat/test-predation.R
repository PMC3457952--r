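# Specialist predator layer: configuration, background mode, starvation,
# stream separation, delayed numerical response.

test_that("predator configuration validates and presets differ", {
  p <- predatorParams("strong")
  expect_true(p$enabled)
  w <- predatorParams("weak")
  expect_gt(w$survive_threshold, p$survive_threshold)
  expect_error(predatorParams(kill_capp = 3), "unknown predator setting")
})

test_that("background-mortality mode guards trapping scenarios", {
  sc <- scenarioTrapMeadow(dims = c(90, 70), years = 3, burnIn = 1,
                           sampleYears = 1)
  expect_error(backgroundMortalityMode(sc, enabled = TRUE),
               "predators off")
  sc2 <- backgroundMortalityMode(scenarioPatches(1, years = 3, burnIn = 1))
  expect_equal(length(sc2@predators), 0)
})

test_that("with predators off there are no predation deaths", {
  sim <- cachedSim("mini", function() runVoleSim(miniBlock(), seed = 1))
  expect_equal(sum(simEvents(sim)$deaths_predation), 0)
})

test_that("predators starve out when there is nothing to eat", {
  # a tiny world whose vole population cannot sustain any predator
  sc <- scenarioPatches(1, extent = c(80, 80), grassAreaM2 = 400,
                        years = 2, burnIn = 1,
                        predators = predatorParams(
                          "strong", start_day = 10, immigration_n = 0,
                          survive_threshold = 50, starvation_days = 20))
  sc@initDensity <- 1
  sim <- runVoleSim(sc, voleParams(), seed = 1)
  cc <- simCounts(sim)
  expect_gt(max(cc$predators), 0)                 # they did arrive
  expect_equal(max(cc$predators[cc$day > 40]), 0) # and starved within 30 d
})

test_that("harmless predators do not perturb the vole draw sequence", {
  sc_off <- scenarioPatches(1, extent = c(150, 150), grassAreaM2 = 10000,
                            years = 2, burnIn = 1, predators = list())
  ghost <- predatorParams("strong", kill_cap = 0, catch_p = 0,
                          start_day = 10)
  sc_on <- scenarioPatches(1, extent = c(150, 150), grassAreaM2 = 10000,
                           years = 2, burnIn = 1, predators = ghost)
  a <- runVoleSim(sc_off, voleParams(), seed = 4)
  b <- runVoleSim(sc_on, voleParams(), seed = 4)
  cc_a <- simCounts(a); cc_b <- simCounts(b)
  expect_identical(cc_a$total, cc_b$total)
  expect_gt(max(cc_b$predators), 0)
})

test_that("predator numbers lag vole numbers (delayed response)", {
  sim <- cachedSim("cycle40", function()
    runVoleSim(scenarioPatches(1, years = 40, burnIn = 10), voleParams(),
               seed = 1))
  cc <- simCounts(sim, postBurnIn = TRUE)
  voles <- as.numeric(tapply(cc$total, cc$year, mean))
  preds <- as.numeric(tapply(cc$predators, cc$year, mean))
  lags <- -2:2
  cors <- sapply(lags, function(k) {
    n <- length(voles)
    if (k >= 0) cor(voles[1:(n - k)], preds[(1 + k):n])
    else cor(voles[(1 - k):n], preds[1:(n + k)])
  })
  expect_gte(lags[which.max(cors)], 1)  # predators follow prey
})

test_that("strong specialists amplify fluctuation over predator-free runs", {
  sim_on <- cachedSim("cycle40", function()
    runVoleSim(scenarioPatches(1, years = 40, burnIn = 10), voleParams(),
               seed = 1))
  sc_off <- scenarioPatches(1, years = 40, burnIn = 10, predators = list())
  sim_off <- cachedSim("cycle40off", function()
    runVoleSim(sc_off, voleParams(), seed = 1))
  amp_on <- cycleMetrics(annualPeaks(simCounts(sim_on,
                                               postBurnIn = TRUE)))$amplitude
  amp_off <- cycleMetrics(annualPeaks(simCounts(sim_off,
                                                postBurnIn = TRUE)))$amplitude
  expect_lte(amp_off, 1)
  expect_gte(amp_on, 2)
})
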