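# Calibration engine: replicates, perturbation, hill climbing, the
# sequential pattern-set loop, sensitivity sweeps.

test_that("perturbation is one-at-a-time, both signs, integers rounded", {
  p <- voleParams()
  one <- perturb(p, subset = "V10")
  expect_lte(length(one), 6)
  vals <- sapply(one, `[[`, "value")
  expect_true(0.003 %in% vals)    # 0.0025 * 1.2
  expect_true(0.002 %in% vals)    # 0.0025 * 0.8

  d <- perturb(p, subset = "V15", fractions = 0.05)
  vals <- sapply(d, `[[`, "value")
  expect_setequal(vals, c(76, 84))  # day-valued parameter rounded

  # small fractions of an integer parameter collapse to duplicates
  tiny <- perturb(p, subset = "V4", fractions = c(0.01, 0.02))
  expect_lte(length(tiny), 2)
})

test_that("hill climbing is greedy and respects budget and tolerance", {
  # toy objective with optimum near (V9, V10) = (0.066, 0.003)
  obj <- function(params) {
    v <- paramValues(params)
    abs(v[["V9"]] - 0.066) + 10 * abs(v[["V10"]] - 0.003)
  }
  p0 <- voleParams()

  # one full iteration accepts exactly the best perturbation candidate
  cands <- perturb(p0, subset = c("V9", "V10"))
  vals <- sapply(cands, function(c) obj(c$params))
  best_first <- cands[[which.min(vals)]]
  hc1 <- hillClimb(obj, p0, subset = c("V9", "V10"),
                   budget = length(cands) + 1)
  acc <- hc1$history[hc1$history$accepted & hc1$history$name != "(start)", ]
  expect_equal(acc$name[1], best_first$name)
  expect_equal(acc$value[1], best_first$value)

  # repeated iterations reach the optimum within one perturbation step
  hc <- hillClimb(obj, p0, subset = c("V9", "V10"), budget = 400,
                  tolerance = 0)
  expect_lt(obj(hc$params), obj(p0))
  v <- paramValues(hc$params)
  expect_lt(abs(v[["V9"]] - 0.066) / 0.066, 0.06)

  # zero budget or already-satisfied tolerance: no movement
  hc0 <- hillClimb(obj, p0, budget = 0)
  expect_equal(paramValues(hc0$params), paramValues(p0))
  hct <- hillClimb(obj, p0, tolerance = 1e6)
  expect_equal(hct$iterations, 0)
  expect_true(hct$converged)
})

test_that("hill climbing never revisits forbidden parameterizations", {
  obj <- function(params) abs(paramValues(params)[["V9"]] - 0.066)
  p0 <- voleParams()
  cands <- perturb(p0, subset = "V9")
  vals <- sapply(cands, function(c) obj(c$params))
  bestKey <- volePOM:::.paramKey(cands[[which.min(vals)]]$params)
  hc <- hillClimb(obj, p0, subset = "V9", budget = 50,
                  forbidden = bestKey)
  expect_false(bestKey %in% hc$history$key)
})

test_that("sequential calibration gates sets and honours the forbidden list", {
  # synthetic evaluators: set 1 optimum at V9 = 0.05; set 2 rejects the
  # first fitted parameterization once, forcing a recheck loop
  seen <- new.env(); seen$keys <- character()
  evals <- list(
    set1 = function(p) abs(paramValues(p)[["V9"]] - 0.05),
    set2 = function(p) {
      k <- volePOM:::.paramKey(p)
      first <- !(k %in% seen$keys)
      seen$keys <- union(seen$keys, k)
      list(pass = !first || length(seen$keys) > 1, deviation = 0)
    },
    set3 = function(p) list(pass = TRUE, deviation = 0),
    set4 = function(p) list(pass = TRUE, deviation = 0))
  fit <- sequentialPom(evals, voleParams(V9 = 0.055), tolerance1 = 0.002,
                       subset = "V9", max_cycles = 4, budget = 60)
  expect_true(fit$converged)
  expect_equal(sort(names(fit$reports)),
               c("set1", "set2", "set3", "set4"))
  expect_lte(fit$reports$set1, 0.002)

  # an impossible later gate surfaces as a structured failure
  evals$set3 <- function(p) list(pass = FALSE, deviation = 99)
  fit2 <- sequentialPom(evals, voleParams(V9 = 0.055), tolerance1 = 0.002,
                        subset = "V9", max_cycles = 2, budget = 60)
  expect_false(fit2$converged)
  expect_equal(fit2$blocking_set, 3L)
  expect_gt(length(fit2$forbidden), 0)
})

test_that("replicate runs are reproducible and warn below the minimum", {
  sc <- miniBlock()
  statFun <- function(sim) c(final = tail(simCounts(sim)$total, 1))
  expect_warning(r <- runReplicates(sc, voleParams(), statFun, n_reps = 3,
                                    base_seed = 5),
                 "fewer than 10")
  expect_equal(nrow(r$replicates), 3)
  expect_gt(r$sd[["final"]], 0)  # stochasticity across seeds
  r2 <- suppressWarnings(runReplicates(sc, voleParams(), statFun,
                                       n_reps = 3, base_seed = 5))
  expect_identical(r$mean, r2$mean)
})

test_that("sensitivity sweep spans +/- 80% in 11 steps per parameter", {
  evalFun <- function(params) {
    v <- paramValues(params)
    c(density = (v[["V10"]] - 0.0025) / 0.0025,
      ratio = (v[["V9"]] - 0.055) / 0.055)
  }
  sw <- sensitivitySweep(voleParams(), evalFun,
                         subset = c("V9", "V10", "V12"))
  expect_equal(nrow(sw), 3 * 11)
  v10 <- sw$value[sw$parameter == "V10"]
  expect_equal(min(v10), 0.0005)
  expect_equal(max(v10), 0.0045)
  expect_true(0.0025 %in% v10)  # the fitted value is the grid centre
  centre <- sw[sw$parameter == "V10" & sw$value == 0.0025, ]
  expect_equal(centre$density, 0)
  expect_true(all(sw$overall <= 1))

  # full protocol queue size: 15 parameters x 11 values
  sw15 <- sensitivitySweep(voleParams(), function(p) c(d = 0))
  expect_lte(nrow(sw15), 15 * 11)
  expect_gte(nrow(sw15), 15 * 11 - 22)  # a few values may violate validity
})
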