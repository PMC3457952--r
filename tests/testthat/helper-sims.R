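# Shared miniature scenarios for the test suite.  Simulations here are
# deliberately small (1 ha blocks, 2-3 years); the acceptance tests use
# the full desk-scale protocols.

miniBlock <- function(years = 2, burnIn = 1, blockSide = 100)
  scenarioBlock(blockSide = blockSide, years = years, burnIn = burnIn)

# cached small run shared across tests in a file
.simCache <- new.env(parent = emptyenv())
cachedSim <- function(key, make) {
  if (is.null(.simCache[[key]])) .simCache[[key]] <- make()
  .simCache[[key]]
}

# a tiny meadow whose trap grid blankets most of the habitat, so
# essentially every resident is identified daily
miniTrapScenario <- function(years = 3, burnIn = 1) {
  land <- generateLandscape("trap_meadow", dims = c(90, 70), border = 20)
  traps <- buildTrapGrids(trapGridSpec(n_grids = 1, rows = 10, cols = 12,
                                       trap_spacing = 7, origin = c(25, 25)))
  sc <- scenarioTrapMeadow()
  sc@landscape <- land
  sc@traps <- traps
  sc@yearsTotal <- years
  sc@yearsBurnIn <- burnIn
  sc@captureYears <- years - burnIn
  sc@weather <- syntheticWeather("denmark_like", years = years, seed = 1990)
  sc
}

# independent brute-force recomputation of the mark-release-recapture
# statistics, used as the oracle for dispersalStats()
bruteForceStats <- function(records, criteria = dispersalCriteria(),
                            params = voleParams(), traps = NULL) {
  v <- paramValues(params)
  records <- records[order(records$vole_id, records$day), ]
  records <- records[!duplicated(records[, c("vole_id", "day")]), ]
  if (is.null(traps)) traps <- unique(records[, c("trap_x", "trap_y")])
  bb <- c(min(traps[, 1]), max(traps[, 1]), min(traps[, 2]), max(traps[, 2]))
  out <- list()
  for (sx in c("male", "female")) {
    two_hr <- if (sx == "male") criteria$male_two_hr_m else
      criteria$female_two_hr_m
    one_hr <- two_hr / 2
    mat <- if (sx == "male") v[["V1"]] else v[["V2"]]
    steps <- adult_steps <- maxd <- natal <- numeric(0)
    rs <- records[records$sex == sx, ]
    for (id in unique(rs$vole_id)) {
      ri <- rs[rs$vole_id == id, ]
      if (ri$natal_x[1] >= bb[1] - one_hr && ri$natal_x[1] <= bb[2] + one_hr &&
          ri$natal_y[1] >= bb[3] - one_hr && ri$natal_y[1] <= bb[4] + one_hr)
        natal <- c(natal, sqrt((ri$trap_x[1] - ri$natal_x[1])^2 +
                                 (ri$trap_y[1] - ri$natal_y[1])^2))
      if (nrow(ri) < 2) next
      for (k in 2:nrow(ri)) {
        d <- sqrt((ri$trap_x[k] - ri$trap_x[k - 1])^2 +
                    (ri$trap_y[k] - ri$trap_y[k - 1])^2)
        steps <- c(steps, d)
        if (ri$age_days[k] >= mat && ri$age_days[k - 1] >= mat)
          adult_steps <- c(adult_steps, d)
      }
      best <- 0
      for (a in 1:nrow(ri)) for (b in 1:nrow(ri))
        best <- max(best, sqrt((ri$trap_x[a] - ri$trap_x[b])^2 +
                                 (ri$trap_y[a] - ri$trap_y[b])^2))
      maxd <- c(maxd, best)
    }
    out[[sx]] <- list(
      philopatry = if (length(adult_steps))
        100 * sum(adult_steps > two_hr) / length(adult_steps) else NA,
      mean_step = if (length(steps)) mean(steps) else NA,
      mean_max = if (length(maxd)) mean(maxd) else NA,
      natal_mean = if (length(natal)) mean(natal) else NA,
      natal_far = if (length(natal))
        100 * sum(natal > two_hr) / length(natal) else NA,
      natal_near = if (length(natal))
        100 * sum(natal <= one_hr) / length(natal) else NA)
  }
  out
}

# random capture-record generator for oracle comparisons
randomRecords <- function(n, n_voles = 8, seed = 1) {
  set.seed(seed)
  data.frame(
    trap_x = sample(seq(0, 91, by = 7), n, replace = TRUE),
    trap_y = sample(seq(0, 91, by = 7), n, replace = TRUE),
    natal_x = runif(n, -30, 120),
    natal_y = runif(n, -30, 120),
    day = sample(1:200, n, replace = TRUE),
    vole_id = sample(seq_len(n_voles), n, replace = TRUE),
    age_days = sample(14:200, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE))
}
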