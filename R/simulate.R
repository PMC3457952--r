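# The daily scheduler: one call = one full run of the compiled engine.

# day-of-year of the 15th of May..September (365-day years)
.MIDMONTH_DOY <- c(May = 135L, Jun = 166L, Jul = 196L, Aug = 227L,
                   Sep = 258L)

#' Run the individual-based vole simulation
#'
#' Advances the whole world day by day: vegetation quality first, then
#' every vole in freshly shuffled order (background and lifespan
#' mortality, aging and maturation, territory assessment and eviction,
#' mating and reproduction, male restlessness, dispersal with per-day
#' dispersal mortality and en-route infanticide), then the predator
#' layer, then output recording.  The run is bit-identical for a fixed
#' (scenario, params, seed): voles and predators draw from separate
#' deterministic streams derived from \code{seed}.
#'
#' @param scenario a \linkS4class{VoleScenario}.
#' @param params a \linkS4class{VoleParams}.
#' @param seed integer seed.
#' @param ageClassEdges upper age bounds (days) of the age classes used
#'   in the mid-month structure snapshots; the last class is open.
#' @return A \linkS4class{VoleSim}.
#' @examples
#' \donttest{
#' sim <- runVoleSim(scenarioBlock(blockSide = 100, years = 3, burnIn = 1),
#'                   voleParams(), seed = 1)
#' tail(simCounts(sim))
#' }
#' @export
runVoleSim <- function(scenario, params = voleParams(), seed = 1,
                       ageClassEdges = c(30, 60, 90, Inf)) {
  validObject(scenario)
  land <- scenario@landscape
  cls <- land@classes
  nDays <- as.integer(scenario@yearsTotal * 365)
  weather <- scenario@weather
  if (nrow(weather) < nDays)
    stop("weather series shorter than the simulation")
  weather <- weather[seq_len(nDays), ]

  bw <- breedingWindow(weather, params)
  breedStart <- as.integer(ifelse(is.na(bw$start_day), -1L, bw$start_day))

  burnDays <- as.integer(scenario@yearsBurnIn * 365)
  # mid-month May-September snapshots in every post-burn-in year
  years <- seq_len(scenario@yearsTotal)
  snapInfo <- expand.grid(month = names(.MIDMONTH_DOY), year = years,
                          stringsAsFactors = FALSE)
  snapInfo$doy <- .MIDMONTH_DOY[snapInfo$month]
  snapInfo$day <- (snapInfo$year - 1L) * 365L + snapInfo$doy - 1L  # 0-based
  snapInfo <- snapInfo[snapInfo$day >= burnDays, ]

  if (scenario@captureYears > 0) {
    capStart <- as.integer((scenario@yearsTotal - scenario@captureYears) *
                             365)
    capEnd <- nDays - 1L
  } else {
    capStart <- nDays  # never
    capEnd <- -1L
  }

  predCfg <- if (length(scenario@predators)) scenario@predators else
    list(enabled = FALSE)
  initN <- max(2L, as.integer(round(scenario@initDensity *
    habitatArea(land, cls$name[cls$base_quality > 0]))))

  raw <- cpp_run_sim(land@codes, land@patches,
                     cls$base_quality, cls$growth_rate, cls$passable,
                     weather$temp_c, breedStart,
                     as.list(c(paramValues(params), paramAux(params),
                               vole_immigration_n = scenario@voleImmigration)),
                     predCfg, scenario@traps, capStart, capEnd,
                     as.integer(snapInfo$day), ageClassEdges,
                     burnDays, max(land@patches), initN,
                     as.integer(seed))

  counts <- as.data.frame(raw$counts)
  counts$day <- seq_len(nDays)
  counts$year <- (counts$day - 1L) %/% 365L + 1L
  counts$doy <- (counts$day - 1L) %% 365L + 1L
  # pattern censuses mirror field sampling of the high-quality habitat:
  # females/males are counted on food-bearing cells; *_all are grid-wide
  counts$females <- counts$census_adult_f + counts$census_juv_f
  counts$males <- counts$census_adult_m + counts$census_juv_m
  counts$females_all <- counts$adult_f + counts$juv_f
  counts$males_all <- counts$adult_m + counts$juv_m
  events <- as.data.frame(raw$events)
  events$births <- events$births_m + events$births_f
  events$day <- seq_len(nDays)

  caps <- raw$captures
  if (nrow(caps)) {
    caps$trap_x <- scenario@traps[caps$trap + 1L, 1]
    caps$trap_y <- scenario@traps[caps$trap + 1L, 2]
    caps$sex <- c("male", "female")[caps$sex + 1L]
    caps <- caps[, c("trap_x", "trap_y", "natal_x", "natal_y", "day",
                     "vole_id", "age_days", "sex")]
  } else {
    caps <- data.frame(trap_x = numeric(0), trap_y = numeric(0),
                       natal_x = numeric(0), natal_y = numeric(0),
                       day = integer(0), vole_id = integer(0),
                       age_days = integer(0), sex = character(0))
  }

  snaps <- raw$age_snapshots
  nCls <- length(ageClassEdges)
  colnames(snaps) <- c(paste0("m_class", seq_len(nCls)),
                       paste0("f_class", seq_len(nCls)))

  new("VoleSim", counts = counts, events = events,
      patchSums = raw$patch_sums, patchDays = raw$patch_days,
      captures = caps, ageSnapshots = snaps,
      snapshotInfo = snapInfo[, c("year", "month", "doy")],
      meta = list(seed = seed, scenario = scenario@id,
                  scaleFactor = scenario@scaleFactor,
                  burnInDays = burnDays, breedingWindow = bw,
                  highQualityAreaHa = habitatArea(land),
                  ageClassEdges = ageClassEdges))
}

#' Accessors for simulation results
#'
#' @param sim a \linkS4class{VoleSim}.
#' @param postBurnIn drop burn-in days.
#' @return \code{simCounts}/\code{simEvents}: data.frame of daily
#'   counts/events; \code{simCaptures}: capture records;
#'   \code{simMeta}: run metadata list.
#' @export
simCounts <- function(sim, postBurnIn = FALSE) {
  x <- sim@counts
  if (postBurnIn) x <- x[x$day > sim@meta$burnInDays, ]
  x
}

#' @rdname simCounts
#' @export
simEvents <- function(sim, postBurnIn = FALSE) {
  x <- sim@events
  if (postBurnIn) x <- x[x$day > sim@meta$burnInDays, ]
  x
}

#' @rdname simCounts
#' @export
simCaptures <- function(sim) sim@captures

#' @rdname simCounts
#' @export
simMeta <- function(sim) sim@meta

#' Seasonal mean densities per habitat patch
#'
#' Converts the per-patch seasonal occupancy tallies of a run into mean
#' vole densities (all stages) per hectare for every qualifying patch
#' (see \code{\link{patchTable}} for the area rules), averaged over the
#' post-burn-in days of each season.  Patches with no occupants in a
#' season are dropped (the comparison targets cover occupied patches).
#'
#' @param sim a \linkS4class{VoleSim}.
#' @param scenario the scenario that produced it.
#' @return data.frame: habitat, season, density (voles/ha).
#' @export
patchSeasonDensities <- function(sim, scenario) {
  pt <- patchTable(scenario@landscape)
  seasons <- colnames(sim@patchSums)
  out <- do.call(rbind, lapply(seq_len(nrow(pt)), function(i) {
    pid <- pt$patch_id[i]
    dens <- sim@patchSums[pid, ] / sim@patchDays / (pt$area_m2[i] / 1e4)
    data.frame(habitat = pt$class[i], patch_id = pid, season = seasons,
               density = as.numeric(dens))
  }))
  out <- out[out$density > 0, ]
  rownames(out) <- NULL
  out
}
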