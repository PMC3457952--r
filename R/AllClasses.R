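#' Habitat raster with patch decomposition
#'
#' A 1 m resolution raster of integer habitat-class codes together with
#' its connected-component (patch) labelling and the class attribute
#' table.  One cell is one square metre; patch area in m2 therefore
#' equals the patch cell count.  Coordinates are 0-based with x along
#' columns and y along rows; positions are cell centres and distances
#' Euclidean in metres.
#'
#' @slot codes integer matrix (rows = y, cols = x) of habitat-class codes.
#' @slot patches integer matrix of the same shape labelling connected
#'   same-class regions (4-connectivity), ids 1..n.
#' @slot classes data.frame with columns \code{code}, \code{name},
#'   \code{base_quality}, \code{growth_rate}, \code{passable}, ordered by
#'   code 0..n-1 with no gaps.
#' @export
setClass("HabitatGrid",
  representation(codes = "matrix", patches = "matrix", classes = "data.frame"))

setValidity("HabitatGrid", function(object) {
  msg <- character()
  cl <- object@classes
  need <- c("code", "name", "base_quality", "growth_rate", "passable")
  if (!all(need %in% names(cl)))
    msg <- c(msg, paste("classes must have columns:", paste(need, collapse = ", ")))
  else {
    if (!identical(cl$code, seq_len(nrow(cl)) - 1L))
      msg <- c(msg, "class codes must be 0..n-1 with no gaps")
    bad <- setdiff(unique(as.vector(object@codes)), cl$code)
    if (length(bad))
      msg <- c(msg, paste("unknown habitat codes in raster:",
                          paste(bad, collapse = ", ")))
  }
  if (!identical(dim(object@codes), dim(object@patches)))
    msg <- c(msg, "codes and patches must have identical dimensions")
  if (length(msg)) msg else TRUE
})

#' Life-history and behavioural parameter set
#'
#' The calibration surface of the vole model: the seventeen headline
#' parameters V1--V17 (reproductive ages, territory radius bounds,
#' eviction age gap, dispersal and background mortality, breeding-season
#' dates, male restlessness, density-dependence threshold, grass growth
#' temperature, infanticide probability) plus auxiliary life-history and
#' movement constants.  Defaults are the post-calibration values; see
#' \code{\link{voleParams}}.
#'
#' @slot values named numeric, V1..V17.
#' @slot aux named numeric of auxiliary constants (gestation, litter
#'   size, lifespan distribution, dispersal step budget, vegetation
#'   growth and dieback, infanticide encounter radius).
#' @export
setClass("VoleParams",
  representation(values = "numeric", aux = "numeric"))

setValidity("VoleParams", function(object) {
  v <- object@values
  msg <- character()
  if (!all(paste0("V", 1:17) %in% names(v)))
    msg <- c(msg, "values must contain V1..V17")
  else {
    pr <- v[c("V9", "V10", "V12", "V17")]
    if (any(pr < 0 | pr > 1)) msg <- c(msg, "probabilities must be in [0, 1]")
    if (v["V4"] > v["V5"]) msg <- c(msg, "female radius: V4 must be <= V5")
    if (v["V6"] > v["V7"]) msg <- c(msg, "male radius: V6 must be <= V7")
    if (v["V15"] >= v["V11"]) msg <- c(msg, "V15 must be < V11")
  }
  if (length(msg)) msg else TRUE
})

#' Simulation scenario
#'
#' Bundles everything a run needs apart from the parameter set and the
#' seed: the landscape, the weather (either a fixed daily series or a
#' synthetic-weather profile name plus its generation seed), run length
#' and burn-in, the predator configuration (empty list = predators off,
#' their effect folded into background mortality), trap coordinates and
#' the number of trailing years with daily trapping, and a scale factor
#' recording any shrinking relative to the full published protocol.
#'
#' @export
setClass("VoleScenario",
  representation(id = "character", landscape = "HabitatGrid",
                 weather = "data.frame", weatherProfile = "character",
                 weatherSeed = "numeric", yearsTotal = "numeric",
                 yearsBurnIn = "numeric", predators = "list",
                 traps = "matrix", captureYears = "numeric",
                 initDensity = "numeric", voleImmigration = "numeric",
                 scaleFactor = "numeric"))

setValidity("VoleScenario", function(object) {
  msg <- character()
  if (object@yearsBurnIn >= object@yearsTotal)
    msg <- c(msg, "burn-in must be shorter than the total run")
  if (length(object@predators) && object@captureYears > 0)
    msg <- c(msg, paste("trapping scenarios run with predators off",
                        "(background-mortality mode)"))
  if (length(msg)) msg else TRUE
})

#' Simulation result
#'
#' Daily output of one engine run: population counts by sex and stage,
#' the event log (births, deaths by cause, evictions, infanticides),
#' per-patch seasonal occupancy tallies, capture records from the
#' virtual trapping module, and mid-month age-structure snapshots.
#'
#' @slot counts data.frame: day, year, doy, adult_m, adult_f, juv_m,
#'   juv_f, total, predators.
#' @slot events data.frame of daily event counts.
#' @slot patchSums matrix patches x seasons of summed daily occupant
#'   counts over the post-burn-in period; \code{patchDays} gives the
#'   number of recorded days per season.
#' @slot captures data.frame of capture records (one per vole per day at
#'   most): trap_x, trap_y, natal_x, natal_y, day, vole_id, age_days, sex.
#' @slot ageSnapshots matrix snapshots x (sex, age-class) counts;
#'   \code{snapshotInfo} maps rows to year/month.
#' @slot meta list: seed, scaleFactor, burn-in days, breeding-window
#'   table, high-quality area (ha), age-class edges.
#' @export
setClass("VoleSim",
  representation(counts = "data.frame", events = "data.frame",
                 patchSums = "matrix", patchDays = "numeric",
                 captures = "data.frame", ageSnapshots = "matrix",
                 snapshotInfo = "data.frame", meta = "list"))

setMethod("show", "HabitatGrid", function(object) {
  d <- dim(object@codes)
  tab <- table(factor(as.vector(object@codes),
                      levels = object@classes$code,
                      labels = object@classes$name))
  cat(sprintf("HabitatGrid: %d x %d m (%d cells), %d patches\n",
              d[2], d[1], prod(d), max(object@patches)))
  tab <- tab[tab > 0]
  for (i in seq_along(tab))
    cat(sprintf("  %-22s %8d m2\n", names(tab)[i], as.integer(tab[i])))
})

setMethod("show", "VoleParams", function(object) {
  cat("VoleParams (V1..V17):\n")
  print(object@values)
  cat("auxiliary:\n")
  print(object@aux)
})

setMethod("show", "VoleScenario", function(object) {
  cat(sprintf("VoleScenario '%s': %d x %d m, %g years (%g burn-in)\n",
              object@id, ncol(object@landscape@codes),
              nrow(object@landscape@codes),
              object@yearsTotal, object@yearsBurnIn))
  cat(sprintf("  predators: %s, traps: %d, scale factor: %g\n",
              if (length(object@predators)) "on" else "off (background mode)",
              nrow(object@traps), object@scaleFactor))
})

setMethod("show", "VoleSim", function(object) {
  n <- nrow(object@counts)
  cat(sprintf("VoleSim: %d days, final population %d (%d captures recorded)\n",
              n, as.integer(object@counts$total[n]), nrow(object@captures)))
})
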