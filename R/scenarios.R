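# The four packaged study scenarios.  Full-protocol dimensions and run
# lengths are available via arguments; the defaults are the desk-scale
# configuration documented in the methods vignette, with the shrink
# recorded in scaleFactor.

.newScenario <- function(id, landscape, yearsTotal, yearsBurnIn,
                         weatherProfile, weatherSeed, predators = list(),
                         traps = matrix(numeric(0), 0, 2),
                         captureYears = 0, initDensity = 25,
                         voleImmigration = 0, scaleFactor = 1,
                         weather = NULL) {
  if (is.null(weather))
    weather <- syntheticWeather(weatherProfile, years = yearsTotal,
                                seed = weatherSeed)
  new("VoleScenario", id = id, landscape = landscape, weather = weather,
      weatherProfile = weatherProfile, weatherSeed = weatherSeed,
      yearsTotal = yearsTotal, yearsBurnIn = yearsBurnIn,
      predators = predators, traps = traps, captureYears = captureYears,
      initDensity = initDensity, voleImmigration = voleImmigration,
      scaleFactor = scaleFactor)
}

#' Packaged study scenarios
#'
#' \code{scenarioBlock()}: a homogeneous high-quality grassland block
#' surrounded by an equally large dispersal-only area, Finland-like
#' weather, predators off; used for the age/sex-structure and density
#' patterns.  The full protocol runs 20 years with 10 discarded; the
#' desk-scale default is a 200 x 200 m block over 10 years with 5
#' discarded.
#'
#' \code{scenarioTrapMeadow()}: a 500 x 400 m grassland meadow
#' surrounded by forest with three 14 x 7 live-trap grids in its centre
#' (7 m trap spacing, 30 m between grids, 1 m capture radius); run to
#' equilibrium, then trapped daily for two years.  Full protocol: 10 + 2
#' years; desk scale: 5 + 2.
#'
#' \code{scenarioPatches()}: 1, 3 or 16 square grassland patches of
#' equal total area in a dispersal-only matrix with specialist predators
#' enabled; 50 years are simulated and annual peak abundances analysed
#' for cycling.
#'
#' \code{scenarioMosaic()}: a synthetic mixed farmland mosaic for
#' habitat-by-season density comparisons, Denmark-like weather; 30
#' years with 20 discarded at full protocol, 10/6 at desk scale.
#'
#' @param blockSide grassland block side (m).
#' @param years,burnIn total and discarded years.
#' @param weatherSeed seed for the synthetic weather series (fixed per
#'   scenario so that replicates share weather, as with a historical
#'   series).
#' @param scaleFactor bookkeeping field recording shrink relative to the
#'   full protocol; carried into all outputs.
#' @return A \linkS4class{VoleScenario}.
#' @export
scenarioBlock <- function(blockSide = 200, years = 10, burnIn = 5,
                          weatherSeed = 1990, scaleFactor = 0.5) {
  .newScenario("set1_block",
               generateLandscape("homogeneous_block", dims = c(blockSide,
                                                               blockSide)),
               years, burnIn, "finland_like", weatherSeed,
               scaleFactor = scaleFactor)
}

#' @rdname scenarioBlock
#' @param dims meadow width and height (m).
#' @param sampleYears trailing years with daily trapping.
#' @export
scenarioTrapMeadow <- function(dims = c(500, 400), years = 7, burnIn = 5,
                               sampleYears = 2, weatherSeed = 1990,
                               scaleFactor = 0.7) {
  land <- generateLandscape("trap_meadow", dims = dims, border = 50)
  traps <- buildTrapGrids(trapGridSpec(
    origin = c(50 + (dims[1] - 186) / 2, 50 + (dims[2] - 91) / 2)))
  .newScenario("set3_trapmeadow", land, years, burnIn, "denmark_like",
               weatherSeed, traps = traps, captureYears = sampleYears,
               scaleFactor = scaleFactor)
}

#' @rdname scenarioBlock
#' @param nPatches 1, 3 or 16 grassland patches.
#' @param extent total landscape extent (m).
#' @param grassAreaM2 summed grassland area shared by the patches.
#' @param predators predator settings (see
#'   \code{\link{predatorParams}}), or \code{list()} for none.
#' @export
scenarioPatches <- function(nPatches = 1, extent = c(700, 700),
                            grassAreaM2 = 62500, years = 50, burnIn = 10,
                            predators = predatorParams("strong"),
                            weatherSeed = 1990, scaleFactor = 0.5) {
  land <- generateLandscape("patches", dims = extent, n_patches = nPatches,
                            seed = nPatches, grass_area_m2 = grassAreaM2)
  .newScenario(sprintf("set4_patches%d", nPatches), land, years, burnIn,
               "denmark_like", weatherSeed, predators = predators,
               voleImmigration = 6, scaleFactor = scaleFactor)
}

#' @rdname scenarioBlock
#' @param extentMosaic total mosaic extent (m).
#' @param landscapeSeed seed of the mosaic generator.
#' @export
scenarioMosaic <- function(extentMosaic = c(500, 500), years = 10,
                           burnIn = 6, landscapeSeed = 7,
                           weatherSeed = 1990, scaleFactor = 0.25) {
  land <- generateLandscape("mosaic", dims = extentMosaic,
                            seed = landscapeSeed)
  .newScenario("set2_mosaic", land, years, burnIn, "denmark_like",
               weatherSeed, scaleFactor = scaleFactor)
}
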