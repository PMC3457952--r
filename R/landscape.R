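# Raster world: habitat classes, vegetation quality, breeding phenology,
# and the scenario landscape generators.

#' Default habitat class table
#'
#' Ten habitat classes with per-class base quality (unitless, multiplied
#' by daily digestibility to give cell quality), a relative vegetation
#' growth rate, and passability for dispersing voles.  Base qualities
#' rank classes from unmanaged grassland (best) down through pastures,
#' set-aside and linear features to field crops and woody habitats;
#' dispersal-only habitat and non-habitat hold no food value, and
#' non-habitat additionally blocks movement.  The paper trail behind the
#' model describes quality only qualitatively, so these scalars are
#' package defaults, adjustable per scenario.
#'
#' @return data.frame with columns code, name, base_quality,
#'   growth_rate, passable.
#' @export
voleHabitatClasses <- function() {
  data.frame(
    code = 0:9,
    name = c("non_habitat", "grassland_unmanaged", "pasture_tussocky",
             "pasture_low_yield", "set_aside", "linear_feature",
             "field_crop", "woodland", "forest_plantation",
             "dispersal_only"),
    base_quality = c(0, 1.0, 0.9, 0.8, 0.85, 0.9, 0.5, 0.4, 0.55, 0),
    growth_rate  = c(0, 1, 1, 1, 1, 1, 1, 0.5, 0.5, 0),
    passable = c(FALSE, rep(TRUE, 9)),
    stringsAsFactors = FALSE)
}

#' Construct a HabitatGrid from a code matrix
#'
#' Labels connected same-class regions (4-connectivity) and attaches the
#' class table.
#'
#' @param codes integer matrix of habitat codes (rows = y, cols = x).
#' @param classes class attribute table; see
#'   \code{\link{voleHabitatClasses}}.
#' @return A \linkS4class{HabitatGrid}.
#' @export
habitatGrid <- function(codes, classes = voleHabitatClasses()) {
  storage.mode(codes) <- "integer"
  patches <- cpp_label_patches(codes)
  new("HabitatGrid", codes = codes, patches = patches, classes = classes)
}

#' Forage quality (digestibility) from the new-green biomass fraction
#'
#' Digestibility is 0.7 plus the square root of the proportion of new
#' green biomass (younger than 14 days) out of total biomass, capped at
#' 1.0.  This gives a 30\% seasonal swing in habitat quality between
#' mature standing vegetation and fresh spring growth.
#'
#' @param new_green_fraction proportion in [0, 1].
#' @return quality value in [0.7, 1.0].
#' @examples
#' digestibility(0)     # 0.7 floor
#' digestibility(0.04)  # 0.9
#' digestibility(1)     # capped at 1.0
#' @export
digestibility <- function(new_green_fraction) {
  if (any(new_green_fraction < 0 | new_green_fraction > 1, na.rm = FALSE) ||
      any(is.na(new_green_fraction)))
    stop("new_green_fraction must be in [0, 1]")
  pmin(1.0, 0.7 + sqrt(new_green_fraction))
}

#' Vegetation cohort ledger
#'
#' Tracks daily biomass cohorts by age: growth on days at or above the
#' grass-growth temperature (V14) enters as an age-0 cohort, cohorts age
#' one day per day, and biomass older than 14 days joins the mature
#' pool.  On days below V14 the mature pool decays by the winter dieback
#' rate, so each spring's new growth again dominates and digestibility
#' recovers.  \code{vegetationState()} builds an empty ledger;
#' \code{updateVegetation()} advances it one day.
#'
#' @param mature initial mature biomass.
#' @return A list with components \code{cohorts} (length-14 biomass by
#'   age 0..13 days), \code{mature}, \code{new_green_fraction} and
#'   \code{digestibility}.
#' @export
vegetationState <- function(mature = 0) {
  st <- list(cohorts = numeric(14), mature = mature)
  .veg_summarize(st)
}

.veg_summarize <- function(st) {
  ng <- sum(st$cohorts)
  tot <- ng + st$mature
  st$new_green_fraction <- if (tot > 0) ng / tot else 0
  st$digestibility <- digestibility(st$new_green_fraction)
  st
}

#' @rdname vegetationState
#' @param state a vegetation state list.
#' @param temp daily mean temperature (deg C).
#' @param params a \linkS4class{VoleParams} (uses V14, growth_increment,
#'   winter_decay).
#' @export
updateVegetation <- function(state, temp, params = voleParams()) {
  v <- paramValues(params); a <- paramAux(params)
  state$mature <- state$mature + state$cohorts[14]
  state$cohorts <- c(0, state$cohorts[-14])
  if (temp >= v[["V14"]]) {
    state$cohorts[1] <- a[["growth_increment"]]
  } else {
    state$mature <- state$mature * (1 - a[["winter_decay"]])
  }
  .veg_summarize(state)
}

#' Weather-driven breeding window
#'
#' Breeding starts on the first day on which the grass-growth
#' temperature (V14) has been reached for 7 consecutive days -- i.e. the
#' 7th qualifying day -- but never before day V15; conception cannot be
#' initiated from day V11 onwards.  Computed per 365-day year.
#'
#' @param weather data.frame with columns \code{doy} and \code{temp_c},
#'   one row per simulated day (years of 365 days).
#' @param params a \linkS4class{VoleParams}.
#' @return data.frame with one row per year: \code{year},
#'   \code{start_day} (NA if breeding never triggers), \code{end_day}.
#' @export
breedingWindow <- function(weather, params = voleParams()) {
  v <- paramValues(params)
  n_years <- nrow(weather) / 365
  if (n_years != floor(n_years))
    stop("weather must cover whole 365-day years")
  out <- data.frame(year = seq_len(n_years), start_day = NA_real_,
                    end_day = v[["V11"]])
  for (yr in seq_len(n_years)) {
    temp <- weather$temp_c[(yr - 1) * 365 + 1:365]
    ok <- temp >= v[["V14"]]
    run <- 0
    for (d in 1:365) {
      run <- if (ok[d]) run + 1 else 0
      if (run >= 7) { out$start_day[yr] <- max(v[["V15"]], d); break }
    }
    if (!is.na(out$start_day[yr]) && out$start_day[yr] > out$end_day[yr])
      out$start_day[yr] <- NA_real_  # empty window
  }
  out
}

# run a generator under a local, seeded RNG without touching the
# caller's RNG state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Scenario landscape generators
#'
#' Deterministic (per seed) generators for the landscape types used by
#' the pattern-testing scenarios:
#' \describe{
#'   \item{homogeneous_block}{a square block of unmanaged grassland
#'     surrounded by an equally large total area of dispersal-only
#'     habitat (age/sex-structure scenario).}
#'   \item{trap_meadow}{a grassland rectangle of exactly
#'     \code{dims[1] x dims[2]} m (default 500 x 400) surrounded by a
#'     woodland belt (dispersal/trapping scenario).}
#'   \item{patches}{\code{n_patches} disjoint square grassland patches of
#'     equal total area in a dispersal-only matrix (cycling scenarios;
#'     1, 3 or 16 patches).}
#'   \item{mosaic}{seeded random rectangles over a multi-class landscape
#'     with Dirichlet-distributed class shares; a synthetic stand-in for
#'     a real mixed farmland map.}
#' }
#'
#' @param kind one of \code{"homogeneous_block"}, \code{"trap_meadow"},
#'   \code{"patches"}, \code{"mosaic"}.
#' @param dims c(width, height) in metres of the core area (block side,
#'   meadow, or total extent for patches/mosaic).
#' @param n_patches number of grassland patches for \code{kind =
#'   "patches"}.
#' @param seed integer seed; output is reproducible given (kind, dims,
#'   seed).
#' @param grass_area_m2 total grassland area for \code{kind = "patches"}.
#' @param border width of the surrounding belt (trap_meadow), m.
#' @param class_shares optional named shares for \code{mosaic}.
#' @return A \linkS4class{HabitatGrid}.
#' @examples
#' g <- generateLandscape("patches", dims = c(300, 300), n_patches = 3,
#'                        seed = 1, grass_area_m2 = 3 * 40^2)
#' @export
generateLandscape <- function(kind, dims = c(200, 200), n_patches = 1,
                              seed = 1, grass_area_m2 = 90000,
                              border = 50, class_shares = NULL) {
  kind <- match.arg(kind, c("homogeneous_block", "trap_meadow", "patches",
                            "mosaic"))
  cls <- voleHabitatClasses()
  code <- function(nm) cls$code[match(nm, cls$name)]
  grid <- switch(kind,
    homogeneous_block = {
      side <- dims[1]
      tot <- ceiling(side * sqrt(2))  # surround area == block area
      m <- matrix(code("dispersal_only"), tot, tot)
      off <- floor((tot - side) / 2)
      m[off + seq_len(side), off + seq_len(side)] <- code("grassland_unmanaged")
      m
    },
    trap_meadow = {
      w <- dims[1]; h <- dims[2]
      m <- matrix(code("woodland"), h + 2 * border, w + 2 * border)
      m[border + seq_len(h), border + seq_len(w)] <- code("grassland_unmanaged")
      m
    },
    patches = {
      W <- dims[1]; H <- dims[2]
      m <- matrix(code("dispersal_only"), H, W)
      side <- floor(sqrt(grass_area_m2 / n_patches))
      if (side > min(W, H) %/% ceiling(sqrt(n_patches)) - 2)
        stop("grass_area_m2 too large for these dims and n_patches")
      ncol_p <- ceiling(sqrt(n_patches))
      nrow_p <- ceiling(n_patches / ncol_p)
      .with_seed(seed, {
        k <- 0
        for (i in seq_len(nrow_p)) for (j in seq_len(ncol_p)) {
          if (k >= n_patches) break
          k <- k + 1
          cx <- floor(W * (j - 0.5) / ncol_p)
          cy <- floor(H * (i - 0.5) / nrow_p)
          jit <- if (n_patches > 1) round(runif(2, -side / 4, side / 4)) else c(0, 0)
          x0 <- min(max(1, cx - side %/% 2 + jit[1]), W - side)
          y0 <- min(max(1, cy - side %/% 2 + jit[2]), H - side)
          m[y0 + seq_len(side) - 1, x0 + seq_len(side) - 1] <-
            code("grassland_unmanaged")
        }
      })
      m
    },
    mosaic = {
      W <- dims[1]; H <- dims[2]
      use <- c("field_crop", "grassland_unmanaged", "pasture_tussocky",
               "pasture_low_yield", "set_aside", "linear_feature",
               "woodland", "forest_plantation")
      if (is.null(class_shares)) {
        class_shares <- .with_seed(seed, {
          g <- rgamma(length(use), shape = c(8, 2, 2, 2, 1.5, 1, 2, 1.5))
          setNames(g / sum(g), use)
        })
      }
      .with_seed(seed + 1, {
        m <- matrix(code("field_crop"), H, W)
        # lay seeded random rectangles, largest class share first
        target <- sort(class_shares, decreasing = TRUE)
        for (nm in names(target)) {
          area <- 0; want <- target[[nm]] * W * H
          while (area < want) {
            w <- sample(20:max(21, W %/% 4), 1)
            h <- sample(20:max(21, H %/% 4), 1)
            if (nm == "linear_feature") { w <- sample(100:min(400, W), 1); h <- 5 }
            x0 <- sample(seq_len(max(1, W - w)), 1)
            y0 <- sample(seq_len(max(1, H - h)), 1)
            m[y0 + seq_len(h) - 1, x0 + seq_len(w) - 1] <- code(nm)
            area <- area + w * h
          }
        }
        m
      })
    })
  habitatGrid(grid, cls)
}

#' Patch table with minimum-area filtering
#'
#' Tabulates the patches of a grid and applies the area filter used when
#' comparing model densities against field estimates: patches qualify
#' only above 1 ha, except unmanaged grassland and linear features
#' (rarely that large in real landscapes) which qualify from 1000 m2.
#' Non-habitat and dispersal-only regions are never tabulated.
#'
#' @param grid a \linkS4class{HabitatGrid}.
#' @param keep_all if TRUE, return all habitat patches with an
#'   \code{included} flag instead of filtering.
#' @return data.frame: patch_id, code, class, area_m2 (and
#'   \code{included} when \code{keep_all}).
#' @export
patchTable <- function(grid, keep_all = FALSE) {
  pid <- as.vector(grid@patches)
  cd <- as.vector(grid@codes)
  area <- tapply(rep(1L, length(pid)), pid, sum)
  pcode <- tapply(cd, pid, function(x) x[1])
  out <- data.frame(patch_id = as.integer(names(area)),
                    code = as.integer(pcode),
                    area_m2 = as.integer(area))
  out$class <- grid@classes$name[match(out$code, grid@classes$code)]
  out <- out[!out$class %in% c("non_habitat", "dispersal_only"), ]
  lim <- ifelse(out$class %in% c("grassland_unmanaged", "linear_feature"),
                1000, 10000)
  out$included <- out$area_m2 >= lim
  out <- out[order(out$patch_id), c("patch_id", "code", "class", "area_m2",
                                    "included")]
  rownames(out) <- NULL
  if (keep_all) out else out[out$included, names(out) != "included"]
}

#' Area of selected habitat classes, in hectares
#'
#' @param grid a \linkS4class{HabitatGrid}.
#' @param classes habitat class names to sum over.
#' @return area in ha (1 cell = 1 m2).
#' @export
habitatArea <- function(grid, classes = "grassland_unmanaged") {
  codes <- grid@classes$code[grid@classes$name %in% classes]
  sum(as.vector(grid@codes) %in% codes) / 1e4
}
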