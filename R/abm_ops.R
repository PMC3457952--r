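# Unit-level behavioural rules of the vole agents.  These are the
# reference semantics of the daily scheduler; the compiled engine applies
# the same rules agent-by-agent inside runVoleSim().

#' Territory acceptability at a location
#'
#' Scans candidate radii from the sex-specific minimum to maximum and
#' returns the smallest radius whose mean cell quality times the quality
#' multiplier (V3) reaches the score threshold of 1.0 and, when
#' \code{local_counts} is supplied, which does not trigger the density
#' rule (see \code{\link{densityEffectsActive}}).
#'
#' @param center c(x, y) in cell coordinates.
#' @param sex "male" or "female".
#' @param quality numeric matrix of per-cell quality (rows = y, cols =
#'   x), e.g. base quality times digestibility.
#' @param params a \linkS4class{VoleParams}.
#' @param local_counts optional function(radius) giving the number of
#'   other voles within that radius of the centre.
#' @return list(acceptable = logical, radius = chosen radius or NA).
#' @export
territoryAcceptable <- function(center, sex = c("female", "male"), quality,
                                params = voleParams(), local_counts = NULL) {
  sex <- match.arg(sex)
  v <- paramValues(params)
  rmin <- if (sex == "male") v[["V6"]] else v[["V4"]]
  rmax <- if (sex == "male") v[["V7"]] else v[["V5"]]
  H <- nrow(quality); W <- ncol(quality)
  for (r in rmin:rmax) {
    dy <- -r:r
    tot <- 0; n <- 0
    for (d in dy) {
      w <- floor(sqrt(r^2 - d^2))
      n <- n + 2 * w + 1
      y <- center[2] + d
      if (y < 0 || y >= H) next
      xs <- max(0, center[1] - w):min(W - 1, center[1] + w)
      tot <- tot + sum(quality[y + 1, xs + 1])
    }
    if (tot / n * v[["V3"]] < 1.0) next
    if (!is.null(local_counts) &&
        densityEffectsActive(local_counts(r), sex, params)) next
    return(list(acceptable = TRUE, radius = r))
  }
  list(acceptable = FALSE, radius = NA_real_)
}

#' Eviction rule
#'
#' An older vole can evict a younger one only within the same sex, when
#' territory overlap exceeds 50\% (measured on the younger vole's
#' territory), and when the age difference reaches the eviction age gap
#' (V8).
#'
#' @param older_age,younger_age ages in days.
#' @param overlap_fraction shared area over the younger vole's territory
#'   area, in [0, 1].
#' @param same_sex logical.
#' @param params a \linkS4class{VoleParams}.
#' @return logical.
#' @examples
#' canEvict(100, 60, 0.6, TRUE)   # TRUE: gap 40 >= 30, overlap > 50%
#' canEvict(100, 80, 0.6, TRUE)   # FALSE: gap 20 < 30
#' @export
canEvict <- function(older_age, younger_age, overlap_fraction,
                     same_sex = TRUE, params = voleParams()) {
  stopifnot(older_age >= 0, younger_age >= 0,
            overlap_fraction >= 0, overlap_fraction <= 1)
  same_sex && overlap_fraction > 0.5 &&
    (older_age - younger_age) >= paramValues(params)[["V8"]]
}

#' Mate choice
#'
#' A female mates with a male whose territory contains her position; if
#' several qualify she chooses the one whose territory centre is
#' nearest, ties broken by lowest id.
#'
#' @param female_location c(x, y).
#' @param males data.frame with columns id, x, y (territory centre),
#'   radius.
#' @return the chosen male id, or NA if no territory overlaps her
#'   position.
#' @export
chooseMate <- function(female_location, males) {
  if (nrow(males) == 0) return(NA_integer_)
  d <- sqrt((males$x - female_location[1])^2 +
              (males$y - female_location[2])^2)
  ok <- d <= males$radius
  if (!any(ok)) return(NA_integer_)
  cand <- males[ok, ]; dc <- d[ok]
  cand <- cand[order(dc, cand$id), ]
  cand$id[1]
}

#' Maturation rule
#'
#' Juveniles become adult at the sex-specific minimum reproductive age
#' (V1 males, V2 females); idempotent thereafter.
#'
#' @param age days; @param sex "male" or "female".
#' @param params a \linkS4class{VoleParams}.
#' @return stage, "juvenile" or "adult".
#' @export
maturationStage <- function(age, sex = c("male", "female"),
                            params = voleParams()) {
  sex <- match.arg(sex)
  v <- paramValues(params)
  thr <- if (sex == "male") v[["V1"]] else v[["V2"]]
  ifelse(age >= thr, "adult", "juvenile")
}

#' Daily survival draw
#'
#' A vole dies with probability \eqn{1 - (1 - V10)(1 - V9 \cdot d)}
#' where \eqn{d} indicates a dispersal day (independent competing
#' hazards), and additionally dies deterministically once age exceeds
#' its assigned physiological lifespan.  Vectorized over voles.
#'
#' @param age,lifespan days.
#' @param dispersed_today logical.
#' @param params a \linkS4class{VoleParams}.
#' @return logical vector, TRUE = survives the day.
#' @export
dailyMortality <- function(age, lifespan, dispersed_today = FALSE,
                           params = voleParams()) {
  v <- paramValues(params)
  p_die <- 1 - (1 - v[["V10"]]) * (1 - v[["V9"]] * as.numeric(dispersed_today))
  n <- max(length(age), length(p_die))
  survives <- runif(n) >= p_die
  survives & (age <= lifespan)
}

#' Draw physiological lifespans
#'
#' Normal with mean 15 and SD 3 months (30.44 days per month),
#' truncated below at 1 day.
#'
#' @param n number of draws.
#' @param params a \linkS4class{VoleParams}.
#' @return lifespans in days.
#' @export
drawLifespan <- function(n, params = voleParams()) {
  a <- paramAux(params)
  pmax(1, rnorm(n, a[["lifespan_mean_months"]], a[["lifespan_sd_months"]]) *
         a[["month_days"]])
}

#' Density-dependence switch
#'
#' Density effects engage once the number of voles within the territory
#' bounds reaches the threshold V13, scaled by the ratio of the
#' sex-specific minimum territory area to the female minimum territory
#' area (males, with larger minimum territories, tolerate
#' proportionally more neighbours).
#'
#' @param local_count voles within the territory bounds (excluding the
#'   focal vole).
#' @param sex "male" or "female".
#' @param params a \linkS4class{VoleParams}.
#' @return logical: TRUE when density effects are active.
#' @export
densityEffectsActive <- function(local_count, sex = c("female", "male"),
                                 params = voleParams()) {
  sex <- match.arg(sex)
  v <- paramValues(params)
  rmin <- if (sex == "male") v[["V6"]] else v[["V4"]]
  local_count >= v[["V13"]] * (rmin^2) / (v[["V4"]]^2)
}

#' Male restlessness
#'
#' During the breeding season a settled adult male with no adult female
#' inside his territory abandons it (and starts moving) with daily
#' probability V12.
#'
#' @param overlapping_females count of adult females inside the
#'   territory.
#' @param n number of independent daily draws.
#' @param params a \linkS4class{VoleParams}.
#' @return logical vector, TRUE = moves.
#' @export
maleRestlessness <- function(overlapping_females, n = 1,
                             params = voleParams()) {
  if (overlapping_females > 0) return(rep(FALSE, n))
  runif(n) < paramValues(params)[["V12"]]
}

#' Infanticide attempt
#'
#' When a mature male beyond the bounds of his original territory
#' encounters a female with an un-weaned litter, he attempts
#' infanticide with probability V17; success depends on the age of the
#' young, declining linearly from certain at age 0 to impossible at
#' weaning: \eqn{P(success) = max(0, 1 - age/14)}.
#'
#' @param litter_age days (must be below weaning age).
#' @param params a \linkS4class{VoleParams}.
#' @return logical: TRUE = litter killed.
#' @export
infanticideAttempt <- function(litter_age, params = voleParams()) {
  v <- paramValues(params); a <- paramAux(params)
  if (litter_age >= a[["weaning_age"]])
    stop("litter already weaned: no infanticide attempt possible")
  if (runif(1) >= v[["V17"]]) return(FALSE)
  runif(1) < max(0, 1 - litter_age / a[["weaning_age"]])
}

#' Draw litter sizes
#'
#' Truncated Poisson (minimum 1) around the configured mean.
#'
#' @param n number of litters.
#' @param params a \linkS4class{VoleParams}.
#' @return integer litter sizes.
#' @export
drawLitterSize <- function(n, params = voleParams()) {
  pmax(1L, stats::rpois(n, paramAux(params)[["litter_mean"]]))
}
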