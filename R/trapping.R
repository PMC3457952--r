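# Virtual ecologist: simulated live-trapping and mark-release-recapture
# statistics replicating a classic field design (three 14 x 7 trap
# grids, 7 m spacing, 30 m between grids, 1 m capture radius, daily
# identification).

#' Trap grid specification
#'
#' Three 14 x 7 grids of live traps with 7 m between traps and 30 m
#' between grids (edge to edge).  Rows run along y, columns along x;
#' the grids are laid side by side along x.
#'
#' @param n_grids,rows,cols grid layout.
#' @param trap_spacing m between traps within a grid.
#' @param inter_grid_gap m between nearest traps of adjacent grids.
#' @param capture_radius m within which a vole is identified at a trap.
#' @param origin c(x, y) of the first trap.
#' @return a list spec for \code{\link{buildTrapGrids}}.
#' @export
trapGridSpec <- function(n_grids = 3, rows = 14, cols = 7,
                         trap_spacing = 7, inter_grid_gap = 30,
                         capture_radius = 1, origin = c(0, 0)) {
  list(n_grids = n_grids, rows = rows, cols = cols,
       trap_spacing = trap_spacing, inter_grid_gap = inter_grid_gap,
       capture_radius = capture_radius, origin = origin)
}

#' @rdname trapGridSpec
#' @param spec a trap grid spec.
#' @return \code{buildTrapGrids}: matrix with columns x, y, one row per
#'   trap (n_grids * rows * cols).
#' @export
buildTrapGrids <- function(spec = trapGridSpec()) {
  gw <- (spec$cols - 1) * spec$trap_spacing  # grid width along x
  out <- do.call(rbind, lapply(seq_len(spec$n_grids), function(g) {
    x0 <- spec$origin[1] + (g - 1) * (gw + spec$inter_grid_gap)
    xs <- x0 + (seq_len(spec$cols) - 1) * spec$trap_spacing
    ys <- spec$origin[2] + (seq_len(spec$rows) - 1) * spec$trap_spacing
    cbind(x = rep(xs, each = spec$rows), y = rep(ys, times = spec$cols))
  }))
  colnames(out) <- c("x", "y")
  out
}

#' Daily capture identification
#'
#' Returns one record per vole whose position (cell centre) lies within
#' the capture radius of any trap; when several traps qualify, the
#' nearest is recorded (ties broken by lowest trap index).
#'
#' @param positions data.frame of voles: vole_id, x, y (cell
#'   coordinates), age_days, sex, natal_x, natal_y.
#' @param traps trap coordinate matrix from
#'   \code{\link{buildTrapGrids}}.
#' @param day day index recorded.
#' @param capture_radius m.
#' @return capture records data.frame: trap_x, trap_y, natal_x,
#'   natal_y, day, vole_id, age_days, sex.
#' @export
recordCaptures <- function(positions, traps, day = 1, capture_radius = 1) {
  hit <- lapply(seq_len(nrow(positions)), function(i) {
    px <- positions$x[i] + 0.5; py <- positions$y[i] + 0.5
    d <- sqrt((traps[, 1] - px)^2 + (traps[, 2] - py)^2)
    j <- which.min(d)
    if (d[j] > capture_radius) return(NULL)
    data.frame(trap_x = traps[j, 1], trap_y = traps[j, 2],
               natal_x = positions$natal_x[i],
               natal_y = positions$natal_y[i], day = day,
               vole_id = positions$vole_id[i],
               age_days = positions$age_days[i], sex = positions$sex[i])
  })
  hit <- hit[!vapply(hit, is.null, logical(1))]
  if (!length(hit))
    return(data.frame(trap_x = numeric(0), trap_y = numeric(0),
                      natal_x = numeric(0), natal_y = numeric(0),
                      day = integer(0), vole_id = integer(0),
                      age_days = integer(0), sex = character(0)))
  do.call(rbind, hit)
}

#' Dispersal criteria
#'
#' Movement thresholds and targets of the dispersal pattern set.  Two
#' home-range diameters span 90 m for males and 70 m for females (one
#' home range therefore 45 and 35 m); adult philopatry requires fewer
#' than 2\% of adult inter-capture movements to exceed two home-range
#' diameters, and the natal-dispersal targets are 13.8\% (+/- 5) of
#' natal distances beyond two home ranges with 60\% (+/- 10) within one.
#'
#' @param male_two_hr_m,female_two_hr_m two home-range diameters (m).
#' @param philopatry_limit_pct pass line for adult long movements.
#' @param natal_far_target_pct,natal_far_tol_pct natal fraction beyond
#'   two home ranges, and tolerance.
#' @param natal_near_target_pct,natal_near_tol_pct natal fraction
#'   within one home range, and tolerance.
#' @return a criteria list.
#' @export
dispersalCriteria <- function(male_two_hr_m = 90, female_two_hr_m = 70,
                              philopatry_limit_pct = 2,
                              natal_far_target_pct = 13.8,
                              natal_far_tol_pct = 5,
                              natal_near_target_pct = 60,
                              natal_near_tol_pct = 10) {
  list(male_two_hr_m = male_two_hr_m, female_two_hr_m = female_two_hr_m,
       philopatry_limit_pct = philopatry_limit_pct,
       natal_far_target_pct = natal_far_target_pct,
       natal_far_tol_pct = natal_far_tol_pct,
       natal_near_target_pct = natal_near_target_pct,
       natal_near_tol_pct = natal_near_tol_pct)
}

#' Mark-release-recapture dispersal statistics
#'
#' Recreates the statistics of the original trapping studies from the
#' capture records of a run, per sex:
#' \itemize{
#'   \item adult philopatry: percentage of inter-capture movements of
#'     adults (both captures at or beyond the sex-specific maturity
#'     age) exceeding two home-range diameters;
#'   \item mean distance between successive captures of the same
#'     individual (all ages), with SD;
#'   \item mean of each individual's maximum pairwise capture distance
#'     (individuals with at least two captures), with SD;
#'   \item natal dispersal: distance from the natal location to the
#'     first capture, restricted to voles born within the bounding box
#'     of the grids dilated by one sex-specific home-range diameter;
#'     fractions beyond two home-range diameters and within one.
#' }
#' At most one record per vole and day enters (duplicates collapse to
#' the first).  Voles with a single capture contribute to the natal
#' statistics only.
#'
#' @param records capture records (see \code{\link{recordCaptures}}).
#' @param criteria a \code{\link{dispersalCriteria}} list.
#' @param params a \linkS4class{VoleParams} (maturity ages V1/V2).
#' @param traps trap coordinates; defaults to the bounding box of the
#'   trap positions present in \code{records}.
#' @return list of per-sex statistics; an empty record set returns a
#'   structure of NAs with \code{n = 0}.
#' @export
dispersalStats <- function(records, criteria = dispersalCriteria(),
                           params = voleParams(), traps = NULL) {
  empty <- list(
    philopatry_pct = c(male = NA_real_, female = NA_real_),
    mean_step_m = c(male = NA_real_, female = NA_real_),
    sd_step_m = c(male = NA_real_, female = NA_real_),
    mean_max_m = c(male = NA_real_, female = NA_real_),
    sd_max_m = c(male = NA_real_, female = NA_real_),
    natal_mean_m = c(male = NA_real_, female = NA_real_),
    natal_far_pct = c(male = NA_real_, female = NA_real_),
    natal_near_pct = c(male = NA_real_, female = NA_real_),
    n_records = 0L, n_individuals = 0L)
  if (nrow(records) == 0) return(empty)

  v <- paramValues(params)
  records <- records[order(records$vole_id, records$day), ]
  records <- records[!duplicated(records[, c("vole_id", "day")]), ]

  if (is.null(traps))
    traps <- unique(records[, c("trap_x", "trap_y")])
  bbox <- c(min(traps[, 1]), max(traps[, 1]), min(traps[, 2]),
            max(traps[, 2]))

  res <- empty
  res$n_records <- nrow(records)
  res$n_individuals <- length(unique(records$vole_id))

  for (sx in c("male", "female")) {
    rs <- records[records$sex == sx, ]
    if (nrow(rs) == 0) next
    two_hr <- if (sx == "male") criteria$male_two_hr_m else
      criteria$female_two_hr_m
    one_hr <- two_hr / 2
    mat_age <- if (sx == "male") v[["V1"]] else v[["V2"]]

    steps <- c(); adult_steps <- c(); maxd <- c()
    natal <- c()
    for (id in unique(rs$vole_id)) {
      ri <- rs[rs$vole_id == id, ]
      # natal sample restriction: born within grids + one home range
      if (ri$natal_x[1] >= bbox[1] - one_hr &&
          ri$natal_x[1] <= bbox[2] + one_hr &&
          ri$natal_y[1] >= bbox[3] - one_hr &&
          ri$natal_y[1] <= bbox[4] + one_hr) {
        natal <- c(natal, sqrt((ri$trap_x[1] - ri$natal_x[1])^2 +
                                 (ri$trap_y[1] - ri$natal_y[1])^2))
      }
      if (nrow(ri) < 2) next
      d <- sqrt(diff(ri$trap_x)^2 + diff(ri$trap_y)^2)
      steps <- c(steps, d)
      adult <- ri$age_days >= mat_age
      adult_steps <- c(adult_steps, d[adult[-length(adult)] & adult[-1]])
      dd <- as.matrix(dist(ri[, c("trap_x", "trap_y")]))
      maxd <- c(maxd, max(dd))
    }
    res$philopatry_pct[sx] <- if (length(adult_steps))
      100 * mean(adult_steps > two_hr) else NA_real_
    if (length(steps)) {
      res$mean_step_m[sx] <- mean(steps)
      res$sd_step_m[sx] <- sd(steps)
    }
    if (length(maxd)) {
      res$mean_max_m[sx] <- mean(maxd)
      res$sd_max_m[sx] <- sd(maxd)
    }
    if (length(natal)) {
      res$natal_mean_m[sx] <- mean(natal)
      res$natal_far_pct[sx] <- 100 * mean(natal > two_hr)
      res$natal_near_pct[sx] <- 100 * mean(natal <= one_hr)
    }
  }
  res
}
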