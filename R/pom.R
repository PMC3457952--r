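# Calibration machinery: replicate management, one-at-a-time parameter
# perturbation, greedy hill climbing, the sequential pattern-set fitting
# loop, and one-at-a-time sensitivity analysis.  The expensive model
# evaluations are injected as functions, so the same engine drives both
# full simulations and cheap toy objectives in tests.

.INTEGER_PARAMS <- c("V1", "V2", "V4", "V5", "V6", "V7", "V8", "V11",
                     "V13", "V15")

.paramKey <- function(params)
  paste(sprintf("%.10g", paramValues(params)[paste0("V", 1:15)]),
        collapse = ",")

#' Replicated simulation runs
#'
#' Runs \code{n_reps} independent replicates (seeds \code{base_seed +
#' 0..n_reps-1}) of a scenario and summarises a statistic function over
#' them.  Fitting against single runs risks chasing noise, so fewer
#' than 10 replicates triggers a warning.
#'
#' @param scenario a \linkS4class{VoleScenario}.
#' @param params a \linkS4class{VoleParams}.
#' @param statFun function(sim) returning a named numeric vector of
#'   statistics.
#' @param n_reps replicate count (minimum 10 for fitting).
#' @param base_seed first replicate seed.
#' @return list: \code{replicates} (matrix reps x stats), \code{mean},
#'   \code{sd}, \code{seeds}.
#' @export
runReplicates <- function(scenario, params, statFun, n_reps = 10,
                          base_seed = 1) {
  if (n_reps < 10)
    warning("fewer than 10 replicates: below the minimum used for ",
            "fitting; statistics may chase stochastic noise")
  seeds <- base_seed + seq_len(n_reps) - 1
  rows <- lapply(seeds, function(s) {
    sim <- tryCatch(runVoleSim(scenario, params, seed = s),
                    error = function(e)
                      stop("replicate with seed ", s, " failed: ",
                           conditionMessage(e)))
    statFun(sim)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- paste0("seed", seeds)
  list(replicates = m, mean = colMeans(m), sd = apply(m, 2, sd),
       seeds = seeds)
}

#' One-at-a-time parameter perturbation
#'
#' Varies each named parameter in turn by the given fractions of its
#' current value, both signs, holding all others fixed.  Day- and
#' count-valued parameters are rounded to integers and duplicate
#' candidates dropped.
#'
#' @param params a \linkS4class{VoleParams}.
#' @param subset parameter names to vary (subset of V1..V15).
#' @param fractions perturbation fractions.
#' @return list of candidates, each \code{list(params, name, value)}.
#' @export
perturb <- function(params, subset = paste0("V", 1:15),
                    fractions = c(0.05, 0.10, 0.20)) {
  stopifnot(all(subset %in% paste0("V", 1:15)))
  out <- list()
  seen <- character()
  for (nm in subset) {
    v0 <- paramValues(params)[[nm]]
    for (f in c(-fractions, fractions)) {
      v <- v0 * (1 + f)
      if (nm %in% .INTEGER_PARAMS) v <- round(v)
      if (v == v0) next
      cand <- tryCatch(setParam(params, nm, v), error = function(e) NULL)
      if (is.null(cand)) next  # violates a validity constraint
      k <- paste(nm, v)
      if (k %in% seen) next
      seen <- c(seen, k)
      out[[length(out) + 1]] <- list(params = cand, name = nm, value = v)
    }
  }
  out
}

#' Greedy hill climbing over one-at-a-time candidates
#'
#' Repeatedly evaluates all one-at-a-time perturbation candidates of
#' the current parameter set and accepts the best strictly improving
#' one; stops when the objective falls below \code{tolerance}, the
#' evaluation budget is exhausted, or no candidate improves.  The full
#' trace of evaluations is retained, and parameterizations in
#' \code{forbidden} are never evaluated.
#'
#' @param objective function(params) returning a scalar deviation
#'   (lower is better).
#' @param params starting \linkS4class{VoleParams}.
#' @param subset parameters allowed to vary.
#' @param fractions perturbation fractions per iteration.
#' @param budget maximum number of objective evaluations.
#' @param tolerance stop once the objective is at or below this.
#' @param forbidden character vector of parameterization keys (see
#'   \code{history$key}) that must not be revisited.
#' @return list: \code{params} (best found), \code{value},
#'   \code{history} (data.frame of all evaluations), \code{iterations},
#'   \code{converged}.
#' @export
hillClimb <- function(objective, params, subset = paste0("V", 1:15),
                      fractions = c(0.05, 0.10, 0.20), budget = 100,
                      tolerance = 0, forbidden = character()) {
  history <- data.frame(key = character(), name = character(),
                        value = numeric(), objective = numeric(),
                        accepted = logical(), stringsAsFactors = FALSE)
  evals <- 0
  record <- function(key, name, value, obj, acc)
    history[nrow(history) + 1, ] <<- list(key, name, value, obj, acc)

  best <- objective(params); evals <- evals + 1
  record(.paramKey(params), "(start)", NA, best, TRUE)
  iter <- 0
  while (best > tolerance && evals < budget) {
    cands <- perturb(params, subset, fractions)
    cands <- Filter(function(c) !(.paramKey(c$params) %in% forbidden),
                    cands)
    if (!length(cands)) break
    vals <- rep(NA_real_, length(cands))
    for (i in seq_along(cands)) {
      if (evals >= budget) break
      vals[i] <- objective(cands[[i]]$params); evals <- evals + 1
      record(.paramKey(cands[[i]]$params), cands[[i]]$name,
             cands[[i]]$value, vals[i], FALSE)
    }
    if (all(is.na(vals)) || min(vals, na.rm = TRUE) >= best) break
    j <- which.min(vals)
    params <- cands[[j]]$params
    best <- vals[j]
    history$accepted[nrow(history) - length(vals) + j] <- TRUE
    iter <- iter + 1
  }
  list(params = params, value = best, history = history,
       iterations = iter, converged = best <= tolerance)
}

#' Sequential pattern-set calibration
#'
#' The staged fitting loop: fit pattern set 1 (age/sex structure and
#' density) to tolerance by hill climbing, then evaluate sets 2, 3 and
#' 4 in turn.  A failure at a later set sends the loop back to set-1
#' fitting with the failed parameterization added to the forbidden set
#' ("previous fits may not be repeated"), and any parameter change at a
#' later stage triggers a re-check of the earlier sets.  Fitting
#' precision is deliberately relaxed down the sequence: set 1 is fitted
#' numerically, sets 2-4 are gates.
#'
#' @param evaluators named list of four functions (\code{set1},
#'   \code{set2}, \code{set3}, \code{set4}).  \code{set1(params)}
#'   returns a scalar deviation; each later evaluator returns
#'   \code{list(pass = logical, deviation = numeric)}.
#' @param params0 starting \linkS4class{VoleParams}.
#' @param tolerance1 set-1 objective tolerance.
#' @param max_cycles outer loop bound.
#' @param ... passed to \code{\link{hillClimb}}.
#' @return a fit state list: \code{params}, \code{converged},
#'   \code{blocking_set} (NA when converged), \code{forbidden},
#'   \code{reports} (per-set evaluations of the final parameters),
#'   \code{history}.
#' @export
sequentialPom <- function(evaluators, params0, tolerance1 = 0.02,
                          max_cycles = 5, ...) {
  stopifnot(all(c("set1", "set2", "set3", "set4") %in% names(evaluators)))
  forbidden <- character()
  history <- list()
  params <- params0
  blocking <- NA_integer_

  for (cycle in seq_len(max_cycles)) {
    hc <- hillClimb(evaluators$set1, params, tolerance = tolerance1,
                    forbidden = forbidden, ...)
    params <- hc$params
    history[[length(history) + 1]] <- hc$history
    if (!hc$converged) { blocking <- 1L; break }

    ok <- TRUE
    for (s in 2:4) {
      res <- evaluators[[paste0("set", s)]](params)
      if (!isTRUE(res$pass)) {
        forbidden <- union(forbidden, .paramKey(params))
        blocking <- as.integer(s)
        ok <- FALSE
        break
      }
    }
    if (ok) { blocking <- NA_integer_; break }
    if (cycle == max_cycles) break
  }

  reports <- list(
    set1 = evaluators$set1(params),
    set2 = evaluators$set2(params),
    set3 = evaluators$set3(params),
    set4 = evaluators$set4(params))
  list(params = params, converged = is.na(blocking),
       blocking_set = blocking, forbidden = forbidden,
       reports = reports, history = do.call(rbind, history))
}

#' One-at-a-time sensitivity sweep
#'
#' For each parameter, evaluates the model at 11 equally spaced values
#' spanning +/- 80\% of its fitted value (the fitted value is the
#' centre), one parameter at a time.  The evaluator returns named
#' proportional deviations from the target patterns; an overall mean
#' deviance, capped at 1.0, is appended.
#'
#' @param params fitted \linkS4class{VoleParams}.
#' @param evalFun function(params) returning named proportional
#'   deviations.
#' @param subset parameters swept (default V1..V15).
#' @param n_values grid size per parameter (odd, so the centre is
#'   included).
#' @param range half-range as a fraction of the fitted value.
#' @return data.frame: parameter, value, one column per deviation,
#'   overall (capped at 1).
#' @export
sensitivitySweep <- function(params, evalFun,
                             subset = paste0("V", 1:15), n_values = 11,
                             range = 0.8) {
  rows <- list()
  for (nm in subset) {
    v0 <- paramValues(params)[[nm]]
    grid <- v0 * seq(1 - range, 1 + range, length.out = n_values)
    for (v in grid) {
      cand <- tryCatch(setParam(params, nm, v), error = function(e) NULL)
      if (is.null(cand)) next  # value violates a validity constraint
      devs <- evalFun(cand)
      row <- data.frame(parameter = nm, value = v, t(devs))
      row$overall <- min(1.0, mean(abs(devs)))
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
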