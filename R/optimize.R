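#' Cost specification for growth-parameter calibration
#'
#' The calibration cost compares simulated axons against target statistics:
#' the dorso-ventral distribution of axon points (as a normalized histogram
#' on fixed bin edges) and the mean tortuosity,
#' \deqn{cost = w_{dv} \, \|p - q\|_1 + w_{tort} \, |T - T^*| / T^*}
#' averaged over simulation replicates run with common random numbers
#' (fixed per-replicate seeds), which makes the cost a deterministic
#' function of the parameters.
#'
#' @param target_hist Tibble from [dv_distribution()] with a `density`
#'   column - the target DV distribution.
#' @param target_tortuosity Target mean tortuosity (scalar).
#' @param w_dv,w_tort Nonnegative weights, not both zero.
#' @param replicates Simulation replicates per evaluation.
#' @param seeds Seeds for the replicates (length `replicates`).
#' @return A list of class `fascicle_cost_spec`.
#' @export
cost_spec <- function(target_hist, target_tortuosity, w_dv = 1, w_tort = 1,
                      replicates = 3, seeds = seq_len(replicates) * 1000 + 1) {
  stopifnot(w_dv >= 0, w_tort >= 0, w_dv + w_tort > 0, replicates >= 1,
            length(seeds) == replicates)
  structure(list(target_hist = target_hist,
                 target_tortuosity = target_tortuosity,
                 w_dv = w_dv, w_tort = w_tort,
                 replicates = replicates, seeds = seeds),
            class = "fascicle_cost_spec")
}

# L1 distance between two normalized histogram densities on shared edges
hist_l1 <- function(p, q) sum(abs(p$density - q$density) * (p$y_hi - p$y_lo))

#' Build calibration targets from a known parameter vector
#'
#' Runs the calibration scenario at `par` with the evaluation seeds and
#' freezes the pooled DV histogram and mean tortuosity as targets. With
#' common random numbers, [growth_cost()] of `par` against its own targets
#' is exactly zero, so parameter-recovery experiments are well-posed.
#'
#' @param simulate The engine context, `(par, seed) -> trajectories`.
#' @param par Named generating parameter vector.
#' @param edges DV histogram bin edges (um).
#' @param replicates,seeds As in [cost_spec()].
#' @param w_dv,w_tort Cost weights.
#' @return A [cost_spec()].
#' @export
calibration_targets <- function(simulate, par, edges = seq(0, 145, by = 5),
                                replicates = 12,
                                seeds = seq_len(replicates) * 1000 + 1,
                                w_dv = 1, w_tort = 1) {
  trs <- lapply(seeds, function(sd) simulate(par, sd))
  th <- dv_distribution(dplyr::bind_rows(trs), bins = edges)
  tt <- mean(unlist(lapply(trs, function(tr) tortuosity(tr)$tortuosity)),
             na.rm = TRUE)
  cost_spec(th, tt, w_dv = w_dv, w_tort = w_tort, replicates = replicates,
            seeds = seeds)
}

#' Calibration cost of a parameter vector
#'
#' @param par Named numeric vector of parameter values.
#' @param spec A [cost_spec()].
#' @param simulate A function `(par, seed) -> trajectories` running the
#'   calibration scenario (the engine context).
#' @param bounds Optional 2-row matrix (rows `lower`, `upper`, columns
#'   matching `par`); out-of-bounds parameters raise an error.
#' @return Nonnegative scalar cost.
#' @export
growth_cost <- function(par, spec, simulate, bounds = NULL) {
  stopifnot(inherits(spec, "fascicle_cost_spec"))
  if (!is.null(bounds) &&
      (any(par < bounds[1, ]) || any(par > bounds[2, ])))
    stop("parameters out of bounds", call. = FALSE)
  edges <- c(spec$target_hist$y_lo, dplyr::last(spec$target_hist$y_hi))
  trs <- lapply(spec$seeds, function(sd) simulate(par, sd))
  pooled <- dplyr::bind_rows(trs)
  cdv <- if (spec$w_dv > 0) {
    hist_l1(dv_distribution(pooled, bins = edges), spec$target_hist)
  } else 0
  ctort <- if (spec$w_tort > 0) {
    tt <- mean(unlist(lapply(trs, function(tr)
      tortuosity(tr)$tortuosity)), na.rm = TRUE)
    abs(tt - spec$target_tortuosity) / spec$target_tortuosity
  } else 0
  spec$w_dv * cdv + spec$w_tort * ctort
}

#' Compass pattern search
#'
#' Derivative-free minimization: from the current point, poll `+step` and
#' `-step` along each coordinate in turn and accept the first strict
#' improvement; if a full poll fails, halve the step. Stops when the step
#' falls below `tol` or after `max_iter` polls. The cost trace is monotone
#' non-increasing.
#'
#' @param fn Function of a named numeric vector returning a scalar cost.
#' @param init Named numeric vector, the starting point (within bounds).
#' @param lower,upper Bounds vectors (poll points outside are skipped).
#' @param step_init Initial step sizes (scalar or per-coordinate).
#' @param shrink Step shrink factor on poll failure.
#' @param tol Terminate when all steps fall below this.
#' @param max_iter Maximum number of polls.
#' @return An object of class `fascicle_pattern_search`: list with `par`,
#'   `value`, `trace` (tibble: iteration, parameters, cost, step size),
#'   `converged`.
#' @examples
#' fit <- pattern_search(function(p) sum((p - 2)^2),
#'                       c(a = 0, b = 0), lower = c(-5, -5),
#'                       upper = c(5, 5), step_init = 1)
#' glance(fit)
#' @export
pattern_search <- function(fn, init, lower, upper, step_init = 0.1,
                           shrink = 0.5, tol = 1e-3, max_iter = 200) {
  stopifnot(all(init >= lower), all(init <= upper))
  par <- init
  step <- rep_len(step_init, length(init))
  best <- fn(par)
  trace <- list(tibble::tibble(iteration = 0L, !!!as.list(par), cost = best,
                               step_size = max(step)))
  it <- 0L
  while (it < max_iter && max(step) >= tol) {
    it <- it + 1L
    improved <- FALSE
    for (j in seq_along(par)) {
      for (dir in c(1, -1)) {
        cand <- par
        cand[j] <- par[j] + dir * step[j]
        if (cand[j] < lower[j] || cand[j] > upper[j]) next
        v <- fn(cand)
        if (v < best) {
          par <- cand; best <- v; improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) step <- step * shrink
    trace[[length(trace) + 1]] <-
      tibble::tibble(iteration = it, !!!as.list(par), cost = best,
                     step_size = max(step))
  }
  structure(list(par = par, value = best,
                 trace = dplyr::bind_rows(trace),
                 converged = max(step) < tol),
            class = "fascicle_pattern_search")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the pattern-search trace
#'
#' @param x A `fascicle_pattern_search`.
#' @param ... Unused.
#' @return The trace tibble (one row per poll, best-so-far parameters and
#'   cost).
#' @export
tidy.fascicle_pattern_search <- function(x, ...) x$trace

#' One-row summary of a pattern-search fit
#'
#' @param x A `fascicle_pattern_search`.
#' @param ... Unused.
#' @return Tibble with final parameters, `cost`, `iterations`, `converged`.
#' @export
glance.fascicle_pattern_search <- function(x, ...) {
  tibble::tibble(!!!as.list(x$par), cost = x$value,
                 iterations = max(x$trace$iteration),
                 converged = x$converged)
}

#' @export
print.fascicle_pattern_search <- function(x, ...) {
  cat("<compass pattern search>\n")
  cat("  best:", paste(names(x$par), signif(x$par, 4), sep = "=",
                       collapse = ", "),
      sprintf("(cost %.4g, %d polls)\n", x$value, max(x$trace$iteration)))
  invisible(x)
}

#' Standard single-type calibration scenario
#'
#' Builds the engine context used for calibration and for parameter-recovery
#' experiments: a small one-type population grown without interaction, where
#' the polled parameters (`k_dv`, `alpha` by default) override the type's
#' defaults.
#'
#' @param cell_type Type to calibrate.
#' @param n Neurons per side.
#' @param environment A [spinal_environment()].
#' @param tables Measurement tables.
#' @return A function `(par, seed) -> trajectories` suitable for
#'   [growth_cost()].
#' @export
calibration_scenario <- function(cell_type = "aIN", n = 16,
                                 environment = spinal_environment(),
                                 tables = make_measurement_tables(1)) {
  counts <- setNames(as.integer(n), cell_type)
  function(par, seed) {
    ov <- tibble::tibble(type = cell_type, phase = "normal")
    for (nm in names(par)) ov[[nm]] <- par[[nm]]
    pop <- build_population(counts, tables, seed = seed,
                            environment = environment)
    pop <- pop[pop$side == "left", ]
    grow_axons(pop, environment, growth_params(overrides = ov),
               interaction_params(0, 0, 1), seed = seed)
  }
}
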