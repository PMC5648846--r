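#' Synthetic anatomical measurement tables
#'
#' The growth model draws each neuron's attributes (soma DV position and
#' initial growth angle, axon lengths, dendritic half-extent, branch-point
#' position) from per-type "measurement tables" by a smoothed bootstrap.
#' The measurements behind the original model come from stained single
#' neurons and are not shipped here; this generator produces synthetic
#' tables from documented Gaussian/log-normal mixtures chosen to mimic the
#' qualitative anatomy (RB somata against the dorsal tract near
#' `|y| = 137`, sensory interneuron somata near `|y| = 127`, motoneurons
#' ventral, commissural initial angles pointing ventrally, and so on).
#' They are synthetic stand-ins, not measured data.
#'
#' All values are in left-side coordinates (`y > 0`); [build_population()]
#' mirrors draws for the right side. Angles are radians counter-clockwise
#' from `+x`, so ascending growth (toward the head) is near `pi`.
#'
#' @param seed Integer seed.
#' @param n Samples per table.
#' @return A named list (one tibble per cell type) with columns `y_soma`,
#'   `theta0`, `theta0_se`, `len_primary`, `len_secondary`, `dend_half`,
#'   `branch_at`.
#' @examples
#' tabs <- make_measurement_tables(seed = 1)
#' mean(tabs$RB$y_soma)
#' @export
make_measurement_tables <- function(seed = 1, n = 120) {
  set.seed(derive_seed(seed, "measurement_tables"))
  rlnorm2 <- function(n, mean, cv) {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
  }
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  # per-type location/spread constants (documented fixture choices)
  spec <- list(
    RB  = list(y = c(134, 1.5), ylim = c(129, 136.5), th = c(pi, 0.12),
               th_se = c(0, 0.12), lp = c(650, 0.2), ls = c(450, 0.25),
               dh = c(8, 2)),
    dla = list(y = c(123, 2), ylim = c(116, 126.5), th = c(pi + 0.35, 0.2),
               th_se = c(-0.35, 0.2), lp = c(520, 0.2), ls = c(350, 0.25),
               dh = c(12, 3)),
    dlc = list(y = c(123, 2), ylim = c(116, 126.5), th = c(-pi / 2, 0.15),
               th_se = c(0.2, 0.2), lp = c(750, 0.2), ls = c(420, 0.25),
               dh = c(12, 3)),
    aIN = list(y = c(62, 8), ylim = c(30, 100), th = c(pi + 0.3, 0.25),
               th_se = c(-0.3, 0.25), lp = c(520, 0.22), ls = c(330, 0.25),
               dh = c(18, 4)),
    cIN = list(y = c(55, 8), ylim = c(28, 95), th = c(-pi / 2, 0.15),
               th_se = c(0.2, 0.2), lp = c(760, 0.2), ls = c(420, 0.25),
               dh = c(18, 4)),
    dIN = list(y = c(45, 7), ylim = c(27, 80), th = c(-0.25, 0.2),
               th_se = c(pi + 0.25, 0.2), lp = c(620, 0.2), ls = c(380, 0.25),
               dh = c(18, 4)),
    mn  = list(y = c(31, 3), ylim = c(26.2, 45), th = c(-0.1, 0.2),
               th_se = c(pi + 0.1, 0.2), lp = c(420, 0.22), ls = c(300, 0.25),
               dh = c(6, 2))
  )
  out <- lapply(cell_types, function(ty) {
    p <- spec[[ty]]
    lp <- rlnorm2(n, p$lp[1], p$lp[2])
    tibble::tibble(
      y_soma = clip(rnorm(n, p$y[1], p$y[2]), p$ylim[1], p$ylim[2]),
      theta0 = wrap_angle(rnorm(n, p$th[1], p$th[2])),
      theta0_se = wrap_angle(rnorm(n, p$th_se[1], p$th_se[2])),
      len_primary = lp,
      len_secondary = rlnorm2(n, p$ls[1], p$ls[2]),
      dend_half = pmax(rnorm(n, p$dh[1], p$dh[2]), 1),
      branch_at = clip(runif(n, 0.15, 0.6) * lp, 10, 0.9 * lp)
    )
  })
  names(out) <- cell_types
  out
}

#' Toy growth scenarios with analytically known behaviour
#'
#' Minimal hand-built populations used to pin down the engine's contracts:
#'
#' * `straight_pioneer_follower`: a zero-noise pioneer growing along
#'   `theta = 0` and a follower starting 0.5 um away; at `s = 1` the follower
#'   locks exactly onto the pioneer's angle.
#' * `two_parallel_pioneers`: two straight pioneers 10 um apart (bundle
#'   metric fixtures).
#' * `commissural_single`: one cIN-like neuron whose axon dives ventrally,
#'   crosses the floor plate and switches phase on the contralateral side.
#' * `gapped_tract_minimal`: a handful of RB-like axons in a gapped dorsal
#'   tract.
#'
#' @param name Scenario name.
#' @param s Interaction sensitivity applied to the scenario's followers.
#' @return A list with `population`, `environment`, `params`,
#'   `interaction`, and `seed` ready for [grow_axons()].
#' @export
make_toy_scenario <- function(name, s = 1) {
  env <- spinal_environment()
  par <- growth_params()
  base <- function(id, type, x, y, th, len, pioneer, start = NA_real_) {
    tibble::tibble(
      id = id, type = type, side = "left", x = x, y = y, theta0 = th,
      len_primary = len, len_secondary = NA_real_, branch_at = NA_real_,
      theta0_se = NA_real_, dend_y_lo = y - 5, dend_y_hi = y + 5,
      pioneer = pioneer, has_secondary = FALSE, start_override = start
    )
  }
  # zero out gradients and noise so trajectories are deterministic straight
  # lines unless the interaction term bends them
  par$g_rc <- 0; par$k_dv <- 0; par$k_off <- 0; par$alpha <- 0
  if (name == "straight_pioneer_follower") {
    pop <- dplyr::bind_rows(
      base(1L, "aIN", 600, 60, 0, 200, TRUE),
      base(2L, "aIN", 600, 60.5, 0.4, 150, FALSE)
    )
    inter <- interaction_params(s_pr = s, s_se = s, r = 1)
  } else if (name == "two_parallel_pioneers") {
    pop <- dplyr::bind_rows(
      base(1L, "aIN", 600, 60, 0, 300, TRUE),
      base(2L, "aIN", 600, 70, 0, 300, TRUE)
    )
    inter <- interaction_params(s_pr = 0, s_se = 0, r = 1)
  } else if (name == "commissural_single") {
    pop <- base(1L, "cIN", 1000, 55, -pi / 2, 300, TRUE)
    par$g_rc[par$type == "cIN" & par$phase == "normal"] <- -0.1
    inter <- interaction_params(s_pr = 0, s_se = 0, r = 1)
  } else if (name == "gapped_tract_minimal") {
    env <- apply_gaps(env, 25, 25)
    pop <- dplyr::bind_rows(lapply(1:5, function(i) {
      base(i, "RB", 600 + 50 * i, 132, pi, 400, i <= 2)
    }))
    par$alpha[par$type == "RB"] <- 0.15
    inter <- interaction_params(s_pr = s, s_se = s, r = 1)
  } else {
    stop("unknown scenario: ", name, call. = FALSE)
  }
  list(population = pop, environment = env, params = par,
       interaction = inter, seed = 1)
}

#' Synthetic spike raster with known swimming structure
#'
#' Builds a motoneuron raster of alternating left/right population bursts at
#' a given cycle frequency, optionally adding dIN neurons that fire
#' mid-cycle spikes (spikes halfway between their own side's bursts). The
#' detector ground truth (`swims`, `frequency`, mid-cycle dIN count) is known
#' by construction, so [detect_swimming()] and [midcycle_din_count()] can be
#' validated independently of the neuron model.
#'
#' @param freq_hz Cycle frequency in Hz (1--50).
#' @param n_cycles Number of swim cycles.
#' @param midcycle_dins Number of dIN neurons given mid-cycle spikes.
#' @param jitter_ms Gaussian jitter added to each spike time.
#' @param n_mn Motoneurons per side.
#' @param seed Integer seed.
#' @return A `fascicle_raster`: tibble of `neuron`, `type`, `side`, `t` (ms)
#'   with attributes `duration` and `dt`.
#' @examples
#' r <- make_synthetic_raster(18, 10, midcycle_dins = 3)
#' detect_swimming(r)
#' @export
make_synthetic_raster <- function(freq_hz, n_cycles = 10, midcycle_dins = 0,
                                  jitter_ms = 0, n_mn = 5, seed = 1) {
  stopifnot(freq_hz >= 1, freq_hz <= 50)
  set.seed(derive_seed(seed, "synthetic_raster"))
  period <- 1000 / freq_hz
  cyc <- seq_len(n_cycles) - 1
  mk <- function(ids, type, side, times) {
    tidyr::expand_grid(neuron = ids, t0 = times) |>
      dplyr::mutate(type = type, side = side,
                    t = .data$t0 + rnorm(dplyr::n(), 0, jitter_ms)) |>
      dplyr::select("neuron", "type", "side", "t")
  }
  left_bursts <- 10 + cyc * period
  right_bursts <- 10 + period / 2 + cyc * period
  raster <- dplyr::bind_rows(
    mk(seq_len(n_mn), "mn", "left", left_bursts),
    mk(n_mn + seq_len(n_mn), "mn", "right", right_bursts)
  )
  n_din <- max(10, midcycle_dins)
  din_ids <- 2 * n_mn + seq_len(n_din)
  # every dIN spikes with its own (left) side's bursts ...
  raster <- dplyr::bind_rows(raster, mk(din_ids, "dIN", "left", left_bursts))
  # ... and the first `midcycle_dins` of them also at own-side mid-cycle
  if (midcycle_dins > 0) {
    mids <- 10 + period / 2 + cyc * period
    raster <- dplyr::bind_rows(
      raster, mk(din_ids[seq_len(midcycle_dins)], "dIN", "left", mids))
  }
  raster <- dplyr::arrange(raster, .data$neuron, .data$t)
  structure(raster, class = c("fascicle_raster", class(raster)),
            duration = max(raster$t) + period, dt = NA_real_)
}
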