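#' Build the growth schedule
#'
#' Axons grow in two waves. Primary wave: within each (type, side) group the
#' pioneer axons all start at `t = 0`; followers start sequentially in
#' rostro-caudal order (most rostral soma first) at `wave_spacing` time-unit
#' intervals, the first follower starting when the last pioneer of its group
#' finishes. Secondary wave: it begins only after *every* primary axon in
#' the whole population has reached full length, and has the same
#' pioneers-then-followers structure (the secondary pioneers are the same
#' neurons as the primary pioneers). One time unit is the time needed to
#' elongate by one step `delta`.
#'
#' A `start_override` column in the population, when non-`NA`, replaces the
#' computed primary start time (used by toy fixtures).
#'
#' @param population A [build_population()] tibble.
#' @param wave_spacing Time units between consecutive follower starts.
#' @param delta Elongation per step, um.
#' @return A tibble with one row per axon: `id`, `axon`
#'   (`"primary"`/`"secondary"`), `start_time`, `n_steps`.
#' @examples
#' pop <- build_population(c(aIN = 6), make_measurement_tables(1), seed = 1)
#' build_schedule(pop)
#' @export
build_schedule <- function(population, wave_spacing = 200, delta = 1) {
  stopifnot(wave_spacing >= 0, delta > 0)
  pop <- population
  pop$n_steps_pr <- as.integer(ceiling(pop$len_primary / delta))
  prim <- pop |>
    dplyr::group_by(.data$type, .data$side) |>
    dplyr::group_modify(function(g, key) {
      g <- g[order(g$x, g$id), ]
      t0 <- if (any(g$pioneer)) max(g$n_steps_pr[g$pioneer]) else 0
      g$start_time <- NA_real_
      g$start_time[g$pioneer] <- 0
      foll <- which(!g$pioneer)
      g$start_time[foll] <- t0 + (seq_along(foll) - 1) * wave_spacing
      g
    }) |>
    dplyr::ungroup()
  if ("start_override" %in% names(prim)) {
    ov <- !is.na(prim$start_override)
    prim$start_time[ov] <- prim$start_override[ov]
  }
  t_sec0 <- max(prim$start_time + prim$n_steps_pr)
  sec <- prim[prim$has_secondary %in% TRUE & !is.na(prim$len_secondary), ]
  sched_sec <- NULL
  if (nrow(sec) > 0) {
    sec <- sec |>
      dplyr::group_by(.data$type, .data$side) |>
      dplyr::group_modify(function(g, key) {
        g <- g[order(g$x, g$id), ]
        g$sec_start <- NA_real_
        g$sec_start[g$pioneer] <- t_sec0
        foll <- which(!g$pioneer)
        g$sec_start[foll] <- t_sec0 + seq_along(foll) * wave_spacing
        g
      }) |>
      dplyr::ungroup()
    sched_sec <- tibble::tibble(
      id = sec$id, axon = "secondary", start_time = sec$sec_start,
      n_steps = as.integer(ceiling(sec$len_secondary / delta)))
  }
  dplyr::bind_rows(
    tibble::tibble(id = prim$id, axon = "primary",
                   start_time = prim$start_time, n_steps = prim$n_steps_pr),
    sched_sec) |>
    dplyr::arrange(.data$axon, .data$id)
}

#' Grow all axons simultaneously
#'
#' Runs the lock-step growth simulation: at every time unit each active axon
#' takes one elongation step of length `delta`, turning according to the
#' gradient cues, per-step uniform noise, and - when another same-type axon
#' point lies within radius `r` - the fasciculation/repulsion term. Growth
#' is bounded by the arena and barriers (a blocked growth cone slides
#' longitudinally along the barrier); commissural axons run a pre-crossing
#' phase with override parameters until they cross the floor plate, and only
#' interact or form synapses after crossing. Secondary axons sprout from the
#' stored branch point once every primary axon has finished.
#'
#' Each axon consumes an independent noise stream derived from
#' `(seed, neuron id, axon class)`, so trajectories are bit-reproducible and
#' growing axons together with `s = 0` equals growing each alone.
#'
#' @param population A [build_population()] tibble (or a toy fixture).
#' @param environment A [spinal_environment()].
#' @param params A [growth_params()] tibble.
#' @param interaction An [interaction_params()] object.
#' @param seed Integer master seed.
#' @param delta Elongation per step, um.
#' @param wave_spacing Follower spacing in time units, see [build_schedule()].
#' @return A `fascicle_trajectories` tibble: one row per laid point with
#'   `neuron_id`, `type`, `side`, `axon`, `step`, `x`, `y`, `theta`,
#'   `phase` (`normal`/`pre_crossing`/`crossed`) and `clipped` (step was
#'   shortened by a barrier or bound). Attributes carry the population,
#'   environment, interaction, seed and the ids of secondary axons dropped
#'   because their commissural parent never crossed.
#' @examples
#' sc <- make_toy_scenario("two_parallel_pioneers")
#' tr <- grow_axons(sc$population, sc$environment, sc$params,
#'                  sc$interaction, seed = 1)
#' dplyr::count(tr, neuron_id)
#' @export
grow_axons <- function(population, environment = spinal_environment(),
                       params = growth_params(),
                       interaction = interaction_params(), seed = 1,
                       delta = 1, wave_spacing = 200) {
  stopifnot(inherits(environment, "fascicle_environment"),
            inherits(interaction, "fascicle_interaction"))
  pop <- dplyr::arrange(population, .data$id)
  sched <- build_schedule(pop, wave_spacing = wave_spacing, delta = delta)
  prim_sched <- sched[sched$axon == "primary", ]
  sec_sched <- sched[sched$axon == "secondary", ]
  pop_o <- pop[match(prim_sched$id, pop$id), ]

  param_row <- function(types, phase, flip_rc = FALSE) {
    idx <- match(paste(types, phase), paste(params$type, params$phase))
    m <- as.matrix(params[idx, c("g_rc", "k_dv", "lambda", "k_off", "alpha")])
    if (flip_rc) m[, 1] <- -m[, 1]
    m[is.na(m)] <- 0
    m
  }

  prim <- tibble::tibble(
    neuron_id = pop_o$id,
    type_id = type_id(pop_o$type),
    side_sign = ifelse(pop_o$side == "left", 1L, -1L),
    class_id = 1L,
    x0 = pop_o$x, y0 = pop_o$y, theta0 = pop_o$theta0,
    n_steps = prim_sched$n_steps,
    start_time = prim_sched$start_time,
    commissural = pop_o$type %in% commissural_types,
    s = interaction$s_pr,
    parent_row = 0L, branch_step = 0L
  )
  pn_prim <- param_row(pop_o$type, "normal")
  has_pre <- paste(pop_o$type, "pre_crossing") %in%
    paste(params$type, params$phase)
  pp_prim <- pn_prim
  pp_prim[has_pre, ] <- param_row(pop_o$type[has_pre], "pre_crossing")[, ]

  ax <- prim
  pn <- pn_prim
  pp <- pp_prim
  if (nrow(sec_sched) > 0) {
    pop_s <- pop[match(sec_sched$id, pop$id), ]
    secondary <- tibble::tibble(
      neuron_id = pop_s$id,
      type_id = type_id(pop_s$type),
      side_sign = ifelse(pop_s$side == "left", 1L, -1L),
      class_id = 2L,
      x0 = 0, y0 = 0, theta0 = pop_s$theta0_se,
      n_steps = sec_sched$n_steps,
      start_time = sec_sched$start_time,
      commissural = pop_s$type %in% commissural_types,
      s = interaction$s_se,
      parent_row = match(pop_s$id, prim$neuron_id),
      branch_step = as.integer(round(pop_s$branch_at / delta))
    )
    pn_sec <- param_row(pop_s$type, "normal", flip_rc = TRUE)
    ax <- dplyr::bind_rows(prim, secondary)
    pn <- rbind(pn_prim, pn_sec)
    pp <- rbind(pp_prim, pn_sec)
  }

  noise <- lapply(seq_len(nrow(ax)), function(i) {
    set.seed(derive_seed(seed, paste0("axon/", ax$neuron_id[i], "/",
                                      ax$class_id[i])))
    runif(ax$n_steps[i], -1, 1)
  })

  t_max <- max(ax$start_time) + max(ax$n_steps) + 10
  res <- grow_axons_cpp(as.data.frame(ax), noise, pn, pp,
                        environment_to_engine(environment),
                        environment$arena$x_min, environment$arena$x_max,
                        environment$arena$y_abs_max,
                        interaction$r, delta, t_max)
  traj <- tibble::tibble(
    neuron_id = ax$neuron_id[res$axon_row],
    type = cell_types[ax$type_id[res$axon_row]],
    side = ifelse(ax$side_sign[res$axon_row] == 1, "left", "right"),
    axon = ifelse(ax$class_id[res$axon_row] == 1, "primary", "secondary"),
    step = res$step, x = res$x, y = res$y, theta = res$theta,
    phase = c("normal", "pre_crossing", "crossed")[res$phase + 1],
    clipped = res$clipped
  )
  structure(traj,
            class = c("fascicle_trajectories", class(traj)),
            population = population, environment = environment,
            interaction = interaction, seed = seed, delta = delta,
            dropped_secondaries = ax$neuron_id[res$dropped])
}

#' Nearest same-type axon point within range
#'
#' Spatial-hash query used by the growth engine, exposed directly: returns
#' the candidate point closest to `tip` within Euclidean distance `r`,
#' together with the growth angle stored at that point, excluding points
#' belonging to neuron `exclude_id`. Ties are broken by lower neuron id,
#' then lower step index.
#'
#' @param tip Numeric length-2, the growth-cone position.
#' @param candidates Tibble with columns `x`, `y`, `theta`, `neuron_id`,
#'   `step`.
#' @param r Query radius, um.
#' @param exclude_id Neuron id whose points are ignored (self-exclusion).
#' @return A one-row tibble (`x`, `y`, `theta`, `neuron_id`, `step`) or
#'   `NULL` if no candidate lies within `r`.
#' @export
nearest_axon_point <- function(tip, candidates, r, exclude_id = -1L) {
  if (nrow(candidates) == 0) return(NULL)
  res <- nearest_point_cpp(tip[1], tip[2], candidates$x, candidates$y,
                           candidates$theta, as.integer(candidates$neuron_id),
                           as.integer(candidates$step), r,
                           as.integer(exclude_id))
  if (!res$found) return(NULL)
  tibble::tibble(x = res$x, y = res$y, theta = res$theta,
                 neuron_id = res$neuron_id, step = res$step)
}

#' Reference single-axon grower (pure R)
#'
#' Grows one axon with no axon-axon interaction, mirroring the engine's
#' per-step operations in plain R: gradient evaluation, noise, angle update,
#' barrier/arena sliding. Used as an independent check of the compiled
#' engine at `s = 0`.
#'
#' @param x0,y0,theta0 Initial position and angle.
#' @param n_steps Number of elongation steps.
#' @param cell_type One of [cell_types].
#' @param side `"left"` or `"right"`.
#' @param environment A [spinal_environment()].
#' @param params A [growth_params()] tibble.
#' @param noise_u Numeric vector in `[-1, 1]`, length `n_steps` (the raw
#'   noise stream; it is scaled by the phase's `alpha`).
#' @param axon `"primary"` or `"secondary"`.
#' @param delta Step length, um.
#' @return Tibble `step`, `x`, `y`, `theta`, `phase`, `clipped`.
#' @export
grow_axon_solo <- function(x0, y0, theta0, n_steps, cell_type,
                           side = "left",
                           environment = spinal_environment(),
                           params = growth_params(), noise_u = NULL,
                           axon = "primary", delta = 1) {
  stopifnot(n_steps >= 0)
  if (is.null(noise_u)) noise_u <- rep(0, n_steps)
  stopifnot(length(noise_u) >= n_steps)
  is_comm <- cell_type %in% commissural_types
  side_sign <- if (side == "left") 1 else -1
  phase <- if (is_comm && axon == "primary") "pre_crossing" else
    if (is_comm) "crossed" else "normal"
  a <- environment$arena
  x <- x0; y <- y0; th <- theta0
  out <- tibble::tibble(step = 0L, x = x, y = y, theta = th, phase = phase,
                        clipped = FALSE)
  stuck <- 0L
  for (n in seq_len(n_steps)) {
    use_phase <- if (phase == "pre_crossing") "pre_crossing" else "normal"
    g <- evaluate_gradient(params, x, y, cell_type, use_phase, axon, side)
    alpha <- params$alpha[params$type == cell_type & params$phase == use_phase]
    thA <- wrap_angle(th - g[["g_rc"]] * sin(th) + g[["g_dv"]] * cos(th) +
                        alpha * noise_u[n])
    px <- x + delta * cos(thA)
    py <- y + delta * sin(thA)
    # barriers + arena bounds; earliest hit wins
    hit <- barrier_blocks(environment, c(x, y), c(px, py), cell_type)
    best_t <- if (hit$blocked) hit$t else Inf
    kind <- if (hit$blocked) "h" else "none"
    level <- if (hit$blocked) hit$point[2] else NA_real_
    for (L in c(-a$y_abs_max, a$y_abs_max)) {
      f0 <- y - L; f1 <- py - L
      if ((f0 > 0 && f1 > 0) || (f0 < 0 && f1 < 0) || f0 == 0) next
      tt <- f0 / (f0 - f1)
      if (tt < best_t) { best_t <- tt; kind <- "h"; level <- L }
    }
    for (B in c(a$x_min, a$x_max)) {
      f0 <- x - B; f1 <- px - B
      if ((f0 > 0 && f1 > 0) || (f0 < 0 && f1 < 0) || f0 == 0) next
      tt <- f0 / (f0 - f1)
      if (tt < best_t) { best_t <- tt; kind <- "v"; level <- B }
    }
    clipped <- kind != "none"
    leaves <- FALSE
    if (!clipped) {
      nx <- px; ny <- py; thn <- thA
    } else if (kind == "h") {
      nx <- x + best_t * (px - x)
      ny <- level + if (y < level) -1e-6 else 1e-6
      thn <- if (px - x >= 0) 0 else pi
    } else {
      # axon reaches the rostral/caudal end of the modelled section
      nx <- level + if (x < level) -1e-6 else 1e-6
      ny <- y + best_t * (py - y)
      thn <- thA
      leaves <- TRUE
    }
    if (sqrt((nx - x)^2 + (ny - y)^2) < 1e-9) stuck <- stuck + 1L else stuck <- 0L
    x <- nx; y <- ny; th <- thn
    if (phase == "pre_crossing" && side_sign * y <= -25) phase <- "crossed"
    out <- dplyr::bind_rows(out, tibble::tibble(
      step = n, x = x, y = y, theta = th, phase = phase, clipped = clipped))
    if (stuck >= 3L || leaves) break
  }
  out
}
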