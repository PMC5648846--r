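#' Smoothed-bootstrap sampling from a measurement table
#'
#' The "generalization" procedure: each draw picks a table row uniformly at
#' random and adds independent zero-mean Gaussian jitter per column
#' (bandwidth 0 reproduces rows exactly). This turns a finite set of
#' anatomical measurements into a continuous sampling distribution.
#'
#' @param table A data frame of measurements (rows = measured cells).
#' @param n Number of draws.
#' @param bandwidth Numeric: jitter SD per column, recycled across columns.
#' @param seed Integer seed.
#' @return A tibble of `n` draws with the table's columns.
#' @examples
#' tab <- tibble::tibble(len = c(100, 200))
#' sample_generalized(tab, 4, bandwidth = 0, seed = 1)
#' @export
sample_generalized <- function(table, n, bandwidth = 0, seed = 1) {
  if (nrow(table) == 0) stop("empty measurement table", call. = FALSE)
  stopifnot(all(bandwidth >= 0))
  bw <- rep_len(bandwidth, ncol(table))
  set.seed(seed)
  rows <- sample.int(nrow(table), n, replace = TRUE)
  out <- table[rows, , drop = FALSE]
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && bw[j] > 0)
      out[[j]] <- out[[j]] + rnorm(n, 0, bw[j])
  }
  tibble::as_tibble(out)
}

#' Default neuron counts per side
#'
#' The per-type population sizes used when a config does not supply its own.
#' These are round working defaults (the counts used for the original
#' full-scale model runs are not reproduced here), except RB = 63 per side
#' which matches the gapped-barrier experiment.
#'
#' @return Named integer vector, neurons per side for each type.
#' @export
default_counts <- function() {
  c(RB = 63L, dla = 30L, dlc = 30L, aIN = 30L, cIN = 40L, dIN = 40L, mn = 30L)
}

#' Build a neuron population
#'
#' Creates `counts[type]` neurons per type on each body side. Soma
#' rostro-caudal positions are laid out on a uniform jittered grid over the
#' arena; DV positions, initial angles, axon lengths, dendritic extents and
#' branch points are drawn from the measurement tables via
#' [sample_generalized()]. Right-side neurons are mirror images of
#' left-side draws (`y -> -y`, `theta -> -theta`). Dendrites are vertical
#' segments centred on the soma, clipped to the soma's body side.
#'
#' @param counts Named integer vector of neurons per side per type; see
#'   [default_counts()].
#' @param tables Measurement tables from [make_measurement_tables()].
#' @param seed Integer master seed.
#' @param environment A [spinal_environment()]; supplies the RC extent.
#' @param pioneers Named integer vector: pioneer axons per type per side.
#'   Defaults to 9 for RB and 4 for every other present type.
#' @param bandwidth Smoothed-bootstrap bandwidths for
#'   (y_soma, theta0, lengths, dend_half, branch_at).
#' @param din_secondary_prob Probability that a dIN has a secondary axon.
#' @return A tibble with one row per neuron: `id`, `type`, `side`, soma
#'   `x`, `y`, `theta0`, `theta0_se`, `len_primary`, `len_secondary`,
#'   `branch_at`, `dend_y_lo`, `dend_y_hi`, `pioneer`, `has_secondary`.
#' @examples
#' pop <- build_population(c(RB = 4), make_measurement_tables(1), seed = 1)
#' nrow(pop)  # 8: 4 per side
#' @export
build_population <- function(counts = default_counts(),
                             tables = make_measurement_tables(),
                             seed = 1,
                             environment = spinal_environment(),
                             pioneers = NULL,
                             bandwidth = c(1, 0.05, 20, 2, 10),
                             din_secondary_prob = 0.5) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) abort_config("no neurons requested")
  if (!all(names(counts) %in% cell_types))
    abort_config("unknown cell type in counts")
  if (is.null(pioneers)) {
    # defaults: 9 pioneers for RB, 4 for other types, clamped to the count
    pioneers <- setNames(ifelse(names(counts) == "RB", 9L, 4L), names(counts))
    pioneers <- pmin(pioneers, counts)
  } else {
    pioneers <- pioneers[names(counts)]
    if (any(is.na(pioneers)) || any(pioneers > counts))
      abort_config("requested more pioneers than neurons of a type")
  }
  a <- environment$arena
  next_id <- 1L
  out <- list()
  for (ty in names(counts)) {
    n_side <- counts[[ty]]
    for (side in c("left", "right")) {
      draws <- sample_generalized(
        tables[[ty]], n_side,
        bandwidth = c(bandwidth[1], bandwidth[2], bandwidth[2], bandwidth[3],
                      bandwidth[3], bandwidth[4], bandwidth[5]),
        seed = derive_seed(seed, paste("pop", ty, side)))
      set.seed(derive_seed(seed, paste("grid", ty, side)))
      margin <- 20
      grid <- seq(a$x_min + margin, a$x_max - margin, length.out = n_side)
      spacing <- if (n_side > 1) diff(grid[1:2]) else (a$x_max - a$x_min) / 2
      xs <- pmin(pmax(grid + runif(n_side, -spacing / 4, spacing / 4),
                      a$x_min + 1), a$x_max - 1)
      mirror <- if (side == "left") 1 else -1
      y <- pmin(pmax(draws$y_soma, 1), a$y_abs_max - 1) * mirror
      has_sec <- if (ty %in% no_secondary_types) {
        rep(FALSE, n_side)
      } else if (ty == "dIN") {
        runif(n_side) < din_secondary_prob
      } else rep(TRUE, n_side)
      len_p <- pmax(draws$len_primary, 5)
      tib <- tibble::tibble(
        id = next_id + seq_len(n_side) - 1L,
        type = ty, side = side,
        x = xs, y = y,
        theta0 = wrap_angle(draws$theta0 * mirror),
        theta0_se = wrap_angle(draws$theta0_se * mirror),
        len_primary = len_p,
        len_secondary = ifelse(has_sec, pmax(draws$len_secondary, 5), NA_real_),
        branch_at = ifelse(has_sec, pmin(pmax(draws$branch_at, 2), 0.9 * len_p),
                           NA_real_),
        dend_y_lo = pmax(pmin(abs(y) - draws$dend_half, a$y_abs_max), 0.5) *
          mirror,
        dend_y_hi = pmax(pmin(abs(y) + draws$dend_half, a$y_abs_max), 0.5) *
          mirror,
        pioneer = FALSE, has_secondary = has_sec,
        start_override = NA_real_
      )
      # signed bounds: ensure lo <= hi after mirroring
      swap <- tib$dend_y_lo > tib$dend_y_hi
      tmp <- tib$dend_y_lo[swap]
      tib$dend_y_lo[swap] <- tib$dend_y_hi[swap]
      tib$dend_y_hi[swap] <- tmp
      tib$pioneer <- assign_pioneers(tib, pioneers[[ty]])$pioneer
      next_id <- next_id + n_side
      out[[paste(ty, side)]] <- tib
    }
  }
  dplyr::bind_rows(out)
}

#' Flag pioneer neurons
#'
#' With the `"equally_spaced"` policy, the `n_pioneers` neurons whose somata
#' lie nearest to equally spaced rostro-caudal positions are flagged (ties
#' broken by lower id). Pioneer axons start growing at the beginning of
#' their wave; followers start sequentially after all pioneers finish.
#'
#' @param neurons Tibble of neurons of one type/side with columns `id`, `x`.
#' @param n_pioneers Number to flag, `0 <= n_pioneers <= nrow(neurons)`.
#' @param policy Only `"equally_spaced"` is implemented.
#' @return The tibble with a logical `pioneer` column.
#' @export
assign_pioneers <- function(neurons, n_pioneers, policy = "equally_spaced") {
  stopifnot(policy == "equally_spaced",
            n_pioneers >= 0, n_pioneers <= nrow(neurons))
  neurons$pioneer <- FALSE
  if (n_pioneers == 0) return(neurons)
  ord <- order(neurons$x, neurons$id)
  targets <- seq(min(neurons$x), max(neurons$x), length.out = n_pioneers)
  taken <- integer(0)
  for (tg in targets) {
    d <- abs(neurons$x - tg)
    d[taken] <- Inf
    cand <- which(d == min(d))
    pick <- cand[which.min(neurons$id[cand])]
    taken <- c(taken, pick)
  }
  neurons$pioneer[taken] <- TRUE
  neurons
}

#' Extract the dendrite table from a population
#'
#' @param population A [build_population()] tibble.
#' @return Tibble `neuron_id`, `type`, `side`, `x`, `y_lo`, `y_hi`.
#' @export
dendrites <- function(population) {
  tibble::tibble(
    neuron_id = population$id, type = population$type,
    side = population$side, x = population$x,
    y_lo = pmin(population$dend_y_lo, population$dend_y_hi),
    y_hi = pmax(population$dend_y_lo, population$dend_y_hi)
  )
}
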