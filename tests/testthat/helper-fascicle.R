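# shared helpers: hand-built populations and brute-force oracles

# minimal population row(s) in the shape build_population() emits
toy_neurons <- function(id, type, x, y, theta0, len, side = "left",
                        pioneer = FALSE, start = NA_real_,
                        dend_half = 5, len_secondary = NA_real_,
                        branch_at = NA_real_, theta0_se = NA_real_) {
  tibble::tibble(
    id = as.integer(id), type = type, side = side, x = x, y = y,
    theta0 = theta0, theta0_se = theta0_se, len_primary = len,
    len_secondary = len_secondary, branch_at = branch_at,
    dend_y_lo = y - dend_half, dend_y_hi = y + dend_half,
    pioneer = pioneer, has_secondary = !is.na(len_secondary),
    start_override = start)
}

# growth params with all cues and noise silenced
null_params <- function() {
  p <- growth_params()
  p$g_rc <- 0; p$k_dv <- 0; p$k_off <- 0; p$alpha <- 0
  p
}

# hand-built trajectory tibble in the engine's output shape
fake_traj <- function(y, x = seq_along(y), id = 1L, axon = "primary") {
  tibble::tibble(neuron_id = id, type = "aIN", side = "left", axon = axon,
                 step = seq_along(y) - 1L, x = x, y = y, theta = 0,
                 phase = "normal", clipped = FALSE)
}

# brute-force nearest-neighbour oracle (the spatial hash is checked against
# this)
brute_nearest <- function(tip, candidates, r, exclude_id = -1L) {
  cand <- candidates[candidates$neuron_id != exclude_id, ]
  if (nrow(cand) == 0) return(NULL)
  d2 <- (cand$x - tip[1])^2 + (cand$y - tip[2])^2
  cand <- cand[d2 <= r^2, ]
  d2 <- d2[d2 <= r^2]
  if (nrow(cand) == 0) return(NULL)
  ord <- order(d2, cand$neuron_id, cand$step)
  cand[ord[1], c("x", "y", "theta", "neuron_id", "step")]
}

# brute-force segment / vertical-dendrite intersection oracle
brute_crossings <- function(segs, dends) {
  out <- list()
  for (i in seq_len(nrow(segs))) {
    for (j in seq_len(nrow(dends))) {
      x0 <- segs$x0[i]; x1 <- segs$x1[i]
      y0 <- segs$y0[i]; y1 <- segs$y1[i]
      xd <- dends$x[j]
      if (xd < min(x0, x1) || xd > max(x0, x1)) next
      if (x0 == x1) {
        if (max(y0, y1) < dends$y_lo[j] || min(y0, y1) > dends$y_hi[j]) next
        yh <- max(min(y0, y1), dends$y_lo[j])
      } else {
        tt <- (xd - x0) / (x1 - x0)
        yh <- y0 + tt * (y1 - y0)
        if (yh < dends$y_lo[j] || yh > dends$y_hi[j]) next
      }
      out[[length(out) + 1]] <- data.frame(seg = i, dendrite = j)
    }
  }
  if (length(out) == 0) return(data.frame(seg = integer(), dendrite = integer()))
  do.call(rbind, out)
}

# grow a single-type, one-sided population (the repeated experiment shape)
grow_one_type <- function(type, n, s, seed, environment = spinal_environment(),
                          params = growth_params(), r = 1,
                          primaries_only = FALSE,
                          tables = make_measurement_tables(1)) {
  pop <- build_population(setNames(n, type), tables, seed = seed,
                          environment = environment)
  pop <- pop[pop$side == "left", ]
  if (primaries_only) {
    pop$has_secondary <- FALSE
    pop$len_secondary <- NA_real_
  }
  grow_axons(pop, environment, params, interaction_params(s, s, r),
             seed = seed)
}
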