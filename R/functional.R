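#' Default cell-model parameters for the spiking layer
#'
#' Single-compartment conductance-based neurons (Na, K, leak, plus a slow K
#' adaptation current). Values are package defaults tuned for robust
#' qualitative behaviour - touch-evoked spiking, dIN repetitive firing
#' under sustained NMDA-type drive - not a fit to voltage-clamp data; the
#' physiological parameter sets behind the original model live in prior
#' work and are out of scope here. Units: pF, nS, mV.
#'
#' @return Tibble with one row per cell type: `C`, `g_na`, `g_k`, `g_leak`,
#'   `g_ks`, `e_na`, `e_k`, `e_leak`.
#' @export
cell_params <- function() {
  base <- tibble::tibble(
    type = cell_types, C = 100, g_na = 5000, g_k = 3000, g_leak = 10,
    g_ks = 0, e_na = 50, e_k = -90, e_leak = -65)
  base$g_ks[base$type == "dIN"] <- 15   # slow K: limits dIN firing rate
  base
}

#' Default synapse parameters for the spiking layer
#'
#' Per presynaptic type: receptor class, dual-exponential time constants,
#' unitary conductance, and delay model. cIN and aIN are inhibitory; the
#' sensory and dIN pathways are excitatory, and dIN->dIN contacts carry an
#' additional slow NMDA-like component that supports pacemaker firing. The
#' total conductance of a connection is the unitary conductance times the
#' number of anatomical contacts between the pair. The delay of a contact
#' is its axonal conduction time (arc length to the contact divided by
#' `conduction_speed`) plus a fixed synaptic delay.
#'
#' @param conduction_speed um/ms.
#' @param synaptic_delay ms.
#' @return List with `pre` (tibble per pre type: `receptor`, `unitary_nS`),
#'   `receptors` (tibble: `tau_rise`, `tau_decay`, `e_rev` for exc, inh,
#'   nmda), `nmda_unitary_nS` (extra dIN->dIN NMDA conductance),
#'   `conduction_speed`, `synaptic_delay`, `gap_g` and `gap_range` for
#'   dIN-dIN electrical coupling.
#' @export
synapse_params <- function(conduction_speed = 1000, synaptic_delay = 1) {
  list(
    pre = tibble::tibble(
      type = cell_types,
      receptor = c("exc", "exc", "exc", "inh", "inh", "exc", "exc"),
      unitary_nS = c(4, 4, 4, 3, 3, 2, 0)),
    receptors = tibble::tibble(
      receptor = c("exc", "inh", "nmda"),
      tau_rise = c(0.5, 1.0, 4.0),
      tau_decay = c(3.0, 12.0, 80.0),
      e_rev = c(0, -75, 0)),
    nmda_unitary_nS = 0.6,
    conduction_speed = conduction_speed,
    synaptic_delay = synaptic_delay,
    gap_g = 0.3, gap_range = 100)
}

#' Simulate spiking activity on a connectome
#'
#' Maps the anatomical connectome to a conductance-based network (synaptic
#' strength = unitary conductance x contact count; per-contact axonal +
#' synaptic delays; dIN-dIN gap junctions between nearby somata) and
#' integrates it with a fixed-step exponential-Euler scheme. The stimulus
#' is a brief depolarizing current to a set of RB neurons on one side,
#' emulating a skin touch.
#'
#' @param connectome A `fascicle_connectome`.
#' @param stimulus Tibble with `neuron_id`, `t_on`, `t_off`, `amp_pA`;
#'   see [touch_stimulus()].
#' @param cell A [cell_params()] tibble.
#' @param syn A [synapse_params()] list.
#' @param dt Integration step, ms (<= 0.05).
#' @param duration Simulated time, ms.
#' @param seed Integer seed (initial membrane-potential jitter).
#' @param nmda_tonic Optional tibble `neuron_id`, `g_nS` of tonic NMDA-type
#'   conductances (single-cell pacemaker experiments).
#' @return A `fascicle_raster` tibble: `neuron`, `type`, `side`, `t` (ms),
#'   with `duration` and `dt` attributes.
#' @export
simulate_network <- function(connectome, stimulus = NULL,
                             cell = cell_params(), syn = synapse_params(),
                             dt = 0.01, duration = 400, seed = 1,
                             nmda_tonic = NULL) {
  stopifnot(dt <= 0.05, dt > 0)
  pop <- dplyr::arrange(connectome$population, .data$id)
  if (!all(pop$type %in% cell$type))
    abort_config("unknown cell type in connectome")
  idx <- match(pop$id, pop$id)  # identity; synapse ids mapped below
  row_of <- setNames(seq_len(nrow(pop)), pop$id)

  synt <- connectome$synapses
  contacts <- NULL
  if (!is.null(synt) && nrow(synt) > 0) {
    rec_of <- setNames(syn$pre$receptor, syn$pre$type)
    uni_of <- setNames(syn$pre$unitary_nS, syn$pre$type)
    contacts <- tibble::tibble(
      pre = row_of[as.character(synt$pre_id)],
      post = row_of[as.character(synt$post_id)],
      receptor = rec_of[synt$pre_type],
      weight = uni_of[synt$pre_type],
      delay = synt$arc_length / syn$conduction_speed + syn$synaptic_delay)
    # dIN->dIN contacts carry an extra slow NMDA-like component
    dd <- synt$pre_type == "dIN" & synt$post_type == "dIN"
    if (any(dd)) {
      contacts <- dplyr::bind_rows(
        contacts,
        dplyr::mutate(contacts[dd, ], receptor = "nmda",
                      weight = syn$nmda_unitary_nS))
    }
    contacts <- contacts[contacts$weight > 0, ]
  }
  if (is.null(contacts) || nrow(contacts) == 0) {
    contacts <- tibble::tibble(pre = integer(), post = integer(),
                               receptor = character(), weight = numeric(),
                               delay = numeric())
  }
  rec_id <- c(exc = 1L, inh = 2L, nmda = 3L)

  # dIN gap junctions: same side, somata within gap_range along the cord
  din <- which(pop$type == "dIN")
  gi <- integer(0); gj <- integer(0)
  if (length(din) > 1 && syn$gap_g > 0) {
    for (a in seq_along(din)) {
      for (b in seq_along(din)) {
        if (b <= a) next
        i <- din[a]; j <- din[b]
        if (pop$side[i] == pop$side[j] &&
            abs(pop$x[i] - pop$x[j]) <= syn$gap_range) {
          gi <- c(gi, i); gj <- c(gj, j)
        }
      }
    }
  }

  if (is.null(stimulus))
    stimulus <- tibble::tibble(neuron_id = integer(), t_on = numeric(),
                               t_off = numeric(), amp_pA = numeric())
  stim_rows <- row_of[as.character(stimulus$neuron_id)]

  nm <- rep(0, nrow(pop))
  if (!is.null(nmda_tonic))
    nm[row_of[as.character(nmda_tonic$neuron_id)]] <- nmda_tonic$g_nS

  set.seed(derive_seed(seed, "vinit"))
  v0 <- -65 + runif(nrow(pop), -1, 1)

  cp <- as.matrix(cell[match(cell_types, cell$type),
                       c("C", "g_na", "g_k", "g_leak", "g_ks",
                         "e_na", "e_k", "e_leak")])
  rp <- as.matrix(syn$receptors[, c("tau_rise", "tau_decay", "e_rev")])

  res <- simulate_network_cpp(
    type_id(pop$type), cp,
    as.integer(contacts$pre), as.integer(contacts$post),
    contacts$weight, rec_id[contacts$receptor], contacts$delay, rp,
    as.integer(gi), as.integer(gj), rep(syn$gap_g, length(gi)),
    as.integer(stim_rows), stimulus$t_on, stimulus$t_off, stimulus$amp_pA,
    nm, v0, dt, duration)

  raster <- tibble::tibble(
    neuron = pop$id[res$neuron], type = pop$type[res$neuron],
    side = pop$side[res$neuron], t = res$t)
  structure(raster, class = c("fascicle_raster", class(raster)),
            duration = duration, dt = dt)
}

#' Touch stimulus on one side's RB neurons
#'
#' @param population A population tibble.
#' @param side `"left"` or `"right"`.
#' @param n Number of RB neurons stimulated (most rostral first).
#' @param t_on,t_off Stimulus window, ms.
#' @param amp_pA Current amplitude.
#' @return A stimulus tibble for [simulate_network()].
#' @export
touch_stimulus <- function(population, side = "left", n = 5, t_on = 10,
                           t_off = 15, amp_pA = 400) {
  rb <- population[population$type == "RB" & population$side == side, ]
  rb <- rb[order(rb$x), ]
  n <- min(n, nrow(rb))
  tibble::tibble(neuron_id = rb$id[seq_len(n)], t_on = t_on, t_off = t_off,
                 amp_pA = amp_pA)
}

# motoneuron population bursts per side: gap-threshold binning of pooled
# mn spike times
mn_bursts <- function(raster, gap_ms = 15) {
  mn <- raster[raster$type == "mn", ]
  lapply(split(mn$t, mn$side), function(ts) {
    ts <- sort(ts)
    if (length(ts) == 0) return(numeric(0))
    cl <- cumsum(c(1, diff(ts) > gap_ms))
    as.numeric(tapply(ts, cl, median))
  })
}

#' Detect swimming in a spike raster
#'
#' Swimming is a stable antiphase rhythm: motoneuron spikes on each side
#' are binned into population bursts (inter-spike gap threshold), and the
#' raster swims if at least `n_cycles` consecutive bursts alternate
#' strictly left/right with a cycle frequency inside `band` (10-25 Hz).
#' The frequency is the reciprocal of the median same-side burst interval.
#'
#' @param raster A `fascicle_raster`.
#' @param gap_ms Burst-binning inter-spike gap, ms.
#' @param n_cycles Minimum consecutive alternating cycles.
#' @param band Frequency acceptance band, Hz.
#' @return A list `swims` (logical), `frequency` (Hz, `NA` if no rhythm),
#'   `n_bursts` per side.
#' @export
detect_swimming <- function(raster, gap_ms = 15, n_cycles = 5,
                            band = c(10, 25)) {
  b <- mn_bursts(raster, gap_ms)
  nb <- vapply(b, length, 1L)
  out <- list(swims = FALSE, frequency = NA_real_, n_bursts = nb)
  if (length(b) < 2 || any(nb == 0)) return(out)
  ev <- dplyr::bind_rows(
    tibble::tibble(t = b[["left"]], side = "left"),
    tibble::tibble(t = b[["right"]], side = "right")) |>
    dplyr::arrange(.data$t)
  # longest run of strict alternation
  is_alt <- ev$side[-1] != ev$side[-nrow(ev)]
  runs <- rle(is_alt)
  best <- if (any(runs$values)) max(runs$lengths[runs$values]) + 1 else 1
  same <- split(ev$t, ev$side)
  per <- stats::median(unlist(lapply(same, function(ts) diff(sort(ts)))))
  freq <- 1000 / per
  # a full cycle is two alternating bursts
  if (!is.na(freq) && best >= 2 * n_cycles &&
      freq >= band[1] && freq <= band[2]) {
    out$swims <- TRUE
  }
  out$frequency <- freq
  out
}

#' Count dINs firing mid-cycle spikes
#'
#' During swimming a healthy dIN fires once per cycle, in phase with its
#' own side's motoneuron burst. A dIN is counted as mid-cycle if at least
#' `k` of its spikes fall inside the middle fraction `f` of the interval
#' between consecutive own-side bursts, i.e. while the opposite side is
#' active. An increase in this count marks degraded swimming.
#'
#' @param raster A `fascicle_raster`.
#' @param swim A [detect_swimming()] result for the raster; must have
#'   `swims = TRUE`.
#' @param k Minimum number of mid-cycle spikes.
#' @param f Width of the mid-cycle window as a fraction of the cycle.
#' @param gap_ms Burst-binning gap, ms.
#' @return Integer count of mid-cycle dINs.
#' @export
midcycle_din_count <- function(raster, swim = detect_swimming(raster),
                               k = 3, f = 0.5, gap_ms = 15) {
  if (!isTRUE(swim$swims))
    stop("midcycle_din_count requires a swimming raster", call. = FALSE)
  bursts <- mn_bursts(raster, gap_ms)
  din <- raster[raster$type == "dIN", ]
  if (nrow(din) == 0) return(0L)
  count_mid <- function(ts, own) {
    own <- sort(own)
    if (length(own) < 2) return(0L)
    mid <- 0L
    for (i in seq_len(length(own) - 1)) {
      lo <- own[i]; hi <- own[i + 1]
      c0 <- (lo + hi) / 2 - f * (hi - lo) / 2
      c1 <- (lo + hi) / 2 + f * (hi - lo) / 2
      mid <- mid + sum(ts > c0 & ts < c1)
    }
    mid
  }
  per_din <- din |>
    dplyr::group_by(.data$neuron, .data$side) |>
    dplyr::summarise(mid = count_mid(.data$t, bursts[[.data$side[1]]]),
                     .groups = "drop")
  sum(per_din$mid >= k)
}
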