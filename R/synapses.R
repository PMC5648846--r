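#' Default synaptic connection-probability matrix
#'
#' Probability that a crossing between a presynaptic axon and a postsynaptic
#' dendrite produces a synapse, by (pre type, post type). The packaged
#' default is a placeholder - 0.5 for every pair - with two structural
#' overrides: sensory RB neurons receive no synapses (`P[, "RB"] = 0`) and
#' motoneuron output leaves the cord to muscle (`P["mn", ] = 0`). The
#' experimentally derived pairwise probabilities behind the original model
#' are not reproduced here; all package behaviour that matters is
#' independent of the specific values.
#'
#' @param base Baseline probability for all pairs.
#' @return A 7x7 numeric matrix with type dimnames.
#' @export
connection_probabilities <- function(base = 0.5) {
  p <- matrix(base, 7, 7, dimnames = list(cell_types, cell_types))
  p[, "RB"] <- 0
  p["mn", ] <- 0
  p
}

#' Detect axon-dendrite crossings
#'
#' Exact 2D intersections between every trajectory step segment and the
#' vertical dendritic segments. Endpoint touching counts as a crossing;
#' dendrites lie on a single body side so a segment can only hit dendrites
#' whose DV interval contains the intersection.
#'
#' @param trajectories A [grow_axons()] result.
#' @param dendrite_table A [dendrites()] tibble.
#' @return A tibble with one row per crossing: `pre_id`, `post_id`,
#'   `pre_type`, `post_type`, `axon`, `step`, `phase`, `x`, `y`,
#'   `arc_length` (distance grown along the presynaptic axon, um).
#' @export
detect_crossings <- function(trajectories, dendrite_table) {
  tr <- dplyr::arrange(trajectories, .data$neuron_id, .data$axon, .data$step)
  grp <- paste(tr$neuron_id, tr$axon)
  n <- nrow(tr)
  first_of_grp <- c(TRUE, grp[-1] != grp[-n])
  # segment i: point i -> point i+1 within one axon
  seg_ok <- which(!c(first_of_grp[-1], TRUE))
  sx0 <- tr$x[seg_ok]; sy0 <- tr$y[seg_ok]
  sx1 <- tr$x[seg_ok + 1]; sy1 <- tr$y[seg_ok + 1]
  dd <- dplyr::arrange(dendrite_table, .data$x)
  hits <- detect_crossings_cpp(sx0, sy0, sx1, sy1, dd$x, dd$y_lo, dd$y_hi)
  i <- seg_ok[hits$seg]       # row of the segment's start point
  delta <- attr(trajectories, "delta", exact = TRUE)
  if (is.null(delta)) delta <- 1
  tibble::tibble(
    pre_id = tr$neuron_id[i],
    post_id = dd$neuron_id[hits$dendrite],
    pre_type = tr$type[i],
    post_type = dd$type[hits$dendrite],
    axon = tr$axon[i],
    step = tr$step[i] + 1L,
    phase = tr$phase[i + 1],  # phase after the step that crossed
    x = hits$x, y = hits$y,
    arc_length = (tr$step[i] + 1) * delta
  )
}

#' Form synapses from axon-dendrite crossings
#'
#' Every crossing (excluding self-crossings, crossings made during the
#' commissural pre-crossing phase, and - for commissural presynaptic
#' neurons - crossings ipsilateral to the soma) draws an independent
#' Bernoulli with probability `P[pre type, post type]`. Repeated crossings
#' of the same pair can therefore yield multiple synaptic contacts; the
#' connectome counts contacts, not connected pairs.
#'
#' @param trajectories A [grow_axons()] result.
#' @param population The population the trajectories were grown from
#'   (defaults to the attribute stored on `trajectories`).
#' @param prob A [connection_probabilities()] matrix.
#' @param seed Integer seed for the Bernoulli draws.
#' @return A `fascicle_connectome`: list with `population`, `synapses`
#'   (tibble of contacts) and provenance (`seed`, `prob`, config hash).
#' @examples
#' sc <- make_toy_scenario("two_parallel_pioneers")
#' tr <- grow_axons(sc$population, sc$environment, sc$params, sc$interaction)
#' con <- form_synapses(tr, sc$population, seed = 1)
#' nrow(con$synapses)
#' @export
form_synapses <- function(trajectories, population = NULL,
                          prob = connection_probabilities(), seed = 1) {
  if (is.null(population))
    population <- attr(trajectories, "population", exact = TRUE)
  cross <- detect_crossings(trajectories, dendrites(population))
  if (any(is.na(prob[cbind(cross$pre_type, cross$post_type)])))
    abort_config("probability matrix is missing an occurring type pair")
  soma_side <- setNames(population$side, population$id)
  post_side <- soma_side[as.character(cross$post_id)]
  pre_side <- soma_side[as.character(cross$pre_id)]
  keep <- cross$pre_id != cross$post_id &
    cross$phase != "pre_crossing" &
    !(cross$pre_type %in% commissural_types & pre_side == post_side)
  cross <- cross[keep, ]
  set.seed(derive_seed(seed, "synapses"))
  p <- prob[cbind(cross$pre_type, cross$post_type)]
  syn <- cross[runif(nrow(cross)) < p, ]
  structure(
    list(population = population,
         synapses = dplyr::select(syn, -"phase"),
         seed = seed, prob = prob,
         hash = config_hash(list(seed = seed, prob = prob))),
    class = "fascicle_connectome")
}

#' @export
print.fascicle_connectome <- function(x, ...) {
  cat("<fascicle connectome>\n")
  cat(sprintf("  %d neurons, %d synaptic contacts\n",
              nrow(x$population), nrow(x$synapses)))
  invisible(x)
}

#' Randomly prune synapses
#'
#' Retains each synaptic contact independently with probability
#' `keep_prob`, emulating a reduced synapse-formation probability.
#'
#' @param connectome A `fascicle_connectome`.
#' @param keep_prob Retention probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The pruned connectome.
#' @export
prune_synapses <- function(connectome, keep_prob, seed = 1) {
  stopifnot(keep_prob >= 0, keep_prob <= 1)
  set.seed(derive_seed(seed, "prune"))
  keep <- runif(nrow(connectome$synapses)) < keep_prob
  connectome$synapses <- connectome$synapses[keep, ]
  connectome
}

#' Type-by-type synapse count matrix
#'
#' Counts synaptic contacts pooled over both body sides for every
#' (pre type, post type) pair, optionally with the elementwise percent
#' change against a reference connectome; pairs whose counts are below
#' `negligible` in both connectomes are flagged.
#'
#' @param connectome A `fascicle_connectome`.
#' @param reference Optional second connectome to compare against.
#' @param negligible Count threshold below which a pair is flagged.
#' @return A tibble `pre_type`, `post_type`, `n`, and when a reference is
#'   given `n_ref`, `pct_change`, `negligible`.
#' @export
synapse_count_matrix <- function(connectome, reference = NULL,
                                 negligible = 50) {
  count1 <- function(con) {
    tidyr::expand_grid(pre_type = cell_types, post_type = cell_types) |>
      dplyr::left_join(
        dplyr::count(con$synapses, .data$pre_type, .data$post_type),
        by = c("pre_type", "post_type")) |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  }
  out <- count1(connectome)
  if (!is.null(reference)) {
    ref <- dplyr::rename(count1(reference), n_ref = "n")
    out <- dplyr::left_join(out, ref, by = c("pre_type", "post_type")) |>
      dplyr::mutate(
        pct_change = ifelse(.data$n_ref > 0,
                            100 * (.data$n - .data$n_ref) / .data$n_ref,
                            NA_real_),
        negligible = .data$n < negligible & .data$n_ref < negligible)
  }
  out
}
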