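#' Assemble a run configuration
#'
#' A run config bundles everything needed to reproduce a simulation from a
#' single master seed: arena/barrier layout, neuron counts, pioneer counts,
#' wave spacing, growth parameters, interaction parameters and the
#' connection-probability matrix. Configs serialize to YAML and every
#' exported artifact is stamped with the config hash and seed.
#'
#' @param counts Named neuron counts per side.
#' @param pioneers Named pioneer counts per type (NULL for defaults).
#' @param interaction An [interaction_params()] object.
#' @param params A [growth_params()] tibble.
#' @param gaps NULL for intact barriers, or `c(gap_length, interval)`.
#' @param wave_spacing Follower spacing, time units.
#' @param prob Connection-probability matrix.
#' @param seed Master seed.
#' @return A list of class `fascicle_config`.
#' @export
run_config <- function(counts = default_counts(), pioneers = NULL,
                       interaction = interaction_params(),
                       params = growth_params(), gaps = NULL,
                       wave_spacing = 200, prob = connection_probabilities(),
                       seed = 1) {
  cfg <- list(counts = counts, pioneers = pioneers,
              interaction = unclass(interaction),
              params = as.data.frame(params), gaps = gaps,
              wave_spacing = wave_spacing, prob = prob, seed = seed)
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), "hash")])
  class(cfg) <- "fascicle_config"
  cfg
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_config` returns the config; `write_config` the path,
#'   invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$counts <- as.list(x$counts)           # keep names through YAML
  if (!is.null(x$pioneers)) x$pioneers <- as.list(x$pioneers)
  x$params <- lapply(as.data.frame(x$params), identity)
  x$prob <- list(types = rownames(x$prob), values = as.vector(x$prob))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$counts <- unlist(x$counts)
  if (!is.null(x$pioneers)) x$pioneers <- unlist(x$pioneers)
  x$params <- tibble::as_tibble(as.data.frame(x$params))
  tys <- x$prob$types
  x$prob <- matrix(unlist(x$prob$values), length(tys), length(tys),
                   dimnames = list(tys, tys))
  x$interaction <- do.call(interaction_params, x$interaction)
  if (!is.null(x$gaps)) x$gaps <- unlist(x$gaps)
  class(x) <- "fascicle_config"
  x
}

#' Run the growth pipeline for a config
#'
#' Convenience wrapper: population -> trajectories -> connectome under one
#' config and seed.
#'
#' @param config A [run_config()].
#' @param seed Overrides the config seed when given.
#' @return List with `population`, `trajectories`, `connectome`,
#'   `environment`, `config`.
#' @export
run_growth <- function(config, seed = NULL) {
  seed <- seed %||% config$seed
  env <- spinal_environment()
  if (!is.null(config$gaps))
    env <- apply_gaps(env, config$gaps[1], config$gaps[2])
  pop <- build_population(config$counts, make_measurement_tables(seed),
                          seed = seed, environment = env,
                          pioneers = config$pioneers)
  inter <- if (inherits(config$interaction, "fascicle_interaction"))
    config$interaction else do.call(interaction_params, config$interaction)
  tr <- grow_axons(pop, env, config$params, inter, seed = seed,
                   wave_spacing = config$wave_spacing)
  con <- form_synapses(tr, pop, config$prob, seed = seed)
  list(population = pop, trajectories = tr, connectome = con,
       environment = env, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write trajectories as tidy CSV
#'
#' @param trajectories A [grow_axons()] result.
#' @param path Output file.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  write.csv(as.data.frame(trajectories), path, row.names = FALSE)
  invisible(path)
}

#' Write a neuron's axon morphology as SWC
#'
#' Standard 7-column SWC: the soma as the root sample (type 1), primary and
#' secondary axon points as type-2 samples; the secondary branch connects
#' at the primary sample nearest its sprout point.
#'
#' @param trajectories A [grow_axons()] result.
#' @param neuron_id Neuron to export.
#' @param path Output file.
#' @export
write_swc <- function(trajectories, neuron_id, path) {
  tr <- trajectories[trajectories$neuron_id == neuron_id, ]
  if (nrow(tr) == 0) stop("no trajectory for this neuron", call. = FALSE)
  prim <- tr[tr$axon == "primary", ]
  sec <- tr[tr$axon == "secondary", ]
  rows <- data.frame(id = 1, type = 1, x = prim$x[1], y = prim$y[1], z = 0,
                     radius = 1, parent = -1)
  np <- nrow(prim)
  rows <- rbind(rows, data.frame(
    id = 1 + seq_len(np), type = 2, x = prim$x, y = prim$y, z = 0,
    radius = 0.5, parent = c(1, 1 + seq_len(np - 1))))
  if (nrow(sec) > 0) {
    d2 <- (prim$x - sec$x[1])^2 + (prim$y - sec$y[1])^2
    attach_id <- 1 + which.min(d2)
    base_id <- 1 + np
    ns <- nrow(sec)
    rows <- rbind(rows, data.frame(
      id = base_id + seq_len(ns), type = 2, x = sec$x, y = sec$y, z = 0,
      radius = 0.5, parent = c(attach_id, base_id + seq_len(ns - 1))))
  }
  writeLines(c("# SWC export", sprintf("%d %d %.3f %.3f %.3f %.3f %d",
                                       rows$id, rows$type, rows$x, rows$y,
                                       rows$z, rows$radius, rows$parent)),
             path)
  invisible(path)
}

#' Write / read a connectome edge list as CSV
#'
#' @param connectome A `fascicle_connectome`.
#' @param path File path.
#' @export
write_connectome_csv <- function(connectome, path) {
  write.csv(as.data.frame(connectome$synapses), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectome_csv
#' @param population The population the edge list refers to.
#' @export
read_connectome_csv <- function(path, population) {
  syn <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  structure(list(population = population, synapses = syn,
                 seed = NA_integer_, prob = NULL, hash = NA_character_),
            class = "fascicle_connectome")
}

#' Export a connectome as GraphML
#'
#' Builds an igraph graph (neurons as vertices with type/side/position,
#' one edge per synaptic contact) and writes GraphML for network tools.
#'
#' @param connectome A `fascicle_connectome`.
#' @param path Output file.
#' @export
write_connectome_graphml <- function(connectome, path) {
  pop <- connectome$population
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(connectome$synapses$pre_id),
                   to = as.character(connectome$synapses$post_id)),
    directed = TRUE,
    vertices = data.frame(name = as.character(pop$id), type = pop$type,
                          side = pop$side, x = pop$x, y = pop$y))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a spike raster as CSV
#'
#' @param raster A `fascicle_raster`.
#' @param path Output file.
#' @export
write_raster_csv <- function(raster, path) {
  write.csv(as.data.frame(raster), path, row.names = FALSE)
  invisible(path)
}

#' Write a metrics report as JSON
#'
#' @param metrics A named list of metric values.
#' @param path Output file.
#' @param config Optional config whose hash and seed are recorded.
#' @export
write_metrics_json <- function(metrics, path, config = NULL) {
  if (!is.null(config))
    metrics <- c(list(config_hash = config$hash, seed = config$seed), metrics)
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
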