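#' Dorso-ventral distribution of axon points
#'
#' Histogram of the `y` values of all trajectory points. Bins are
#' left-closed, right-open, with the final bin closed.
#'
#' @param trajectories A [grow_axons()] result (or any tibble with `y`).
#' @param bins Number of bins (>= 2) or a vector of bin edges.
#' @param range Histogram range when `bins` is a count; defaults to the
#'   data range.
#' @param normalize If `TRUE`, add a `density` column integrating to 1.
#' @return A tibble `y_lo`, `y_hi`, `mid`, `count` (and `density`).
#' @export
dv_distribution <- function(trajectories, bins = 30, range = NULL,
                            normalize = TRUE) {
  y <- trajectories$y
  if (length(y) == 0) stop("no trajectory points", call. = FALSE)
  if (length(bins) == 1) {
    stopifnot(bins >= 2)
    if (is.null(range)) range <- c(min(y), max(y) + 1e-9)
    edges <- seq(range[1], range[2], length.out = bins + 1)
  } else {
    edges <- bins
  }
  k <- findInterval(y, edges, rightmost.closed = TRUE)
  k <- k[k >= 1 & k <= length(edges) - 1]
  counts <- tabulate(k, nbins = length(edges) - 1)
  out <- tibble::tibble(
    y_lo = edges[-length(edges)], y_hi = edges[-1],
    mid = (edges[-1] + edges[-length(edges)]) / 2,
    count = counts)
  if (normalize) {
    w <- out$y_hi - out$y_lo
    out$density <- out$count / (sum(out$count) * w)
  }
  out
}

#' Tortuosity of trajectories
#'
#' Arc length divided by the end-to-end Euclidean distance; 1 for a
#' straight path, `Inf` when the endpoints coincide.
#'
#' @param trajectories A [grow_axons()] result.
#' @return A tibble with one row per axon: `neuron_id`, `axon`,
#'   `tortuosity`.
#' @export
tortuosity <- function(trajectories) {
  trajectories |>
    dplyr::group_by(.data$neuron_id, .data$axon) |>
    dplyr::arrange(.data$step, .by_group = TRUE) |>
    dplyr::summarise(
      tortuosity = {
        if (dplyr::n() < 2) NA_real_ else {
          arc <- sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2))
          ee <- sqrt((dplyr::last(.data$x) - dplyr::first(.data$x))^2 +
                       (dplyr::last(.data$y) - dplyr::first(.data$y))^2)
          if (ee == 0) Inf else arc / ee
        }
      }, .groups = "drop")
}

#' Fraction of axon points outside the dorsal tract
#'
#' Pools primary and secondary axon points (each elongation-step point
#' weighted equally) and reports the percentage lying outside
#' `y_inner <= |y| <= y_outer`.
#'
#' The tract is only defined over the RC extent where both soma columns
#' exist (caudal of the dla/dlc column, `x >= 700` by default); points
#' rostral of that, where the corridor has no ventral wall, are excluded
#' from the denominator when the tract carries an `x_start`.
#'
#' @param trajectories A [grow_axons()] result.
#' @param tract A list with `y_inner`, `y_outer` and optionally `x_start`
#'   (defaults to the tract of the environment stored on the trajectories).
#' @return Percentage in `[0, 100]`.
#' @export
escape_fraction <- function(trajectories, tract = NULL) {
  if (is.null(tract)) {
    env <- attr(trajectories, "environment", exact = TRUE)
    if (is.null(env)) stop("no tract given", call. = FALSE)
    tract <- env$tract
  }
  y <- trajectories$y
  if (!is.null(tract$x_start)) y <- y[trajectories$x >= tract$x_start]
  outside <- abs(y) < tract$y_inner | abs(y) > tract$y_outer
  100 * mean(outside)
}

#' Bundle statistics at rostro-caudal slices
#'
#' At each RC slice the DV positions where axons cross are sorted and split
#' into clusters wherever the gap between neighbours exceeds
#' `gap_threshold`; each cluster is one bundle. A trajectory crossing a
#' slice several times contributes each crossing.
#'
#' @param trajectories A [grow_axons()] result.
#' @param slice_spacing Distance between slices, um.
#' @param gap_threshold Cluster-splitting gap, um.
#' @return A list with `slices` (tibble: `x`, `n_axons`, `n_bundles`,
#'   `mean_size`) and the summary scalars `mean_bundle_count`,
#'   `mean_bundle_size`.
#' @export
bundle_stats <- function(trajectories, slice_spacing = 50,
                         gap_threshold = 5) {
  stopifnot(slice_spacing > 0, gap_threshold > 0)
  xr <- range(trajectories$x)
  slices <- seq(xr[1] + slice_spacing / 2, xr[2], by = slice_spacing)
  tr <- dplyr::arrange(trajectories, .data$neuron_id, .data$axon, .data$step)
  grp <- paste(tr$neuron_id, tr$axon)
  n <- nrow(tr)
  same <- c(grp[-1] == grp[-n], FALSE)
  x0 <- tr$x[-n][same[-n]]; x1 <- tr$x[-1][same[-n]]
  y0 <- tr$y[-n][same[-n]]; y1 <- tr$y[-1][same[-n]]
  per_slice <- lapply(slices, function(xs) {
    # half-open rule so a vertex exactly on the slice is counted once
    hit <- (x0 < xs & x1 >= xs) | (x0 > xs & x1 <= xs)
    if (!any(hit)) return(NULL)
    tt <- (xs - x0[hit]) / (x1[hit] - x0[hit])
    ys <- sort(y0[hit] + tt * (y1[hit] - y0[hit]))
    cl <- cumsum(c(1, diff(ys) > gap_threshold))
    tibble::tibble(x = xs, n_axons = length(ys),
                   n_bundles = max(cl),
                   mean_size = length(ys) / max(cl))
  })
  slices_tbl <- dplyr::bind_rows(per_slice)
  list(slices = slices_tbl,
       mean_bundle_count = mean(slices_tbl$n_bundles),
       mean_bundle_size = mean(slices_tbl$mean_size))
}

#' DV dispersion of axons at RC slices
#'
#' Mean (over slices) of the standard deviation of the DV positions at
#' which axons cross each slice - the spread that fasciculation shrinks.
#'
#' @inheritParams bundle_stats
#' @return A scalar, um.
#' @export
dv_dispersion <- function(trajectories, slice_spacing = 50) {
  xr <- range(trajectories$x)
  slices <- seq(xr[1] + slice_spacing / 2, xr[2], by = slice_spacing)
  tr <- dplyr::arrange(trajectories, .data$neuron_id, .data$axon, .data$step)
  grp <- paste(tr$neuron_id, tr$axon)
  n <- nrow(tr)
  same <- c(grp[-1] == grp[-n], FALSE)
  x0 <- tr$x[-n][same[-n]]; x1 <- tr$x[-1][same[-n]]
  y0 <- tr$y[-n][same[-n]]; y1 <- tr$y[-1][same[-n]]
  sds <- vapply(slices, function(xs) {
    hit <- (x0 < xs & x1 >= xs) | (x0 > xs & x1 <= xs)
    if (sum(hit) < 2) return(NA_real_)
    tt <- (xs - x0[hit]) / (x1[hit] - x0[hit])
    sd(y0[hit] + tt * (y1[hit] - y0[hit]))
  }, numeric(1))
  mean(sds, na.rm = TRUE)
}

#' Number of dINs with no dIN input
#'
#' Counts dIN neurons that receive zero synaptic contacts whose presynaptic
#' neuron is also a dIN. Fasciculated connectomes concentrate dIN-dIN
#' excitation onto fewer cells, raising this count.
#'
#' @param connectome A `fascicle_connectome`.
#' @return Integer count.
#' @export
isolated_din_count <- function(connectome) {
  dins <- connectome$population$id[connectome$population$type == "dIN"]
  syn <- connectome$synapses
  fed <- unique(syn$post_id[syn$pre_type == "dIN" & syn$post_type == "dIN"])
  sum(!dins %in% fed)
}
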