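#' Build the standard growth environment
#'
#' The spinal cord is modelled as a 2D rectangle: `x` runs rostro-caudally
#' (distance from the midbrain, 500--2000 um) and `y` dorso-ventrally
#' (distance from the ventral midline; `y > 0` is the left side). Axon growth
#' is confined by the arena bounds and by three longitudinal barriers per
#' side:
#'
#' * `y = +/-137` for `x > 500`: the column of RB somata (dorsal wall of the
#'   dorsal tract),
#' * `y = +/-127` for `x > 700`: the column of dla/dlc somata (ventral wall
#'   of the dorsal tract),
#' * `y = +/-25` over the whole length: the floor-plate boundary, passable
#'   only by commissural axons (dlc, cIN).
#'
#' @param x_min,x_max,y_abs_max Arena bounds in um.
#' @param rb_barrier_y,dl_barrier_y,floor_plate_y Barrier levels in um
#'   (unsigned; both sides are built).
#' @param rb_barrier_x_start,dl_barrier_x_start Rostral end of the two dorsal
#'   barriers.
#' @return An object of class `fascicle_environment`: a list with `arena`,
#'   a `barriers` tibble, a list `gaps` of per-barrier gap matrices, and the
#'   dorsal `tract` bounds.
#' @examples
#' env <- spinal_environment()
#' env
#' @export
spinal_environment <- function(x_min = 500, x_max = 2000, y_abs_max = 145,
                               rb_barrier_y = 137, dl_barrier_y = 127,
                               floor_plate_y = 25,
                               rb_barrier_x_start = 500,
                               dl_barrier_x_start = 700) {
  if (!(x_min < x_max)) abort_config("arena requires x_min < x_max")
  if (!(y_abs_max > 0)) abort_config("arena requires y_abs_max > 0")
  lv <- c(rb_barrier_y, dl_barrier_y, floor_plate_y)
  if (any(lv <= 0) || any(lv >= y_abs_max))
    abort_config("barrier levels must lie strictly inside (0, y_abs_max)")
  barriers <- tibble::tibble(
    name = rep(c("RB_somata", "dl_somata", "floor_plate"), each = 2),
    y_level = c(rb_barrier_y, -rb_barrier_y, dl_barrier_y, -dl_barrier_y,
                floor_plate_y, -floor_plate_y),
    x_start = c(rb_barrier_x_start, rb_barrier_x_start,
                dl_barrier_x_start, dl_barrier_x_start, x_min, x_min),
    x_end = x_max,
    exempt_commissural = rep(c(FALSE, FALSE, TRUE), each = 2)
  )
  if (any(barriers$x_start >= barriers$x_end))
    abort_config("barrier requires x_start < x_end")
  structure(
    list(
      arena = list(x_min = x_min, x_max = x_max, y_abs_max = y_abs_max),
      barriers = barriers,
      gaps = rep(list(matrix(numeric(0), ncol = 2,
                             dimnames = list(NULL, c("lo", "hi")))),
                 nrow(barriers)),
      tract = list(y_inner = dl_barrier_y, y_outer = rb_barrier_y,
                   x_start = dl_barrier_x_start)
    ),
    class = "fascicle_environment"
  )
}

#' Punch periodic gaps into the dorsal-tract barriers
#'
#' Replaces the two barriers bounding the dorsal tract (the RB- and
#' dla/dlc-soma columns) with an alternating pattern of blocked intervals and
#' open gaps, starting blocked at the barrier's rostral end. This emulates
#' imperfect soma barriers with spaces between the somata.
#'
#' @param environment A [spinal_environment()] object.
#' @param gap_length Length of each open gap, um.
#' @param interval Length of each blocked interval, um.
#' @return The environment with gapped dorsal-tract barriers.
#' @examples
#' env <- spinal_environment() |> apply_gaps(25, 25)
#' nrow(barrier_gaps(env, "RB_somata", side = 1))
#' @export
apply_gaps <- function(environment, gap_length = 25, interval = 25) {
  stopifnot(inherits(environment, "fascicle_environment"))
  if (gap_length <= 0 || interval <= 0)
    abort_config("gap_length and interval must be positive")
  idx <- which(environment$barriers$name %in% c("RB_somata", "dl_somata"))
  for (i in idx) {
    x0 <- environment$barriers$x_start[i]
    x1 <- environment$barriers$x_end[i]
    lo <- seq(x0 + interval, x1, by = interval + gap_length)
    hi <- pmin(lo + gap_length, x1)
    keep <- lo < x1
    environment$gaps[[i]] <- cbind(lo = lo[keep], hi = hi[keep])
  }
  environment
}

#' Gap intervals of a named barrier
#'
#' @param environment A [spinal_environment()] object.
#' @param name Barrier name (`"RB_somata"`, `"dl_somata"`, `"floor_plate"`).
#' @param side `1` (left) or `-1` (right).
#' @return A tibble with columns `lo`, `hi` (open intervals, um).
#' @export
barrier_gaps <- function(environment, name, side = 1) {
  i <- which(environment$barriers$name == name &
               sign(environment$barriers$y_level) == side)
  tibble::as_tibble(as.data.frame(environment$gaps[[i]]))
}

#' Test whether a step segment is blocked by a barrier
#'
#' Checks a proposed growth-cone step against every barrier: a segment is
#' blocked if it crosses a barrier's `y` level at an `x` position inside the
#' barrier's blocked range (outside any gap), unless the cell type is exempt
#' (commissural axons may cross the floor plate). Arena bounds are not
#' checked here.
#'
#' @param environment A [spinal_environment()] object.
#' @param p0,p1 Numeric length-2 vectors, the segment endpoints (um).
#' @param cell_type One of [cell_types].
#' @return A list with `blocked` (logical) and, when blocked, `point` (the
#'   intersection with the first barrier hit) and `barrier` (its name).
#' @examples
#' env <- spinal_environment()
#' barrier_blocks(env, c(800, 136.5), c(800, 137.5), "RB")$blocked
#' @export
barrier_blocks <- function(environment, p0, p1, cell_type) {
  stopifnot(inherits(environment, "fascicle_environment"),
            length(p0) == 2, length(p1) == 2)
  is_comm <- cell_type %in% commissural_types
  best <- list(blocked = FALSE)
  best_t <- Inf
  for (i in seq_len(nrow(environment$barriers))) {
    b <- environment$barriers[i, ]
    if (b$exempt_commissural && is_comm) next
    f0 <- p0[2] - b$y_level
    f1 <- p1[2] - b$y_level
    if ((f0 > 0 && f1 > 0) || (f0 < 0 && f1 < 0) || f0 == 0) next
    tt <- if (f0 != f1) f0 / (f0 - f1) else 1
    xh <- p0[1] + tt * (p1[1] - p0[1])
    if (xh < b$x_start || xh > b$x_end) next
    g <- environment$gaps[[i]]
    if (nrow(g) > 0 && any(xh > g[, 1] & xh < g[, 2])) next
    if (tt < best_t) {
      best_t <- tt
      best <- list(blocked = TRUE, point = c(xh, b$y_level), barrier = b$name,
                   t = tt)
    }
  }
  best
}

#' Dorsal-tract membership test
#'
#' @param environment A [spinal_environment()] object.
#' @param y Numeric vector of DV positions (um, signed).
#' @return Logical vector: `TRUE` where `y_inner <= |y| <= y_outer`.
#' @export
in_dorsal_tract <- function(environment, y) {
  abs(y) >= environment$tract$y_inner & abs(y) <= environment$tract$y_outer
}

# flat list describing the environment, for the C++ engine
environment_to_engine <- function(environment) {
  lapply(seq_len(nrow(environment$barriers)), function(i) {
    b <- environment$barriers[i, ]
    list(y_level = b$y_level, x_start = b$x_start, x_end = b$x_end,
         exempt_commissural = b$exempt_commissural,
         gaps = environment$gaps[[i]])
  })
}
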