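#' Per-type gradient-guidance parameters
#'
#' Axon turning is driven by two chemotactic cue functions evaluated at the
#' growth-cone position: a rostro-caudal cue `G_RC(x, y)` and a dorso-ventral
#' cue `G_DV(x, y)`. The default field family is
#'
#' \deqn{G_{RC}(x, y) = g_{rc}, \qquad
#'       G_{DV}(x, y) = k_{dv}\,\mathrm{sgn}(y)\,e^{-|y|/\lambda} + k_{off}}
#'
#' with per-type coefficients. The sign conventions follow the turning rule
#' (`theta' = theta - G_RC sin theta + G_DV cos theta + xi`): `g_rc < 0`
#' attracts the growth angle to the ascending direction (`theta = pi`,
#' toward the head) and `g_rc > 0` to the descending direction; `k_dv < 0`
#' pushes axons ventrally on both sides of the body (the exponential makes
#' the ventral cue strongest near the floor plate), `k_dv > 0` dorsally.
#' `k_off` is a side-asymmetry offset, 0 by default so the field is
#' left/right mirror-symmetric. `alpha` is the half-width of the uniform
#' per-step angular noise.
#'
#' Commissural types (dlc, cIN) carry a second `pre_crossing` row: before
#' reaching the contralateral floor-plate boundary their axons are driven by
#' a strong ventral cue, and switch to the regular row after crossing.
#'
#' The numeric values are package defaults chosen to give each type its
#' qualitative trajectory class (RB longitudinal in the dorsal tract,
#' interneurons descending ventrally then turning longitudinal, commissural
#' dives); they are calibration targets for [pattern_search()], not measured
#' constants.
#'
#' @param overrides Optional tibble with columns from the parameter table
#'   (`type`, `phase`, and any of `g_rc`, `k_dv`, `lambda`, `k_off`,
#'   `alpha`) used to replace defaults.
#' @return A tibble with one row per (type, phase).
#' @examples
#' growth_params() |> dplyr::filter(type == "cIN")
#' @export
growth_params <- function(overrides = NULL) {
  p <- tibble::tribble(
    ~type, ~phase,          ~g_rc, ~k_dv, ~lambda, ~k_off, ~alpha,
    "RB",  "normal",        -0.20,  0.00,     100,      0,   0.08,
    "dla", "normal",        -0.08, -0.03,     150,      0,   0.20,
    "dlc", "normal",        -0.08,  0.04,     150,      0,   0.20,
    "dlc", "pre_crossing",   0.00, -0.45,     600,      0,   0.05,
    "aIN", "normal",        -0.06, -0.05,     120,      0,   0.25,
    "cIN", "normal",        -0.07,  0.03,     150,      0,   0.20,
    "cIN", "pre_crossing",   0.00, -0.45,     600,      0,   0.05,
    "dIN", "normal",         0.07, -0.04,     120,      0,   0.20,
    "mn",  "normal",         0.08, -0.04,     120,      0,   0.15
  )
  if (!is.null(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      o <- overrides[i, ]
      ph <- if ("phase" %in% names(o)) o$phase else "normal"
      j <- which(p$type == o$type & p$phase == ph)
      if (length(j) != 1) abort_config("unknown type/phase in overrides")
      for (col in intersect(names(o), c("g_rc", "k_dv", "lambda", "k_off", "alpha")))
        p[[col]][j] <- o[[col]]
    }
  }
  p
}

#' Axon--axon interaction parameters
#'
#' `s_pr` and `s_se` are the sensitivities of primary and secondary axons to
#' the nearest same-type axon within range `r` (um). `s > 0` is attraction
#' (fasciculation), `s < 0` repulsion, `s = 0` no interaction; at `|s| = 1`
#' gradients and noise have no influence while a neighbour is in range.
#'
#' @param s_pr,s_se Sensitivities in `[-1, 1]`.
#' @param r Interaction radius in um, `> 0`.
#' @return A list of class `fascicle_interaction`.
#' @examples
#' interaction_params(s_pr = 0.2, s_se = 0.2, r = 1)
#' @export
interaction_params <- function(s_pr = 0, s_se = 0, r = 1) {
  if (abs(s_pr) > 1 || abs(s_se) > 1) abort_config("|s| must be <= 1")
  if (r <= 0) abort_config("interaction radius r must be positive")
  structure(list(s_pr = s_pr, s_se = s_se, r = r),
            class = "fascicle_interaction")
}

#' Evaluate the guidance cues at a position
#'
#' @param params A [growth_params()] tibble.
#' @param x,y Position (um); must lie inside the arena.
#' @param cell_type One of [cell_types].
#' @param phase `"normal"` or `"pre_crossing"`.
#' @param axon `"primary"` or `"secondary"` (secondary axons see the
#'   rostro-caudal cue with opposite sign, as they grow the other way).
#' @param side `"left"` or `"right"`: in the `pre_crossing` phase the DV
#'   cue's sign is anchored to the soma side (the floor-plate-directed
#'   drive persists through the midline) rather than to `sign(y)`.
#' @param environment Optional [spinal_environment()] used to validate that
#'   the point lies inside the arena.
#' @return Named numeric vector `c(g_rc, g_dv)` (radians-scale influences).
#' @examples
#' evaluate_gradient(growth_params(), 1000, 50, "aIN")
#' @export
evaluate_gradient <- function(params, x, y, cell_type, phase = "normal",
                              axon = "primary", side = "left",
                              environment = NULL) {
  if (!is.null(environment)) {
    a <- environment$arena
    if (x < a$x_min || x > a$x_max || abs(y) > a$y_abs_max)
      stop("point outside arena", call. = FALSE)
  }
  row <- params[params$type == cell_type & params$phase == phase, ]
  if (nrow(row) != 1) abort_config("no parameter row for this type/phase")
  g_rc <- row$g_rc * if (axon == "secondary") -1 else 1
  sgn <- if (phase == "pre_crossing") {
    if (side == "left") 1 else -1
  } else sign(y)
  g_dv <- row$k_dv * sgn * exp(-abs(y) / row$lambda) + row$k_off
  c(g_rc = g_rc, g_dv = g_dv)
}

#' Sample per-step angular noise
#'
#' Uniform on `[-alpha, alpha]` radians; exactly zero when `alpha = 0`.
#'
#' @param alpha Half-width in radians, `>= 0`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_noise <- function(alpha, n = 1) {
  stopifnot(alpha >= 0)
  if (alpha == 0) return(rep(0, n))
  runif(n, -alpha, alpha)
}
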