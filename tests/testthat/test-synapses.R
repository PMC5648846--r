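make_conn <- function(pre_id, post_id, pre_type, post_type, pop) {
  structure(list(
    population = pop,
    synapses = tibble::tibble(
      pre_id = pre_id, post_id = post_id, pre_type = pre_type,
      post_type = post_type, axon = "primary", step = 1L,
      x = 1000, y = 60, arc_length = 1),
    seed = 1, prob = NULL, hash = "h"), class = "fascicle_connectome")
}

test_that("crossing detection finds exact intersections", {
  tr <- tibble::tibble(
    neuron_id = 1L, type = "aIN", side = "left", axon = "primary",
    step = 0:1, x = c(99.5, 100.5), y = c(10, 10),
    theta = 0, phase = "normal", clipped = FALSE)
  dd <- tibble::tibble(neuron_id = 2L, type = "mn", side = "left",
                       x = 100, y_lo = 0, y_hi = 20)
  hit <- detect_crossings(tr, dd)
  expect_equal(nrow(hit), 1)
  expect_equal(c(hit$x, hit$y), c(100, 10))
  # dendrite out of DV reach
  dd2 <- dplyr::mutate(dd, y_lo = 11)
  expect_equal(nrow(detect_crossings(tr, dd2)), 0)
  # endpoint touching counts
  tr2 <- dplyr::mutate(tr, x = c(99, 100))
  expect_equal(nrow(detect_crossings(tr2, dd)), 1)
})

test_that("crossing detection matches the brute-force oracle", {
  set.seed(31)
  nseg <- 400
  segs <- tibble::tibble(
    x0 = runif(nseg, 0, 100), y0 = runif(nseg, 0, 50),
    x1 = NA_real_, y1 = NA_real_)
  ang <- runif(nseg, -pi, pi)
  segs$x1 <- segs$x0 + cos(ang)
  segs$y1 <- segs$y0 + sin(ang)
  dends <- tibble::tibble(
    x = runif(60, 0, 100), y_lo = runif(60, 0, 40))
  dends$y_hi <- dends$y_lo + runif(60, 1, 15)
  got <- with(list(d = dplyr::arrange(dends, x)), {
    h <- detect_crossings_cpp(segs$x0, segs$y0, segs$x1, segs$y1,
                              d$x, d$y_lo, d$y_hi)
    ord <- order(dplyr::arrange(dends, x)$x)
    data.frame(seg = h$seg, dendrite = order(dends$x)[h$dendrite])
  })
  want <- brute_crossings(segs, dends)
  key <- function(z) sort(paste(z$seg, z$dendrite))
  expect_identical(key(got), key(want))
})

test_that("spatial-hash nearest point matches the brute-force oracle", {
  set.seed(77)
  for (case in 1:50) {
    m <- sample(5:200, 1)
    cand <- tibble::tibble(
      x = runif(m, 0, 50), y = runif(m, -20, 20),
      theta = runif(m, -pi, pi),
      neuron_id = sample.int(20, m, replace = TRUE),
      step = sample.int(500, m, replace = TRUE) - 1L)
    tip <- c(runif(1, 0, 50), runif(1, -20, 20))
    r <- runif(1, 0.5, 6)
    excl <- sample.int(20, 1)
    got <- nearest_axon_point(tip, cand, r, exclude_id = excl)
    want <- brute_nearest(tip, cand, r, exclude_id = excl)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(as.data.frame(got), as.data.frame(want),
                   ignore_attr = TRUE)
    }
  }
})

test_that("synapse formation follows the probability matrix", {
  env <- spinal_environment()
  # one aIN axon crossing many aIN dendrites downstream
  # one growing aIN axon; the rest of the population only contributes
  # dendrites spanning its path
  pop <- dplyr::bind_rows(
    toy_neurons(1, "aIN", 1500, 60, pi, 600, pioneer = TRUE),
    lapply(2:40, function(i) toy_neurons(i, "aIN", 1500 - 12 * i, 60, pi, 5,
                                         dend_half = 30)))
  tr <- grow_axons(pop[1, ], env, null_params(), interaction_params(0, 0, 1),
                   seed = 1)
  p1 <- connection_probabilities(base = 1); p1[] <- 1
  con1 <- form_synapses(tr, pop, p1, seed = 1)
  cross <- detect_crossings(tr, dendrites(pop))
  ncross <- sum(cross$pre_id != cross$post_id)  # autapses are excluded
  expect_gt(ncross, 30)
  expect_equal(nrow(con1$synapses), ncross)   # P = 1 keeps every crossing
  p0 <- p1; p0[] <- 0
  expect_equal(nrow(form_synapses(tr, pop, p0, seed = 1)$synapses), 0)
  # P = 0.5: binomial 4-sigma band
  ph <- p1; ph[] <- 0.5
  nh <- nrow(form_synapses(tr, pop, ph, seed = 1)$synapses)
  expect_lt(abs(nh - ncross / 2), 4 * sqrt(ncross * 0.25) + 1)
  # missing entry for an occurring pair errors
  pna <- p1; pna["aIN", "aIN"] <- NA
  expect_error(form_synapses(tr, pop, pna, seed = 1), "missing")
})

test_that("pruning is an independent Bernoulli thinning", {
  pop <- toy_neurons(1, "aIN", 1000, 60, 0, 5)
  n0 <- 8000
  con <- make_conn(rep(1L, n0), rep(2L, n0), rep("aIN", n0), rep("aIN", n0),
                   pop)
  expect_equal(nrow(prune_synapses(con, 1, seed = 1)$synapses), n0)
  expect_equal(nrow(prune_synapses(con, 0, seed = 1)$synapses), 0)
  nk <- nrow(prune_synapses(con, 0.55, seed = 1)$synapses)
  expect_lt(abs(nk - n0 * 0.55), 4 * sqrt(n0 * 0.55 * 0.45))
})

test_that("synapse count matrix counts contacts and percent change", {
  pop <- toy_neurons(1, "aIN", 1000, 60, 0, 5)
  con <- make_conn(c(1L, 1L, 2L), c(2L, 2L, 3L),
                   c("aIN", "aIN", "dIN"), c("cIN", "cIN", "mn"), pop)
  m <- synapse_count_matrix(con)
  expect_equal(m$n[m$pre_type == "aIN" & m$post_type == "cIN"], 3 - 1)
  expect_equal(sum(m$n), 3)
  empty <- make_conn(integer(), integer(), character(), character(), pop)
  expect_true(all(synapse_count_matrix(empty)$n == 0))
  mm <- synapse_count_matrix(con, reference = con)
  expect_true(all(mm$pct_change[mm$n_ref > 0] == 0))
})

test_that("commissural synapses are contralateral and pre-crossing makes none", {
  env <- spinal_environment()
  tabs <- make_measurement_tables(1)
  pop <- build_population(c(cIN = 8, dIN = 8, mn = 6), tabs, seed = 3,
                          environment = env)
  tr <- grow_axons(pop, env, growth_params(), interaction_params(0.2, 0.2, 1),
                   seed = 3)
  p1 <- connection_probabilities(); p1[] <- 1
  con <- form_synapses(tr, pop, p1, seed = 3)
  syn <- con$synapses
  side_of <- setNames(pop$side, pop$id)
  comm <- syn[syn$pre_type %in% c("cIN", "dlc"), ]
  expect_gt(nrow(comm), 0)
  expect_true(all(side_of[as.character(comm$pre_id)] !=
                    side_of[as.character(comm$post_id)]))
  # crossings in the pre-crossing phase are never kept
  cross <- detect_crossings(tr, dendrites(pop))
  expect_gt(sum(cross$phase == "pre_crossing"), 0)
  expect_false(any(paste(syn$pre_id, syn$post_id, syn$step) %in%
                     paste(cross$pre_id[cross$phase == "pre_crossing"],
                           cross$post_id[cross$phase == "pre_crossing"],
                           cross$step[cross$phase == "pre_crossing"])))
})
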