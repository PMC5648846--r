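test_that("single growth step follows the turning rule", {
  # theta = 0, g_rc = 0.1, g_dv = 0.05, no noise: theta' = 0.05
  p <- growth_params(overrides = tibble::tibble(
    type = "aIN", phase = "normal", g_rc = 0.1, k_dv = 0.05, lambda = 1e9,
    k_off = 0, alpha = 0))
  tr <- grow_axon_solo(1000, 60, 0, 1, "aIN", params = p)
  expect_equal(tr$theta[2], 0 - 0.1 * sin(0) + 0.05 * exp(-60 / 1e9) * cos(0),
               tolerance = 1e-12)
  expect_equal(tr$x[2], 1000 + cos(tr$theta[2]))
  expect_equal(tr$y[2], 60 + sin(tr$theta[2]))
  expect_error(grow_axon_solo(1000, 60, 0, -1, "aIN"), "n_steps")
})

test_that("interaction blend: midpoint of theta_A and theta_B at s = 0.5", {
  # pioneer laid along angle 0.6; follower starts with theta 0.2 and zero
  # gradients/noise, so theta_A = 0.2, theta_B = 0.6, s = 0.5 -> 0.4
  pop <- dplyr::bind_rows(
    toy_neurons(1, "aIN", 1000, 60, 0.6, 5, pioneer = TRUE),
    toy_neurons(2, "aIN", 1000, 60.4, 0.2, 3, start = 10))
  tr <- grow_axons(pop, spinal_environment(), null_params(),
                   interaction_params(0.5, 0.5, 1), seed = 1)
  f <- tr[tr$neuron_id == 2, ]
  expect_equal(f$theta[2], 0.4, tolerance = 1e-12)
})

test_that("schedule: pioneers first, followers spaced, secondaries wait", {
  pop <- dplyr::bind_rows(lapply(1:6, function(i) {
    toy_neurons(i, "aIN", 500 + 100 * i, 60, 0, 500, pioneer = i <= 4)
  }))
  # two followers (ids 5, 6 at the caudal end)
  sch <- build_schedule(pop, wave_spacing = 200)
  expect_equal(sch$start_time[sch$id %in% 1:4], rep(0, 4))
  expect_equal(sort(sch$start_time[sch$id %in% 5:6]), c(500, 700))
  # follower order tracks soma x, most rostral first
  pop2 <- dplyr::bind_rows(
    toy_neurons(1, "aIN", 600, 60, 0, 100, pioneer = TRUE),
    toy_neurons(2, "aIN", 1500, 60, 0, 50),
    toy_neurons(3, "aIN", 900, 60, 0, 50))
  sch2 <- build_schedule(pop2, wave_spacing = 200)
  expect_lt(sch2$start_time[sch2$id == 3], sch2$start_time[sch2$id == 2])
  # secondary wave starts only after every primary has finished
  pop3 <- dplyr::bind_rows(
    toy_neurons(1, "aIN", 800, 60, pi, 100, pioneer = TRUE,
                len_secondary = 50, branch_at = 30, theta0_se = 0),
    toy_neurons(2, "aIN", 1200, 60, pi, 400))
  sch3 <- build_schedule(pop3, wave_spacing = 200)
  sec <- sch3[sch3$axon == "secondary", ]
  prim_end <- max(sch3$start_time[sch3$axon == "primary"] +
                    sch3$n_steps[sch3$axon == "primary"])
  expect_true(all(sec$start_time >= prim_end))
})

test_that("s = 0 growth in company is bit-identical to growing alone", {
  env <- spinal_environment()
  tabs <- make_measurement_tables(1)
  pop <- build_population(c(aIN = 6, dIN = 4), tabs, seed = 11,
                          environment = env)
  par <- growth_params()
  tr_all <- grow_axons(pop, env, par, interaction_params(0, 0, 1), seed = 5)
  for (i in c(1, 7)) {
    solo <- grow_axons(pop[pop$id == pop$id[i], ], env, par,
                       interaction_params(0, 0, 1), seed = 5)
    both <- tr_all[tr_all$neuron_id == pop$id[i], ]
    expect_identical(both$x, solo$x)
    expect_identical(both$y, solo$y)
    expect_identical(both$theta, solo$theta)
  }
})

test_that("engine agrees with the pure-R reference grower", {
  env <- spinal_environment()
  tabs <- make_measurement_tables(1)
  pop <- build_population(c(dla = 3), tabs, seed = 2, environment = env)
  pop <- pop[pop$side == "left", ]
  pop$has_secondary <- FALSE; pop$len_secondary <- NA_real_
  tr <- grow_axons(pop, env, growth_params(), interaction_params(0, 0, 1),
                   seed = 8)
  for (i in seq_len(nrow(pop))) {
    ns <- as.integer(ceiling(pop$len_primary[i]))
    set.seed(derive_seed(8, paste0("axon/", pop$id[i], "/1")))
    u <- runif(ns, -1, 1)
    ref <- grow_axon_solo(pop$x[i], pop$y[i], pop$theta0[i], ns, "dla",
                          pop$side[i], env, growth_params(), u)
    eng <- tr[tr$neuron_id == pop$id[i], ]
    expect_identical(eng$x, ref$x)
    expect_identical(eng$y, ref$y)
    expect_identical(eng$theta, ref$theta)
  }
})

test_that("|s| = 1 locks the follower to the pioneer axis or perpendicular", {
  sc <- make_toy_scenario("straight_pioneer_follower", s = 1)
  tr <- grow_axons(sc$population, sc$environment, sc$params, sc$interaction,
                   seed = 1)
  f <- tr[tr$neuron_id == 2 & tr$step > 0, ]
  expect_true(all(f$theta == 0))          # pioneer angle, exactly
  expect_true(all(f$y == f$y[1]))         # parallel track
  # repulsion at s = -1: first step is the away-pointing perpendicular
  scr <- make_toy_scenario("straight_pioneer_follower", s = -1)
  trr <- grow_axons(scr$population, scr$environment, scr$params,
                    scr$interaction, seed = 1)
  fr <- trr[trr$neuron_id == 2, ]
  expect_equal(fr$theta[2], pi / 2)       # neighbour below -> straight up
})

test_that("same seed gives bit-identical runs; different seed differs", {
  a <- grow_one_type("cIN", 5, s = 0.2, seed = 3)
  b <- grow_one_type("cIN", 5, s = 0.2, seed = 3)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- grow_one_type("cIN", 5, s = 0.2, seed = 4)
  expect_false(identical(a$y, c$y))
})

test_that("unclipped steps are exactly delta long", {
  tr <- grow_one_type("aIN", 6, s = 0.3, seed = 2)
  tr <- dplyr::arrange(tr, neuron_id, axon, step)
  grp <- paste(tr$neuron_id, tr$axon)
  n <- nrow(tr)
  same <- c(grp[-1] == grp[-n], FALSE)
  len <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)[same[-n]]
  clipped <- tr$clipped[-1][same[-n]]
  expect_equal(len[!clipped], rep(1, sum(!clipped)), tolerance = 1e-9)
  expect_true(all(len <= 1 + 1e-9))
})

test_that("axons only interact within their own type (locality)", {
  env <- spinal_environment()
  tabs <- make_measurement_tables(1)
  pop <- build_population(c(aIN = 8, dIN = 8), tabs, seed = 6,
                          environment = env)
  par <- growth_params()
  inter <- interaction_params(0.5, 0.5, 3)
  tr_mix <- grow_axons(pop, env, par, inter, seed = 2)
  tr_aIN <- grow_axons(pop[pop$type == "aIN", ], env, par, inter, seed = 2)
  a_mix <- tr_mix[tr_mix$type == "aIN", ]
  expect_identical(a_mix$x, tr_aIN$x)
  expect_identical(a_mix$y, tr_aIN$y)
})

test_that("commissural axons cross, switch phase, and ignore neighbours before", {
  sc <- make_toy_scenario("commissural_single")
  tr <- grow_axons(sc$population, sc$environment, sc$params, sc$interaction,
                   seed = 1)
  # crossed exactly at the first point at/below y = -25
  first_crossed <- which(tr$phase == "crossed")[1]
  expect_false(is.na(first_crossed))
  expect_true(all(tr$y[seq_len(first_crossed - 1)] > -25))
  expect_lte(tr$y[first_crossed], -25)
  expect_true(all(tr$phase[first_crossed:nrow(tr)] == "crossed"))
  # a cIN meandering ipsilaterally above the floor plate stays pre_crossing
  pop <- toy_neurons(1, "cIN", 1000, 60, pi, 50)
  p <- null_params()
  tr2 <- grow_axons(pop, spinal_environment(), p, interaction_params(0, 0, 1),
                    seed = 1)
  expect_true(all(tr2$phase == "pre_crossing"))
  # pre-crossing neighbours exert no pull (interaction suppressed)
  pop3 <- dplyr::bind_rows(
    toy_neurons(1, "cIN", 1000, 60, -pi / 2, 20, pioneer = TRUE),
    toy_neurons(2, "cIN", 1000.5, 60, -pi / 2 + 0.3, 20, start = 30))
  tr3a <- grow_axons(pop3, spinal_environment(), p,
                     interaction_params(1, 1, 2), seed = 1)
  tr3b <- grow_axons(pop3[2, ], spinal_environment(), p,
                     interaction_params(1, 1, 2), seed = 1)
  f3 <- tr3a[tr3a$neuron_id == 2, ]
  expect_identical(f3$theta, tr3b$theta)
})

test_that("secondary axons sprout at the branch point, reversed", {
  pop <- toy_neurons(1, "aIN", 1000, 60, pi, 100, pioneer = TRUE,
                     len_secondary = 40, branch_at = 30, theta0_se = 0)
  tr <- grow_axons(pop, spinal_environment(), null_params(),
                   interaction_params(0, 0, 1), seed = 1)
  sec <- tr[tr$axon == "secondary", ]
  prim <- tr[tr$axon == "primary", ]
  expect_equal(nrow(sec), 41)
  expect_equal(sec$x[1], prim$x[31])   # arc length 30 along the primary
  expect_equal(sec$y[1], prim$y[31])
  # primary ascends (-x), secondary descends (+x)
  expect_lt(prim$x[101], prim$x[1])
  expect_gt(sec$x[41], sec$x[1])
})

test_that("nearest-axon-point query honours radius, exclusion and ties", {
  cand <- tibble::tibble(x = c(0.5, 2), y = c(0, 0), theta = c(0.3, 1),
                         neuron_id = c(10L, 11L), step = c(4L, 0L))
  hit <- nearest_axon_point(c(0, 0), cand, r = 1)
  expect_equal(hit$theta, 0.3)
  expect_null(nearest_axon_point(c(0, 0), cand, r = 0.4))
  expect_null(nearest_axon_point(c(0, 0), cand[1, ], r = 1, exclude_id = 10L))
  # tie at equal distance: lower neuron id wins
  tie <- tibble::tibble(x = c(0, 0), y = c(1, -1), theta = c(1, 2),
                        neuron_id = c(7L, 3L), step = c(0L, 0L))
  expect_equal(nearest_axon_point(c(0, 0), tie, r = 2)$neuron_id, 3L)
})
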