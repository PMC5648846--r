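test_that("standard environment has the standard barrier layout", {
  env <- spinal_environment()
  expect_equal(nrow(env$barriers), 6)
  expect_setequal(env$barriers$y_level, c(137, -137, 127, -127, 25, -25))
  fp <- env$barriers[env$barriers$name == "floor_plate", ]
  expect_true(all(fp$exempt_commissural))
  expect_true(all(fp$x_start == env$arena$x_min))
  dl <- env$barriers[env$barriers$name == "dl_somata", ]
  expect_true(all(dl$x_start == 700))
  expect_error(spinal_environment(y_abs_max = 0), "y_abs_max")
  expect_error(spinal_environment(x_min = 2000, x_max = 500), "x_min")
})

test_that("dorsal tract membership is an interval test on |y|", {
  env <- spinal_environment()
  expect_true(in_dorsal_tract(env, 130))
  expect_true(in_dorsal_tract(env, -130))
  expect_false(in_dorsal_tract(env, 100))
  expect_true(all(in_dorsal_tract(env, c(127, 137, -127, -137))))
})

test_that("gap pattern alternates blocked/gap starting blocked", {
  env <- apply_gaps(spinal_environment(), 25, 25)
  g <- barrier_gaps(env, "dl_somata", side = 1)  # spans [700, 2000]
  expect_equal(nrow(g), 26)
  expect_equal(sum(g$hi - g$lo), 650)
  expect_equal(g$lo[1], 725)              # first block [700, 725] intact
  expect_true(all(g$lo >= 700 & g$hi <= 2000))
  expect_true(all(diff(as.vector(t(as.matrix(g)))) > 0))  # disjoint, ordered
  # a single huge gap truncates at the barrier end
  env2 <- apply_gaps(spinal_environment(), 1300, 25)
  g2 <- barrier_gaps(env2, "dl_somata", side = 1)
  expect_equal(nrow(g2), 1)
  expect_equal(unname(unlist(g2)), c(725, 2000))
  expect_error(apply_gaps(spinal_environment(), 0, 25), "positive")
  # deterministic
  expect_identical(apply_gaps(spinal_environment(), 25, 25),
                   apply_gaps(spinal_environment(), 25, 25))
})

test_that("blocks() respects barrier spans, gaps and commissural exemption", {
  env <- spinal_environment()
  hit <- barrier_blocks(env, c(800, 136.5), c(800, 137.5), "RB")
  expect_true(hit$blocked)
  expect_equal(hit$point, c(800, 137))
  # same segment through a gap is free
  genv <- env
  genv$gaps[[1]] <- cbind(lo = 790, hi = 810)
  expect_false(barrier_blocks(genv, c(800, 136.5), c(800, 137.5), "RB")$blocked)
  # commissural types pass the floor plate, others do not
  expect_false(barrier_blocks(env, c(1000, 25.5), c(1000, 24.5), "cIN")$blocked)
  expect_false(barrier_blocks(env, c(1000, 25.5), c(1000, 24.5), "dlc")$blocked)
  expect_true(barrier_blocks(env, c(1000, 25.5), c(1000, 24.5), "aIN")$blocked)
  # outside a barrier's RC span nothing blocks
  expect_false(barrier_blocks(env, c(600, 126.5), c(600, 127.5), "RB")$blocked)
})

test_that("grown trajectories never violate arena bounds or cross barriers", {
  env <- spinal_environment()
  tr <- grow_one_type("RB", 12, s = 0.2, seed = 4, environment = env)
  a <- env$arena
  expect_true(all(tr$x >= a$x_min & tr$x <= a$x_max))
  expect_true(all(abs(tr$y) <= a$y_abs_max))
  # no step segment pierces a blocked barrier span (impenetrability, exact)
  tr <- dplyr::arrange(tr, neuron_id, axon, step)
  grp <- paste(tr$neuron_id, tr$axon)
  n <- nrow(tr)
  same <- c(grp[-1] == grp[-n], FALSE)
  y0 <- tr$y[-n][same[-n]]; y1 <- tr$y[-1][same[-n]]
  x0 <- tr$x[-n][same[-n]]; x1 <- tr$x[-1][same[-n]]
  for (lvl in c(137, 127)) {
    cross <- (y0 - lvl) * (y1 - lvl) < 0
    if (!any(cross)) next
    tt <- (lvl - y0[cross]) / (y1[cross] - y0[cross])
    xh <- x0[cross] + tt * (x1[cross] - x0[cross])
    xs <- if (lvl == 137) 500 else 700
    expect_true(all(xh < xs))   # crossings only rostral of the barrier span
  }
})
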