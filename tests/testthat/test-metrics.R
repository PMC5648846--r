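test_that("DV histogram puts mass where the points are", {
  tr <- fake_traj(rep(130, 50))
  h <- dv_distribution(tr, bins = seq(0, 145, by = 5))
  expect_equal(sum(h$count > 0), 1)
  expect_equal(h$count[h$y_lo == 130], 50)
  expect_equal(sum(h$density * (h$y_hi - h$y_lo)), 1)
  expect_error(dv_distribution(fake_traj(numeric(0))), "points")
  # near-uniform synthetic points fill bins evenly (multinomial bound)
  set.seed(5)
  tru <- fake_traj(runif(1e4, 0, 100))
  hu <- dv_distribution(tru, bins = seq(0, 100, by = 10))
  expect_lt(max(hu$count) / min(hu$count), 1.5)
})

test_that("tortuosity is arc length over end-to-end distance", {
  straight <- fake_traj(rep(0, 100), x = 1:100)
  expect_equal(tortuosity(straight)$tortuosity, 1)
  # right-angle L of two 100-um legs -> sqrt(2)
  lshape <- fake_traj(c(rep(0, 101), 1:100),
                      x = c(1:101, rep(101, 100)))
  expect_equal(tortuosity(lshape)$tortuosity, 200 / sqrt(2 * 100^2),
               tolerance = 1e-9)
  # closed loop reports the infinity sentinel
  loop <- fake_traj(c(0, 1, 1, 0, 0), x = c(0, 0, 1, 1, 0))
  expect_equal(tortuosity(loop)$tortuosity, Inf)
})

test_that("escape fraction counts points outside the tract", {
  tract <- list(y_inner = 127, y_outer = 137)
  tr <- fake_traj(c(rep(130, 6), 120, 120, 140, 140), x = 701:710)
  expect_equal(escape_fraction(tr, tract), 40)
  expect_equal(escape_fraction(fake_traj(rep(132, 10)), tract), 0)
  # the windowed form ignores points rostral of the tract
  tract2 <- c(tract, x_start = 700)
  tr2 <- fake_traj(c(rep(120, 5), rep(130, 5)), x = c(600:604, 800:804))
  expect_equal(escape_fraction(tr2, tract2), 0)
})

test_that("bundle statistics cluster slice crossings by gaps", {
  two <- dplyr::bind_rows(fake_traj(rep(0, 100), x = 1:100, id = 1L),
                          fake_traj(rep(10, 100), x = 1:100, id = 2L))
  b5 <- bundle_stats(two, slice_spacing = 20, gap_threshold = 5)
  expect_true(all(b5$slices$n_bundles == 2))
  expect_equal(b5$mean_bundle_count, 2)
  b20 <- bundle_stats(two, slice_spacing = 20, gap_threshold = 20)
  expect_true(all(b20$slices$n_bundles == 1))
  expect_equal(b20$mean_bundle_size, 2)
})

test_that("isolated dIN count looks only at dIN -> dIN input", {
  pop <- dplyr::bind_rows(lapply(1:10, function(i)
    toy_neurons(i, "dIN", 1000 + i, 40, 0, 5)))
  mk <- function(pre, post) structure(list(
    population = pop,
    synapses = tibble::tibble(
      pre_id = pre, post_id = post,
      pre_type = pop$type[match(pre, pop$id)],
      post_type = pop$type[match(post, pop$id)],
      axon = "primary", step = 1L, x = 1000, y = 40, arc_length = 1),
    seed = 1, prob = NULL, hash = "h"), class = "fascicle_connectome")
  expect_equal(isolated_din_count(mk(integer(), integer())), 10)
  con <- mk(c(1L, 1L, 2L), c(4L, 5L, 6L))   # dINs 4, 5, 6 are fed
  expect_equal(isolated_din_count(con), 7)
})

test_that("metrics are pure functions of their inputs", {
  tr <- grow_one_type("aIN", 5, s = 0.2, seed = 9)
  expect_identical(dv_dispersion(tr), dv_dispersion(tr))
  expect_identical(bundle_stats(tr), bundle_stats(tr))
  expect_identical(escape_fraction(tr, list(y_inner = 127, y_outer = 137)),
                   escape_fraction(tr, list(y_inner = 127, y_outer = 137)))
})
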