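make_scene <- function(name, seed = 5L, shape = c(24, 24), noiseless = TRUE) {
  pre <- scenario_presets(name)
  noise <- if (noiseless) noise_spec(0, seed = seed) else {
    pre$noise$seed <- seed; pre$noise
  }
  generate_image(pre$stack, noise, shape)
}

test_that("a constant-retarder image maps to a constant retardance grid", {
  sp <- layer_spec(10, 1.8, 40)
  sc <- generate_image(stack_spec(sp), noise_spec(0, seed = 1), c(8, 8))
  dec <- decompose_image(sc$image, "differential")
  expect_lt(diff(range(dec$differential$rt_deg)), 1e-9)
  expect_equal(dec$differential$rt_deg[1, 1], 18, tolerance = 1e-9)
})

test_that("hole pixels carry near-zero retardance and are flagged below the floor", {
  sp <- layer_spec(10, 1.8, 90, azimuth_jitter_deg = 6, retardance_cv = 0.15,
                   hole_fraction = 0.15, hole_radius_px = 3L)
  sc <- generate_image(stack_spec(sp), noise_spec(0, seed = 4), c(32, 32))
  dec <- decompose_image(sc$image, "differential")
  holes <- sc$truth$hole_mask
  expect_gt(sum(holes), 0)
  expect_lt(max(dec$differential$rt_deg[holes]), 1e-8)
  expect_true(all(dec$below_floor[holes]))
  expect_true(all(dec$mask$reason[holes] == "below-noise-floor"))
})

test_that("method both produces two property sets sharing one mask", {
  sc <- make_scene("crossed45", shape = c(16, 16))
  dec <- decompose_image(sc$image, "both")
  expect_named(dec, c("mask", "below_floor", "min_eigenvalue",
                      "noise_floor_deg", "differential", "lu_chipman"),
               ignore.order = TRUE)
  expect_true(all(is.finite(dec$differential$rt_deg[dec$mask$valid])))
  expect_true(all(is.finite(dec$lu_chipman$rt_deg[dec$mask$valid])))
})

test_that("box-whisker summaries follow the Tukey rule with type-7 quartiles", {
  s <- boxwhisker_summary(matrix(18, 4, 5))
  expect_equal(s$median, 18)
  expect_equal(s$q3 - s$q1, 0)
  expect_equal(s$n_outliers, 0)
  # hand-computed example under linear-interpolation quartiles
  s <- boxwhisker_summary(matrix(c(1, 2, 3, 4, 100), 1, 5))
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$whisker_high, 4)
  expect_equal(s$whisker_low, 1)
  expect_equal(s$n_outliers, 1)
  # empty input flagged
  s <- boxwhisker_summary(matrix(1, 2, 2), matrix(FALSE, 2, 2))
  expect_equal(s$n_valid, 0)
  expect_true(is.na(s$median))
})

test_that("summaries are invariant under permutation of the valid pixels", {
  set.seed(6)
  m <- matrix(rexp(60, 1 / 10), 6, 10)
  valid <- matrix(runif(60) > 0.2, 6, 10)
  s1 <- boxwhisker_summary(m, valid)
  vals <- m[valid]
  m2 <- m
  m2[valid] <- sample(vals)
  s2 <- boxwhisker_summary(m2, valid)
  expect_equal(s1, s2)
})

test_that("azimuth summaries respect the retardance floor", {
  theta <- matrix(90, 10, 10)
  rt <- matrix(18, 10, 10)
  s <- azimuth_summary(theta, rt)
  expect_equal(s$median, 90)
  expect_equal(s$n_valid, 100)
  # crossed equal-layer scene: compensation leaves almost nothing above the floor
  eq <- layer_spec(10, 1.8, 110, azimuth_jitter_deg = 6, retardance_cv = 0.15,
                   depol_per_um = 0.01)
  sc <- generate_image(stack_spec(list(eq, eq), 90), noise_spec(seed = 7L),
                       c(32, 32), share_layer_fields = TRUE)
  dec <- decompose_image(sc$image, "differential")
  s <- azimuth_summary(dec$differential$theta_deg, dec$differential$rt_deg,
                       dec$mask, floor_deg = 3)
  expect_lt(s$n_valid, 0.1 * sum(dec$mask$valid))
  # on a noisy hole-rich scene the floor tightens the azimuth spread
  sc <- make_scene("single", seed = 8L, shape = c(32, 32), noiseless = FALSE)
  dec <- decompose_image(sc$image, "differential")
  s0 <- azimuth_summary(dec$differential$theta_deg, dec$differential$rt_deg,
                        dec$mask, floor_deg = 0)
  s3 <- azimuth_summary(dec$differential$theta_deg, dec$differential$rt_deg,
                        dec$mask, floor_deg = 3)
  expect_lt(s3$q3 - s3$q1, s0$q3 - s0$q1)
  # circular option agrees with the linear one away from the wrap point
  sc_ <- azimuth_summary(dec$differential$theta_deg, dec$differential$rt_deg,
                         dec$mask, floor_deg = 3, circular = TRUE)
  expect_lt(ang_dist(sc_$median, s3$median), 1.5)
})

test_that("quiver export samples a sparse grid with normalized stick lengths", {
  theta <- matrix(40, 100, 100)
  rt <- matrix(12, 100, 100)
  qv <- quiver_export(theta, rt, grid_step_px = 20)
  expect_equal(nrow(qv), 25)
  expect_true(all(qv$length_norm == 1))
  expect_true(all(qv$angle_deg == 40))
  # a hole at a grid node drops that stick
  valid <- matrix(TRUE, 100, 100)
  valid[10, 10] <- FALSE
  qv <- quiver_export(theta, rt, pixel_mask(valid), grid_step_px = 20)
  expect_equal(nrow(qv), 24)
  # zero retardance everywhere: all lengths zero
  qv <- quiver_export(theta, matrix(0, 100, 100), grid_step_px = 20)
  expect_true(all(qv$length_norm == 0))
  # sticks of a parallel-stack scene cluster near the generator azimuth
  sc <- make_scene("parallel", shape = c(48, 48))
  dec <- decompose_image(sc$image, "differential")
  qv <- quiver_export(dec$differential$theta_deg, dec$differential$rt_deg,
                      dec$mask, grid_step_px = 8)
  expect_lt(median(ang_dist(qv$angle_deg, 110)), 10)
})

test_that("method comparison is zero on identical inputs and tiny on noiseless scenes", {
  sc <- make_scene("crossed45", shape = c(24, 24))
  dec <- decompose_image(sc$image, "both")
  cmp0 <- compare_methods(dec$differential, dec$differential, dec$mask)
  expect_equal(cmp0$stats$max_abs_delta_rt_deg, 0)
  cmp <- compare_methods(dec$differential, dec$lu_chipman, dec$mask)
  expect_lt(cmp$stats$max_abs_delta_rt_deg, 0.1)
  expect_lt(cmp$stats$max_abs_delta_theta_deg, 0.1)
})

test_that("the two depolarization maps are strictly co-monotone on heterogeneous scenes", {
  # spatially varying depolarization strength: the two conventions live
  # on different scales but must rank every pixel identically
  H <- 12; W <- 12
  px <- array(0, c(H, W, 4, 4))
  for (i in seq_len(H)) for (j in seq_len(W)) {
    a <- 0.55 + 0.4 * ((i - 1) * W + j - 1) / (H * W)
    px[i, j, , ] <- depolarizer_mueller(a) %*%
      retarder_mueller(10 + i, 10 * j)
  }
  dec <- decompose_image(mueller_image(px), "both")
  cmp <- compare_methods(dec$differential, dec$lu_chipman, dec$mask)
  expect_equal(cmp$stats$depol_rank_cor, 1, tolerance = 1e-12)
  # exact exponential link pixel-wise, with LC values running lower on
  # the shared [0, 1]-style ordering through 1 - exp(-x)
  expect_lt(max(abs(dec$lu_chipman$alpha_t -
                    (1 - exp(-dec$differential$alpha_t)))), 1e-9)
  expect_true(all(dec$lu_chipman$alpha_t <= dec$differential$alpha_t))
})

test_that("decomposition of the same image twice is bit-identical", {
  sc <- make_scene("single", shape = c(16, 16), noiseless = FALSE)
  d1 <- decompose_image(sc$image, "both")
  d2 <- decompose_image(sc$image, "both")
  expect_identical(d1, d2)
})

test_that("noiseless scene medians order as parallel > crossed45 > single > crossed90", {
  med <- vapply(c("single", "parallel", "crossed45", "crossed90"),
                function(nm) {
                  sc <- make_scene(nm, shape = c(32, 32))
                  dec <- decompose_image(sc$image, "differential")
                  median(dec$differential$rt_deg[dec$mask$valid])
                }, numeric(1))
  expect_true(med[["parallel"]] > med[["crossed45"]])
  expect_true(med[["crossed45"]] > med[["single"]])
  expect_true(med[["single"]] > med[["crossed90"]])
})
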