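test_that("elementary simulator matrices match closed forms", {
  expect_equal(retarder_mueller(0, 0), diag(4))
  expect_equal(retarder_mueller(180, 0), diag(c(1, 1, -1, -1)),
               tolerance = 1e-12)
  # decomposition round trip at arbitrary parameters
  for (p in list(c(12, 0), c(90, 45), c(150, 179))) {
    lc <- lu_chipman_decompose(retarder_mueller(p[1], p[2]))
    expect_equal(lc$rt_deg, p[1], tolerance = 1e-9)
    expect_lt(ang_dist(lc$theta_deg, p[2]), 1e-9)
  }
  expect_equal(depolarizer_mueller(1), diag(4))
  expect_equal(depolarizer_mueller(0), diag(c(1, 0, 0, 0)))
  expect_equal(lu_chipman_decompose(depolarizer_mueller(0.55))$alpha_t,
               0.45, tolerance = 1e-12)
  expect_error(depolarizer_mueller(1.2), "\\[0, 1\\]")
})

test_that("layer matrices commute and accumulate retardance with thickness", {
  sp <- layer_spec(10, 1.8, 90, depol_per_um = 0.01)
  M <- layer_mueller(sp)
  a <- exp(-0.1)
  expect_equal(M, depolarizer_mueller(a) %*% retarder_mueller(18, 90),
               tolerance = 1e-12)
  expect_equal(M, retarder_mueller(18, 90) %*% depolarizer_mueller(a),
               tolerance = 1e-12)
  expect_equal(differential_decompose(M)$rt_deg, 18, tolerance = 1e-9)
  # pure cases
  expect_equal(layer_mueller(layer_spec(10, 1.8, 30)),
               retarder_mueller(18, 30))
  expect_equal(layer_mueller(layer_spec(10, 0, 0, depol_per_um = 0.02)),
               depolarizer_mueller(exp(-0.2)))
  expect_error(layer_spec(101, 1.8, 0), "180")
})

test_that("stack composition follows propagation order and crossing angle", {
  l18 <- layer_spec(10, 1.8, 0)
  l9 <- layer_spec(5, 1.8, 0)
  # equal layers crossed at 90 degrees compensate exactly
  M <- stack_mueller(stack_spec(list(l18, l18), 90))
  expect_lt(max(abs(M - diag(4))), 1e-12)
  # parallel layers add
  expect_equal(differential_decompose(
    stack_mueller(stack_spec(list(l18, l9), 0)))$rt_deg, 27,
    tolerance = 1e-9)
  # unequal layers crossed at 90: residual is the difference
  expect_equal(lu_chipman_decompose(
    stack_mueller(stack_spec(list(l18, l9), 90)))$rt_deg, 9,
    tolerance = 1e-9)
})

test_that("noiseless homogeneous scenes decompose back to ground truth exactly", {
  sp <- layer_spec(10, 1.8, 90, azimuth_jitter_deg = 0, retardance_cv = 0,
                   depol_per_um = 0.01)
  sc <- generate_image(stack_spec(sp), noise_spec(0, seed = 1), c(8, 8))
  dec <- decompose_image(sc$image, "both")
  expect_true(all(dec$mask$valid))
  expect_lt(max(abs(dec$differential$rt_deg - 18)), 1e-6)
  expect_lt(max(ang_dist(dec$differential$theta_deg, 90)), 1e-6)
  expect_lt(max(abs(dec$lu_chipman$rt_deg - 18)), 1e-6)
  expect_lt(max(abs(dec$differential$alpha_t - 0.1)), 1e-9)
})

test_that("scenes are seed-deterministic and seeds differ only statistically", {
  pre <- scenario_presets("single")
  pre$noise$seed <- 9L
  a <- generate_image(pre$stack, pre$noise, c(24, 24))
  b <- generate_image(pre$stack, pre$noise, c(24, 24))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$rt_deg, b$truth$rt_deg)
  pre$noise$seed <- 10L
  c_ <- generate_image(pre$stack, pre$noise, c(24, 24))
  expect_false(identical(a$image$pixels, c_$image$pixels))
  expect_lt(abs(median(a$truth$rt_deg) - median(c_$truth$rt_deg)), 2.5)
})

test_that("noiseless simulator output is physical and passive", {
  for (nm in c("single", "crossed45")) {
    pre <- scenario_presets(nm)
    sc <- generate_image(pre$stack, noise_spec(0, seed = 2), c(12, 12))
    for (k in 1:20) {
      i <- ((k * 7) %% 12) + 1; j <- ((k * 5) %% 12) + 1
      M <- sc$image$pixels[i, j, , ]
      expect_true(is_physical(M))
      expect_lte(max(abs(M)), M[1, 1] + 1e-12)
      expect_identical(cloude_filter(M)$M, M)
    }
  }
})

test_that("presets encode the four measured arrangements", {
  s <- scenario_presets("single")
  expect_length(s$stack$layers, 1)
  expect_equal(s$stack$layers[[1]]$thickness_um, 10)
  expect_equal(s$stack$layers[[1]]$azimuth_deg, 90)
  expect_equal(s$stack$layers[[1]]$hole_fraction, 0.10)
  p <- scenario_presets("parallel")
  expect_equal(vapply(p$stack$layers, `[[`, numeric(1), "thickness_um"),
               c(10, 5))
  expect_equal(p$stack$crossing_angle_deg, 0)
  expect_equal(scenario_presets("crossed90")$stack$crossing_angle_deg, 90)
  expect_error(scenario_presets("other"))
})

test_that("stack depolarization exceeds the single layer by 2.5-3x and ignores crossing", {
  single <- differential_decompose(
    stack_mueller(scenario_presets("single")$stack))$alpha_t
  ratios <- vapply(c("parallel", "crossed45", "crossed90"), function(nm)
    differential_decompose(
      stack_mueller(scenario_presets(nm)$stack))$alpha_t / single,
    numeric(1))
  expect_true(all(ratios >= 2.5 & ratios <= 3))
  expect_lt(max(ratios) - min(ratios), 1e-9)
  lc_ratio <- lu_chipman_decompose(
    stack_mueller(scenario_presets("parallel")$stack))$alpha_t /
    lu_chipman_decompose(
      stack_mueller(scenario_presets("single")$stack))$alpha_t
  expect_true(lc_ratio >= 2.5 && lc_ratio <= 3)
})

test_that("the calibrated element noise puts the blank-pixel retardance floor at 2-3 degrees", {
  q <- calibrate_noise_floor(noise_spec()$element_sigma, n = 400, seed = 3,
                             probs = c(0.5, 0.95))
  expect_gt(q[[2]], 2)
  expect_lt(q[[2]], 3)
})
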