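test_that("an empty scene renders as uniform background in all channels", {
  sc <- simulate_scene(scene_config(seed = 1, n_cells = 0, background = 10))
  cube <- render_three_cube(sc, noise = FALSE)
  expect_true(all(cube$I_DD == 10))
  expect_true(all(cube$I_DA == 10))
  expect_true(all(cube$I_AA == 10))
})

test_that("donor-only bleed-through follows the forward model exactly", {
  sc <- small_scene(seed = 4, background = 0, bleedthrough_a = 0.2)
  cube <- render_three_cube(sc, mode = "donor_only", noise = FALSE)
  sig <- scene_density(sc) > 0
  expect_equal(cube$I_DA[sig] / cube$I_DD[sig], rep(0.2, sum(sig)),
               tolerance = 1e-12)
  expect_true(all(cube$I_AA == 0))
})

test_that("rendered values saturate at the bit-depth ceiling", {
  sc <- small_scene(seed = 4, signal_scale = 3500 * 50, bit_depth = 12)
  cube <- render_three_cube(sc, noise = FALSE)
  expect_lte(max(cube$I_DD), 4095)
  sig <- scene_density(sc) > 0
  expect_true(any(cube$I_DD[sig] == 4095))
  expect_false(any(cube$valid_mask[which(cube$I_DD == 4095)]))
})

test_that("donor quenching and sensitized emission trade off with efficiency", {
  base <- list(seed = 4, background = 0)
  lowE <- render_three_cube(do.call(small_scene,
                                    c(base, fret_efficiency = 0.2)),
                            noise = FALSE)
  highE <- render_three_cube(do.call(small_scene,
                                     c(base, fret_efficiency = 0.5)),
                             noise = FALSE)
  sig <- lowE$I_DD > 0
  expect_true(all(highE$I_DD[sig] < lowE$I_DD[sig]))
  sens_low <- lowE$I_DA - 0.2 * lowE$I_DD - 0.1 * lowE$I_AA
  sens_high <- highE$I_DA - 0.2 * highE$I_DD - 0.1 * highE$I_AA
  expect_true(all(sens_high[sig] > sens_low[sig]))
})

test_that("renders are deterministic under a fixed seed", {
  sc <- small_scene(seed = 9)
  c1 <- render_three_cube(sc, seed = 5)
  c2 <- render_three_cube(sc, seed = 5)
  expect_identical(c1$I_DA, c2$I_DA)
  st1 <- render_lambda_stack(sc, list(fluors$AF488, fluors$AF647), seed = 5)
  st2 <- render_lambda_stack(sc, list(fluors$AF488, fluors$AF647), seed = 5)
  expect_identical(st1$blocks[["488"]][[5]], st2$blocks[["488"]][[5]])
})

test_that("the default lambda layout is 24 ten-nm windows over 500-740 nm per laser", {
  w <- default_windows()
  expect_equal(nrow(w), 24)
  expect_equal(w[1, 1], 500)
  expect_equal(w[24, 2], 740)
  expect_true(all(w[, 2] - w[, 1] == 10))
  sc <- small_scene(seed = 2, n_cells = 2)
  st <- render_lambda_stack(sc, list(fluors$AF488))
  expect_equal(length(st$blocks), 3)
  expect_true(all(lengths(st$blocks) == 24))
})

test_that("a single-fluorophore noiseless stack is a scalar multiple of its fingerprint", {
  sc <- small_scene(seed = 6, n_cells = 3, background = 0)
  st <- render_lambda_stack(sc, list(fluors$AF546), noise = FALSE)
  fp <- component_fingerprint(fluors$AF546)$vector
  imgs <- unlist(st$blocks, recursive = FALSE)
  dens <- scene_density(sc)
  px <- which(dens > 0)[c(1, 50, 200)]
  for (p in px) {
    spec <- unname(vapply(imgs, function(im) im[p], numeric(1)))
    expect_equal(spec / sum(spec), fp, tolerance = 1e-9)
  }
})

test_that("a two-fluorophore stack is the sum of the single-fluorophore stacks", {
  sc <- small_scene(seed = 6, n_cells = 3, background = 0)
  both <- render_lambda_stack(sc, list(fluors$AF546, fluors$AF647),
                              pair = NULL, noise = FALSE)
  one <- render_lambda_stack(sc, list(fluors$AF546), noise = FALSE)
  two <- render_lambda_stack(sc, list(fluors$AF647), noise = FALSE)
  for (L in names(both$blocks)) {
    for (wi in c(1, 8, 17, 24)) {
      expect_equal(both$blocks[[L]][[wi]],
                   one$blocks[[L]][[wi]] + two$blocks[[L]][[wi]],
                   tolerance = 1e-10)
    }
  }
})

test_that("windows outside the modeled spectral range are rejected", {
  sc <- small_scene(seed = 2, n_cells = 2)
  expect_error(render_lambda_stack(sc, list(fluors$AF488),
                                   windows = list(c(400, 450))),
               "spectral range")
  expect_error(render_lambda_stack(sc, list(fluors$AF488), lasers = numeric(0)),
               "non-empty")
})

test_that("simulated binding series follow the Hill law with truncated noise", {
  cfg <- emsa_sim_config(kd = 50, hill_n = 2, eps = 1,
                         concentrations = c(10, 25, 50, 100, 200),
                         noise_sd = 0)
  s <- simulate_emsa(cfg)
  expect_equal(s$theta[s$concentration == 50], 0.5)
  cfg2 <- emsa_sim_config(kd = 5, hill_n = 1, eps = 0.9,
                          concentrations = c(1, 5, 500), noise_sd = 0)
  s2 <- simulate_emsa(cfg2)
  expect_lt(abs(s2$theta[3] - 0.9) / 0.9, 0.01)
  # noise calibration: replicate draws at theta ~ 0.5 (no truncation)
  reps <- vapply(1:1000, function(i) {
    simulate_emsa(emsa_sim_config(kd = 50, hill_n = 1, eps = 1,
                                  concentrations = c(10, 50, 100),
                                  noise_sd = 0.02, seed = i))$theta[2]
  }, numeric(1))
  expect_lt(abs(sd(reps) - 0.02) / 0.02, 0.10)
  expect_true(all(simulate_emsa(emsa_sim_config(
    kd = 1, hill_n = 1, eps = 1,
    concentrations = c(100, 200, 400), noise_sd = 0.5, seed = 2))$theta <= 1))
})

test_that("invalid binding configurations are rejected", {
  expect_error(emsa_sim_config(kd = -1), "kd")
  expect_error(emsa_sim_config(kd = 1, concentrations = c(5, 2)), "increasing")
  expect_error(emsa_sim_config(kd = 1, eps = 1.5), "eps")
})

test_that("spot images are deterministic and honor the request table", {
  sc <- small_scene(seed = 5, n_cells = 4, shape = c(128, 128))
  req <- stats::setNames(c(3L, 0L, 5L, 2L), sc$cells$cell_id)
  i1 <- simulate_spots(sc, req, seed = 77)
  i2 <- simulate_spots(sc, req, seed = 77)
  expect_identical(unclass(i1), unclass(i2))
  tbl <- attr(i1, "requested")
  expect_true(all(tbl$placed <= tbl$n_spots))
  expect_equal(tbl$placed[tbl$n_spots == 0], 0L)
  # all zero -> background only
  blank <- simulate_spots(sc, stats::setNames(rep(0L, 4), sc$cells$cell_id),
                          noise = FALSE)
  expect_true(all(blank == sc$config$background))
  expect_error(simulate_spots(sc, c("99" = 3L)), "unknown cell")
})
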