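test_that("fingerprint extraction normalizes and handles degenerate spectra", {
  # one-hot: component emitting in exactly one channel
  W <- list(matrix(c(0, 100, 100, 0), 2, 2))
  vecs <- matrix(c(0, 1, 0), ncol = 1)
  st <- build_stack(W, vecs)
  fp <- extract_fingerprint(st, W[[1]] > 0, background = 0)
  expect_equal(fp$vector, c(0, 1, 0))

  # flat spectrum across C channels -> every entry 1/C
  vecs_flat <- matrix(rep(1, 4), ncol = 1)
  st2 <- build_stack(W, vecs_flat)
  fp2 <- extract_fingerprint(st2, W[[1]] > 0, background = 0)
  expect_equal(fp2$vector, rep(0.25, 4))

  expect_error(extract_fingerprint(st, matrix(FALSE, 2, 2)), "no valid")
  zero <- build_stack(list(matrix(0, 2, 2)), vecs)
  expect_error(extract_fingerprint(zero, matrix(TRUE, 2, 2), background = 0),
               "zero")
})

test_that("noisy fingerprints recover the true spectrum to high cosine similarity", {
  set.seed(8)
  truth <- c(0.05, 0.1, 0.3, 0.35, 0.15, 0.05)
  W <- list(matrix(runif(32 * 32, 150, 400), 32, 32))
  # SNR ~ 20 at typical signal: sd = signal/20
  st <- build_stack(W, matrix(truth, ncol = 1), noise_sd = 275 * 0.25 / 20,
                    seed = 8)
  fp <- extract_fingerprint(st, matrix(TRUE, 32, 32), background = 0)
  cosine <- sum(fp$vector * truth) / sqrt(sum(fp$vector^2) * sum(truth^2))
  expect_gte(cosine, 0.999)
})

test_that("two-component unmixing solves the exact system and zero pixels stay zero", {
  F <- cbind(c(1, 0), c(0.5, 0.5))
  W <- list(matrix(c(0.5, 0, 1, 0), 2, 2), matrix(c(0.5, 0, 0, 2), 2, 2))
  st <- build_stack(W, F, windows = list(c(500, 510), c(520, 530)))
  fps <- list(new_fp <- structure(list(name = "f1", vector = F[, 1] / sum(F[, 1])),
                                  class = "fingerprint"),
              structure(list(name = "f2", vector = F[, 2] / sum(F[, 2])),
                        class = "fingerprint"))
  res <- unmix_stack(st, fps)
  # pixel (1,1): s = (0.75, 0.25) -> weights (0.5, 0.5) in unit-column units
  expect_equal(res$abundance[["f1"]][1, 1], 0.5, tolerance = 1e-10)
  expect_equal(res$abundance[["f2"]][1, 1], 0.5, tolerance = 1e-10)
  # zero pixel
  expect_equal(res$abundance[["f1"]][2, 1], 0)
  expect_equal(res$abundance[["f2"]][2, 1], 0)
  expect_equal(res$residual[2, 1], 0)
  expect_true(all(unlist(res$abundance) >= 0))
})

test_that("NNLS solutions beat a dense nonnegative grid oracle", {
  set.seed(42)
  f1 <- c(1, 0.2, 0); f1 <- f1 / sum(f1)
  f2 <- c(0.1, 0.5, 0.4)
  fps <- list(structure(list(name = "f1", vector = f1), class = "fingerprint"),
              structure(list(name = "f2", vector = f2), class = "fingerprint"))
  F <- cbind(f1, f2)
  # pixels engineered to force active constraints (negative unconstrained LS)
  pixels <- list(c(1, 0, 0), c(0, 0, 1), c(0.2, 0.9, 0.1), c(0.5, 0.5, 0.5),
                 c(1, 0.01, 0.9))
  for (s in pixels) {
    W <- list(matrix(0, 1, 2), matrix(0, 1, 2))
    st <- lambda_stack(list("488" = list(matrix(s[1], 2, 2), matrix(s[2], 2, 2),
                                         matrix(s[3], 2, 2))),
                       list(c(500, 510), c(520, 530), c(540, 550)),
                       bit_depth = 16)
    res <- unmix_stack(st, fps)
    w <- c(res$abundance[["f1"]][1, 1], res$abundance[["f2"]][1, 1])
    sse <- sum((F %*% w - s)^2)
    oracle <- grid_nnls_sse(F, s, wmax = 2.5, n_grid = 201)
    expect_lte(sse, oracle + 1e-9)
  }
})

test_that("collinear fingerprints are rejected with the offending pair named", {
  f <- c(0.2, 0.5, 0.3)
  fps <- list(structure(list(name = "compA", vector = f), class = "fingerprint"),
              structure(list(name = "compB", vector = f), class = "fingerprint"))
  st <- lambda_stack(list("488" = list(matrix(1, 2, 2), matrix(1, 2, 2),
                                       matrix(1, 2, 2))),
                     list(c(500, 510), c(520, 530), c(540, 550)))
  expect_error(unmix_stack(st, fps), "compA.*compB|collinear")
})

test_that("noiseless renders unmix to abundances exactly proportional to truth", {
  sc <- simulate_scene(scene_config(seed = 11, n_cells = 6,
                                    image_shape = c(96, 96), background = 0))
  st <- render_lambda_stack(sc, list(fluors$AF488, fluors$AF647), noise = FALSE)
  fps <- standard_fingerprints(st)
  res <- unmix_stack(st, fps)
  dens <- scene_density(sc)
  sig <- dens > 0
  for (nm in names(res$abundance)) {
    ratio <- res$abundance[[nm]][sig] / dens[sig]
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
  }
})

test_that("constructed noiseless stacks unmix to exact ground truth", {
  set.seed(5)
  f1 <- c(0.5, 0.3, 0.15, 0.05)
  f2 <- c(0.05, 0.15, 0.3, 0.5)
  W <- list(matrix(runif(64, 0, 300), 8, 8), matrix(runif(64, 0, 300), 8, 8))
  st <- build_stack(W, cbind(f1, f2))
  fps <- list(structure(list(name = "c1", vector = f1), class = "fingerprint"),
              structure(list(name = "c2", vector = f2), class = "fingerprint"))
  res <- unmix_stack(st, fps)
  expect_equal(res$abundance[["c1"]], W[[1]], tolerance = 1e-9)
  expect_equal(res$abundance[["c2"]], W[[2]], tolerance = 1e-9)
  expect_lt(max(res$residual), 1e-8)
})

test_that("abundance recovery at SNR 20 has relative RMSE below 5 percent", {
  set.seed(6)
  f1 <- c(0.6, 0.3, 0.1)
  f2 <- c(0.05, 0.25, 0.7)
  W <- list(matrix(runif(1024, 200, 600), 32, 32),
            matrix(runif(1024, 200, 600), 32, 32))
  # SNR 20 per component: channel noise sized so each component's summed
  # signal (mean 400) carries 1/20 relative noise; the check is that
  # unmixing does not inflate that input noise
  noise_sd <- 400 / 20 / sqrt(3)
  st <- build_stack(W, cbind(f1, f2), noise_sd = noise_sd, seed = 6)
  fps <- list(structure(list(name = "c1", vector = f1), class = "fingerprint"),
              structure(list(name = "c2", vector = f2), class = "fingerprint"))
  res <- unmix_stack(st, fps)
  for (i in 1:2) {
    err <- res$abundance[[paste0("c", i)]] - W[[i]]
    rel_rmse <- sqrt(mean(err^2)) / mean(W[[i]])
    expect_lt(rel_rmse, 0.05)
  }
})

test_that("acceptor-only stacks yield a corrected FRET component consistent with zero", {
  sc1 <- spectral_scene(31)
  sc2 <- spectral_scene(32)
  st1 <- preprocess_stack(render_lambda_stack(sc1, list(fluors$AF647)))
  st2 <- preprocess_stack(render_lambda_stack(sc2, list(fluors$AF647)))
  fps <- standard_fingerprints(st1)
  r1 <- unmix_stack(st1, fps)
  b <- estimate_unmix_bleedthrough(r1, "FRET(AF647)", "AF647")
  r2 <- unmix_stack(st2, fps)
  corrected <- correct_unmixed_fret(r2$abundance[["FRET(AF647)"]],
                                    r2$abundance[["AF647"]], b$b,
                                    valid_mask = r2$valid_mask)
  sig <- scene_density(sc2) > 0 & r2$valid_mask
  m <- mean(corrected[sig])
  se <- sqrt(var(corrected[sig]) / sum(sig) +
               (mean(r2$abundance[["AF647"]][sig]) * b$slope_se)^2)
  expect_lt(abs(m), 2 * se)
})

test_that("the manual correction is exact arithmetic", {
  fr <- matrix(60, 3, 3); ac <- matrix(200, 3, 3)
  expect_true(all(correct_unmixed_fret(fr, ac, 0.1) == 40))
  expect_identical(correct_unmixed_fret(fr, ac, 0), fr)
  expect_error(correct_unmixed_fret(fr, matrix(1, 2, 2), 0.1), "shape")
})

test_that("bleed-through stability is flagged correctly across intensity series", {
  f_acc <- c(0, 0, 0.4, 0.6)       # acceptor: own-laser block only
  f_fret <- c(0.4, 0.6, 0, 0)      # acceptor shape under donor laser
  fps <- list(structure(list(name = "acc", vector = f_acc), class = "fingerprint"),
              structure(list(name = "fret", vector = f_fret), class = "fingerprint"))
  two_lasers <- list(c(500, 510), c(520, 530))
  make_ctl <- function(level, b) {
    W_acc <- matrix(rep(c(0, 0, level, 2 * level), each = 64), 16, 16)
    W_fret <- b * W_acc
    build_stack(list(W_acc, W_fret), cbind(f_acc, f_fret),
                windows = two_lasers, lasers = c("488", "639"),
                noise_sd = level / 50, seed = level)
  }
  stable_series <- lapply(c(100, 300, 1000, 3000), make_ctl, b = 0.05)
  out <- assess_bleedthrough_stability(stable_series, fps, "fret", "acc")
  expect_true(out$stable)
  expect_lt(abs(out$mean_ratio - 0.05) / 0.05, 0.02)

  # ratio doubling across the range must be flagged
  drifting <- lapply(seq_along(c(100, 300, 1000, 3000)), function(i)
    make_ctl(c(100, 300, 1000, 3000)[i], b = 0.05 * c(1, 1.3, 1.7, 2)[i]))
  expect_false(assess_bleedthrough_stability(drifting, fps,
                                             "fret", "acc")$stable)
  expect_error(assess_bleedthrough_stability(stable_series[1:2], fps,
                                             "fret", "acc"), ">= 3")
})

test_that("spectral and three-cube pipelines rank cells identically", {
  # same geometry and abundances, each route at its own photon budget
  sc <- simulate_scene(scene_config(seed = 61, n_cells = 8,
                                    image_shape = c(128, 128)))
  sc_spec <- spectral_scene(61)
  # three-cube route
  cube <- render_three_cube(sc)
  ctl <- control_pair()
  pp <- cfret_pipeline(cube, ctl$donor, ctl$acceptor)
  tab_cube <- per_cell_fret(pp$cfret, sc$label_map)
  # spectral route
  st <- preprocess_stack(render_lambda_stack(sc_spec, list(fluors$AF488,
                                                           fluors$AF647)))
  fps <- standard_fingerprints(st)
  res <- unmix_stack(st, fps)
  b <- 0.03 / 1.08  # generative direct-excitation ratio of AF647
  corrected <- correct_unmixed_fret(res$abundance[["FRET(AF647)"]],
                                    res$abundance[["AF647"]], b,
                                    valid_mask = res$valid_mask)
  tab_spec <- per_cell_fret(corrected, sc$label_map,
                            excluded = !res$valid_mask)
  rho <- cor(tab_cube$fret_sum, tab_spec$fret_sum, method = "spearman")
  expect_gt(rho, 0.95)
})
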