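# shared fixtures: small scenes, toy cubes and constructed lambda stacks

fluors <- default_fluorophores()

# a small standard scene for render-based tests
small_scene <- function(seed = 1, n_cells = 6, shape = c(96, 96), ...) {
  simulate_scene(scene_config(seed = seed, n_cells = n_cells,
                              image_shape = shape, ...))
}

# three_cube built from constant-valued channels
toy_cube <- function(dd, da, aa, n = 20, bit_depth = 12) {
  three_cube(matrix(dd, n, n), matrix(da, n, n), matrix(aa, n, n),
             bit_depth = bit_depth)
}

# lambda stack assembled directly from abundance maps and spectral vectors:
# expectation per channel ch = sum_k W[[k]] * vecs[ch, k]  (+ noise_sd gauss)
build_stack <- function(W, vecs, windows = NULL, lasers = "488",
                        noise_sd = 0, seed = 1) {
  k <- length(W)
  nch <- nrow(vecs)
  nw <- nch / length(lasers)
  if (is.null(windows)) {
    starts <- seq(500, by = 10, length.out = nw)
    windows <- cbind(starts, starts + 10)
  }
  dims <- dim(W[[1]])
  set.seed(seed)
  blocks <- stats::setNames(vector("list", length(lasers)), lasers)
  for (li in seq_along(lasers)) {
    blocks[[li]] <- lapply(seq_len(nw), function(wi) {
      ch <- (li - 1L) * nw + wi
      mu <- Reduce(`+`, lapply(seq_len(k), function(j) W[[j]] * vecs[ch, j]),
                   matrix(0, dims[1], dims[2]))
      if (noise_sd > 0) mu <- mu + matrix(rnorm(prod(dims), 0, noise_sd),
                                          dims[1], dims[2])
      pmax(mu, 0)
    })
  }
  lambda_stack(blocks, windows, bit_depth = 16)
}

# dense nonnegative grid search oracle for 2-component least squares
grid_nnls_sse <- function(F, s, wmax, n_grid = 201) {
  g <- seq(0, wmax, length.out = n_grid)
  best <- Inf
  for (w1 in g) {
    r1 <- s - w1 * F[, 1]
    sse <- colSums((outer(r1, rep(1, n_grid)) -
                      outer(F[, 2], g))^2)
    best <- min(best, min(sse))
  }
  best
}

# spectral acquisitions integrate long enough that each 10-nm window
# collects counts comparable to a wide-band sensitized-emission channel;
# this keeps the unmixed FRET component well above the nonnegativity
# floor so its statistics are unbiased
spectral_scene <- function(seed, n_cells = 8, shape = c(128, 128), ...) {
  simulate_scene(scene_config(seed = seed, n_cells = n_cells,
                              image_shape = shape, signal_scale = 56000, ...))
}

# abundance-ladder study conditions: four expression levels spaced ~2.2x
# (the span of a differentiation time course), 12 cells per level so the
# level means are resolvable against the lognormal cell-to-cell spread
ladder_meanlogs <- c(3.0, 3.8, 4.6, 5.4)

ladder_scene <- function(seed, meanlog) {
  simulate_scene(scene_config(seed = seed, n_cells = 12,
                              image_shape = c(160, 160),
                              abundance_meanlog = meanlog,
                              signal_scale = 2000))
}

# standard control pair for cFRET pipelines (bright, many pixels, so the
# constants carry negligible uncertainty into the null statistics)
control_pair <- function() {
  dc <- render_three_cube(simulate_scene(scene_config(
    seed = 201, n_cells = 14, image_shape = c(192, 192))), mode = "donor_only")
  ac <- render_three_cube(simulate_scene(scene_config(
    seed = 202, n_cells = 14, image_shape = c(192, 192))), mode = "acceptor_only")
  list(donor = dc, acceptor = ac)
}

# standard fingerprint set for the AF488/AF647 FRET pair, extracted from
# noiseless single-label control renders
standard_fingerprints <- function(stack_for_layout) {
  scA <- simulate_scene(scene_config(seed = 12, n_cells = 6,
                                     image_shape = c(96, 96), background = 0))
  stA <- render_lambda_stack(scA, list(fluors$AF647), noise = FALSE)
  fpA <- extract_fingerprint(stA, scene_density(scA) > 0,
                             lasers = c(561, 639), name = "AF647")
  scD <- simulate_scene(scene_config(seed = 13, n_cells = 6,
                                     image_shape = c(96, 96), background = 0))
  stD <- render_lambda_stack(scD, list(fluors$AF488), noise = FALSE)
  fpD <- extract_fingerprint(stD, scene_density(scD) > 0, name = "AF488")
  fpF <- fret_fingerprint(fpA, stack_for_layout, source_laser = 639,
                          excitation = fluors$AF488)
  list(donor = fpD, acceptor = fpA, fret = fpF)
}
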