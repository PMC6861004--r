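#' Configuration for a synthetic imaging scene
#'
#' Defines the ground-truth geometry, per-cell mRNA abundance distribution,
#' FRET and bleed-through parameters and the detector model used by the
#' renderers.  Cells are ellipses with elliptical nuclei; per-cell mRNA
#' abundance is log-normal and split between nucleus and cytoplasm by a
#' per-cell retention fraction.
#'
#' @param image_shape `c(ny, nx)` in pixels.
#' @param n_cells number of non-overlapping cells to place.
#' @param cell_axes `c(major, minor)` semi-axes of the cell ellipse, pixels.
#' @param nucleus_scale nucleus semi-axes as a fraction of the cell's.
#' @param abundance_meanlog,abundance_sdlog log-normal parameters of the
#'   per-cell mRNA abundance (arbitrary units).
#' @param nuclear_retention fraction of each cell's transcripts retained in
#'   the nucleus; scalar or one value per cell.
#' @param fret_efficiency effective FRET efficiency E in \[0, 1\] of
#'   probe-bound donor.
#' @param bleedthrough_a donor emission detected in the raw-FRET channel,
#'   as a fraction of the donor-channel signal.
#' @param bleedthrough_b directly excited acceptor emission in the raw-FRET
#'   channel, as a fraction of the acceptor-channel signal.
#' @param background additive background level, counts.
#' @param signal_scale expected counts contributed by one abundance unit
#'   spread over one pixel (sets the photon budget, hence the SNR).
#' @param sens_gain relative detection efficiency of sensitized emission.
#' @param gain detector gain, counts per photon.
#' @param read_noise_sd Gaussian read noise, counts.
#' @param bit_depth one of 8, 12, 16; values clip at `2^bit_depth - 1`.
#' @param seed integer seed making every derived render reproducible.
#' @return a `scene_config` object.
#' @export
scene_config <- function(image_shape = c(128, 128),
                         n_cells = 8,
                         cell_axes = c(14, 10),
                         nucleus_scale = 0.45,
                         abundance_meanlog = 4,
                         abundance_sdlog = 0.5,
                         nuclear_retention = 0.25,
                         fret_efficiency = 0.35,
                         bleedthrough_a = 0.2,
                         bleedthrough_b = 0.1,
                         background = 20,
                         signal_scale = 3500,
                         sens_gain = 1,
                         gain = 1,
                         read_noise_sd = 2,
                         bit_depth = 12,
                         seed = 1) {
  if (length(image_shape) != 2L || any(image_shape < 8))
    stopf("`image_shape` must be c(ny, nx), each >= 8")
  if (n_cells < 0) stopf("`n_cells` must be >= 0")
  assert_fraction(nucleus_scale, "nucleus_scale")
  assert_fraction(nuclear_retention, "nuclear_retention")
  assert_fraction(fret_efficiency, "fret_efficiency")
  if (bleedthrough_a < 0 || bleedthrough_b < 0)
    stopf("bleed-through fractions must be >= 0")
  if (!bit_depth %in% c(8, 12, 16))
    stopf("`bit_depth` must be one of 8, 12, 16")
  if (gain <= 0 || signal_scale < 0 || read_noise_sd < 0 || background < 0)
    stopf("detector parameters must be nonnegative (gain > 0)")
  structure(
    list(image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
         cell_axes = cell_axes, nucleus_scale = nucleus_scale,
         abundance_meanlog = abundance_meanlog,
         abundance_sdlog = abundance_sdlog,
         nuclear_retention = nuclear_retention,
         fret_efficiency = fret_efficiency,
         bleedthrough_a = bleedthrough_a, bleedthrough_b = bleedthrough_b,
         background = background, signal_scale = signal_scale,
         sens_gain = sens_gain, gain = gain, read_noise_sd = read_noise_sd,
         bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
    class = "scene_config")
}

#' Generate a ground-truth scene
#'
#' Places `n_cells` non-overlapping elliptical cells with elliptical
#' nuclei, draws a log-normal abundance per cell, and returns the label
#' map, nuclear mask and per-cell table that serve as the oracle for every
#' downstream recovery test.  Deterministic for a fixed `config$seed`.
#'
#' @param config a [scene_config()].
#' @return a `ground_truth_scene`: `label_map` (integer matrix, 0 =
#'   background), `nuclear_mask` (logical matrix), `cells` (data.frame with
#'   cell_id, centroid, area, abundance, nuclear_retention) and the config.
#' @export
simulate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  ny <- config$image_shape[1]; nx <- config$image_shape[2]
  a <- config$cell_axes[1]; b <- config$cell_axes[2]
  n <- config$n_cells
  with_seed(config$seed, {
    label_map <- matrix(0L, ny, nx)
    nuclear_mask <- matrix(FALSE, ny, nx)
    centers <- matrix(NA_real_, n, 2)
    angles <- numeric(n)
    margin <- a + 1
    if (n > 0 && (ny <= 2 * margin || nx <= 2 * margin))
      stopf("cell placement failed: image too small for cells of semi-major axis %g", a)
    max_tries <- 300L * max(n, 1L)
    placed <- 0L; tries <- 0L
    while (placed < n && tries <= max_tries) {
      tries <- tries + 1L
      cy <- stats::runif(1, margin, ny - margin)
      cx <- stats::runif(1, margin, nx - margin)
      # bounding-circle separation keeps ellipses disjoint for any rotation
      if (placed > 0) {
        d2 <- (centers[seq_len(placed), 1] - cy)^2 +
              (centers[seq_len(placed), 2] - cx)^2
        if (any(d2 < (2 * a + 2)^2)) next
      }
      placed <- placed + 1L
      centers[placed, ] <- c(cy, cx)
      angles[placed] <- stats::runif(1, 0, pi)
    }
    if (placed < n) {
      # dense layouts: fall back to a jittered grid of feasible centers
      spacing <- 2 * a + 5
      gy <- seq(margin, ny - margin, by = spacing)
      gx <- seq(margin, nx - margin, by = spacing)
      grid <- as.matrix(expand.grid(gy, gx))
      if (nrow(grid) < n)
        stopf("cell placement failed: could not fit %d non-overlapping cells in a %dx%d image",
              n, ny, nx)
      pick <- grid[sample.int(nrow(grid), n), , drop = FALSE]
      centers[seq_len(n), ] <- pick + matrix(stats::runif(2 * n, -1.5, 1.5), n, 2)
      angles <- stats::runif(n, 0, pi)
    }
    for (i in seq_len(n)) {
      cell_px <- ellipse_pixels(ny, nx, centers[i, ], c(a, b), angles[i])
      nuc_px <- ellipse_pixels(ny, nx, centers[i, ],
                               c(a, b) * config$nucleus_scale, angles[i])
      label_map[cell_px] <- i
      nuclear_mask[nuc_px] <- TRUE
    }
    abundance <- stats::rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
    retention <- rep_len(config$nuclear_retention, max(n, 1L))[seq_len(n)]
    cells <- data.frame(
      cell_id = seq_len(n),
      centroid_y = centers[seq_len(n), 1],
      centroid_x = centers[seq_len(n), 2],
      area = as.integer(tabulate(label_map[label_map > 0], nbins = n)),
      abundance = abundance,
      nuclear_retention = retention)
    structure(
      list(label_map = label_map, nuclear_mask = nuclear_mask,
           cells = cells, config = config, seed = config$seed),
      class = "ground_truth_scene")
  })
}

# linear indices of pixels inside a rotated ellipse
ellipse_pixels <- function(ny, nx, center, axes, angle) {
  yy <- matrix(seq_len(ny), ny, nx) - center[1]
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - center[2]
  u <- xx * cos(angle) + yy * sin(angle)
  v <- -xx * sin(angle) + yy * cos(angle)
  which((u / axes[1])^2 + (v / axes[2])^2 <= 1)
}

#' Per-pixel expected fluorophore density of a scene
#'
#' Spreads each cell's abundance over its compartments: the nuclear share
#' (`nuclear_retention`) uniformly over nuclear pixels, the remainder over
#' cytoplasmic pixels.  This density, times `signal_scale`, is the
#' noiseless signal the renderers start from.
#'
#' @param scene a [simulate_scene()] result.
#' @return matrix of abundance density per pixel (abundance units / pixel).
#' @export
scene_density <- function(scene) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  dens <- matrix(0, nrow(scene$label_map), ncol(scene$label_map))
  for (i in seq_len(nrow(scene$cells))) {
    in_cell <- scene$label_map == i
    nuc <- in_cell & scene$nuclear_mask
    cyt <- in_cell & !scene$nuclear_mask
    ab <- scene$cells$abundance[i]
    ret <- scene$cells$nuclear_retention[i]
    if (any(nuc)) dens[nuc] <- ab * ret / sum(nuc)
    if (any(cyt)) dens[cyt] <- ab * (1 - ret) / sum(cyt)
  }
  dens
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat(sprintf("ground-truth scene: %d x %d px, %d cells, seed %d\n",
              nrow(x$label_map), ncol(x$label_map), nrow(x$cells), x$seed))
  invisible(x)
}
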