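#' Simulate a diffraction-limited smFISH-like spot image
#'
#' Places the requested number of spots per cell at uniformly drawn
#' in-cell pixel locations and renders each as an isotropic Gaussian of
#' width `psf_sigma`.  A minimum center-to-center separation can be
#' enforced by rejection sampling; spots that cannot be placed within the
#' try budget are dropped and reported in the returned spot table, so the
#' realized count per cell is always available as ground truth.
#'
#' @param scene a [simulate_scene()] result.
#' @param spots_per_cell named integer vector (names = cell ids) or
#'   data.frame with columns `cell_id` and `n_spots`.
#' @param psf_sigma Gaussian PSF width in pixels (> 0).
#' @param amplitude peak counts added by one spot.
#' @param min_separation minimum distance between spot centers, pixels
#'   (`0` disables the constraint).
#' @param noise apply the scene's detector noise model.
#' @param seed RNG seed (default: independent of the scene geometry draw).
#' @return image matrix with attributes `spots` (data.frame cell_id, y, x)
#'   and `requested` (the input table, with a `placed` count per cell).
#' @export
simulate_spots <- function(scene, spots_per_cell, psf_sigma = 1.5,
                           amplitude = 800, min_separation = 0,
                           noise = TRUE, seed = scene$seed + 3L) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  if (psf_sigma <= 0) stopf("`psf_sigma` must be > 0")
  tbl <- normalize_spot_table(spots_per_cell)
  known <- scene$cells$cell_id
  if (length(setdiff(tbl$cell_id, known)) > 0)
    stopf("`spots_per_cell` references unknown cell id(s): %s",
          paste(setdiff(tbl$cell_id, known), collapse = ", "))
  cfg <- scene$config
  ny <- nrow(scene$label_map); nx <- ncol(scene$label_map)
  img <- matrix(0, ny, nx)
  spots <- list()
  with_seed(seed, {
    for (r in seq_len(nrow(tbl))) {
      cid <- tbl$cell_id[r]
      px <- which(scene$label_map == cid)
      if (length(px) == 0L || tbl$n_spots[r] == 0L) { tbl$placed[r] <- 0L; next }
      coords <- arrayInd(px, c(ny, nx))
      placed <- matrix(numeric(0), 0, 2)
      tries <- 0L
      while (nrow(placed) < tbl$n_spots[r] && tries < 200L * tbl$n_spots[r]) {
        tries <- tries + 1L
        cand <- coords[sample.int(nrow(coords), 1L), ] +
          stats::runif(2, -0.5, 0.5)
        if (min_separation > 0 && nrow(placed) > 0) {
          d2 <- (placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2
          if (any(d2 < min_separation^2)) next
        }
        placed <- rbind(placed, cand)
      }
      tbl$placed[r] <- nrow(placed)
      if (nrow(placed) > 0)
        spots[[length(spots) + 1L]] <-
          data.frame(cell_id = cid, y = placed[, 1], x = placed[, 2])
    }
    spot_tbl <- if (length(spots)) do.call(rbind, spots) else
      data.frame(cell_id = integer(0), y = numeric(0), x = numeric(0))
    for (s in seq_len(nrow(spot_tbl)))
      img <- img + gaussian_spot(ny, nx, spot_tbl$y[s], spot_tbl$x[s],
                                 psf_sigma, amplitude)
    out <- apply_detector_noise(img + cfg$background, cfg, noise)
    attr(out, "spots") <- spot_tbl
    attr(out, "requested") <- tbl
    out
  })
}

normalize_spot_table <- function(spots_per_cell) {
  if (is.data.frame(spots_per_cell)) {
    if (!all(c("cell_id", "n_spots") %in% names(spots_per_cell)))
      stopf("`spots_per_cell` data.frame needs columns cell_id, n_spots")
    tbl <- spots_per_cell[, c("cell_id", "n_spots")]
  } else {
    if (is.null(names(spots_per_cell)))
      stopf("`spots_per_cell` vector must be named by cell id")
    tbl <- data.frame(cell_id = as.integer(names(spots_per_cell)),
                      n_spots = as.integer(spots_per_cell))
  }
  if (any(tbl$n_spots < 0)) stopf("spot counts must be >= 0")
  tbl$placed <- NA_integer_
  tbl
}

# additive Gaussian kernel, evaluated on a local window for speed
gaussian_spot <- function(ny, nx, y0, x0, sigma, amplitude) {
  img <- matrix(0, ny, nx)
  r <- ceiling(4 * sigma)
  ys <- max(1, floor(y0 - r)):min(ny, ceiling(y0 + r))
  xs <- max(1, floor(x0 - r)):min(nx, ceiling(x0 + r))
  gy <- exp(-(ys - y0)^2 / (2 * sigma^2))
  gx <- exp(-(xs - x0)^2 / (2 * sigma^2))
  img[ys, xs] <- amplitude * outer(gy, gx)
  img
}
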