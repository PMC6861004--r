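#' Label cells in a mask or intensity image
#'
#' `mode = "provided"`: connected-component labeling (8-connectivity) of a
#' boolean mask.  `mode = "threshold"`: Otsu threshold of an intensity
#' image, then components, then a minimum-area filter.  An empty mask
#' yields zero cells with a warning, not an error.
#'
#' @param x logical mask or numeric intensity image (matrix).
#' @param mode `"provided"` or `"threshold"`.
#' @param min_area components smaller than this (pixels) are dropped in
#'   threshold mode.
#' @return integer label map (0 = background), labels consecutive from 1.
#' @export
label_cells <- function(x, mode = c("provided", "threshold"), min_area = 200) {
  mode <- match.arg(mode)
  if (mode == "provided") {
    mask <- x > 0
  } else {
    assert_image(x)
    thr <- otsu_threshold(as.numeric(x))
    mask <- x > thr
  }
  if (!any(mask)) {
    warnf("empty mask: no cells labeled")
    return(matrix(0L, nrow(mask), ncol(mask)))
  }
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (mode == "threshold" && min_area > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area)
    relab <- integer(length(sizes))
    relab[keep] <- seq_along(keep)
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  lab
}

#' Per-cell FRET quantification
#'
#' For each labeled cell, sums the cFRET signal over valid in-cell pixels
#' (`fret_sum`, the "FRET/cell" readout), normalizes by the valid-pixel
#' count (`cfret_per_area`), and by the population maximum
#' (`normalized_fret`).  The per-cell mean is also emitted.  Excluded
#' pixels are omitted from both numerator and denominator; a fully
#' excluded cell is flagged and its metrics are `NA`.
#'
#' @param cfret a [compute_cfret()] result, or a plain image matrix.
#' @param labels integer label map aligned with the image.
#' @param excluded optional logical matrix of excluded pixels (taken from
#'   `cfret` when it is a `cfret_image`).
#' @return data.frame, one row per cell: cell_id, area, valid_area,
#'   excluded_fraction, fret_sum, fret_mean, cfret_per_area,
#'   normalized_fret, fully_excluded.
#' @export
per_cell_fret <- function(cfret, labels, excluded = NULL) {
  if (inherits(cfret, "cfret_image")) {
    img <- cfret$image
    if (is.null(excluded)) excluded <- cfret$excluded
  } else img <- cfret
  assert_image(img)
  if (is.null(excluded)) excluded <- matrix(FALSE, nrow(img), ncol(img))
  assert_same_shape(img, labels, excluded)
  ids <- sort(unique(labels[labels > 0]))
  rows <- lapply(ids, function(id) {
    in_cell <- labels == id
    ok <- in_cell & !excluded
    nv <- sum(ok)
    s <- if (nv > 0) sum(img[ok]) else NA_real_
    data.frame(cell_id = id, area = sum(in_cell), valid_area = nv,
               excluded_fraction = 1 - nv / sum(in_cell),
               fret_sum = s,
               fret_mean = if (nv > 0) s / nv else NA_real_,
               cfret_per_area = if (nv > 0) s / nv else NA_real_,
               fully_excluded = nv == 0)
  })
  out <- do.call(rbind, rows)
  mx <- suppressWarnings(max(out$fret_sum, na.rm = TRUE))
  out$normalized_fret <- if (is.finite(mx) && mx != 0) out$fret_sum / mx else NA_real_
  out
}

#' Nuclear-to-cytoplasmic intensity ratio
#'
#' Mean intensity over the nucleus divided by the mean over the cytoplasm
#' (cell minus nucleus), valid pixels only.  Detects nuclear retention of
#' a transcript: a uniform field gives exactly 1.
#'
#' @param intensity_image matrix of (background-subtracted) intensities.
#' @param nuclear_mask,cell_mask logical matrices, nucleus within cell.
#' @param valid_mask optional logical matrix of usable pixels.
#' @return the dimensionless ratio.
#' @export
nc_ratio <- function(intensity_image, nuclear_mask, cell_mask,
                     valid_mask = NULL) {
  assert_image(intensity_image)
  assert_same_shape(intensity_image, nuclear_mask, cell_mask)
  if (any(nuclear_mask & !cell_mask))
    stopf("`nuclear_mask` must lie within `cell_mask`")
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, nrow(intensity_image),
                                                ncol(intensity_image))
  nuc <- nuclear_mask & valid_mask
  cyt <- cell_mask & !nuclear_mask & valid_mask
  if (!any(cyt)) stopf("cytoplasmic region is empty")
  if (!any(nuc)) stopf("nuclear region is empty")
  mean(intensity_image[nuc]) / mean(intensity_image[cyt])
}

#' Manders overlap coefficient
#'
#' `MOC = sum(R * G) / sqrt(sum(R^2) * sum(G^2))` over masked valid
#' pixels; 1 for colinear signals, 0 for disjoint supports, invariant to
#' positive rescaling of either channel.  Images should be
#' background-subtracted.  The split coefficients M1/M2 (fraction of each
#' channel's intensity over pixels where the other is positive) are
#' available from [manders_coefficients()].
#'
#' @param image1,image2 aligned nonnegative image matrices.
#' @param mask optional logical matrix restricting the computation.
#' @return MOC in \[0, 1\].
#' @export
manders_overlap <- function(image1, image2, mask = NULL) {
  manders_coefficients(image1, image2, mask)$moc
}

#' @rdname manders_overlap
#' @export
manders_coefficients <- function(image1, image2, mask = NULL) {
  assert_image(image1); assert_image(image2)
  assert_same_shape(image1, image2)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image1), ncol(image1))
  assert_same_shape(image1, mask)
  r <- image1[mask]; g <- image2[mask]
  sr2 <- sum(r^2); sg2 <- sum(g^2)
  if (sr2 == 0 || sg2 == 0)
    stopf("Manders overlap undefined: a channel is all zero within the mask")
  list(moc = sum(r * g) / sqrt(sr2 * sg2),
       m1 = sum(r[g > 0]) / sum(r),
       m2 = sum(g[r > 0]) / sum(g))
}

#' Count diffraction-limited spots
#'
#' Laplacian-of-Gaussian detection: the image is convolved with a
#' scale-normalized LoG kernel matched to the spot width, local maxima of
#' the response above `median + k * MAD` (computed within the mask) are
#' kept, and maxima closer than `2 * sigma` are suppressed greedily in
#' order of response.  A blank image yields zero spots.
#'
#' @param image matrix of counts.
#' @param mask optional logical matrix restricting detection.
#' @param sigma PSF width in pixels (match the generative `psf_sigma`).
#' @param k MAD multiplier of the response threshold.
#' @param min_prominence candidate maxima below this fraction of the
#'   strongest response are ignored; suppresses the faint sidelobes a
#'   Gaussian spot leaves in the LoG response when the image is nearly
#'   noise-free (where the MAD threshold degenerates to zero).
#' @param labels optional label map for per-cell counts.
#' @return list: `count`, `spots` (data.frame y, x, response, cell_id),
#'   `per_cell` (named counts when `labels` given).
#' @export
count_spots <- function(image, mask = NULL, sigma = 1.5, k = 8,
                        min_prominence = 0.1, labels = NULL) {
  assert_image(image)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  assert_same_shape(image, mask)
  resp <- log_response(image, sigma)
  vals <- resp[mask]
  thr <- max(stats::median(vals) + k * stats::mad(vals),
             min_prominence * max(vals, 0))
  if (max(vals) <= 0)
    return(list(count = 0L,
                spots = data.frame(y = integer(0), x = integer(0),
                                   response = numeric(0)),
                per_cell = NULL))
  # local maxima within a (2r+1)^2 window
  r <- max(1L, ceiling(sigma))
  mx <- max_filter(resp, r)
  peaks <- which(resp == mx & resp > thr & mask)
  if (length(peaks) == 0)
    return(list(count = 0L,
                spots = data.frame(y = integer(0), x = integer(0),
                                   response = numeric(0)),
                per_cell = NULL))
  coords <- arrayInd(peaks, dim(resp))
  ord <- order(resp[peaks], decreasing = TRUE)
  coords <- coords[ord, , drop = FALSE]
  responses <- resp[peaks][ord]
  min_sep <- 2 * sigma
  keep <- logical(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    if (i == 1) { keep[1] <- TRUE; next }
    prev <- which(keep)
    d2 <- (coords[prev, 1] - coords[i, 1])^2 + (coords[prev, 2] - coords[i, 2])^2
    keep[i] <- all(d2 >= min_sep^2)
  }
  spots <- data.frame(y = coords[keep, 1], x = coords[keep, 2],
                      response = responses[keep])
  per_cell <- NULL
  if (!is.null(labels)) {
    assert_same_shape(image, labels)
    spots$cell_id <- labels[cbind(spots$y, spots$x)]
    ids <- sort(unique(labels[labels > 0]))
    per_cell <- stats::setNames(
      vapply(ids, function(id) sum(spots$cell_id == id), integer(1)),
      ids)
  }
  list(count = nrow(spots), spots = spots, per_cell = per_cell)
}

# scale-normalized negative LoG response (bright blobs -> positive peaks)
log_response <- function(image, sigma) {
  r <- ceiling(4 * sigma)
  xs <- -r:r
  g2 <- outer(xs, xs, function(y, x) {
    r2 <- (x^2 + y^2) / (2 * sigma^2)
    (1 - r2) * exp(-r2)
  })
  kern <- g2 - mean(g2)  # zero-mean: flat background gives zero response
  conv2_same(image, kern)
}

# direct 2-D convolution with edge-replicate padding ("same" size);
# replication keeps a flat image's response flat up to the border
conv2_same <- function(img, kern) {
  ny <- nrow(img); nx <- ncol(img)
  kr <- (nrow(kern) - 1L) / 2L
  idx_y <- pmin(pmax(seq_len(ny + 2 * kr) - kr, 1L), ny)
  idx_x <- pmin(pmax(seq_len(nx + 2 * kr) - kr, 1L), nx)
  padded <- img[idx_y, idx_x, drop = FALSE]
  out <- matrix(0, ny, nx)
  for (i in seq_len(nrow(kern))) {
    for (j in seq_len(ncol(kern))) {
      if (kern[i, j] == 0) next
      out <- out + kern[i, j] *
        padded[(i - 1L) + seq_len(ny), (j - 1L) + seq_len(nx)]
    }
  }
  out
}

# grayscale max filter over a (2r+1)^2 box
max_filter <- function(img, r) {
  ny <- nrow(img); nx <- ncol(img)
  out <- matrix(-Inf, ny, nx)
  for (dy in -r:r) {
    for (dx in -r:r) {
      ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
      ok_y <- ys >= 1 & ys <= ny; ok_x <- xs >= 1 & xs <= nx
      sub <- matrix(-Inf, ny, nx)
      sub[which(ok_y), which(ok_x)] <- img[ys[ok_y], xs[ok_x]]
      out <- pmax(out, sub)
    }
  }
  out
}

#' Pearson correlation between paired per-cell measurements
#'
#' The cross-assay readout: e.g. per-cell smFISH intensity against
#' per-cell FRET.  Errors on fewer than 3 pairs or zero variance.
#'
#' @param x,y equal-length numeric vectors (one value per cell).
#' @return list: `r` (Pearson correlation) and `table` (paired data.frame
#'   for plotting).
#' @export
correlate_cells <- function(x, y) {
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("need at least 3 paired cells")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("correlation undefined: zero variance")
  list(r = stats::cor(x, y), table = data.frame(x = x, y = y))
}
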