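#' Construct a three-cube sensitized-emission image set
#'
#' @param I_DD donor-excitation / donor-emission image (counts).
#' @param I_DA donor-excitation / acceptor-emission image (the raw FRET
#'   channel, counts).
#' @param I_AA acceptor-excitation / acceptor-emission image (counts).
#' @param valid_mask logical matrix; defaults to marking every pixel below
#'   the saturation level in all three channels.
#' @param bit_depth acquisition bit depth.
#' @return a `three_cube` object.
#' @export
three_cube <- function(I_DD, I_DA, I_AA, valid_mask = NULL, bit_depth = 12) {
  assert_image(I_DD); assert_image(I_DA); assert_image(I_AA)
  assert_same_shape(I_DD, I_DA, I_AA)
  sat <- saturation_value(bit_depth)
  auto <- I_DD < sat & I_DA < sat & I_AA < sat
  valid_mask <- if (is.null(valid_mask)) auto else (valid_mask & auto)
  structure(list(I_DD = I_DD, I_DA = I_DA, I_AA = I_AA,
                 valid_mask = valid_mask, bit_depth = as.integer(bit_depth)),
            class = "three_cube")
}

#' @export
print.three_cube <- function(x, ...) {
  cat(sprintf("three-cube set: %d x %d px, %d-bit, %.1f%% valid\n",
              nrow(x$I_DD), ncol(x$I_DD), x$bit_depth,
              100 * mean(x$valid_mask)))
  invisible(x)
}

#' Background-correct, saturation-threshold and median-filter one channel
#'
#' Pixels at or above `saturation_level` are marked invalid and excluded
#' from every downstream statistic; they propagate as excluded pixels in
#' the final cFRET image.  The estimated background is subtracted with a
#' floor at zero, then a median filter over valid pixels only reduces
#' noise (invalid neighbours are ignored, not smoothed over).
#'
#' @param image matrix of counts.
#' @param background one of `"background-mean"` (mean of the sub-Otsu
#'   background region, the default), `"mode"` (most frequent integer
#'   count) or a numeric level.
#' @param saturation_level counts; defaults to `2^bit_depth - 1`.
#' @param median_radius radius of the median window (1 = 3x3); `0` skips
#'   filtering.
#' @param bit_depth used for the default saturation level.
#' @param clip_negative floor the background-subtracted image at 0.  The
#'   default suits display and single-image use; pipelines that average
#'   over pixels keep negatives (`FALSE`), because rectifying zero-mean
#'   noise on signal-free channels biases every downstream mean.
#' @return list with `image` (corrected), `valid_mask`, `background`.
#' @export
preprocess_channel <- function(image, background = "background-mean",
                               saturation_level = NULL, median_radius = 1,
                               bit_depth = 12, clip_negative = TRUE) {
  assert_image(image)
  if (is.null(saturation_level)) saturation_level <- saturation_value(bit_depth)
  if (saturation_level > saturation_value(bit_depth))
    stopf("`saturation_level` exceeds the %d-bit ceiling", bit_depth)
  valid <- image < saturation_level
  if (!any(valid)) stopf("all pixels are saturated")
  bg <- estimate_background(image[valid], background)
  corrected <- image - bg
  if (clip_negative) corrected <- pmax(corrected, 0)
  if (median_radius > 0)
    corrected <- median_filter_masked(corrected, valid, median_radius)
  list(image = corrected, valid_mask = valid, background = bg)
}

estimate_background <- function(values, method) {
  if (is.numeric(method)) return(method)
  switch(method,
    "background-mean" = {
      # mean of the sub-threshold (background) population; unbiased for
      # Poisson counts, unlike the histogram mode.  If the Otsu split does
      # not separate two real populations (signal-free channel), the whole
      # image is background.
      thr <- otsu_threshold(values)
      lo <- values[values <= thr]
      hi <- values[values > thr]
      if (length(hi) == 0 || length(lo) < 2 ||
          mean(hi) - mean(lo) < 4 * stats::sd(lo)) mean(values)
      else mean(lo)
    },
    "mode" = {
      tab <- table(round(values))
      as.numeric(names(tab)[which.max(tab)])
    },
    stopf("unknown background method '%s'", method))
}

# Otsu's threshold on a numeric sample (256-bin histogram)
otsu_threshold <- function(values) {
  r <- range(values)
  if (diff(r) == 0) return(r[1])
  breaks <- seq(r[1], r[2], length.out = 257)
  h <- tabulate(findInterval(values, breaks, all.inside = TRUE), nbins = 256)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w <- cumsum(h); m <- cumsum(h * mids)
  tot_w <- w[256]; tot_m <- m[256]
  between <- (tot_m * w - tot_w * m)^2 / (w * (tot_w - w))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# median filter ignoring invalid pixels; window (2r+1)^2
median_filter_masked <- function(img, valid, radius) {
  ny <- nrow(img); nx <- ncol(img)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  stack <- array(NA_real_, c(ny, nx, nrow(offs)))
  vals <- img
  vals[!valid] <- NA_real_
  for (k in seq_len(nrow(offs))) {
    dy <- offs$dy[k]; dx <- offs$dx[k]
    ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
    ok_y <- ys >= 1 & ys <= ny; ok_x <- xs >= 1 & xs <= nx
    stack[which(ok_y), which(ok_x), k] <- vals[ys[ok_y], xs[ok_x]]
  }
  out <- apply(stack, c(1, 2), stats::median, na.rm = TRUE)
  out[!is.finite(out)] <- img[!is.finite(out)]
  out[!valid] <- img[!valid]
  out
}

#' Estimate the integer translation between two images
#'
#' Cross-correlation via FFT of the zero-mean images.  The returned
#' `c(dy, dx)` is the displacement of `moving` relative to `reference`:
#' shifting `moving` by `-c(dy, dx)` (see [apply_shift()]) aligns it.
#'
#' @param reference,moving same-shape image matrices.
#' @return integer vector `c(dy, dx)`.
#' @export
register_translation <- function(reference, moving) {
  assert_image(reference); assert_image(moving)
  assert_same_shape(reference, moving)
  if (stats::sd(reference) == 0 || stats::sd(moving) == 0)
    stopf("translation is undefined for a constant image")
  f1 <- stats::fft(reference - mean(reference))
  f2 <- stats::fft(moving - mean(moving))
  cc <- Re(stats::fft(f1 * Conj(f2), inverse = TRUE))
  idx <- arrayInd(which.max(cc), dim(cc)) - 1L
  ny <- nrow(reference); nx <- ncol(reference)
  dy <- if (idx[1] > ny / 2) idx[1] - ny else idx[1]
  dx <- if (idx[2] > nx / 2) idx[2] - nx else idx[2]
  -c(dy = dy, dx = dx)
}

#' Translate an image by an integer shift, padding with zero
#'
#' `apply_shift(img, c(dy, dx))` moves content down by `dy` and right by
#' `dx`.  To align a moving image to a reference, apply the negative of
#' [register_translation()]'s estimate.
#'
#' @param img image matrix.
#' @param shift integer `c(dy, dx)`.
#' @param fill value for uncovered pixels.
#' @export
apply_shift <- function(img, shift, fill = 0) {
  assert_image(img)
  dy <- as.integer(round(shift[1])); dx <- as.integer(round(shift[2]))
  ny <- nrow(img); nx <- ncol(img)
  out <- matrix(fill, ny, nx)
  ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
  ok_y <- ys >= 1 & ys <= ny; ok_x <- xs >= 1 & xs <= nx
  out[which(ok_y), which(ok_x)] <- img[ys[ok_y], xs[ok_x]]
  out
}

#' Estimate a spectral bleed-through constant from a single-label control
#'
#' On a donor-only specimen the raw FRET channel contains only donor
#' bleed-through, so the constant `a` is the slope of the least-squares
#' regression through the origin of `I_DA` on `I_DD` over bright, valid
#' pixels; on an acceptor-only specimen `b` is the slope of `I_DA` on
#' `I_AA`.  A median-of-ratios estimator is available for robustness
#' comparisons.
#'
#' @param control a preprocessed [three_cube()] from a single-label
#'   specimen (background-subtracted channels).
#' @param which `"donor"` (estimates `a`) or `"acceptor"` (estimates `b`).
#' @param signal_threshold counts; pixels with reference-channel signal at
#'   or below it are ignored.  Default: Otsu threshold of that channel.
#' @param min_pixels minimum usable pixel count.
#' @param method `"regression"` (default) or `"median_ratio"`.
#' @return a `bleedthrough_constant`: value, which, n_pixels_used,
#'   fit_residual (RMS counts), method.
#' @export
estimate_bleedthrough <- function(control, which = c("donor", "acceptor"),
                                  signal_threshold = NULL, min_pixels = 100,
                                  method = c("regression", "median_ratio")) {
  stopifnot(inherits(control, "three_cube"))
  which <- match.arg(which)
  method <- match.arg(method)
  x <- if (which == "donor") control$I_DD else control$I_AA
  y <- control$I_DA
  if (is.null(signal_threshold))
    signal_threshold <- otsu_threshold(x[control$valid_mask])
  use <- control$valid_mask & x > signal_threshold
  n <- sum(use)
  if (n < min_pixels)
    stopf("only %d usable pixels (need >= %d); is this a single-label control with signal?",
          n, min_pixels)
  xv <- x[use]; yv <- y[use]
  value <- if (method == "regression") slope_through_origin(xv, yv)
           else stats::median(yv / xv)
  res <- yv - value * xv
  structure(list(value = value, which = which, n_pixels_used = n,
                 fit_residual = sqrt(mean(res^2)),
                 # heteroscedasticity-robust (sandwich) standard error of
                 # the through-origin slope; shot noise scales with signal
                 slope_se = sqrt(sum(res^2 * xv^2)) / sum(xv^2),
                 signal_threshold = signal_threshold, method = method),
            class = "bleedthrough_constant")
}

#' @export
print.bleedthrough_constant <- function(x, ...) {
  cat(sprintf("%s bleed-through %s = %.4f (%d px, rms residual %.2f counts)\n",
              x$which, if (x$which == "donor") "a" else "b",
              x$value, x$n_pixels_used, x$fit_residual))
  invisible(x)
}

#' Compute the corrected FRET (cFRET) image
#'
#' Per valid pixel, `cFRET = I_DA - a * I_DD - b * I_AA`, removing donor
#' bleed-through and directly excited acceptor emission from the raw FRET
#' channel.  Pixels invalid in any channel, or outside `cell_mask`, are
#' flagged excluded; they carry no value in any per-cell statistic and are
#' rendered black for display.  Negative values are retained in the stored
#' image (clip only for display, see [cfret_display()]).
#'
#' @param cube a preprocessed, registered [three_cube()].
#' @param constants list with elements `a` and `b` (numbers or
#'   [estimate_bleedthrough()] results).
#' @param cell_mask optional logical matrix restricting the analysis.
#' @return a `cfret_image`: `image` (counts) and `excluded` (logical).
#' @export
compute_cfret <- function(cube, constants, cell_mask = NULL) {
  stopifnot(inherits(cube, "three_cube"))
  a <- constant_value(constants$a, "a")
  b <- constant_value(constants$b, "b")
  if (!is.null(cell_mask)) {
    assert_same_shape(cube$I_DA, cell_mask)
  } else {
    cell_mask <- matrix(TRUE, nrow(cube$I_DA), ncol(cube$I_DA))
  }
  img <- cube$I_DA - a * cube$I_DD - b * cube$I_AA
  excluded <- !cube$valid_mask | !cell_mask
  structure(list(image = img, excluded = excluded, a = a, b = b),
            class = "cfret_image")
}

constant_value <- function(x, name) {
  if (is.null(x)) stopf("bleed-through constant `%s` is missing", name)
  if (inherits(x, "bleedthrough_constant")) x <- x$value
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0)
    stopf("bleed-through constant `%s` must be a single nonnegative number", name)
  x
}

#' Display version of a cFRET image (excluded black, negatives clipped)
#' @param cfret a [compute_cfret()] result.
#' @export
cfret_display <- function(cfret) {
  stopifnot(inherits(cfret, "cfret_image"))
  img <- pmax(cfret$image, 0)
  img[cfret$excluded] <- 0
  img
}

#' Full three-cube pipeline: preprocess, estimate constants, correct
#'
#' Convenience wrapper tying the module together: background-corrects and
#' saturation-thresholds the sample and both single-label controls,
#' estimates the bleed-through constants from the controls, computes the
#' sample's cFRET image, and median-filters the combined cFRET image.
#' The filter is applied after the channel combination (not per channel)
#' because the cFRET noise is approximately symmetric, so its median is
#' unbiased, whereas median-filtering the low-count raw channels pulls
#' their skewed shot noise below the mean; the unfiltered image is kept
#' in `cfret$unfiltered`.  Constants are estimated from unfiltered
#' controls for the same reason.
#'
#' @param sample,donor_control,acceptor_control raw [three_cube()] sets.
#' @param cell_mask optional logical matrix.
#' @param median_radius radius of the median filter applied to the cFRET
#'   image (0 disables).
#' @param ... passed to [preprocess_channel()] (background method etc.).
#' @return list: `cfret` (with `unfiltered` field), `a`, `b`, `sample`
#'   (preprocessed cube).
#' @export
cfret_pipeline <- function(sample, donor_control, acceptor_control,
                           cell_mask = NULL, median_radius = 1, ...) {
  s <- preprocess_cube(sample, median_radius = 0, clip_negative = FALSE, ...)
  dc <- preprocess_cube(donor_control, median_radius = 0,
                        clip_negative = FALSE, ...)
  ac <- preprocess_cube(acceptor_control, median_radius = 0,
                        clip_negative = FALSE, ...)
  a <- estimate_bleedthrough(dc, "donor")
  b <- estimate_bleedthrough(ac, "acceptor")
  cf <- compute_cfret(s, list(a = a, b = b), cell_mask)
  cf$unfiltered <- cf$image
  if (median_radius > 0)
    cf$image <- median_filter_masked(cf$image, !cf$excluded, median_radius)
  list(cfret = cf, a = a, b = b, sample = s)
}

#' Preprocess all three channels of a cube
#'
#' By default the background is estimated from a joint cell-free region:
#' each channel's Otsu split (with a bimodality guard) proposes signal
#' pixels, their union defines the specimen footprint, and every
#' channel's background is the mean over the remaining pixels.  This is
#' what makes weak channels tractable — e.g. the raw FRET channel of an
#' acceptor-only control carries only a few counts of bleed-through
#' signal, not enough for its own histogram to separate, but the
#' footprint is obvious in the acceptor channel.  Pass `background` to
#' force per-channel estimation instead ([preprocess_channel()] methods).
#'
#' @param cube a raw [three_cube()].
#' @param background `"joint"` (default) or a [preprocess_channel()]
#'   background method applied per channel.
#' @param ... passed to [preprocess_channel()].
#' @return a [three_cube()] with background-subtracted channels and the
#'   intersection of the per-channel validity masks.
#' @export
preprocess_cube <- function(cube, background = "joint", ...) {
  stopifnot(inherits(cube, "three_cube"))
  channels <- list(cube$I_DD, cube$I_DA, cube$I_AA)
  if (identical(background, "joint")) {
    bg_region <- joint_background_region(channels, cube$valid_mask)
    background <- vapply(channels, function(ch) mean(ch[bg_region]),
                         numeric(1))
  } else {
    background <- rep_len(list(background), 3L)
  }
  pp <- lapply(seq_len(3L), function(i)
    preprocess_channel(channels[[i]], background = background[[i]],
                       bit_depth = cube$bit_depth, ...))
  three_cube(pp[[1]]$image, pp[[2]]$image, pp[[3]]$image,
             valid_mask = pp[[1]]$valid_mask & pp[[2]]$valid_mask &
               pp[[3]]$valid_mask & cube$valid_mask,
             bit_depth = cube$bit_depth)
}

# cell-free pixels: valid and below the Otsu signal split of every channel
# that shows a real (bimodal) signal population
joint_background_region <- function(channels, valid_mask) {
  region <- valid_mask
  any_signal <- FALSE
  for (ch in channels) {
    vals <- ch[valid_mask]
    thr <- otsu_threshold(vals)
    lo <- vals[vals <= thr]
    hi <- vals[vals > thr]
    if (length(hi) > 0 && length(lo) > 1 &&
        mean(hi) - mean(lo) >= 4 * stats::sd(lo)) {
      any_signal <- TRUE
      region <- region & ch <= thr
    }
  }
  if (!any(region)) region <- valid_mask
  region
}
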