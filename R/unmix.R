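#' Construct a lambda stack
#'
#' A lambda stack groups, per excitation laser, one image per emission
#' detection window.  All blocks must share the same window grid and image
#' shape.
#'
#' @param blocks named list (names = laser nm) of lists of image matrices,
#'   one per detection window, in window order.
#' @param window_edges windows as `c(start, end)` pairs (list or 2-column
#'   matrix), strictly increasing and non-overlapping.
#' @param valid_mask logical matrix; defaults to marking pixels below the
#'   saturation level in every channel.
#' @param bit_depth acquisition bit depth.
#' @export
lambda_stack <- function(blocks, window_edges, valid_mask = NULL,
                         bit_depth = 12) {
  if (!is.list(blocks) || is.null(names(blocks)) || length(blocks) == 0)
    stopf("`blocks` must be a non-empty named list (laser -> channel images)")
  window_edges <- as_window_matrix(window_edges)
  nw <- nrow(window_edges)
  for (nm in names(blocks)) {
    if (length(blocks[[nm]]) != nw)
      stopf("block '%s' has %d channels but %d windows are defined",
            nm, length(blocks[[nm]]), nw)
    lapply(blocks[[nm]], assert_image, name = paste0("block ", nm))
  }
  all_imgs <- unlist(blocks, recursive = FALSE)
  do.call(assert_same_shape, all_imgs)
  sat <- saturation_value(bit_depth)
  auto <- Reduce(`&`, lapply(all_imgs, function(im) im < sat))
  valid_mask <- if (is.null(valid_mask)) auto else (valid_mask & auto)
  structure(list(blocks = blocks, window_edges = window_edges,
                 valid_mask = valid_mask, bit_depth = as.integer(bit_depth)),
            class = "lambda_stack")
}

#' @export
print.lambda_stack <- function(x, ...) {
  cat(sprintf("lambda stack: %s nm lasers x %d windows (%g-%g nm), %d x %d px\n",
              paste(names(x$blocks), collapse = "/"), nrow(x$window_edges),
              min(x$window_edges), max(x$window_edges),
              nrow(x$valid_mask), ncol(x$valid_mask)))
  invisible(x)
}

stack_lasers <- function(stack) names(stack$blocks)

n_stack_channels <- function(stack)
  length(stack$blocks) * nrow(stack$window_edges)

# channels x pixels matrix, channel order: laser-major, window-minor
stack_matrix <- function(stack) {
  imgs <- unlist(stack$blocks, recursive = FALSE)
  t(vapply(imgs, as.numeric, numeric(length(stack$valid_mask))))
}

# logical channel selector for a subset of lasers
laser_channel_index <- function(stack, lasers) {
  nw <- nrow(stack$window_edges)
  sel <- rep(FALSE, n_stack_channels(stack))
  for (L in as.character(lasers)) {
    i <- match(L, names(stack$blocks))
    if (is.na(i)) stopf("laser %s nm not present in the stack", L)
    sel[(i - 1L) * nw + seq_len(nw)] <- TRUE
  }
  sel
}

#' Background-correct a lambda stack
#'
#' Detector background offsets every channel and would otherwise be
#' unmixed into spurious abundance.  The specimen footprint is located by
#' Otsu on the summed-intensity image; each channel's background is then
#' its mean over the remaining (cell-free) pixels and is subtracted.
#' Negative residual noise is retained so that downstream means stay
#' unbiased.
#'
#' @param stack a [lambda_stack()].
#' @param background `"auto"` (cell-free-region mean per channel) or a
#'   numeric scalar/vector (one value per channel) subtracted as-is.
#' @return a background-subtracted [lambda_stack()].
#' @export
preprocess_stack <- function(stack, background = "auto") {
  stopifnot(inherits(stack, "lambda_stack"))
  nw <- nrow(stack$window_edges)
  nch <- n_stack_channels(stack)
  if (identical(background, "auto")) {
    total <- Reduce(`+`, unlist(stack$blocks, recursive = FALSE))
    vals <- total[stack$valid_mask]
    thr <- otsu_threshold(vals)
    lo <- vals[vals <= thr]; hi <- vals[vals > thr]
    bg_region <- if (length(hi) > 0 && length(lo) > 1 &&
                     mean(hi) - mean(lo) >= 4 * stats::sd(lo))
      stack$valid_mask & total <= thr else stack$valid_mask
    bg <- unlist(lapply(stack$blocks, function(bl)
      vapply(bl, function(im) mean(im[bg_region]), numeric(1))))
  } else {
    bg <- rep_len(as.numeric(background), nch)
  }
  blocks <- stack$blocks
  ch <- 0L
  for (L in names(blocks)) {
    for (wi in seq_len(nw)) {
      ch <- ch + 1L
      blocks[[L]][[wi]] <- blocks[[L]][[wi]] - bg[ch]
    }
  }
  out <- lambda_stack(blocks, stack$window_edges,
                      valid_mask = stack$valid_mask,
                      bit_depth = stack$bit_depth)
  attr(out, "background") <- bg
  out
}

new_fingerprint <- function(vec, name, lasers = NULL, windows = NULL) {
  vec <- pmax(as.numeric(vec), 0)
  s <- sum(vec)
  if (s <= 0) stopf("fingerprint of '%s' is all zero", name)
  structure(list(name = name, vector = vec / s, lasers = lasers,
                 windows = windows),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("fingerprint '%s': %d channels, peak channel %d\n",
              x$name, length(x$vector), which.max(x$vector)))
  invisible(x)
}

#' Extract a spectral fingerprint from a single-component control stack
#'
#' The fingerprint is the L1-normalized mean spectrum over masked valid
#' pixels after per-channel background subtraction.  Restricting to a
#' subset of lasers (`lasers`) zeroes the remaining blocks; this is how an
#' acceptor fingerprint is confined to its own excitation block so that
#' directly excited acceptor emission under the donor laser is left to the
#' FRET component (the bleed-through that unmixing cannot remove).
#'
#' @param control a single-component [lambda_stack()].
#' @param mask logical matrix selecting signal pixels.
#' @param background per-channel background: `"auto"` (median over
#'   out-of-mask valid pixels, the default), a numeric scalar/vector, or
#'   `0`.
#' @param lasers optional subset of laser lines to keep; others zeroed.
#' @param name component name stored with the fingerprint.
#' @return a `fingerprint` (entries >= 0, summing to 1).
#' @export
extract_fingerprint <- function(control, mask, background = "auto",
                                lasers = NULL, name = "component") {
  stopifnot(inherits(control, "lambda_stack"))
  assert_same_shape(control$valid_mask, mask)
  use <- mask & control$valid_mask
  if (!any(use)) stopf("fingerprint mask selects no valid pixels")
  S <- stack_matrix(control)
  bg_use <- !mask & control$valid_mask
  bg <- if (identical(background, "auto")) {
    if (any(bg_use)) apply(S[, which(bg_use), drop = FALSE], 1, stats::median)
    else rep(0, nrow(S))
  } else rep_len(as.numeric(background), nrow(S))
  spec <- rowMeans(S[, which(use), drop = FALSE]) - bg
  spec <- pmax(spec, 0)
  if (!is.null(lasers)) spec[!laser_channel_index(control, lasers)] <- 0
  new_fingerprint(spec, name = name, lasers = stack_lasers(control),
                  windows = control$window_edges)
}

#' Build a FRET fingerprint from an acceptor fingerprint
#'
#' Sensitized emission has the acceptor's spectral shape but is excited
#' through the donor, so it appears in each laser block in proportion to
#' the donor's excitation efficiency there — dominantly the donor laser.
#' This helper takes the acceptor's window profile from `source_laser`'s
#' block and replicates it into every block, weighted by `excitation`
#' (a named laser -> efficiency vector, or a donor [fluorophore_spec()]).
#'
#' @param acceptor_fp acceptor [extract_fingerprint()] result.
#' @param stack a [lambda_stack()] defining the channel layout.
#' @param source_laser laser whose block holds the acceptor's emission
#'   profile.
#' @param excitation donor excitation efficiencies per laser: a named
#'   numeric vector, a [fluorophore_spec()], or a single laser line
#'   (shorthand for weight 1 on that laser).
#' @export
fret_fingerprint <- function(acceptor_fp, stack, source_laser,
                             excitation = 488) {
  stopifnot(inherits(acceptor_fp, "fingerprint"),
            inherits(stack, "lambda_stack"))
  if (inherits(excitation, "fluorophore_spec"))
    excitation <- excitation$excitation_efficiency
  if (is.null(names(excitation))) {
    if (length(excitation) != 1)
      stopf("`excitation` must be named (laser -> efficiency) or one laser line")
    excitation <- stats::setNames(1, as.character(excitation))
  }
  src <- laser_channel_index(stack, source_laser)
  shape <- acceptor_fp$vector[which(src)]
  vec <- rep(0, n_stack_channels(stack))
  for (L in names(stack$blocks)) {
    w <- excitation[L]
    if (is.na(w) || w == 0) next
    vec[which(laser_channel_index(stack, L))] <- w * shape
  }
  new_fingerprint(vec, name = paste0("FRET(", acceptor_fp$name, ")"),
                  lasers = stack_lasers(stack), windows = stack$window_edges)
}

#' Per-pixel nonnegative linear unmixing of a lambda stack
#'
#' Solves, for every valid pixel with spectrum `s`,
#' `min || F w - s ||^2  subject to  w >= 0`
#' where the columns of `F` are the component fingerprints
#' (Lawson-Hanson active-set NNLS).  Pixels whose unconstrained
#' least-squares solution is already nonnegative are solved in one
#' vectorized pass; only the remainder go through the active-set solver.
#'
#' @param stack a [lambda_stack()].
#' @param fingerprints list of `fingerprint` objects (length >= 1).
#' @param condition_limit error if the fingerprint matrix condition number
#'   exceeds this (collinear fingerprints cannot be separated).
#' @return an `unmix_result`: `abundance` (named list of images, >= 0),
#'   `residual` (root-sum-square counts per pixel), `valid_mask`.
#' @export
unmix_stack <- function(stack, fingerprints, condition_limit = 1e6) {
  stopifnot(inherits(stack, "lambda_stack"))
  if (inherits(fingerprints, "fingerprint")) fingerprints <- list(fingerprints)
  if (length(fingerprints) < 1) stopf("need at least one fingerprint")
  F <- vapply(fingerprints, function(f) f$vector,
              numeric(n_stack_channels(stack)))
  F <- matrix(F, ncol = length(fingerprints))
  nms <- vapply(fingerprints, function(f) f$name, character(1))
  colnames(F) <- nms
  check_fingerprint_conditioning(F, condition_limit)

  S <- stack_matrix(stack)
  npx <- ncol(S)
  k <- ncol(F)
  W <- matrix(0, k, npx)
  valid <- as.vector(stack$valid_mask)
  idx <- which(valid)
  if (length(idx) > 0) {
    FtF <- crossprod(F)
    # unconstrained solve for all pixels at once
    Wu <- solve(FtF, crossprod(F, S[, idx, drop = FALSE]))
    neg <- which(apply(Wu, 2, function(w) any(w < -1e-10)))
    Wu[Wu < 0] <- 0
    for (j in neg) {
      px <- idx[j]
      Wu[, j] <- pracma::lsqnonneg(F, S[, px])$x
    }
    W[, idx] <- Wu
  }
  resid_vec <- sqrt(colSums((S - F %*% W)^2))
  dims <- dim(stack$valid_mask)
  abundance <- lapply(seq_len(k), function(i) matrix(W[i, ], dims[1], dims[2]))
  names(abundance) <- nms
  residual <- matrix(resid_vec, dims[1], dims[2])
  residual[!stack$valid_mask] <- 0
  structure(list(abundance = abundance, residual = residual,
                 valid_mask = stack$valid_mask, fingerprints = fingerprints),
            class = "unmix_result")
}

check_fingerprint_conditioning <- function(F, condition_limit) {
  if (ncol(F) == 1L) return(invisible(TRUE))
  cond <- kappa(F, exact = TRUE)
  if (cond > condition_limit) {
    cs <- crossprod(F / sqrt(colSums(F^2) + .Machine$double.eps))
    diag(cs) <- 0
    worst <- arrayInd(which.max(cs), dim(cs))
    stopf(paste0("fingerprint matrix is ill-conditioned (condition %.3g > %.3g); ",
                 "most collinear pair: '%s' and '%s'"),
          cond, condition_limit,
          colnames(F)[worst[1]], colnames(F)[worst[2]])
  }
  invisible(TRUE)
}

#' Remove acceptor bleed-through from an unmixed FRET component
#'
#' Linear unmixing assigns directly excited acceptor emission under the
#' donor laser to the FRET component; it is removed computationally as
#' `corrected = fret - b * acceptor` per valid pixel, with `b` measured on
#' an acceptor-only control (see [estimate_unmix_bleedthrough()]).
#'
#' @param fret_component,acceptor_component unmixed abundance images.
#' @param b acceptor bleed-through fraction.
#' @param valid_mask optional logical matrix; excluded pixels set to 0.
#' @return corrected FRET image.
#' @export
correct_unmixed_fret <- function(fret_component, acceptor_component, b,
                                 valid_mask = NULL) {
  assert_image(fret_component); assert_image(acceptor_component)
  assert_same_shape(fret_component, acceptor_component)
  out <- fret_component - b * acceptor_component
  if (!is.null(valid_mask)) {
    assert_same_shape(out, valid_mask)
    out[!valid_mask] <- 0
  }
  out
}

#' Measure the post-unmixing acceptor bleed-through on a control
#'
#' On an acceptor-only specimen the unmixed FRET component contains only
#' acceptor bleed-through, so `b` is the ratio of total unmixed FRET to
#' total unmixed acceptor over signal pixels.  The ratio-of-sums
#' estimator is preferred over a regression slope because nonnegative
#' unmixing truncates the FRET component at zero, which adds a small
#' positive offset at dim pixels; the ratio of sums measures exactly the
#' quantity that [correct_unmixed_fret()] must cancel on specimens with a
#' comparable intensity distribution.  `method = "slope"` gives the
#' through-origin regression instead.
#'
#' @param result an [unmix_stack()] result from an acceptor-only control.
#' @param fret,acceptor component names in `result$abundance`.
#' @param signal_threshold acceptor abundance above which pixels count as
#'   signal; default Otsu.
#' @param method `"ratio"` (default) or `"slope"`.
#' @return list: `b`, `n_pixels_used`, `slope_se` (delta-method standard
#'   error of `b`).
#' @export
estimate_unmix_bleedthrough <- function(result, fret, acceptor,
                                        signal_threshold = NULL,
                                        method = c("ratio", "slope")) {
  stopifnot(inherits(result, "unmix_result"))
  method <- match.arg(method)
  fr <- result$abundance[[fret]]
  ac <- result$abundance[[acceptor]]
  if (is.null(fr) || is.null(ac))
    stopf("components '%s'/'%s' not found in unmix result", fret, acceptor)
  if (is.null(signal_threshold))
    signal_threshold <- otsu_threshold(ac[result$valid_mask])
  use <- result$valid_mask & ac > signal_threshold
  n <- sum(use)
  if (n < 50) stopf("too few signal pixels to estimate bleed-through")
  x <- ac[use]; y <- fr[use]
  if (method == "ratio") {
    b <- sum(y) / sum(x)
    se <- stats::sd(y - b * x) / sqrt(n) / mean(x)
  } else {
    b <- slope_through_origin(x, y)
    res <- y - b * x
    se <- sqrt(sum(res^2 * x^2)) / sum(x^2)
  }
  list(b = b, n_pixels_used = n, slope_se = se, method = method)
}

#' Check that acceptor bleed-through is stable across intensity
#'
#' Computational removal of acceptor bleed-through after unmixing is only
#' justified if the bleed-through ratio does not drift with acceptor
#' brightness.  Given acceptor-only control stacks spanning a range of
#' intensities, this regresses the apparent ratio (unmixed FRET /
#' unmixed acceptor) on log10 mean acceptor intensity; the series is
#' flagged stable when the fitted drift per intensity decade is below
#' `tolerance` times the mean ratio.
#'
#' @param controls list (>= 3) of acceptor-only [lambda_stack()]s at
#'   graded intensities.
#' @param fingerprints fingerprints passed to [unmix_stack()]; must
#'   include `fret` and `acceptor`.
#' @param fret,acceptor component names.
#' @param tolerance allowed relative drift per intensity decade.
#' @return list: `slope` (ratio per decade), `intercept`, `mean_ratio`,
#'   `ratios` (per control), `intensities`, `stable`.
#' @export
assess_bleedthrough_stability <- function(controls, fingerprints,
                                          fret, acceptor,
                                          tolerance = 0.05) {
  if (length(controls) < 3)
    stopf("need >= 3 intensity levels to assess stability, got %d",
          length(controls))
  ratios <- numeric(length(controls))
  intens <- numeric(length(controls))
  for (i in seq_along(controls)) {
    res <- unmix_stack(controls[[i]], fingerprints)
    est <- estimate_unmix_bleedthrough(res, fret, acceptor)
    ac <- res$abundance[[acceptor]]
    thr <- otsu_threshold(ac[res$valid_mask])
    ratios[i] <- est$b
    intens[i] <- mean(ac[res$valid_mask & ac > thr])
  }
  fit <- stats::lm(ratios ~ log10(intens))
  slope <- unname(stats::coef(fit)[2])
  mean_ratio <- mean(ratios)
  list(slope = slope, intercept = unname(stats::coef(fit)[1]),
       mean_ratio = mean_ratio, ratios = ratios, intensities = intens,
       stable = abs(slope) <= tolerance * abs(mean_ratio))
}
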