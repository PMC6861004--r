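#' Define a fluorophore for synthetic rendering
#'
#' A fluorophore is described by a skew-normal emission spectrum (peak,
#' width, skew), a per-laser excitation efficiency, and a quantum yield.
#' The emission density integrates to 1 over the modeled spectral range
#' (480--800 nm), so the product
#' \code{abundance * excitation_efficiency[laser] * emission-in-window}
#' gives the expected photon count in a detection window.
#'
#' The shipped spectra are synthetic stand-ins with vendor-typical peaks;
#' they are not measured dye spectra.
#'
#' @param name character name, e.g. `"AF488"`.
#' @param emission_peak emission maximum in nm.
#' @param emission_width spectral width (scale of the skew-normal) in nm.
#' @param excitation_efficiency named numeric vector, names are laser lines
#'   in nm, values are relative excitation efficiencies in \[0, 1\].
#' @param quantum_yield fraction in (0, 1\].
#' @param skew skewness of the emission shape (dye spectra have red tails).
#' @return an object of class `fluorophore_spec`.
#' @seealso [default_fluorophores()]
#' @export
fluorophore_spec <- function(name, emission_peak, emission_width,
                             excitation_efficiency, quantum_yield = 0.9,
                             skew = 4) {
  if (is.null(names(excitation_efficiency)) ||
      any(!nzchar(names(excitation_efficiency))))
    stopf("`excitation_efficiency` must be a named vector (laser nm -> fraction)")
  assert_fraction(excitation_efficiency, "excitation_efficiency")
  if (!is.numeric(quantum_yield) || quantum_yield <= 0 || quantum_yield > 1)
    stopf("`quantum_yield` must be in (0, 1]")
  if (emission_width <= 0) stopf("`emission_width` must be positive")
  structure(
    list(name = as.character(name),
         emission_peak = emission_peak,
         emission_width = emission_width,
         excitation_efficiency = excitation_efficiency,
         quantum_yield = quantum_yield,
         skew = skew),
    class = "fluorophore_spec")
}

# modeled spectral range, nm
SPECTRAL_RANGE <- c(480, 800)

#' Emission density of a fluorophore on a wavelength grid
#'
#' Skew-normal shape normalized to integrate to 1 over the modeled
#' 480--800 nm range.
#'
#' @param fluor a [fluorophore_spec()].
#' @param wavelengths numeric vector of wavelengths in nm.
#' @return density values (1/nm) at `wavelengths`.
#' @export
emission_density <- function(fluor, wavelengths) {
  stopifnot(inherits(fluor, "fluorophore_spec"))
  z <- (wavelengths - fluor$emission_peak) / fluor$emission_width
  shape <- stats::dnorm(z) * stats::pnorm(fluor$skew * z)
  grid <- seq(SPECTRAL_RANGE[1], SPECTRAL_RANGE[2], by = 0.5)
  zg <- (grid - fluor$emission_peak) / fluor$emission_width
  norm <- sum(stats::dnorm(zg) * stats::pnorm(fluor$skew * zg)) * 0.5
  if (norm <= 0) stopf("emission spectrum of %s is zero over the modeled range", fluor$name)
  shape / norm
}

#' Integrated emission per detection window
#'
#' @param fluor a [fluorophore_spec()].
#' @param windows a list of `c(start, end)` wavelength windows in nm, or a
#'   two-column matrix.
#' @return fraction of total emission falling in each window.
#' @export
emission_in_windows <- function(fluor, windows) {
  windows <- as_window_matrix(windows)
  vapply(seq_len(nrow(windows)), function(i) {
    grid <- seq(windows[i, 1], windows[i, 2], by = 0.5)
    sum(emission_density(fluor, grid)) * 0.5
  }, numeric(1))
}

as_window_matrix <- function(windows) {
  if (is.list(windows)) windows <- do.call(rbind, windows)
  windows <- matrix(as.numeric(windows), ncol = 2)
  if (any(windows[, 2] <= windows[, 1]))
    stopf("each window must satisfy start < end")
  if (nrow(windows) > 1) {
    o <- order(windows[, 1])
    w <- windows[o, , drop = FALSE]
    if (any(w[-1, 1] < w[-nrow(w), 2]))
      stopf("windows must be non-overlapping")
    if (any(o != seq_len(nrow(windows))))
      stopf("windows must be given in increasing order")
  }
  if (any(windows < SPECTRAL_RANGE[1]) || any(windows > SPECTRAL_RANGE[2]))
    stopf("windows must lie within the modeled spectral range [%d, %d] nm",
          SPECTRAL_RANGE[1], SPECTRAL_RANGE[2])
  windows
}

#' Default detection windows: 24 contiguous 10-nm bins over 500--740 nm
#' @return a 24 x 2 matrix of window edges in nm.
#' @export
default_windows <- function() {
  starts <- seq(500, 730, by = 10)
  matrix(c(starts, starts + 10), ncol = 2)
}

#' Default laser lines (nm)
#' @export
default_lasers <- function() c(488, 561, 639)

#' Built-in fluorophore set
#'
#' The donor (AF488, quantum yield 0.92) and the three acceptors used for
#' multiplex FRET (AF546, AF594, AF647).  Peaks follow vendor-typical
#' values (519, 573, 617, 668 nm); excitation efficiencies encode the
#' cross-excitation that gives rise to spectral bleed-through.
#'
#' @return named list of [fluorophore_spec()] objects.
#' @export
default_fluorophores <- function() {
  list(
    AF488 = fluorophore_spec("AF488", 519, 22,
                             c("488" = 1.00, "561" = 0.02, "639" = 0.00),
                             quantum_yield = 0.92),
    AF546 = fluorophore_spec("AF546", 573, 25,
                             c("488" = 0.10, "561" = 1.00, "639" = 0.01),
                             quantum_yield = 0.79),
    AF594 = fluorophore_spec("AF594", 617, 27,
                             c("488" = 0.05, "561" = 0.45, "639" = 0.05),
                             quantum_yield = 0.66),
    AF647 = fluorophore_spec("AF647", 668, 25,
                             c("488" = 0.03, "561" = 0.08, "639" = 1.00),
                             quantum_yield = 0.33)
  )
}

#' Theoretical spectral fingerprint of a component
#'
#' Concatenates, across laser blocks, the excitation-weighted emission of
#' the component in each detection window, L1-normalized.  For a FRET pair
#' the component is excited through the donor but emits with the acceptor
#' spectrum; pass `excitation_of` to override the excitation side.
#'
#' @param fluor emission-side [fluorophore_spec()].
#' @param windows detection windows (see [default_windows()]).
#' @param lasers laser lines in nm.
#' @param excitation_of optional [fluorophore_spec()] providing the
#'   excitation efficiencies (defaults to `fluor` itself).
#' @return a `fingerprint` object (see [extract_fingerprint()]).
#' @export
component_fingerprint <- function(fluor, windows = default_windows(),
                                  lasers = default_lasers(),
                                  excitation_of = NULL) {
  windows <- as_window_matrix(windows)
  exc_src <- if (is.null(excitation_of)) fluor else excitation_of
  em <- emission_in_windows(fluor, windows)
  vec <- unlist(lapply(lasers, function(L) {
    eff <- exc_src$excitation_efficiency[as.character(L)]
    if (is.na(eff)) eff <- 0
    as.numeric(eff) * em
  }))
  new_fingerprint(vec, name = fluor$name, lasers = lasers, windows = windows)
}
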