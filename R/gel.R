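#' Quantify gel-shift lanes
#'
#' From per-lane band intensities, computes for each lane:
#' * `relative_shift` = shifted / (shifted + free), the fraction of RNA
#'   bound (also the hybridized fraction on annealing gels);
#' * `fret_of_shift` = FRET-channel intensity of the shifted band;
#' * `fret_per_shift` = FRET-channel shifted-band intensity divided by
#'   RNA-channel shifted-band intensity.
#'
#' @param lanes data.frame with columns `lane` (id), `band_free`,
#'   `band_shifted` (RNA-channel intensities) and optionally `band_fret`
#'   (FRET-channel shifted-band intensity).
#' @return data.frame: lane, relative_shift, hybridized_fraction,
#'   fret_of_shift, fret_per_shift.
#' @export
gel_metrics <- function(lanes) {
  req <- c("band_free", "band_shifted")
  if (!is.data.frame(lanes) || !all(req %in% names(lanes)))
    stopf("`lanes` must be a data.frame with columns band_free, band_shifted")
  if (!"lane" %in% names(lanes)) lanes$lane <- seq_len(nrow(lanes))
  if (!"band_fret" %in% names(lanes)) lanes$band_fret <- NA_real_
  with(lanes, {
    if (any(c(band_free, band_shifted) < 0, na.rm = TRUE) ||
        any(band_fret < 0, na.rm = TRUE))
      stopf("band intensities must be >= 0")
    tot <- band_free + band_shifted
    if (any(tot == 0))
      stopf("relative shift undefined for lane(s) %s: shifted + free = 0",
            paste(lane[tot == 0], collapse = ", "))
    shift <- band_shifted / tot
    data.frame(lane = lane,
               relative_shift = shift,
               hybridized_fraction = shift,
               fret_of_shift = band_fret,
               fret_per_shift = ifelse(band_shifted > 0,
                                       band_fret / band_shifted, NA_real_))
  })
}

#' Degree of labeling from absorbance readings
#'
#' Average dyes per protein molecule:
#' `DOL = (A_dye / eps_dye) / ((A280 - cf * A_dye) / eps_protein)`.
#' The dye's absorbance at 280 nm is removed via the vendor correction
#' factor `cf` before converting to protein concentration.  The default
#' protein extinction coefficient (12045 M^-1 cm^-1) is that of the
#' dsRNA-binding domain used as the FRET donor carrier.
#'
#' @param a_dye absorbance at the dye maximum.
#' @param a280 absorbance at 280 nm.
#' @param eps_dye dye extinction coefficient, M^-1 cm^-1 (vendor value).
#' @param eps_protein protein extinction coefficient, M^-1 cm^-1.
#' @param cf dye correction factor at 280 nm (vendor value).
#' @return dyes per protein (dimensionless).
#' @export
degree_of_labeling <- function(a_dye, a280, eps_dye, eps_protein = 12045,
                               cf = 0.11) {
  if (any(c(a_dye, a280) < 0)) stopf("absorbances must be >= 0")
  if (eps_dye <= 0 || eps_protein <= 0)
    stopf("extinction coefficients must be > 0")
  if (a_dye == 0) return(0)
  corrected <- a280 - cf * a_dye
  if (corrected <= 1e-12)
    stopf("corrected protein absorbance <= 0 (A280 = %g, cf * A_dye = %g); over-labeled or implausible input",
          a280, cf * a_dye)
  (a_dye / eps_dye) / (corrected / eps_protein)
}
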