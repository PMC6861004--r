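# Forward models: render a ground-truth scene into detector images.
#
# Noiseless expectation per pixel (density d, signal scale S, efficiency E):
#   donor channel      I_DD = bg + S*d*(1 - E)
#   acceptor channel   I_AA = bg + S*d*q_acc
#   raw FRET channel   I_DA = bg + sens_gain*S*d*E + a*(I_DD - bg) + b*(I_AA - bg)
# Noise: counts = Poisson(gain * mu) / gain + N(0, read_noise_sd), then
# clipped to [0, 2^bit_depth - 1].

apply_detector_noise <- function(mu, config, noise = TRUE) {
  sat <- saturation_value(config$bit_depth)
  if (noise) {
    n <- length(mu)
    shot <- stats::rpois(n, pmax(config$gain * mu, 0)) / config$gain
    out <- shot + stats::rnorm(n, 0, config$read_noise_sd)
  } else {
    out <- mu
  }
  matrix(pmin(pmax(out, 0), sat), nrow(mu), ncol(mu))
}

#' Render a scene into a three-cube sensitized-emission set
#'
#' Produces the registered donor-excitation/donor-emission (`I_DD`),
#' donor-excitation/acceptor-emission (`I_DA`, the raw FRET channel) and
#' acceptor-excitation/acceptor-emission (`I_AA`) images.  Single-label
#' control specimens are rendered with `mode = "donor_only"` (no acceptor,
#' hence no FRET) or `mode = "acceptor_only"`.
#'
#' @param scene a [simulate_scene()] result.
#' @param donor,acceptor [fluorophore_spec()] objects; only the acceptor's
#'   relative brightness (quantum yield ratio) enters the three-cube model.
#' @param mode `"full"`, `"donor_only"` or `"acceptor_only"`.
#' @param noise apply the Poisson-Gaussian detector model (`TRUE`) or
#'   return clipped expectations (`FALSE`).
#' @param seed RNG seed; defaults to `scene$seed + 1` so renders and scene
#'   geometry draw from independent streams.
#' @return a [three_cube()] set.
#' @export
render_three_cube <- function(scene,
                              donor = default_fluorophores()$AF488,
                              acceptor = default_fluorophores()$AF647,
                              mode = c("full", "donor_only", "acceptor_only"),
                              noise = TRUE,
                              seed = scene$seed + 1L) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  mode <- match.arg(mode)
  cfg <- scene$config
  dens <- scene_density(scene)
  S <- cfg$signal_scale
  has_donor <- mode != "acceptor_only"
  has_acceptor <- mode != "donor_only"
  E <- if (mode == "full") cfg$fret_efficiency else 0
  q_rel <- acceptor$quantum_yield / donor$quantum_yield

  dd_sig <- if (has_donor) S * dens * (1 - E) else dens * 0
  aa_sig <- if (has_acceptor) S * dens * q_rel else dens * 0
  sens <- if (mode == "full") cfg$sens_gain * S * dens * E else dens * 0
  da_sig <- sens + cfg$bleedthrough_a * dd_sig + cfg$bleedthrough_b * aa_sig

  bg <- cfg$background
  with_seed(seed, {
    I_DD <- apply_detector_noise(dd_sig + bg, cfg, noise)
    I_DA <- apply_detector_noise(da_sig + bg, cfg, noise)
    I_AA <- apply_detector_noise(aa_sig + bg, cfg, noise)
    three_cube(I_DD, I_DA, I_AA, bit_depth = cfg$bit_depth)
  })
}

#' Render a scene into a lambda stack
#'
#' For each laser, renders one image per detection window.  Each
#' fluorescent component contributes linearly:
#' `expectation = sum_components amplitude * fingerprint`.  When a
#' donor/acceptor pair is given, probe-bound donor is quenched by the
#' scene's FRET efficiency and a distinct FRET component (acceptor-shaped
#' emission excited through the donor) is added, so the stack contains the
#' acceptor bleed-through that linear unmixing cannot remove.
#'
#' @param scene a [simulate_scene()] result.
#' @param fluors list of [fluorophore_spec()]s present on the transcripts.
#' @param windows detection windows, see [default_windows()].
#' @param lasers laser lines in nm, see [default_lasers()].
#' @param pair `c(donor_index, acceptor_index)` into `fluors` enabling the
#'   FRET component; `NULL` disables FRET.  Defaults to `c(1, 2)` when two
#'   fluorophores are supplied.
#' @param noise,seed as in [render_three_cube()].
#' @return a [lambda_stack()].
#' @export
render_lambda_stack <- function(scene, fluors,
                                windows = default_windows(),
                                lasers = default_lasers(),
                                pair = if (length(fluors) == 2L) c(1L, 2L) else NULL,
                                noise = TRUE,
                                seed = scene$seed + 2L) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  if (length(lasers) == 0) stopf("`lasers` must be non-empty")
  if (inherits(fluors, "fluorophore_spec")) fluors <- list(fluors)
  windows <- as_window_matrix(windows)
  cfg <- scene$config
  dens <- scene_density(scene)
  S <- cfg$signal_scale
  E <- if (is.null(pair)) 0 else cfg$fret_efficiency

  # per-component (amplitude image, unnormalized spectral vector)
  comps <- list()
  for (i in seq_along(fluors)) {
    quench <- if (!is.null(pair) && i == pair[1]) (1 - E) else 1
    comps[[length(comps) + 1L]] <- list(
      amp = S * dens * quench * fluors[[i]]$quantum_yield,
      vec = raw_component_vector(fluors[[i]], windows, lasers))
  }
  if (!is.null(pair) && E > 0) {
    comps[[length(comps) + 1L]] <- list(
      amp = cfg$sens_gain * S * dens * E * fluors[[pair[2]]]$quantum_yield,
      vec = raw_component_vector(fluors[[pair[2]]], windows, lasers,
                                 excitation_of = fluors[[pair[1]]]))
  }

  nw <- nrow(windows)
  blocks <- stats::setNames(vector("list", length(lasers)), as.character(lasers))
  with_seed(seed, {
    for (li in seq_along(lasers)) {
      imgs <- vector("list", nw)
      for (wi in seq_len(nw)) {
        ch <- (li - 1L) * nw + wi
        mu <- Reduce(`+`, lapply(comps, function(cp) cp$amp * cp$vec[ch]),
                     matrix(0, nrow(dens), ncol(dens)))
        imgs[[wi]] <- apply_detector_noise(mu + cfg$background, cfg, noise)
      }
      blocks[[li]] <- imgs
    }
    lambda_stack(blocks, windows, bit_depth = cfg$bit_depth)
  })
}

# unnormalized per-channel weights: excitation efficiency x emission fraction
raw_component_vector <- function(fluor, windows, lasers, excitation_of = NULL) {
  exc_src <- if (is.null(excitation_of)) fluor else excitation_of
  em <- emission_in_windows(fluor, windows)
  unlist(lapply(lasers, function(L) {
    eff <- exc_src$excitation_efficiency[as.character(L)]
    if (is.na(eff)) eff <- 0
    as.numeric(eff) * em
  }))
}
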