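#' Configuration for a simulated gel-shift binding series
#'
#' Generative counterpart of the Hill model fitted by [fit_hill()]:
#' `theta = eps * c^n / (c^n + kd^n)` plus Gaussian measurement noise,
#' truncated to \[0, 1\].
#'
#' @param kd dissociation constant, nM (> 0).
#' @param hill_n Hill coefficient (> 0).
#' @param eps observed maximum fraction bound, in (0, 1\].
#' @param concentrations strictly increasing protein concentrations, nM.
#' @param noise_sd Gaussian noise on the fraction bound.
#' @param seed integer RNG seed.
#' @export
emsa_sim_config <- function(kd, hill_n = 1, eps = 1,
                            concentrations = signif(10^seq(0, 3, length.out = 12), 4),
                            noise_sd = 0, seed = 1) {
  if (kd <= 0) stopf("`kd` must be > 0")
  if (hill_n <= 0) stopf("`hill_n` must be > 0")
  if (eps <= 0 || eps > 1) stopf("`eps` must be in (0, 1]")
  if (any(concentrations < 0) || any(diff(concentrations) <= 0))
    stopf("`concentrations` must be >= 0 and strictly increasing")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  structure(list(kd = kd, hill_n = hill_n, eps = eps,
                 concentrations = concentrations, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "emsa_sim_config")
}

#' Hill binding curve
#'
#' Fraction bound at protein concentration `conc`:
#' `eps * conc^n / (conc^n + kd^n)`.
#'
#' @param conc concentration, nM.
#' @param eps maximum fraction bound.
#' @param kd dissociation constant, nM.
#' @param n Hill coefficient.
#' @export
hill_theta <- function(conc, eps, kd, n) {
  # compute in log space so large conc^n cannot overflow
  ifelse(conc == 0, 0, eps / (1 + exp(n * (log(kd) - log(conc)))))
}

#' Simulate a gel-shift binding series
#'
#' @param config an [emsa_sim_config()].
#' @param replicate replicate identifier stored with the series.
#' @return a `binding_series` data.frame with columns `concentration` and
#'   `theta` (fraction bound in \[0, 1\]).
#' @export
simulate_emsa <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "emsa_sim_config"))
  with_seed(config$seed, {
    clean <- hill_theta(config$concentrations, config$eps, config$kd, config$hill_n)
    theta <- clean + stats::rnorm(length(clean), 0, config$noise_sd)
    theta <- pmin(pmax(theta, 0), 1)
    binding_series(config$concentrations, theta, replicate = replicate)
  })
}

#' Construct a binding series
#'
#' @param concentrations strictly increasing concentrations, nM.
#' @param theta fraction bound per concentration, each in \[0, 1\].
#' @param replicate replicate identifier.
#' @export
binding_series <- function(concentrations, theta, replicate = 1L) {
  if (length(concentrations) != length(theta))
    stopf("`concentrations` and `theta` must have the same length")
  if (any(diff(concentrations) <= 0))
    stopf("`concentrations` must be strictly increasing")
  if (any(theta < 0 | theta > 1)) stopf("`theta` must lie in [0, 1]")
  structure(data.frame(concentration = concentrations, theta = theta,
                       replicate = replicate),
            class = c("binding_series", "data.frame"))
}
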