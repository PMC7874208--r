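#' Generative parameters of a synthetic larva
#'
#' Phenomenological model of the evoked tail response. Each stimulus cycle
#' draws on a releasable resource pool `R` in `[0, 1]` (standing in for the
#' readily releasable vesicle complement of the vestibular pathway without
#' modeling its biology): a stimulated cycle depletes the pool by
#' `depletion_per_cycle`, a bout of peak amplitude
#' `bout_amplitude_deg * R * (1 - adaptation_rate)^cycle` fires with
#' probability `bout_prob` whenever `R >= response_threshold`, and during
#' rest periods the pool relaxes back toward 1 with time constant
#' `recovery_tau_s`.
#'
#' @param bout_amplitude_deg Peak evoked tail deflection in degrees at full
#'   resource (0 for the mechanotransduction-null phenotype).
#' @param bout_prob Per-cycle probability that a bout fires when resource is
#'   above threshold, in `[0, 1]`.
#' @param adaptation_rate Per-cycle multiplicative decay of bout amplitude
#'   (wild-type stimulus adaptation), in `[0, 1]`.
#' @param startle_rate Per-cycle probability of a spontaneous startle
#'   excursion exceeding 45 degrees, in `[0, 1]`.
#' @param sway_amplitude_deg Amplitude of the passive platform-sway baseline
#'   (degrees), the movement artifact tracked by the rolling median.
#' @param noise_sd_deg Per-frame Gaussian angle noise (degrees).
#' @param pool_init Initial resource `R0` in `[0, 1]`.
#' @param depletion_per_cycle Resource consumed per stimulated cycle
#'   (`delta`), >= 0.
#' @param recovery_tau_s Exponential resource recovery time constant during
#'   rest (`tau_rec`, seconds), >= 0; 0 means instantaneous recovery.
#' @param response_threshold Minimal resource for a bout to occur, in `[0, 1]`.
#' @param seed Integer RNG seed stored with the parameters; used by
#'   [simulate_trace()] unless overridden.
#' @return An object of class `vsr_phenotype`.
#' @seealso [phenotype_wildtype()], [phenotype_null()], [phenotype_synj1()]
#' @export
phenotype_params <- function(bout_amplitude_deg = 30, bout_prob = 0.9,
                             adaptation_rate = 0.015, startle_rate = 0.005,
                             sway_amplitude_deg = 8, noise_sd_deg = 0.8,
                             pool_init = 1, depletion_per_cycle = 0,
                             recovery_tau_s = 5, response_threshold = 0.2,
                             seed = 1L) {
  probs <- c(bout_prob = bout_prob, startle_rate = startle_rate,
             pool_init = pool_init, response_threshold = response_threshold,
             adaptation_rate = adaptation_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("invalid phenotype: probabilities, pool_init, response_threshold and ",
         "adaptation_rate must lie in [0, 1]", call. = FALSE)
  }
  nn <- c(bout_amplitude_deg = bout_amplitude_deg,
          sway_amplitude_deg = sway_amplitude_deg, noise_sd_deg = noise_sd_deg,
          depletion_per_cycle = depletion_per_cycle,
          recovery_tau_s = recovery_tau_s)
  if (any(!is.finite(nn)) || any(nn < 0)) {
    stop("invalid phenotype: amplitudes, noise, depletion and recovery tau ",
         "must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(bout_amplitude_deg = bout_amplitude_deg, bout_prob = bout_prob,
         adaptation_rate = adaptation_rate, startle_rate = startle_rate,
         sway_amplitude_deg = sway_amplitude_deg, noise_sd_deg = noise_sd_deg,
         pool_init = pool_init, depletion_per_cycle = depletion_per_cycle,
         recovery_tau_s = recovery_tau_s,
         response_threshold = response_threshold,
         seed = as.integer(seed)),
    class = "vsr_phenotype"
  )
}

#' Phenotype presets
#'
#' Three canonical parameter sets:
#' \describe{
#'   \item{`phenotype_wildtype()`}{sustained evoked response with mild
#'     per-cycle adaptation and negligible depletion.}
#'   \item{`phenotype_null()`}{mechanotransduction-null: no evoked bouts at
#'     all (e.g. loss of hair-cell tip links); only sway and frame noise.}
#'   \item{`phenotype_synj1()`}{depletion/recovery phenotype: normal initial
#'     bouts, rapid resource rundown (`delta = 0.25` per cycle) and slow
#'     recovery (`tau_rec = 15` s), producing early cessation, long pauses
#'     and a need for tens of seconds of rest.}
#' }
#'
#' @param ... Overrides passed to [phenotype_params()].
#' @return A `vsr_phenotype`.
#' @rdname phenotype_presets
#' @export
phenotype_wildtype <- function(...) {
  phenotype_params(...)
}

#' @rdname phenotype_presets
#' @export
phenotype_null <- function(...) {
  args <- utils::modifyList(
    list(bout_amplitude_deg = 0, bout_prob = 0, startle_rate = 0), list(...))
  do.call(phenotype_params, args)
}

#' @rdname phenotype_presets
#' @export
phenotype_synj1 <- function(...) {
  args <- utils::modifyList(
    list(adaptation_rate = 0, depletion_per_cycle = 0.25,
         recovery_tau_s = 15), list(...))
  do.call(phenotype_params, args)
}

#' @export
print.vsr_phenotype <- function(x, ...) {
  cat(sprintf(
    "VSR phenotype: bout %g deg (p=%g), delta=%g/cycle, tau_rec=%g s, threshold=%g\n",
    x$bout_amplitude_deg, x$bout_prob, x$depletion_per_cycle,
    x$recovery_tau_s, x$response_threshold))
  invisible(x)
}
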