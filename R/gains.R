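#' Cellular component gains for the ERG forward model
#'
#' A `cellular_gains` object collects the per-subject amplitudes,
#' sensitivities and kinetic parameters of the five modelled generators:
#' rod and cone photoreceptor PIII, rod- and cone-driven ON-bipolar PII, the
#' cone-driven OFF-bipolar component, and amacrine-cell oscillatory
#' potentials.  Amplitude-like parameters are in microvolts; times in
#' milliseconds; sensitivities in (photopic cd m^-2 s)^-1 ms^-2.
#'
#' Pathway drive saturates hyperbolically with flash strength
#' (`I / (I + I50)`); the per-pathway half-saturation constants set how the
#' relative ON/OFF balance shifts with flash strength, which is what makes
#' the OFF contribution to the b-wave prominent for the standard
#' light-adapted flash but minor for bright flashes on the blue background.
#'
#' @param rod_pr_max,cone_pr_max Saturated PIII amplitudes (uV).
#' @param rod_sensitivity,cone_sensitivity PIII sensitivity parameters.
#' @param rod_delay,cone_delay Transduction delays (ms).
#' @param on_bipolar_gain ON-bipolar (PII) gain (uV), split between the rod
#'   and cone pathways by `rod_pii_weight` / `cone_pii_weight`.
#' @param off_bipolar_gain Cone OFF-bipolar gain (uV): the full-drive
#'   amplitude of the OFF kernel's early negative lobe (the postreceptoral
#'   share of the cone a-wave); the positive lobe scales as
#'   `off_pos_weight` times this gain.  The per-allele dosage effect acts
#'   multiplicatively on this single gain, so both lobes scale together.
#' @param op_gain Oscillatory-potential gain (uV).
#' @param rod_pii_weight,cone_pii_weight Pathway shares of `on_bipolar_gain`.
#' @param rod_i50,cone_on_i50,off_i50 Half-saturation flash strengths
#'   (photopic cd m^-2 s) of the rod-PII, cone-ON and cone-OFF
#'   (negative-lobe) drives.
#' @param off_pos_i50,off_pos_sat Flash-strength dependence of the OFF
#'   positive lobe: its drive is `I/(I + off_pos_i50) *
#'   off_pos_sat/(off_pos_sat + I)` — a band-pass in flash strength, so
#'   the OFF contribution to the b-wave is prominent for the standard
#'   light-adapted flash but minor for bright flashes (the push-pull
#'   cancellation seen clinically).
#' @param rod_pii_peak,cone_pii_peak ON kernel peak times (ms).
#' @param rod_pii_onset,cone_pii_onset ON kernel synaptic onset delays
#'   (ms): the PII contribution is identically zero before its onset.  The
#'   rod-PII onset (shared by the oscillatory potentials through
#'   `op_onset`) sits at the upper edge of the default a-wave window, so
#'   dark-adapted and rod-isolated a-wave troughs are purely
#'   photoreceptor-driven.
#' @param pii_shape ON kernel shape exponent.
#' @param off_peak_neg,off_peak_pos OFF kernel lobe peak times (ms);
#'   the negative lobe precedes the positive lobe.
#' @param off_shape OFF kernel shape exponent.
#' @param off_pos_weight Amplitude of the OFF positive lobe relative to
#'   `off_bipolar_gain`.
#' @param op_frequency Oscillatory-potential frequency (Hz).
#' @param op_damping Exponential damping rate (ms^-1).
#' @param op_onset Oscillatory-potential onset time (ms).
#' @param white_cone_adapt Single scalar applied to all cone-pathway gains on
#'   the white photopic background (light adaptation).
#' @param flicker_gain Scalar mapping adapted cone-pathway amplitudes to the
#'   steady-state 30-Hz flicker peak-to-trough amplitude.
#'
#' @return An object of class `cellular_gains` (a named list).
#' @seealso [default_gains()], [apply_lesion()]
#' @export
cellular_gains <- function(rod_pr_max, cone_pr_max,
                           rod_sensitivity, cone_sensitivity,
                           rod_delay, cone_delay,
                           on_bipolar_gain, off_bipolar_gain, op_gain,
                           rod_pii_weight, cone_pii_weight,
                           rod_i50, cone_on_i50, off_i50,
                           off_pos_i50, off_pos_sat,
                           rod_pii_peak, cone_pii_peak,
                           rod_pii_onset, cone_pii_onset, pii_shape,
                           off_peak_neg, off_peak_pos, off_shape,
                           off_pos_weight,
                           op_frequency, op_damping, op_onset,
                           white_cone_adapt, flicker_gain) {
  g <- as.list(environment())
  amp <- c("rod_pr_max", "cone_pr_max", "on_bipolar_gain",
           "off_bipolar_gain", "op_gain")
  for (nm in amp) {
    if (!is.finite(g[[nm]]) || g[[nm]] < 0) {
      stop(sprintf("gain `%s` must be finite and >= 0", nm))
    }
  }
  for (nm in c("rod_delay", "cone_delay", "op_onset")) {
    if (g[[nm]] < 0) stop(sprintf("`%s` must be >= 0", nm))
  }
  for (nm in c("rod_pii_peak", "cone_pii_peak", "off_peak_neg",
               "off_peak_pos")) {
    if (g[[nm]] <= 0) stop(sprintf("kernel peak time `%s` must be > 0", nm))
  }
  if (g$rod_pii_onset < 0 || g$cone_pii_onset < 0) {
    stop("PII onsets must be >= 0")
  }
  if (g$rod_pii_peak <= g$rod_pii_onset ||
      g$cone_pii_peak <= g$cone_pii_onset) {
    stop("PII peak times must exceed their onsets")
  }
  if (g$rod_sensitivity <= 0 || g$cone_sensitivity <= 0) {
    stop("sensitivities must be > 0")
  }
  structure(g, class = "cellular_gains")
}

#' Default (group-0) cellular gains
#'
#' The frozen baseline parameterization.  Amplitude gains were calibrated
#' once so that noiseless responses of a baseline subject land near the
#' anchor values used throughout (dark-adapted standard-flash a-wave near
#' 150 uV, light-adapted standard-flash b-wave near 102 uV, cone-driven
#' a-wave at the brightest xenon flash near 56 uV) and reproduce the
#' qualitative waveform features the analysis relies on.
#'
#' @return A `cellular_gains` object.
#' @export
default_gains <- function() {
  cellular_gains(
    rod_pr_max = 160, cone_pr_max = 45,
    rod_sensitivity = 2.6e-3, cone_sensitivity = 2.5e-3,
    rod_delay = 2.5, cone_delay = 1.5,
    on_bipolar_gain = 330, off_bipolar_gain = 15, op_gain = 12,
    rod_pii_weight = 0.80, cone_pii_weight = 2.4,
    rod_i50 = 0.003, cone_on_i50 = 15, off_i50 = 6,
    off_pos_i50 = 1, off_pos_sat = 5,
    rod_pii_peak = 48, cone_pii_peak = 31,
    rod_pii_onset = 28, cone_pii_onset = 14, pii_shape = 4,
    off_peak_neg = 13, off_peak_pos = 34, off_shape = 8,
    off_pos_weight = 13,
    op_frequency = 130, op_damping = 0.12, op_onset = 28,
    white_cone_adapt = 0.5, flicker_gain = 0.60)
}

#' @export
print.cellular_gains <- function(x, ...) {
  cat("<cellular_gains>\n")
  cat(sprintf("  rod PIII: max %.1f uV, S %.2g, delay %.1f ms\n",
              x$rod_pr_max, x$rod_sensitivity, x$rod_delay))
  cat(sprintf("  cone PIII: max %.1f uV, S %.2g, delay %.1f ms\n",
              x$cone_pr_max, x$cone_sensitivity, x$cone_delay))
  cat(sprintf("  ON-bipolar gain %.1f uV (rod %.0f%%, cone %.0f%%), OFF %.1f uV, OP %.1f uV\n",
              x$on_bipolar_gain, 100 * x$rod_pii_weight,
              100 * x$cone_pii_weight, x$off_bipolar_gain, x$op_gain))
  invisible(x)
}

#' Apply a retinal lesion to a set of cellular gains
#'
#' `"crao"` (central retinal artery occlusion) silences every postreceptoral
#' generator — ON-bipolar, OFF-bipolar and oscillatory potentials — while
#' leaving photoreceptor parameters untouched.  `"ccsnb"` (complete
#' congenital stationary night blindness) silences the ON-bipolar pathway
#' only, leaving the OFF pathway intact.  `"none"` is the identity.
#'
#' @param gains A `cellular_gains` object.
#' @param lesion One of `"none"`, `"crao"`, `"ccsnb"`.
#' @return A `cellular_gains` object.
#' @export
apply_lesion <- function(gains, lesion = c("none", "crao", "ccsnb")) {
  stopifnot(inherits(gains, "cellular_gains"))
  lesion <- match.arg(lesion)
  if (lesion == "crao") {
    gains$on_bipolar_gain <- 0
    gains$off_bipolar_gain <- 0
    gains$op_gain <- 0
  } else if (lesion == "ccsnb") {
    gains$on_bipolar_gain <- 0
  }
  gains
}
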