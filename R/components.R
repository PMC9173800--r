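#' Photoreceptor PIII response
#'
#' Saturating-exponential model of the photoreceptor contribution to the
#' a-wave (hyperpolarization following shutoff of the CNG current):
#' `-max_amp * (1 - exp(-I * S * (t - delay)^2))` for `t > delay`, zero
#' before.  Negative-going; its magnitude is nondecreasing in both time and
#' flash strength.
#'
#' @param t Time since flash onset (ms); vectorized.
#' @param flash_strength Flash strength I (photopic cd m^-2 s, >= 0).
#' @param sensitivity Sensitivity S ((cd m^-2 s)^-1 ms^-2, > 0).
#' @param max_amp Saturated amplitude (uV, >= 0).
#' @param delay Transduction delay (ms, >= 0).
#' @return Voltage (uV), same length as `t`.
#' @export
photoreceptor_piii <- function(t, flash_strength, sensitivity, max_amp,
                               delay = 0) {
  if (flash_strength < 0) stop("`flash_strength` must be >= 0")
  if (sensitivity <= 0) stop("`sensitivity` must be > 0")
  if (max_amp < 0) stop("`max_amp` must be >= 0")
  if (delay < 0) stop("`delay` must be >= 0")
  tt <- pmax(t - delay, 0)
  -max_amp * (1 - exp(-flash_strength * sensitivity * tt^2))
}

# unit-peak gamma bump: (t/tp)^n exp(n (1 - t/tp)) for t > 0; peak value 1 at tp
gamma_bump <- function(t, peak_time, shape) {
  out <- numeric(length(t))
  pos <- t > 0
  x <- t[pos] / peak_time
  out[pos] <- x^shape * exp(shape * (1 - x))
  out
}

#' Bipolar-cell kernels
#'
#' ON kernel: a positive gamma bump with unit peak at `peak_time`, scaled by
#' `gain` (the depolarizing PII process behind the b-wave).  OFF kernel: a
#' biphasic difference of two gamma bumps — an early negative lobe (peaking
#' at `off_trough_time`) that adds to the a-wave trough, followed by a later
#' positive lobe (peaking at `peak_time`) that adds to the b-wave region.
#' Shifts in the relative ON/OFF weighting reshape the rising limb of the
#' light-adapted flash response around 25 ms.
#'
#' @param t Time since flash onset (ms); vectorized.
#' @param gain Kernel amplitude (uV, >= 0); for the OFF kernel this is the
#'   positive-lobe amplitude and the negative lobe is
#'   `off_trough_weight * gain`.
#' @param peak_time Peak time (ms, > 0) of the (positive) lobe.
#' @param shape_exponent Gamma shape exponent.
#' @param polarity `"on"` or `"off"`.
#' @param onset Synaptic onset delay (ms): the kernel is identically zero
#'   for `t <= onset` (ON kernel only; the OFF kernel starts at 0).
#' @param off_trough_time Negative-lobe peak time (ms), OFF kernel only;
#'   must precede `peak_time`.
#' @param off_trough_weight Negative-lobe relative amplitude, OFF only.
#' @return Voltage (uV), same length as `t`.
#' @export
bipolar_kernel <- function(t, gain, peak_time, shape_exponent = 3,
                           polarity = c("on", "off"), onset = 0,
                           off_trough_time = peak_time / 2,
                           off_trough_weight = 1) {
  polarity <- match.arg(polarity)
  if (gain < 0) stop("`gain` must be >= 0")
  if (peak_time <= onset) stop("`peak_time` must exceed `onset`")
  if (polarity == "on") {
    return(gain * gamma_bump(t - onset, peak_time - onset, shape_exponent))
  }
  if (off_trough_time <= 0 || off_trough_time >= peak_time) {
    stop("OFF kernel requires 0 < off_trough_time < peak_time")
  }
  gain * (gamma_bump(t, peak_time, shape_exponent) -
            off_trough_weight * gamma_bump(t, off_trough_time, shape_exponent))
}

#' Oscillatory potentials
#'
#' Damped sinusoid superposed on the rising b-wave, standing in for the
#' fast rhythmic wavelets generated by amacrine-cell circuitry.  Zero
#' before `onset`.
#'
#' @param t Time since flash onset (ms); vectorized.
#' @param gain Initial amplitude (uV, >= 0).
#' @param frequency Oscillation frequency (Hz).
#' @param damping Exponential decay rate (ms^-1).
#' @param onset Onset time (ms).
#' @return Voltage (uV), same length as `t`.
#' @export
oscillatory_potentials <- function(t, gain, frequency = 130, damping = 0.12,
                                   onset = 12) {
  if (gain < 0) stop("`gain` must be >= 0")
  out <- numeric(length(t))
  pos <- t > onset
  tt <- t[pos] - onset
  out[pos] <- gain * exp(-damping * tt) * sin(2 * pi * frequency * tt / 1000)
  out
}
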