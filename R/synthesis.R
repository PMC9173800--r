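#' Time grid for synthesized sweeps
#'
#' Uniform sampling grid in ms with time zero at flash onset.  The default
#' (0.5-ms steps, -20 to +250 ms) resolves every measured waveform feature
#' and provides the 20-ms pre-stimulus span required by baseline estimation.
#'
#' @param pre Pre-stimulus span (ms, >= 20 for baseline work).
#' @param post Post-stimulus span (ms).
#' @param dt Sample interval (ms).
#' @return Numeric vector of sample times.
#' @export
trace_grid <- function(pre = 20, post = 250, dt = 0.5) {
  seq(-pre, post, by = dt)
}

#' ERG trace container
#'
#' A uniformly sampled voltage-vs-time sweep with stimulus/subject metadata.
#'
#' @param time Sample times (ms), strictly uniform, zero at flash onset.
#' @param voltage Voltages (uV), same length as `time`.
#' @param meta Named list: typically `stimulus`, `subject_id`, `eye`,
#'   `sweep`, `component`.
#' @return An object of class `erg_trace`.
#' @export
erg_trace <- function(time, voltage, meta = list()) {
  if (length(time) != length(voltage)) {
    stop("`time` and `voltage` lengths differ")
  }
  dt <- diff(time)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-9) {
    stop("`time` must be a strictly uniform grid")
  }
  structure(list(time = time, voltage = voltage, meta = meta),
            class = "erg_trace")
}

#' @export
print.erg_trace <- function(x, ...) {
  cat(sprintf("<erg_trace> %d samples, %.3g to %.3g ms, dt = %.3g ms",
              length(x$time), min(x$time), max(x$time),
              if (length(x$time) > 1) x$time[2] - x$time[1] else NA_real_))
  if (!is.null(x$meta$stimulus)) cat(sprintf(", stimulus '%s'", x$meta$stimulus))
  if (!is.null(x$meta$component)) cat(sprintf(", component '%s'", x$meta$component))
  cat("\n")
  invisible(x)
}

#' @export
plot.erg_trace <- function(x, ..., xlab = "Time (ms)", ylab = "Voltage (uV)") {
  graphics::plot(x$time, x$voltage, type = "l", xlab = xlab, ylab = ylab, ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

# hyperbolic drive saturation of a pathway with flash strength
drive_sat <- function(I, i50) I / (I + i50)

# cone OFF component: biphasic kernel with per-lobe flash-strength drives
off_component <- function(time, g, dr_neg, dr_pos) {
  pos_amp <- g$off_bipolar_gain * g$off_pos_weight * dr_pos
  neg_amp <- g$off_bipolar_gain * dr_neg
  if (pos_amp <= 0 && neg_amp <= 0) return(numeric(length(time)))
  if (pos_amp <= 0) {
    return(-neg_amp * gamma_bump(time, g$off_peak_neg, g$off_shape))
  }
  bipolar_kernel(time, pos_amp, g$off_peak_pos, g$off_shape, "off",
                 off_trough_time = g$off_peak_neg,
                 off_trough_weight = neg_amp / pos_amp)
}

# effective per-component amplitudes and factors for a stimulus
component_setup <- function(stimulus, gains, lesion, rod_suppression) {
  g <- apply_lesion(gains, lesion)
  I <- stimulus$flash_strength
  on_background <- stimulus$background_kind != "dark"
  rod_factor <- if (on_background) 1 - rod_suppression else 1
  cone_factor <- if (stimulus$background_kind == "white_photopic")
    g$white_cone_adapt else 1
  list(g = g, I = I,
       rod_factor = rod_factor, cone_factor = cone_factor,
       dr_rod = drive_sat(I, g$rod_i50),
       dr_cone_on = drive_sat(I, g$cone_on_i50),
       dr_off_neg = drive_sat(I, g$off_i50),
       dr_off_pos = drive_sat(I, g$off_pos_i50) *
         g$off_pos_sat / (g$off_pos_sat + I))
}

#' Synthesize a noiseless single-flash ERG response
#'
#' Sums six labelled cellular components on a common grid: rod and cone
#' photoreceptor PIII, rod- and cone-driven ON-bipolar PII, the biphasic
#' cone OFF-bipolar component and oscillatory potentials.  On the blue
#' rod-saturating and white photopic backgrounds every rod-pathway
#' component (rod PIII, rod-driven PII, and the oscillatory potentials,
#' which are modelled as rod-pathway amacrine activity) is multiplied by
#' `1 - rod_suppression`; the default `rod_suppression = 1` is the
#' idealized mode in which rod suppression by the background is complete.
#' On the white photopic background all cone-pathway components are scaled
#' by the single light-adaptation scalar `white_cone_adapt`.  Oscillatory
#' potentials additionally require an intact ON pathway (amacrine cells
#' are driven through ON bipolar cells), so they vanish under either
#' lesion.
#'
#' @param stimulus A [stimulus_spec()] with `mode = "single_flash"`.
#' @param gains A [cellular_gains()] object.
#' @param lesion `"none"`, `"crao"` or `"ccsnb"` (see [apply_lesion()]).
#' @param time Sample grid (ms), see [trace_grid()].
#' @param rod_suppression Fraction of the rod pathway suppressed by a
#'   non-dark background, in `[0, 1]`; 1 = idealized complete suppression.
#' @param meta Extra metadata stored on the returned traces.
#' @return A list with `trace` (the summed `erg_trace`) and `components`
#'   (named list of component `erg_trace`s: `rod_pr`, `cone_pr`, `rod_on`,
#'   `cone_on`, `cone_off`, `op`).  The sum equals the component sum
#'   exactly.
#' @export
synthesize_flash_response <- function(stimulus, gains, lesion = "none",
                                      time = trace_grid(),
                                      rod_suppression = 1,
                                      meta = list()) {
  stopifnot(inherits(stimulus, "stimulus_spec"))
  if (stimulus$mode != "single_flash") {
    stop("flicker-mode stimulus: use synthesize_flicker_response()")
  }
  if (rod_suppression < 0 || rod_suppression > 1) {
    stop("`rod_suppression` must be in [0, 1]")
  }
  s <- component_setup(stimulus, gains, lesion, rod_suppression)
  g <- s$g

  comp <- list(
    rod_pr = s$rod_factor *
      photoreceptor_piii(time, s$I, g$rod_sensitivity, g$rod_pr_max,
                         g$rod_delay),
    cone_pr = s$cone_factor *
      photoreceptor_piii(time, s$I, g$cone_sensitivity, g$cone_pr_max,
                         g$cone_delay),
    rod_on = s$rod_factor *
      bipolar_kernel(time, g$on_bipolar_gain * g$rod_pii_weight * s$dr_rod,
                     g$rod_pii_peak, g$pii_shape, "on",
                     onset = g$rod_pii_onset),
    cone_on = s$cone_factor *
      bipolar_kernel(time, g$on_bipolar_gain * g$cone_pii_weight *
                       s$dr_cone_on,
                     g$cone_pii_peak, g$pii_shape, "on",
                     onset = g$cone_pii_onset),
    cone_off = s$cone_factor *
      off_component(time, g, s$dr_off_neg, s$dr_off_pos),
    op = s$rod_factor * (g$on_bipolar_gain > 0) *
      oscillatory_potentials(time, g$op_gain * s$dr_rod, g$op_frequency,
                             g$op_damping, g$op_onset))

  total <- Reduce(`+`, comp)
  base_meta <- c(meta, list(stimulus = stimulus$label, lesion = lesion))
  list(
    trace = erg_trace(time, total, base_meta),
    components = lapply(stats::setNames(names(comp), names(comp)), function(nm)
      erg_trace(time, comp[[nm]], c(base_meta, list(component = nm)))))
}

#' Synthesize a steady-state 30-Hz flicker response
#'
#' The light-adapted flicker response is modelled directly in its periodic
#' steady state: a sinusoid at exactly 30 Hz (period 1000/30 ms) starting
#' at flash onset, with peak-to-trough amplitude
#' `flicker_gain * cone_adapt * (0.25 cone_pr_max + cone ON amplitude +
#' cone OFF amplitude)` at the per-flash drives.  The rod pathway
#' contributes nothing (the stimulus is delivered on the white photopic
#' background).
#'
#' @inheritParams synthesize_flash_response
#' @param stimulus A [stimulus_spec()] with `mode = "flicker_30hz"`.
#' @return An `erg_trace` (zero before flash onset).
#' @export
synthesize_flicker_response <- function(stimulus, gains, lesion = "none",
                                        time = trace_grid(),
                                        meta = list()) {
  stopifnot(inherits(stimulus, "stimulus_spec"))
  if (stimulus$mode != "flicker_30hz") {
    stop("single-flash stimulus: use synthesize_flash_response()")
  }
  s <- component_setup(stimulus, gains, lesion, rod_suppression = 1)
  g <- s$g
  amp <- g$flicker_gain * s$cone_factor *
    (0.25 * g$cone_pr_max +
       g$on_bipolar_gain * g$cone_pii_weight * s$dr_cone_on +
       g$off_bipolar_gain * (s$dr_off_neg +
                               g$off_pos_weight * s$dr_off_pos))
  v <- ifelse(time >= 0, (amp / 2) * sin(2 * pi * 30 * time / 1000), 0)
  erg_trace(time, v, c(meta, list(stimulus = stimulus$label, lesion = lesion)))
}

# run a function with a temporary RNG state derived from `seed`
with_seed <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fun()
}

#' Add recording noise to a trace
#'
#' White Gaussian noise per sample plus an optional slow baseline drift
#' (a random offset-plus-slope component over the sweep).  Reproducible
#' under a fixed seed.
#'
#' @param trace An `erg_trace`.
#' @param noise_sd Per-sample white-noise SD (uV, >= 0).
#' @param drift_sd SD of the random drift offset and end-to-end excursion
#'   (uV, >= 0).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return An `erg_trace`.
#' @export
add_noise <- function(trace, noise_sd, drift_sd = 0, seed = NULL) {
  stopifnot(inherits(trace, "erg_trace"))
  if (noise_sd < 0 || drift_sd < 0) stop("noise SDs must be >= 0")
  n <- length(trace$time)
  with_seed(seed, function() {
    v <- trace$voltage
    if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)
    if (drift_sd > 0) {
      span <- max(trace$time) - min(trace$time)
      cc <- stats::rnorm(2, 0, drift_sd)
      v <- v + cc[1] + cc[2] * (trace$time - min(trace$time)) / span
    }
    erg_trace(trace$time, v, trace$meta)
  })
}
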