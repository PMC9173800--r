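#' Estimate the pre-stimulus baseline
#'
#' Arithmetic mean of the samples in the 20 ms immediately preceding flash
#' delivery (times in `[-20, 0)` ms).
#'
#' @param trace An `erg_trace` whose grid spans at least 20 ms before 0.
#' @return Baseline voltage (uV).
#' @export
estimate_baseline <- function(trace) {
  stopifnot(inherits(trace, "erg_trace"))
  sel <- trace$time >= -20 & trace$time < 0
  if (min(trace$time) > -20 + 1e-9 || !any(sel)) {
    stop("trace has less than 20 ms of pre-stimulus data")
  }
  mean(trace$voltage[sel])
}

#' Reject artifact-contaminated sweeps
#'
#' A sweep is rejected when its absolute voltage exceeds `abs_cap` or when
#' the RMS of its deviation from the pointwise median sweep exceeds `k`
#' times the robust spread of those RMS deviations (median + k * MAD).  If
#' every sweep fails, the single sweep with the smallest RMS deviation is
#' retained and flagged, so that averaging always has an input.
#'
#' @param sweeps A list of `erg_trace` sweeps on a common grid.
#' @param abs_cap Absolute voltage cap (uV).
#' @param k Robust-deviation multiplier.
#' @return A list with `kept` (list of traces), `log` (data frame with one
#'   row per sweep: rms deviation, exceeded cap, rejected) and
#'   `all_failed` (logical flag).
#' @export
reject_artifacts <- function(sweeps, abs_cap = 1000, k = 5) {
  if (!length(sweeps)) stop("no sweeps supplied")
  V <- vapply(sweeps, function(s) s$voltage, numeric(length(sweeps[[1]]$time)))
  med <- row_medians(V)
  rms <- sqrt(colMeans((V - med)^2))
  over_cap <- vapply(seq_len(ncol(V)),
                     function(j) any(abs(V[, j]) > abs_cap), NA)
  spread <- stats::mad(rms, constant = 1.4826)
  thr <- stats::median(rms) + k * max(spread, 1e-12)
  reject <- over_cap | rms > thr
  all_failed <- all(reject)
  if (all_failed) {
    keep_one <- which.min(rms)
    reject[keep_one] <- FALSE
  }
  list(kept = sweeps[!reject],
       log = data.frame(sweep = seq_along(sweeps), rms_dev = rms,
                        over_cap = over_cap, rejected = reject),
       all_failed = all_failed)
}

# vectorized row-wise median: bubble sorting network over columns
# (pmin/pmax on whole columns), O(k^2) vector ops instead of one
# median() call per sample
row_medians <- function(V) {
  k <- ncol(V)
  if (k == 1L) return(V[, 1])
  if (k > 16L) return(apply(V, 1, stats::median))
  for (i in seq_len(k - 1L)) {
    for (j in seq_len(k - i)) {
      lo <- pmin(V[, j], V[, j + 1L])
      hi <- pmax(V[, j], V[, j + 1L])
      V[, j] <- lo; V[, j + 1L] <- hi
    }
  }
  if (k %% 2L == 1L) V[, (k + 1L) %/% 2L] else
    (V[, k %/% 2L] + V[, k %/% 2L + 1L]) / 2
}

#' Average sweeps on a common grid
#'
#' Pointwise mean.  Sweep-to-trace averaging happens within eye; feature
#' values are then measured per eye and averaged across eyes (see
#' [extract_features()]), while trace-level eye averages are available for
#' display.
#'
#' @param traces A list of `erg_trace`s on identical grids.
#' @return An `erg_trace`.
#' @export
average_traces <- function(traces) {
  if (!length(traces)) stop("no traces supplied")
  t0 <- traces[[1]]$time
  for (tr in traces) {
    if (length(tr$time) != length(t0) || any(abs(tr$time - t0) > 1e-9)) {
      stop("trace grids differ")
    }
  }
  V <- vapply(traces, function(s) s$voltage, numeric(length(t0)))
  erg_trace(t0, rowMeans(V), traces[[1]]$meta)
}

#' Measure the a-wave
#'
#' Trough = minimum voltage within the a-window (default 3-28 ms);
#' amplitude = baseline - trough, reported positive and floored at 0;
#' peak time = time of the minimum (earliest sample wins ties).
#'
#' @param trace An `erg_trace`.
#' @param baseline Baseline voltage (uV), see [estimate_baseline()].
#' @param window Search window `c(lo, hi)` in ms.
#' @return List with `amplitude` (uV), `peak_time` (ms) and `trough`
#'   (absolute trough voltage, used by [measure_b_wave()]).
#' @export
measure_a_wave <- function(trace, baseline, window = c(3, 28)) {
  sel <- which(trace$time >= window[1] & trace$time <= window[2])
  if (!length(sel)) stop("a-window lies outside the trace")
  v <- trace$voltage[sel]
  i <- which.min(v)          # which.min returns the earliest minimum
  list(amplitude = max(baseline - v[i], 0),
       peak_time = trace$time[sel[i]],
       trough = v[i])
}

#' Measure the b-wave
#'
#' Amplitude = (maximum voltage within the b-window, default 10-80 ms)
#' minus the a-wave trough voltage (trough-to-peak convention); when the
#' a-wave is absent (dim flashes) the baseline plays the role of the
#' trough.  Peak time = time of the maximum, earliest sample wins ties.
#'
#' @param trace An `erg_trace`.
#' @param baseline Baseline voltage (uV).
#' @param a_window a-wave search window (ms); ignored when
#'   `has_a_wave = FALSE`.
#' @param b_window b-wave search window (ms).
#' @param has_a_wave Whether an a-wave trough is defined for this stimulus.
#' @return List with `amplitude` (uV) and `peak_time` (ms).
#' @export
measure_b_wave <- function(trace, baseline, a_window = c(3, 28),
                           b_window = c(10, 80), has_a_wave = TRUE) {
  if (a_window[1] > b_window[1] || b_window[1] > b_window[2]) {
    stop("windows must be ordered")
  }
  sel <- which(trace$time >= b_window[1] & trace$time <= b_window[2])
  if (!length(sel)) stop("b-window lies outside the trace")
  trough <- if (has_a_wave) {
    measure_a_wave(trace, baseline, a_window)$trough
  } else baseline
  v <- trace$voltage[sel]
  i <- which.max(v)
  list(amplitude = max(v[i] - trough, 0), peak_time = trace$time[sel[i]])
}

#' Measure the steady-state flicker amplitude
#'
#' Discards the first 30-Hz cycle after flash onset and returns the mean
#' peak-to-trough amplitude over the remaining complete cycles.
#'
#' @param trace An `erg_trace` of a 30-Hz flicker response.
#' @return Amplitude (uV).
#' @export
measure_flicker_amplitude <- function(trace) {
  period <- 1000 / 30
  t_end <- max(trace$time)
  n_cycles <- floor((t_end - period) / period)
  if (n_cycles < 2) stop("fewer than 2 complete steady-state cycles")
  amps <- vapply(seq_len(n_cycles), function(k) {
    lo <- period * k; hi <- period * (k + 1)
    sel <- trace$time >= lo & trace$time < hi
    diff(range(trace$voltage[sel]))
  }, 0)
  mean(amps)
}

#' Isolate the rod-driven response by subtraction
#'
#' Pointwise subtraction of the response to a flash delivered on the
#' rod-saturating blue background (cone-driven) from the response to the
#' identical flash delivered in the dark (rod- plus cone-driven), yielding
#' the estimated dark-adapted rod-driven response.
#'
#' @param dark_trace,blue_background_trace `erg_trace`s recorded to
#'   identical flashes on a common grid; the stimulus flash strengths (in
#'   `meta$flash_strength`, when present) must match.
#' @return An `erg_trace`; `meta$parents` records both source labels.
#' @export
isolate_rod_response <- function(dark_trace, blue_background_trace) {
  a <- dark_trace; b <- blue_background_trace
  if (length(a$time) != length(b$time) || any(abs(a$time - b$time) > 1e-9)) {
    stop("trace grids differ")
  }
  fa <- a$meta$flash_strength; fb <- b$meta$flash_strength
  if (!is.null(fa) && !is.null(fb) && !isTRUE(all.equal(fa, fb))) {
    stop("flash strengths differ: subtraction is defined for identical flashes")
  }
  erg_trace(a$time, a$voltage - b$voltage,
            list(stimulus = paste0(a$meta$stimulus, " minus ",
                                   b$meta$stimulus),
                 component = "rod_isolated",
                 parents = c(a$meta$stimulus, b$meta$stimulus)))
}

# stimulus labels for which no a-wave is reported (dim dark-adapted flash)
has_a_wave_for <- function(label) !identical(label, "DA 0.01")

# measure features on a single averaged trace for one stimulus
measure_trace_features <- function(trace, label, mode,
                                   a_window = c(3, 28), b_window = c(10, 80)) {
  if (mode == "flicker_30hz") {
    return(data.frame(parameter = paste0(label, " peak"),
                      value = measure_flicker_amplitude(trace)))
  }
  bl <- estimate_baseline(trace)
  out <- list()
  if (has_a_wave_for(label)) {
    aw <- measure_a_wave(trace, bl, a_window)
    out[[length(out) + 1L]] <- data.frame(
      parameter = c(paste0(label, " a-wave"), paste0(label, " a-time")),
      value = c(aw$amplitude, aw$peak_time))
  }
  bw <- measure_b_wave(trace, bl, a_window, b_window,
                       has_a_wave = has_a_wave_for(label))
  out[[length(out) + 1L]] <- data.frame(
    parameter = c(paste0(label, " b-wave"), paste0(label, " b-time")),
    value = c(bw$amplitude, bw$peak_time))
  do.call(rbind, out)
}

#' Extract the ERG feature set from a recording session
#'
#' For each stimulus: sweeps are artifact-screened and averaged within
#' eye; the a-wave, b-wave (or flicker peak) parameters are measured on
#' each eye's average; and the two eyes' parameter values are averaged.
#' Rod-isolated a-waves are computed for each xenon flash strength by
#' subtracting the blue-background eye-average from the dark eye-average
#' (per eye, then parameter-averaged across eyes).
#'
#' @param session An `erg_session` from [simulate_session()].
#' @param protocol The protocol used to record it (named list of
#'   [stimulus_spec()]).
#' @param a_window,b_window Measurement windows (ms).
#' @param abs_cap,k Artifact-rejection settings, see [reject_artifacts()].
#' @return A list with `features` (data frame: subject_id, parameter,
#'   value), `rejection_log` (data frame) and `eye_averages` (list of
#'   per-stimulus, per-eye averaged `erg_trace`s).
#' @export
extract_features <- function(session, protocol,
                             a_window = c(3, 28), b_window = c(10, 80),
                             abs_cap = 1000, k = 5) {
  stopifnot(inherits(session, "erg_session"))
  eye_avg <- list()
  rej_rows <- list()
  feat_rows <- list()
  for (label in intersect(names(protocol), names(session$sweeps))) {
    stim <- protocol[[label]]
    per_eye <- list()
    for (eye in c("RE", "LE")) {
      rr <- reject_artifacts(session$sweeps[[label]][[eye]], abs_cap, k)
      lg <- rr$log
      lg$subject_id <- session$subject_id
      lg$stimulus <- label; lg$eye <- eye
      rej_rows[[length(rej_rows) + 1L]] <- lg
      avg <- average_traces(rr$kept)
      avg$meta$flash_strength <- stim$flash_strength
      per_eye[[eye]] <- avg
    }
    eye_avg[[label]] <- per_eye
    fe <- lapply(per_eye, measure_trace_features, label = label,
                 mode = stim$mode, a_window = a_window, b_window = b_window)
    merged <- fe$RE
    merged$value <- (fe$RE$value + fe$LE$value) / 2
    feat_rows[[length(feat_rows) + 1L]] <- merged
  }
  # rod isolation for dark/blue xenon pairs present in the session
  for (s in xenon_strengths()) {
    dl <- sprintf("X%g-dark", s); bl <- sprintf("X%g-blue", s)
    if (is.null(eye_avg[[dl]]) || is.null(eye_avg[[bl]])) next
    vals <- vapply(c("RE", "LE"), function(eye) {
      iso <- isolate_rod_response(eye_avg[[dl]][[eye]], eye_avg[[bl]][[eye]])
      bl0 <- estimate_baseline(iso)
      measure_a_wave(iso, bl0, a_window)$amplitude
    }, 0)
    feat_rows[[length(feat_rows) + 1L]] <- data.frame(
      parameter = sprintf("X%g-rod a-wave", s), value = mean(vals))
  }
  features <- do.call(rbind, feat_rows)
  features <- data.frame(subject_id = session$subject_id, features,
                         stringsAsFactors = FALSE)
  rownames(features) <- NULL
  list(features = features,
       rejection_log = do.call(rbind, rej_rows),
       eye_averages = eye_avg)
}
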