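#' Cohort specification for the synthetic twin study
#'
#' Defaults describe the study conditions emulated throughout: roughly 93
#' twin pairs (about 186 analyzed subjects), a heavily female cohort with
#' mean (SD) age 64.2 (9.7) years, a biallelic risk locus with allele
#' frequency 0.5296 (the frequency implied by a 37/101/48 dosage split),
#' and a per-allele multiplicative effect confined to the cone OFF-bipolar
#' gain.
#'
#' @param n_pairs Number of twin pairs.
#' @param n_singletons Additional unrelated singletons.
#' @param fraction_mz Fraction of pairs that are monozygotic.
#' @param risk_allele_frequency Risk-allele frequency p in `[0, 1]`.
#' @param age_mean,age_sd Age distribution (years), truncated to
#'   `[18, 95]`.
#' @param female_fraction Probability a subject is female.
#' @param off_effect Per-allele multiplicative effect on
#'   `off_bipolar_gain`: gain scales by `1 + dosage * off_effect`.
#' @param other_effects Optional named numeric vector of per-allele
#'   multiplicative effects on other gain fields (default none).
#' @param subject_sd SD (log scale) of the lognormal between-subject
#'   multiplier applied to all amplitude gains.
#' @param family_sd SD (log scale) of the lognormal family-shared
#'   multiplier (induces gain correlation within families).
#' @param eye_sd SD (log scale) of the small inter-eye deviation.
#' @param noise_sd Per-sample sweep noise SD (uV).
#' @param drift_sd Baseline drift SD (uV).
#' @param n_sweeps Sweeps recorded per stimulus per eye.
#' @param artifact_rate Probability a sweep carries an injected artifact.
#' @param artifact_amp Amplitude (uV) of injected artifact transients.
#' @param baseline_gains Baseline [cellular_gains()] for dosage 0 at the
#'   population gain mean.
#' @param seed Master seed (mandatory; every downstream draw derives from
#'   it).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pairs = 93, n_singletons = 0, fraction_mz = 0.5,
                        risk_allele_frequency = 0.5296,
                        age_mean = 64.2, age_sd = 9.7,
                        female_fraction = 0.95,
                        off_effect = -0.35, other_effects = NULL,
                        subject_sd = 0.2, family_sd = 0.1, eye_sd = 0.03,
                        noise_sd = 8, drift_sd = 4,
                        n_sweeps = 4, artifact_rate = 0.02,
                        artifact_amp = 2000,
                        baseline_gains = default_gains(),
                        seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  p <- risk_allele_frequency
  if (p < 0 || p > 1) stop("`risk_allele_frequency` must be in [0, 1]")
  for (nm in c("fraction_mz", "female_fraction", "artifact_rate")) {
    v <- get(nm)
    if (v < 0 || v > 1) stop(sprintf("`%s` must be in [0, 1]", nm))
  }
  if (!is.finite(off_effect)) stop("`off_effect` must be finite")
  if (1 + 2 * off_effect < 0) stop("`off_effect` would make a gain negative")
  if (!is.null(other_effects)) {
    if (is.null(names(other_effects)) ||
        !all(names(other_effects) %in% names(baseline_gains))) {
      stop("`other_effects` must be named after cellular_gains fields")
    }
    if (any(1 + 2 * other_effects < 0)) {
      stop("`other_effects` would make a gain negative")
    }
  }
  stopifnot(inherits(baseline_gains, "cellular_gains"))
  structure(as.list(environment())[c(
    "n_pairs", "n_singletons", "fraction_mz", "risk_allele_frequency",
    "age_mean", "age_sd", "female_fraction", "off_effect", "other_effects",
    "subject_sd", "family_sd", "eye_sd", "noise_sd", "drift_sd",
    "n_sweeps", "artifact_rate", "artifact_amp", "baseline_gains", "seed")],
    class = "cohort_spec")
}

# deterministic per-stage seed derived from the master seed (kept < 2^31)
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629 + 1)
}

# one Hardy-Weinberg genotype draw: dosage = number of risk alleles
hwe_draw <- function(n, p) {
  stats::rbinom(n, 2L, p)
}

# transmit one allele from a parental genotype (dosage 0/1/2)
transmit <- function(parent_dosage) {
  ifelse(parent_dosage == 2L, 1L,
         ifelse(parent_dosage == 0L, 0L,
                stats::rbinom(length(parent_dosage), 1L, 0.5)))
}

#' Draw genotype dosages for a structured cohort
#'
#' Singletons and twin-pair founders are drawn under Hardy-Weinberg
#' equilibrium at the risk-allele frequency.  MZ co-twins copy their
#' co-twin's genotype; DZ co-twins are generated by simulating two parental
#' genotypes (HWE) and two independent Mendelian transmissions per twin, so
#' allele sharing between DZ twins is exactly Mendelian.
#'
#' @param subjects A data frame with columns `family_id` and `zygosity`
#'   (`"MZ"`, `"DZ"`, `"singleton"`); twins share `family_id`.
#' @param p Risk-allele frequency in `[0, 1]`.
#' @return Integer vector of dosages (0/1/2), one per row of `subjects`.
#' @export
draw_genotypes <- function(subjects, p) {
  if (p < 0 || p > 1) stop("`p` must be in [0, 1]")
  n <- nrow(subjects)
  dosage <- integer(n)
  fams <- split(seq_len(n), subjects$family_id)
  for (idx in fams) {
    zyg <- subjects$zygosity[idx[1]]
    if (zyg == "MZ" && length(idx) == 2L) {
      d <- hwe_draw(1L, p)
      dosage[idx] <- d
    } else if (zyg == "DZ" && length(idx) == 2L) {
      parents <- hwe_draw(2L, p)
      for (i in idx) {
        dosage[i] <- transmit(parents[1]) + transmit(parents[2])
      }
    } else {
      dosage[idx] <- hwe_draw(length(idx), p)
    }
  }
  dosage
}

#' Assign cellular gains given a dosage
#'
#' The OFF-bipolar gain is scaled by `1 + dosage * off_effect`, an optional
#' set of other per-allele effects is applied the same way, and all
#' amplitude gains are then multiplied by a family-shared and a
#' subject-level lognormal deviation (both mean 1 on the natural scale).
#' Rod-pathway gains do not depend on dosage unless explicitly requested
#' through `other_effects`.
#'
#' @param dosage Risk-allele count (0, 1 or 2).
#' @param spec A [cohort_spec()].
#' @param family_multiplier Family-shared lognormal multiplier (draw one
#'   per family with [family_multiplier()]).
#' @return A [cellular_gains()] object.
#' @export
assign_gains <- function(dosage, spec, family_multiplier = 1) {
  if (!dosage %in% 0:2) stop("`dosage` must be 0, 1 or 2")
  g <- spec$baseline_gains
  fac <- 1 + dosage * spec$off_effect
  if (fac < 0) stop("`off_effect` makes off_bipolar_gain negative")
  g$off_bipolar_gain <- g$off_bipolar_gain * fac
  if (!is.null(spec$other_effects)) {
    for (nm in names(spec$other_effects)) {
      f2 <- 1 + dosage * spec$other_effects[[nm]]
      if (f2 < 0) stop(sprintf("effect on `%s` makes it negative", nm))
      g[[nm]] <- g[[nm]] * f2
    }
  }
  subj_mult <- lognormal_mult(1L, spec$subject_sd)
  m <- family_multiplier * subj_mult
  for (nm in c("rod_pr_max", "cone_pr_max", "on_bipolar_gain",
               "off_bipolar_gain", "op_gain")) {
    g[[nm]] <- g[[nm]] * m
  }
  g
}

# mean-one lognormal multipliers
lognormal_mult <- function(n, sdlog) {
  if (sdlog <= 0) return(rep(1, n))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' @rdname assign_gains
#' @param spec A [cohort_spec()].
#' @export
family_multiplier <- function(spec) lognormal_mult(1L, spec$family_sd)

#' Build the expected additive kinship matrix
#'
#' Diagonal 1; MZ co-twins 1; DZ co-twins 0.5; unrelated pairs 0.
#'
#' @param subjects Data frame with columns `subject_id`, `family_id`,
#'   `zygosity`.
#' @return A symmetric matrix with subject ids as dimnames.
#' @export
build_kinship <- function(subjects) {
  ids <- subjects$subject_id
  if (anyDuplicated(ids)) stop("duplicated subject id")
  n <- length(ids)
  K <- diag(1, n)
  fams <- split(seq_len(n), subjects$family_id)
  for (idx in fams) {
    if (length(idx) < 2L) next
    zyg <- subjects$zygosity[idx[1]]
    r <- if (zyg == "MZ") 1 else 0.5
    for (i in idx) for (j in idx) if (i != j) K[i, j] <- r
  }
  dimnames(K) <- list(ids, ids)
  K
}

#' Simulate a twin cohort
#'
#' Draws family structure, zygosity, ages (truncated normal on
#' `[18, 95]`), sex, Hardy-Weinberg/Mendelian genotypes and per-subject
#' cellular gains, and assembles the kinship matrix.  Fully reproducible
#' from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `erg_cohort`: `subjects` (data frame with
#'   subject_id, family_id, zygosity, age, sex, dosage), `gains` (list of
#'   [cellular_gains()] keyed by subject id), `kinship` (matrix), and
#'   `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(derive_seed(spec$seed, "cohort"), function() {
    fam <- integer(0); zyg <- character(0)
    for (f in seq_len(spec$n_pairs)) {
      z <- if (stats::runif(1) < spec$fraction_mz) "MZ" else "DZ"
      fam <- c(fam, f, f); zyg <- c(zyg, z, z)
    }
    if (spec$n_singletons > 0) {
      f0 <- spec$n_pairs
      fam <- c(fam, f0 + seq_len(spec$n_singletons))
      zyg <- c(zyg, rep("singleton", spec$n_singletons))
    }
    n <- length(fam)
    subjects <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      family_id = sprintf("F%03d", fam),
      zygosity = zyg,
      stringsAsFactors = FALSE)
    age <- stats::rnorm(n, spec$age_mean, spec$age_sd)
    while (any(bad <- age < 18 | age > 95)) {
      age[bad] <- stats::rnorm(sum(bad), spec$age_mean, spec$age_sd)
    }
    subjects$age <- round(age, 1)
    # co-twins share age
    first <- !duplicated(subjects$family_id)
    subjects$age <- subjects$age[match(subjects$family_id,
                                       subjects$family_id[first])]
    subjects$sex <- ifelse(stats::runif(n) < spec$female_fraction, "F", "M")
    # MZ co-twins share sex
    mz_first <- which(first & subjects$zygosity == "MZ")
    for (i in mz_first) {
      idx <- which(subjects$family_id == subjects$family_id[i])
      subjects$sex[idx] <- subjects$sex[i]
    }
    subjects$dosage <- draw_genotypes(subjects, spec$risk_allele_frequency)
    fam_ids <- unique(subjects$family_id)
    fmult <- stats::setNames(
      vapply(fam_ids, function(f) family_multiplier(spec), 0), fam_ids)
    gains <- lapply(seq_len(n), function(i) {
      assign_gains(subjects$dosage[i], spec,
                   family_multiplier = fmult[[subjects$family_id[i]]])
    })
    names(gains) <- subjects$subject_id
    structure(list(subjects = subjects, gains = gains,
                   kinship = build_kinship(subjects), spec = spec),
              class = "erg_cohort")
  })
}

#' @export
print.erg_cohort <- function(x, ...) {
  s <- x$subjects
  cat(sprintf("<erg_cohort> %d subjects (%d MZ, %d DZ, %d singleton)\n",
              nrow(s), sum(s$zygosity == "MZ"), sum(s$zygosity == "DZ"),
              sum(s$zygosity == "singleton")))
  cat("  dosage split:",
      paste(sprintf("%d:%d", 0:2, tabulate(factor(s$dosage, 0:2), 3)),
            collapse = " "), "\n")
  invisible(x)
}

#' Simulate a full recording session for one subject
#'
#' For each stimulus and each eye, synthesizes the subject's noiseless
#' response (the two eyes share the subject's gains up to a small
#' lognormal inter-eye deviation) and records `n_sweeps` noisy sweeps.
#' With probability `artifact_rate` a sweep receives a large injected
#' transient (to exercise artifact rejection); injections are recorded in
#' the sweep metadata and in the session's `artifact_log`.
#'
#' @param subject One-row data frame (or list) with `subject_id` and
#'   `dosage`.
#' @param gains The subject's [cellular_gains()].
#' @param protocol Named list of [stimulus_spec()] (see
#'   [standard_protocol()]).
#' @param spec A [cohort_spec()] (noise, sweep and artifact settings).
#' @param seed Integer seed for this session.
#' @return A list of class `erg_session`: `sweeps` (list keyed by stimulus
#'   label, each a list with per-eye sweep lists `RE`/`LE`), and
#'   `artifact_log` (data frame of injected artifacts).
#' @export
simulate_session <- function(subject, gains, protocol, spec, seed) {
  if (!length(protocol)) stop("`protocol` must be non-empty")
  with_seed(seed, function() {
    art_log <- list()
    sweeps <- lapply(protocol, function(stim) {
      eyes <- lapply(c(RE = "RE", LE = "LE"), function(eye) {
        eg <- gains
        emult <- lognormal_mult(1L, spec$eye_sd)
        for (nm in c("rod_pr_max", "cone_pr_max", "on_bipolar_gain",
                     "off_bipolar_gain", "op_gain")) {
          eg[[nm]] <- eg[[nm]] * emult
        }
        clean <- if (stim$mode == "flicker_30hz") {
          synthesize_flicker_response(stim, eg)
        } else {
          synthesize_flash_response(stim, eg)$trace
        }
        lapply(seq_len(spec$n_sweeps), function(k) {
          sw <- add_noise(clean, spec$noise_sd, spec$drift_sd)
          injected <- stats::runif(1) < spec$artifact_rate
          if (injected) {
            at <- stats::runif(1, min(sw$time), max(sw$time))
            width <- 5
            sw$voltage <- sw$voltage +
              spec$artifact_amp * exp(-((sw$time - at) / width)^2)
            art_log[[length(art_log) + 1L]] <<- data.frame(
              subject_id = subject$subject_id, stimulus = stim$label,
              eye = eye, sweep = k, at_ms = at)
          }
          sw$meta <- c(sw$meta, list(subject_id = subject$subject_id,
                                     eye = eye, sweep = k,
                                     artifact_injected = injected))
          sw
        })
      })
      eyes
    })
    names(sweeps) <- vapply(protocol, `[[`, "", "label")
    structure(list(subject_id = subject$subject_id, sweeps = sweeps,
                   artifact_log = if (length(art_log))
                     do.call(rbind, art_log) else
                       data.frame(subject_id = character(0),
                                  stimulus = character(0),
                                  eye = character(0), sweep = integer(0),
                                  at_ms = numeric(0))),
              class = "erg_session")
  })
}
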