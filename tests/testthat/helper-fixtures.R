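# shared fixtures: small cohorts and deterministic subject tables

# a subject table with explicit structure (no randomness)
make_subjects <- function(zygosities) {
  n_fam <- length(zygosities)
  fam <- rep(seq_len(n_fam), ifelse(zygosities == "singleton", 1L, 2L))
  zyg <- rep(zygosities, ifelse(zygosities == "singleton", 1L, 2L))
  data.frame(subject_id = sprintf("S%03d", seq_along(fam)),
             family_id = sprintf("F%03d", fam),
             zygosity = zyg,
             stringsAsFactors = FALSE)
}

# simulated twin-structured null phenotype on a given kinship matrix
sim_twin_null <- function(K, sigma_g2 = 2, sigma_e2 = 1) {
  n <- nrow(K)
  u <- drop(t(chol(K + 1e-8 * diag(n))) %*% stats::rnorm(n)) * sqrt(sigma_g2)
  u + stats::rnorm(n, 0, sqrt(sigma_e2))
}

# quick design matrix with random covariates for n subjects
random_design <- function(subjects) {
  n <- nrow(subjects)
  cbind(intercept = 1,
        dosage = as.numeric(subjects$dosage),
        age = rep(stats::rnorm(n), 1),
        sexM = stats::rbinom(n, 1, 0.3))
}

# cohort spec scaled down for unit tests
tiny_spec <- function(seed, ...) {
  cohort_spec(n_pairs = 4, n_singletons = 2, noise_sd = 3, drift_sd = 1,
              n_sweeps = 3, artifact_rate = 0, female_fraction = 0.6,
              seed = seed, ...)
}
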