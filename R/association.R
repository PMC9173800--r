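#' Build the fixed-effect design matrix
#'
#' Intercept, additive allelic dosage (0/1/2), age and a sex indicator,
#' row-aligned to the supplied subjects.  With `coding = "genotypic"`,
#' dosage is expanded into separate heterozygote/homozygote indicators.
#'
#' @param subjects Data frame with `dosage`, `age`, `sex`.
#' @param coding `"additive"` (default) or `"genotypic"`.
#' @return A numeric design matrix with named columns.
#' @export
design_matrix <- function(subjects, coding = c("additive", "genotypic")) {
  coding <- match.arg(coding)
  n <- nrow(subjects)
  if (coding == "additive") {
    X <- cbind(intercept = rep(1, n),
               dosage = as.numeric(subjects$dosage),
               age = subjects$age,
               sexM = as.numeric(subjects$sex == "M"))
  } else {
    X <- cbind(intercept = rep(1, n),
               het = as.numeric(subjects$dosage == 1),
               hom = as.numeric(subjects$dosage == 2),
               age = subjects$age,
               sexM = as.numeric(subjects$sex == "M"))
  }
  X
}

#' Kinship-adjusted association scan over ERG parameters
#'
#' For each requested parameter, fits the kinship linear mixed model with
#' allelic dosage, age and sex as fixed effects ([fit_lmm()]) and reports
#' the dosage effect, its standard error, the Wald p-value and the variance
#' components.  Rows with a missing phenotype are dropped per parameter
#' (complete-case; counts are reported).  Significance is flagged at
#' P < 0.05 with no multiple-testing correction by default; an optional
#' Benjamini-Hochberg column can be added.
#'
#' @param features Long feature table (`subject_id`, `parameter`, `value`),
#'   e.g. from [extract_features()] stacked over subjects.
#' @param subjects Cohort table with `subject_id`, `dosage`, `age`, `sex`,
#'   ordered as the kinship matrix.
#' @param K Kinship matrix over `subjects` (in the same order).
#' @param parameters Character vector of parameter names to test
#'   (default: all amplitude parameters present, i.e. those not ending in
#'   `-time`).
#' @param alpha Significance level for the flag (default 0.05).
#' @param bh Add a Benjamini-Hochberg adjusted column (`p_bh`)?
#' @param method Passed to [fit_lmm()].
#' @return Data frame: parameter, beta, se, p, sigma_g2, sigma_e2, lambda,
#'   n, significant (and optionally p_bh).
#' @export
association_scan <- function(features, subjects, K, parameters = NULL,
                             alpha = 0.05, bh = FALSE,
                             method = c("REML", "ML")) {
  method <- match.arg(method)
  if (is.null(parameters)) {
    parameters <- setdiff(unique(features$parameter),
                          grep("-time$", unique(features$parameter),
                               value = TRUE))
  }
  if (!length(parameters)) {
    return(data.frame(parameter = character(0), beta = numeric(0),
                      se = numeric(0), p = numeric(0),
                      sigma_g2 = numeric(0), sigma_e2 = numeric(0),
                      lambda = numeric(0), n = integer(0),
                      significant = logical(0)))
  }
  rows <- lapply(parameters, function(par) {
    f <- features[features$parameter == par, c("subject_id", "value")]
    y <- f$value[match(subjects$subject_id, f$subject_id)]
    ok <- !is.na(y)
    if (sum(ok) < 8) {
      return(data.frame(parameter = par, beta = NA_real_, se = NA_real_,
                        p = NA_real_, sigma_g2 = NA_real_,
                        sigma_e2 = NA_real_, lambda = NA_real_,
                        n = sum(ok), significant = NA))
    }
    X <- design_matrix(subjects[ok, , drop = FALSE])
    fit <- fit_lmm(y[ok], X, K[ok, ok, drop = FALSE], method = method,
                   test_column = "dosage")
    data.frame(parameter = par,
               beta = unname(fit$beta["dosage"]),
               se = unname(fit$se["dosage"]),
               p = fit$p_wald,
               sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
               lambda = fit$lambda, n = fit$n,
               significant = fit$p_wald < alpha)
  })
  out <- do.call(rbind, rows)
  if (bh) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Grouped summary of ERG parameters by allelic dosage
#'
#' Mean (SD) per parameter per dosage group with group sizes, mirroring the
#' layout of grouped amplitude tables.  A group with a single observation
#' reports SD 0 (declared convention); an empty group reports blank (NA)
#' cells.
#'
#' @param features Long feature table (`subject_id`, `parameter`, `value`).
#' @param dosages Named vector (or data frame with `subject_id`, `dosage`)
#'   giving each subject's dosage.
#' @param parameters Parameters to include (default: all amplitude
#'   parameters).
#' @return Data frame: parameter, then mean_g0/sd_g0/n_g0 .. mean_g2/...
#' @export
summarize_by_group <- function(features, dosages, parameters = NULL) {
  if (is.data.frame(dosages)) {
    dosages <- stats::setNames(dosages$dosage, dosages$subject_id)
  }
  if (!all(stats::na.omit(unique(dosages)) %in% 0:2)) {
    stop("dosages must be 0, 1 or 2")
  }
  if (is.null(parameters)) {
    parameters <- setdiff(unique(features$parameter),
                          grep("-time$", unique(features$parameter),
                               value = TRUE))
  }
  rows <- lapply(parameters, function(par) {
    f <- features[features$parameter == par, ]
    d <- dosages[f$subject_id]
    row <- list(parameter = par)
    for (g in 0:2) {
      v <- f$value[!is.na(d) & d == g]
      row[[sprintf("mean_g%d", g)]] <-
        if (length(v)) mean(v) else NA_real_
      row[[sprintf("sd_g%d", g)]] <-
        if (length(v) > 1) stats::sd(v) else if (length(v) == 1) 0 else
          NA_real_
      row[[sprintf("n_g%d", g)]] <- length(v)
    }
    as.data.frame(row)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
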