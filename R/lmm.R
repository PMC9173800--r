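#' Fit a kinship linear mixed model by spectral (RE)ML
#'
#' Fits `y = X beta + u + e` with `u ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)`.  `K` is eigendecomposed once; `y` and `X` are
#' rotated into the eigenbasis, so for any variance ratio
#' `lambda = sigma_g^2 / sigma_e^2` the covariance is diagonal and the
#' profiled restricted (or full) log-likelihood is cheap to evaluate.
#' `lambda` is maximized on a 100-point log grid spanning `[1e-5, 1e5]`
#' followed by golden-section refinement (tolerance 1e-6 in log lambda).
#' At the optimum, GLS estimates, standard errors and a Wald t test with
#' `n - rank(X)` degrees of freedom are returned for every column.
#'
#' @param y Numeric phenotype vector.
#' @param X Design matrix (include the intercept column); rank-deficient
#'   columns are dropped with a warning.
#' @param K Kinship matrix, symmetric positive semidefinite (a small ridge
#'   is applied automatically if slightly indefinite).
#' @param method `"REML"` (default) or `"ML"`.
#' @param test_column Name or index of the column whose Wald p-value is
#'   reported as `p_wald` (default `"dosage"` if present, else column 2).
#' @param lambda_range Search range for lambda.
#' @return An object of class `erg_lmm` with elements `beta`, `se`,
#'   `sigma_g2`, `sigma_e2`, `lambda`, `loglik` (restricted or full),
#'   `p_wald`, `t_wald`, `df`, `p` (per-column p-values), `n`, `method`,
#'   plus fitted internals for the methods.
#' @seealso [gls_oracle()] for the slow dense-verification route.
#' @export
fit_lmm <- function(y, X, K, method = c("REML", "ML"), test_column = NULL,
                    lambda_range = c(1e-5, 1e5)) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  if (nrow(X) != n || nrow(K) != n || ncol(K) != n) {
    stop("dimensions of y, X and K disagree")
  }
  if (max(abs(K - t(K))) > 1e-8) stop("K must be symmetric")
  # drop degenerate columns
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    warning(sprintf("dropping rank-deficient column(s): %s",
                    paste(colnames(X)[drop], collapse = ", ")))
    X <- X[, -drop, drop = FALSE]
  }
  p <- ncol(X)
  eK <- eigen(K, symmetric = TRUE)
  d <- eK$values
  if (min(d) < -1e-6 * max(abs(d))) {
    stop("K is not positive semidefinite beyond ridge tolerance")
  }
  d <- pmax(d, 0)
  U <- eK$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  ldXtX <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)

  crit <- function(log_lambda) {
    -spectral_loglik(exp(log_lambda), ys, Xs, d, n, p, method, ldXtX)
  }
  grid <- seq(log(lambda_range[1]), log(lambda_range[2]), length.out = 100)
  vals <- vapply(grid, crit, 0)
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- golden_section(crit, lo, hi, tol = 1e-6)
  lambda <- exp(opt$x)

  fit <- spectral_gls(lambda, ys, Xs, d, n, p, method)
  beta <- fit$beta
  names(beta) <- colnames(X)
  se <- sqrt(diag(fit$cov_beta))
  names(se) <- colnames(X)
  df <- n - p
  tstat <- beta / se
  pvals <- 2 * stats::pt(-abs(tstat), df)
  if (is.null(test_column)) {
    test_column <- if ("dosage" %in% colnames(X)) "dosage" else
      min(2L, p)
  }
  structure(list(beta = beta, se = se,
                 sigma_g2 = lambda * fit$sigma_e2, sigma_e2 = fit$sigma_e2,
                 lambda = lambda,
                 loglik = spectral_loglik(lambda, ys, Xs, d, n, p, method,
                                          ldXtX),
                 t_wald = tstat, p = pvals,
                 p_wald = unname(pvals[test_column]),
                 df = df, n = n, method = method,
                 test_column = test_column,
                 cov_beta = fit$cov_beta, X = X, y = y,
                 fitted = drop(X %*% beta)),
            class = "erg_lmm")
}

# profiled log-likelihood in the eigenbasis; REML uses the restricted form
spectral_loglik <- function(lambda, ys, Xs, d, n, p, method, ldXtX) {
  w <- 1 / (lambda * d + 1)
  XtWX <- crossprod(Xs, Xs * w)
  XtWy <- crossprod(Xs, ys * w)
  beta <- solve(XtWX, XtWy)
  r <- ys - Xs %*% beta
  rss <- sum(w * r^2)
  ldV <- sum(log(lambda * d + 1))
  if (method == "REML") {
    df <- n - p
    s2 <- rss / df
    -0.5 * (df * (log(2 * pi * s2) + 1) + ldV +
              as.numeric(determinant(XtWX, logarithm = TRUE)$modulus) - ldXtX)
  } else {
    s2 <- rss / n
    -0.5 * (n * (log(2 * pi * s2) + 1) + ldV)
  }
}

# GLS point estimates at a fixed lambda (eigenbasis)
spectral_gls <- function(lambda, ys, Xs, d, n, p, method) {
  w <- 1 / (lambda * d + 1)
  XtWX <- crossprod(Xs, Xs * w)
  XtWXi <- solve(XtWX)
  beta <- drop(XtWXi %*% crossprod(Xs, ys * w))
  r <- ys - drop(Xs %*% beta)
  rss <- sum(w * r^2)
  s2 <- rss / (if (method == "REML") n - p else n)
  list(beta = beta, sigma_e2 = s2, cov_beta = s2 * XtWXi)
}

# deterministic golden-section minimization on [lo, hi]
golden_section <- function(f, lo, hi, tol = 1e-6) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - phi * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + phi * (b - a); f2 <- f(c2)
    }
  }
  x <- (a + b) / 2
  list(x = x, value = f(x))
}

#' Dense GLS oracle for the kinship mixed model
#'
#' Verification route for [fit_lmm()]: for each candidate lambda it forms
#' `V = lambda K + I` explicitly, solves the GLS equations by dense
#' factorization and evaluates the restricted (or full) log-likelihood
#' directly.  The grid optimum is refined with [stats::optimize()] between
#' the neighbouring grid points.  Intentionally simple and slow; use only
#' at small n.
#'
#' @inheritParams fit_lmm
#' @param lambda_grid Candidate lambda values (default a dense log grid).
#' @return A list shaped like an `erg_lmm` fit (beta, se, sigma_g2,
#'   sigma_e2, lambda, loglik, p_wald).
#' @export
gls_oracle <- function(y, X, K, lambda_grid = exp(seq(log(1e-5), log(1e5),
                                                      length.out = 200)),
                       method = c("REML", "ML"), test_column = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  p <- ncol(X)
  ldXtX <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)

  ll_at <- function(lambda) {
    V <- lambda * K + diag(n)
    Vi <- tryCatch(solve(V), error = function(e) NULL)
    if (is.null(Vi)) return(-Inf)
    XtViX <- t(X) %*% Vi %*% X
    beta <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    rss <- drop(t(r) %*% Vi %*% r)
    ldV <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
    if (method == "REML") {
      df <- n - p
      s2 <- rss / df
      -0.5 * (df * (log(2 * pi * s2) + 1) + ldV +
                as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) - ldXtX)
    } else {
      s2 <- rss / n
      -0.5 * (n * (log(2 * pi * s2) + 1) + ldV)
    }
  }
  lls <- vapply(lambda_grid, ll_at, 0)
  i <- which.max(lls)
  lo <- lambda_grid[max(i - 1L, 1L)]
  hi <- lambda_grid[min(i + 1L, length(lambda_grid))]
  lambda <- if (lo < hi) {
    stats::optimize(function(ll) ll_at(exp(ll)), c(log(lo), log(hi)),
                    maximum = TRUE, tol = 1e-7)$maximum
  } else log(lambda_grid[i])
  lambda <- exp(lambda)

  V <- lambda * K + diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  XtViXi <- solve(XtViX)
  beta <- drop(XtViXi %*% t(X) %*% Vi %*% y)
  names(beta) <- colnames(X)
  r <- y - drop(X %*% beta)
  rss <- drop(t(r) %*% Vi %*% r)
  s2 <- rss / (if (method == "REML") n - p else n)
  se <- sqrt(diag(s2 * XtViXi))
  names(se) <- colnames(X)
  df <- n - p
  pvals <- 2 * stats::pt(-abs(beta / se), df)
  if (is.null(test_column)) {
    test_column <- if ("dosage" %in% colnames(X)) "dosage" else min(2L, p)
  }
  list(beta = beta, se = se, sigma_g2 = lambda * s2, sigma_e2 = s2,
       lambda = lambda, loglik = ll_at(lambda),
       p = pvals, p_wald = unname(pvals[test_column]), df = df, n = n,
       method = method)
}

#' @export
print.erg_lmm <- function(x, ...) {
  cat(sprintf("<erg_lmm> n = %d, %s; lambda = %.4g (sigma_g2 = %.4g, sigma_e2 = %.4g)\n",
              x$n, x$method, x$lambda, x$sigma_g2, x$sigma_e2))
  cat(sprintf("  Wald test on '%s': p = %.4g\n",
              if (is.character(x$test_column)) x$test_column
              else colnames(x$X)[x$test_column], x$p_wald))
  print(round(rbind(beta = x$beta, se = x$se), 4))
  invisible(x)
}

#' @export
summary.erg_lmm <- function(object, ...) {
  tab <- data.frame(estimate = object$beta, se = object$se,
                    t = object$t_wald, p = object$p)
  structure(list(coefficients = tab, sigma_g2 = object$sigma_g2,
                 sigma_e2 = object$sigma_e2, lambda = object$lambda,
                 loglik = object$loglik, n = object$n, df = object$df,
                 method = object$method),
            class = "summary.erg_lmm")
}

#' @export
print.summary.erg_lmm <- function(x, ...) {
  cat(sprintf("Kinship linear mixed model (%s), n = %d\n", x$method, x$n))
  cat(sprintf("Variance components: sigma_g2 = %.4g, sigma_e2 = %.4g (lambda = %.4g)\n",
              x$sigma_g2, x$sigma_e2, x$lambda))
  cat(sprintf("Log-likelihood (%s): %.4f\n", x$method, x$loglik))
  stats::printCoefmat(as.matrix(x$coefficients), P.values = TRUE,
                      has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.erg_lmm <- function(object, ...) object$beta

#' @export
vcov.erg_lmm <- function(object, ...) object$cov_beta

#' @export
logLik.erg_lmm <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) + 2,
            class = "logLik")
}

#' @export
residuals.erg_lmm <- function(object, ...) object$y - object$fitted

#' @export
fitted.erg_lmm <- function(object, ...) object$fitted

#' @export
confint.erg_lmm <- function(object, parm = NULL, level = 0.95, ...) {
  q <- stats::qt((1 + level) / 2, object$df)
  ci <- cbind(object$beta - q * object$se, object$beta + q * object$se)
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                             (1 + level) / 2))
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}
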