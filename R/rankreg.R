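#' Spearman correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (ties receive average ranks); the
#' p-value uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors (pairs with missing values are dropped).
#' @return data.frame with columns rho, p, n.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need n >= 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for constant input", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else
    2 * stats::pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2)
  data.frame(rho = rho, p = p, n = n)
}

#' Wilcoxon rank scores
#'
#' `a(i) = sqrt(12) * (i / (n + 1) - 1/2)`; the scores sum to zero.
#'
#' @param n sample size.
#' @return numeric vector of length `n`.
#' @export
wilcoxon_scores <- function(n) sqrt(12) * (seq_len(n) / (n + 1) - 0.5)

#' Jaeckel rank dispersion of residuals
#'
#' `D(e) = sum a(R(e_i)) * e_i` with Wilcoxon scores and mid-ranks `R`.
#' Nonnegative, location-free, and (for the no-tie case) equal to
#' `sqrt(12)/(2(n+1)) * sum_{i<j} |e_i - e_j|`.
#'
#' @param e residual vector.
#' @return the dispersion (a single nonnegative number).
#' @export
rank_dispersion <- function(e) {
  n <- length(e)
  a <- sqrt(12) * (rank(e) / (n + 1) - 0.5)
  sum(a * e)
}

#' Rank-based linear regression (Wilcoxon scores)
#'
#' Estimates `y = alpha + X beta + e` by minimizing Jaeckel's rank
#' dispersion of the residuals: a robust, nonparametric alternative to
#' least squares. Predictors and response are mean-centered internally;
#' the objective is convex and piecewise linear in `beta`, minimized by
#' Nelder-Mead (single predictor: golden-section via [stats::optimize()])
#' started from the least-squares solution. The intercept is the median of
#' the raw residuals. Standard errors use the scale `tau` from the
#' Koul-Sievers-McKean pairwise-difference window estimator:
#' `SE = sqrt(diag(tau^2 (Xc' Xc)^{-1}))`, with t-based p-values on
#' `n - p - 1` df. The dispersion-based R2 analog is
#' `1 - D(full) / D(response)`.
#'
#' @param y response vector.
#' @param X predictor matrix (or vector for a single predictor).
#' @param max_restarts extra Nelder-Mead restarts from the current optimum
#'   (polishing; the objective is piecewise linear).
#' @return an object of class `rank_fit`: coefficients, intercept,
#'   dispersion at the optimum, `tau`, per-coefficient `se`/`t`/`p`,
#'   `r2_disp`, `n`, `converged`.
#' @export
rank_fit <- function(y, X, max_restarts = 2L) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  ok <- stats::complete.cases(y, X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (n <= p + 2) stop("need n > p + 2", call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (qr(Xc)$rank < p)
    stop("rank-deficient predictor matrix", call. = FALSE)
  yc <- y - mean(y)
  obj <- function(b) rank_dispersion(yc - Xc %*% b)
  b0 <- stats::lm.fit(Xc, yc)$coefficients
  if (p == 1) {
    span <- max(1, 10 * abs(b0))
    op <- stats::optimize(function(b) obj(b), interval = c(b0 - span, b0 + span),
                          tol = 1e-9)
    beta <- op$minimum; dmin <- op$objective
    conv <- TRUE
  } else {
    op <- stats::optim(b0, obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12))
    for (r in seq_len(max_restarts)) {
      op2 <- stats::optim(op$par, obj, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-12))
      if (op2$value < op$value - 1e-12) op <- op2 else { op <- op2; break }
    }
    beta <- op$par; dmin <- op$value
    conv <- op$convergence == 0
    if (!conv)
      stop("rank_fit did not converge (Nelder-Mead code ", op$convergence,
           ")", call. = FALSE)
  }
  beta <- stats::setNames(as.numeric(beta), colnames(X))
  resid <- as.numeric(y - X %*% beta)
  intercept <- stats::median(resid)
  tau <- ksm_tau(resid - intercept, p)
  xtx_inv <- solve(crossprod(Xc))
  se <- sqrt(diag(tau^2 * xtx_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), n - p - 1)
  d_null <- rank_dispersion(yc)
  structure(list(coefficients = beta, intercept = intercept,
                 dispersion = dmin, dispersion_null = d_null,
                 tau = tau, se = se, t = tval, p = pval,
                 r2_disp = if (d_null > 0) 1 - dmin / d_null else NA_real_,
                 residuals = resid - intercept, n = n, p_predictors = p,
                 converged = conv),
            class = "rank_fit")
}

#' @export
print.rank_fit <- function(x, ...) {
  cat(sprintf("<rank_fit> n = %d, dispersion = %.4f, tau = %.4f, R2(disp) = %.3f\n",
              x$n, x$dispersion, x$tau, x$r2_disp))
  tab <- data.frame(beta = x$coefficients, se = x$se, t = x$t, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

## Koul-Sievers-McKean window estimator of the scale tau for Wilcoxon
## scores: the density of pairwise residual differences at zero estimates
## the Wilcoxon information integral f* = int f^2; tau = 1/(sqrt(12) f*).
## Window = delta-quantile of |e_i - e_j| / sqrt(n); the p smallest
## differences are discarded; a df correction sqrt(n/(n-p-1)) is applied.
ksm_tau <- function(e, p, delta = if (length(e) / max(p, 1) > 5) 0.8 else 0.95) {
  n <- length(e)
  d <- sort(abs(as.vector(stats::dist(e))))
  if (p >= 1 && length(d) > p) d <- d[-seq_len(p)]
  tn <- stats::quantile(d, delta, names = FALSE) / sqrt(n)
  w <- sum(d < tn)
  cn <- 2 / (n * (n - 1))
  sc <- wilcoxon_scores(n)
  sc <- (sc - mean(sc)) / sqrt(sum((sc - mean(sc))^2) / (n + 1))
  dn <- sc[n] - sc[1]
  if (w == 0 || tn <= 0) return(Inf)
  sqrt(n / (n - p - 1)) * (2 * tn) / (dn * w * cn)
}

#' Dispersion-reduction test for nested rank regressions
#'
#' The drop-in-dispersion analog of the partial F (or chi-square) test:
#' `F = [(D_reduced - D_full) / q] / (tau_full / 2)` for `q` dropped
#' predictors, referred to an F distribution on `(q, n - p_full - 1)` df.
#'
#' @param full,reduced `rank_fit` objects on the same observations, with
#'   the reduced model's predictors a strict subset of the full model's
#'   (the null model with 0 predictors may be represented by passing
#'   `reduced = NULL`, using the full model's null dispersion).
#' @return data.frame with columns F, df1, df2, p.
#' @export
dispersion_reduction_test <- function(full, reduced = NULL) {
  q <- full$p_predictors - if (is.null(reduced)) 0L else reduced$p_predictors
  d_red <- if (is.null(reduced)) full$dispersion_null else reduced$dispersion
  if (!is.null(reduced)) {
    if (reduced$n != full$n)
      stop("models fit on different observation counts", call. = FALSE)
    if (q <= 0 && abs(d_red - full$dispersion) > 1e-10)
      stop("models are not nested", call. = FALSE)
    if (!all(names(reduced$coefficients) %in% names(full$coefficients)))
      stop("models are not nested: reduced has predictors absent from full",
           call. = FALSE)
  }
  if (q == 0)
    return(data.frame(F = 0, df1 = 0, df2 = full$n - full$p_predictors - 1,
                      p = 1))
  drop_d <- max(d_red - full$dispersion, 0)
  fstat <- (drop_d / q) / (full$tau / 2)
  df2 <- full$n - full$p_predictors - 1
  data.frame(F = fstat, df1 = q, df2 = df2,
             p = stats::pf(fstat, q, df2, lower.tail = FALSE))
}

#' Residualize a predictor, then refit
#'
#' Implements the regressing-out workflow for separating shared from
#' unique predictive variance: the target predictor is rank-regressed on
#' the nuisance predictors, and the response is then rank-regressed on the
#' residualized target. The report compares the dispersion-based R2 analog
#' of this model with the unresidualized simple model, quantifying how
#' much of the target's predictive value the nuisances carried.
#'
#' @param y response vector.
#' @param target predictor of interest.
#' @param nuisances matrix or vector of predictors to regress out of
#'   `target`.
#' @return list with `fit` (the `rank_fit` of `y` on the residualized
#'   target), `simple_fit` (`y` on the raw target), `nuisance_fit`,
#'   `delta_r2` (simple minus residualized R2 analog) and `test`
#'   (dispersion-reduction test of the residualized model against the null).
#' @export
regress_out_then_refit <- function(y, target, nuisances) {
  nuis <- as.matrix(nuisances)
  nfit <- rank_fit(target, nuis)
  resid_target <- nfit$residuals
  if (stats::sd(resid_target) < 1e-10 * max(stats::sd(target), 1))
    stop("target is fully explained by the nuisance predictors; ",
         "residualized model undefined", call. = FALSE)
  fit <- rank_fit(y, matrix(resid_target, ncol = 1,
                            dimnames = list(NULL, "target_resid")))
  simple <- rank_fit(y, matrix(target, ncol = 1,
                               dimnames = list(NULL, "target")))
  list(fit = fit, simple_fit = simple, nuisance_fit = nfit,
       delta_r2 = simple$r2_disp - fit$r2_disp,
       test = dispersion_reduction_test(fit))
}
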