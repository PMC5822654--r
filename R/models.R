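#' Ordinary least squares with school-cluster-robust standard errors
#'
#' Fits the baseline linear model by least squares and computes the
#' cluster-sandwich covariance
#' \deqn{\hat V = c\,(X'X)^{-1}\Big(\sum_g X_g'e_g e_g'X_g\Big)(X'X)^{-1},
#'   \quad c = \frac{G}{G-1}\cdot\frac{n-1}{n-k},}
#' the standard small-sample correction for G clusters. The Gaussian
#' log-likelihood (with \eqn{\hat\sigma^2 = RSS/n}) and AIC (k parameters =
#' coefficients + 1 for the variance) are reported.
#'
#' @param y numeric outcome vector.
#' @param X design matrix including the intercept column.
#' @param cluster_ids cluster (school) membership, length `n`.
#' @return object of class `ols_fit`: `beta`, `vcov_cluster`, `se`, `ci`
#'   (95% Wald), `residuals`, `fitted`, `sigma2`, `loglik`, `aic`, `n`, `k`,
#'   `n_clusters`.
#' @export
fit_ols <- function(y, X, cluster_ids) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n || length(cluster_ids) != n) stop_("dimension mismatch")
  if (length(unique(cluster_ids)) < 2) stop_("need at least 2 clusters")
  qx <- qr(X)
  if (qx$rank < p)
    stop_("rank-deficient design: collinear column(s) %s",
          paste(colnames(X)[qx$pivot[(qx$rank + 1):p]], collapse = ", "))
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  XtXinv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  G <- length(unique(cluster_ids))
  Xu <- rowsum(X * res, cluster_ids)           # per-cluster score sums X_g' e_g
  meat <- crossprod(Xu)
  adj <- G / (G - 1) * (n - 1) / (n - p)
  V <- adj * XtXinv %*% meat %*% XtXinv
  dimnames(V) <- list(colnames(X), colnames(X))
  sigma2 <- sum(res^2) / n
  ll <- -n / 2 * (log(2 * pi) + log(sigma2) + 1)
  se <- sqrt(diag(V))
  structure(list(beta = setNames(beta, colnames(X)), vcov_cluster = V,
                 se = se,
                 ci = cbind(lower = beta - qnorm(0.975) * se,
                            upper = beta + qnorm(0.975) * se),
                 residuals = res, fitted = y - res, sigma2 = sigma2,
                 loglik = ll, aic = 2 * (p + 1) - 2 * ll,
                 n = n, k = p + 1L, n_clusters = G),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit (cluster-robust SEs, %d clusters), n = %d, AIC = %.1f\n",
              x$n_clusters, x$n, x$aic))
  print(round(cbind(coefficient = x$beta, se = x$se, x$ci), 4))
  invisible(x)
}

#' Concentrated (profile) log-likelihood of the network lag model
#'
#' For \eqn{y = \rho W y + X\beta + \epsilon} with Gaussian errors, the
#' log-likelihood concentrated over \eqn{(\beta, \sigma^2)} is
#' \deqn{\ell_p(\rho) = -\frac{n}{2}\big(\log 2\pi + 1\big)
#'   - \frac{n}{2}\log\hat\sigma^2(\rho) + \sum_i \log|1-\rho\lambda_i|,}
#' where \eqn{\hat\sigma^2(\rho) = RSS(\rho)/n} from regressing
#' \eqn{z = (I-\rho W)y} on X, and the \eqn{\lambda_i} are the eigenvalues
#' of W (complex moduli for directed W).
#'
#' @param rho scalar network dependence parameter.
#' @param y outcome vector.
#' @param X design matrix (with intercept).
#' @param W a [weight_matrix()].
#' @param ev eigenvalues of W (computed and cached if omitted).
#' @return scalar profile log-likelihood.
#' @export
profile_loglik <- function(rho, y, X, W, ev = NULL) {
  wm <- as_weight_matrix(W)
  ev <- ev %||% weight_eigenvalues(wm)
  m <- Mod(1 - rho * ev)
  if (any(m < 1e-12))
    stop_("singularity: |1 - rho*lambda| = 0 at rho = %.6f", rho)
  n <- length(y)
  z <- y - rho * as.numeric(wm$W %*% y)
  res <- qr.resid(qr(as.matrix(X)), z)
  sigma2 <- sum(res^2) / n
  -n / 2 * (log(2 * pi) + 1) - n / 2 * log(sigma2) + sum(log(m))
}

# full log-likelihood in (rho, beta, sigma2); used for the numerical Hessian
full_loglik <- function(par, y, X, Wy, ev) {
  p <- ncol(X)
  rho <- par[1]; beta <- par[2:(p + 1)]; sigma2 <- par[p + 2]
  m <- Mod(1 - rho * ev)
  if (sigma2 <= 0 || any(m < 1e-12)) return(-1e10)
  n <- length(y)
  e <- y - rho * Wy - drop(X %*% beta)
  -n / 2 * log(2 * pi * sigma2) - sum(e^2) / (2 * sigma2) + sum(log(m))
}

#' Fit the network autocorrelation (spatial lag) model by maximum likelihood
#'
#' Maximises the concentrated log-likelihood over the feasible interval of
#' \eqn{\rho} (see [feasible_interval()]) by a coarse grid followed by
#' Brent-style bounded scalar optimisation (tolerance 1e-8 in \eqn{\rho});
#' \eqn{\hat\beta} and \eqn{\hat\sigma^2} follow at \eqn{\hat\rho}. The
#' asymptotic covariance of \eqn{(\rho, \beta)} comes from the negative
#' inverse numerical Hessian of the full log-likelihood at the optimum.
#' Boundary solutions and failed Hessians are flagged, never silently
#' returned.
#'
#' @inheritParams fit_ols
#' @param W a row-standardised [weight_matrix()].
#' @param fix_rho optional value at which to hold \eqn{\rho} fixed (e.g. 0,
#'   which reproduces the OLS fit).
#' @return object of class `network_fit`: `rho`, `beta`, `sigma2`, `loglik`,
#'   `aic` (k = #coefficients + 2), `vcov` (for \eqn{(\rho, \beta)}), `se`,
#'   `ci`, `rho_ci`, `feasible_interval`, `converged`, `residuals`, `n`, `k`.
#' @export
fit_network_model <- function(y, X, W, fix_rho = NULL) {
  wm <- as_weight_matrix(W)
  if (!isTRUE(wm$standardised))
    stop_("W must be row-standardised")
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n || nrow(wm$W) != n) stop_("dimension mismatch")
  ev <- weight_eigenvalues(wm)
  fi <- feasible_interval(ev)
  Wy <- as.numeric(wm$W %*% y)
  qx <- qr(X)
  if (qx$rank < p)
    stop_("rank-deficient design: collinear column(s) %s",
          paste(colnames(X)[qx$pivot[(qx$rank + 1):p]], collapse = ", "))
  e0 <- qr.resid(qx, y)
  e1 <- qr.resid(qx, Wy)
  a <- sum(e0^2); b <- sum(e0 * e1); cc <- sum(e1^2)
  const <- -n / 2 * (log(2 * pi) + 1)
  pll <- function(rho)
    const - n / 2 * log((a - 2 * rho * b + rho^2 * cc) / n) +
      sum(log(Mod(1 - rho * ev)))
  boundary <- FALSE
  if (is.null(fix_rho)) {
    eps <- 1e-6 * diff(fi)
    grid <- seq(fi[1] + eps, fi[2] - eps, length.out = 101)
    gv <- vapply(grid, pll, numeric(1))
    gi <- which.max(gv)
    lo <- grid[max(1, gi - 1)]; hi <- grid[min(length(grid), gi + 1)]
    opt <- optimize(pll, c(lo, hi), maximum = TRUE, tol = 1e-9)
    rho <- opt$maximum
    boundary <- min(rho - fi[1], fi[2] - rho) < 1e-4 * diff(fi)
  } else {
    if (fix_rho <= fi[1] || fix_rho >= fi[2])
      stop_("fix_rho = %.4f outside the feasible interval (%.4f, %.4f)",
            fix_rho, fi[1], fi[2])
    rho <- fix_rho
  }
  beta <- qr.coef(qx, y - rho * Wy)
  sigma2 <- (a - 2 * rho * b + rho^2 * cc) / n
  ll <- pll(rho)
  k <- p + 2L
  # asymptotic vcov of (rho, beta) from the full-likelihood Hessian
  par <- c(rho, beta, sigma2)
  vc <- NULL; converged <- !boundary
  H <- try(optimHess(par, full_loglik, y = y, X = X, Wy = Wy, ev = ev,
                     control = list(ndeps = pmax(abs(par) * 1e-4, 1e-6))),
           silent = TRUE)
  if (!inherits(H, "try-error")) {
    Vfull <- try(solve(-H), silent = TRUE)
    if (!inherits(Vfull, "try-error") && all(diag(Vfull)[1:(p + 1)] > 0))
      vc <- Vfull[1:(p + 1), 1:(p + 1), drop = FALSE]
  }
  if (is.null(vc)) {
    converged <- FALSE
    vc <- matrix(NA_real_, p + 1, p + 1)
  }
  nm <- c("rho", colnames(X) %||% paste0("x", seq_len(p)))
  dimnames(vc) <- list(nm, nm)
  se <- sqrt(diag(vc))
  est <- c(rho = rho, setNames(beta, colnames(X)))
  ci <- cbind(lower = est - qnorm(0.975) * se,
              upper = est + qnorm(0.975) * se)
  structure(list(rho = rho, beta = setNames(beta, colnames(X)),
                 sigma2 = sigma2, loglik = ll, aic = 2 * k - 2 * ll,
                 vcov = vc, se = se, ci = ci,
                 rho_ci = ci[1, ],
                 feasible_interval = fi,
                 converged = converged, boundary = boundary,
                 residuals = y - rho * Wy - drop(X %*% beta),
                 n = n, k = k, ids = wm$ids),
            class = "network_fit")
}

#' @export
print.network_fit <- function(x, ...) {
  cat(sprintf("Network autocorrelation model, n = %d, AIC = %.1f%s\n",
              x$n, x$aic, if (x$converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("  network dependence rho = %.3f (95%% CI %.3f to %.3f)\n",
              x$rho, x$rho_ci[1], x$rho_ci[2]))
  est <- cbind(coefficient = c(x$rho, x$beta), se = x$se, x$ci)
  print(round(est, 4))
  invisible(x)
}

#' Akaike information criterion of a fitted model
#'
#' `AIC = 2k - 2 loglik`; k counts the intercept, slopes and error variance,
#' plus the network dependence parameter for the lag model.
#'
#' @param fit an `ols_fit` or `network_fit`.
#' @return scalar AIC.
#' @export
model_aic <- function(fit) {
  stopifnot(is.finite(fit$loglik))
  2 * fit$k - 2 * fit$loglik
}
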