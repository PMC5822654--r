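# mean diagonal and mean row-sum of M = (I - rho W)^{-1}, computed exactly
# per school block (M is block-diagonal when W is)
impact_multipliers <- function(wm, rho) {
  n <- nrow(wm$W)
  sdiag <- 0; srow <- 0
  for (idx in school_blocks(wm)) {
    A <- diag(length(idx)) - rho * as.matrix(wm$W[idx, idx, drop = FALSE])
    M <- tryCatch(solve(A), error = function(e)
      stop_("singular (I - rho W) at rho = %.4f", rho))
    sdiag <- sdiag + sum(diag(M))
    srow <- srow + sum(M)
  }
  c(mdiag = sdiag / n, mrow = srow / n)
}

#' Direct, indirect and total impacts of the covariates
#'
#' In the network lag model a unit change in covariate k for every child
#' changes the outcome vector by \eqn{M \beta_k} with
#' \eqn{M = (I - \hat\rho W)^{-1}}. The summary measures follow the standard
#' averaging convention: direct = \eqn{\hat\beta_k} times the mean diagonal
#' of M (own-child effect including feedback), total = \eqn{\hat\beta_k}
#' times the mean row sum of M, and indirect ("spillover") = total - direct,
#' exactly.
#'
#' @param fit a converged [fit_network_model()] result.
#' @param W the [weight_matrix()] used in the fit.
#' @param covariates names of coefficients to decompose (default: all but
#'   the first, assumed to be the intercept).
#' @return object of class `impact_summary`: data frame with columns
#'   `covariate`, `direct`, `indirect`, `total`.
#' @export
impact_point_estimates <- function(fit, W,
                                   covariates = names(fit$beta)[-1]) {
  wm <- as_weight_matrix(W)
  if (!isTRUE(fit$converged))
    warning("impacts from a fit flagged as not converged", call. = FALSE)
  mm <- impact_multipliers(wm, fit$rho)
  b <- fit$beta[covariates]
  out <- data.frame(covariate = covariates,
                    direct = unname(b * mm["mdiag"]),
                    total = unname(b * mm["mrow"]),
                    stringsAsFactors = FALSE)
  out$indirect <- out$total - out$direct
  out <- out[, c("covariate", "direct", "indirect", "total")]
  class(out) <- c("impact_summary", "data.frame")
  out
}

#' Percentile confidence intervals for the impacts
#'
#' Draws `n_sims` parameter vectors from the multivariate normal centred at
#' \eqn{(\hat\rho, \hat\beta)} with the fit's asymptotic covariance,
#' discards draws whose \eqn{\rho} falls outside the feasible interval
#' (count reported; more than 50% infeasible is an error), recomputes the
#' impacts for each retained draw, and reports the 2.5 and 97.5 percentiles.
#'
#' @inheritParams impact_point_estimates
#' @param n_sims number of simulation draws (default 200).
#' @param seed integer seed.
#' @param keep_draws attach the per-draw impact array (covariate x measure x
#'   draw) as attribute `"draws"`?
#' @return an `impact_summary` data frame with additional columns
#'   `direct_lo`, `direct_hi`, `indirect_lo`, `indirect_hi`, `total_lo`,
#'   `total_hi`; attributes `n_sims`, `n_infeasible`, `seed`.
#' @export
impact_intervals <- function(fit, W, n_sims = 200, seed = 1L,
                             covariates = names(fit$beta)[-1],
                             keep_draws = FALSE) {
  wm <- as_weight_matrix(W)
  if (any(!is.finite(fit$vcov)))
    stop_("fit has no usable (rho, beta) covariance")
  point <- impact_point_estimates(fit, W, covariates)
  set.seed(seed)
  mu <- c(fit$rho, fit$beta)
  draws <- MASS::mvrnorm(n_sims, mu = mu, Sigma = fit$vcov)
  fi <- fit$feasible_interval
  ok <- draws[, 1] > fi[1] & draws[, 1] < fi[2]
  if (mean(ok) < 0.5)
    stop_("%d of %d draws have infeasible rho; the model may be misfit",
          sum(!ok), n_sims)
  draws <- draws[ok, , drop = FALSE]
  ci <- array(NA_real_, c(length(covariates), 3, nrow(draws)),
              dimnames = list(covariates, c("direct", "indirect", "total"), NULL))
  kidx <- match(covariates, names(fit$beta)) + 1L
  for (s in seq_len(nrow(draws))) {
    mm <- impact_multipliers(wm, draws[s, 1])
    bd <- draws[s, kidx]
    ci[, "direct", s] <- bd * mm["mdiag"]
    ci[, "total", s] <- bd * mm["mrow"]
    ci[, "indirect", s] <- ci[, "total", s] - ci[, "direct", s]
  }
  q <- apply(ci, c(1, 2), quantile, probs = c(0.025, 0.975), names = FALSE)
  for (m in c("direct", "indirect", "total")) {
    point[[paste0(m, "_lo")]] <- q[1, , m]
    point[[paste0(m, "_hi")]] <- q[2, , m]
  }
  outside <- with(point, direct < direct_lo | direct > direct_hi |
                    total < total_lo | total > total_hi)
  if (any(outside))
    message("percentile CI excludes the point estimate for: ",
            paste(point$covariate[outside], collapse = ", "))
  attr(point, "n_sims") <- n_sims
  attr(point, "n_infeasible") <- sum(!ok)
  attr(point, "seed") <- seed
  if (keep_draws) attr(point, "draws") <- ci
  point
}

#' @export
print.impact_summary <- function(x, ...) {
  cat("Impact decomposition (outcome units per covariate unit)\n")
  print.data.frame(cbind(covariate = x$covariate,
                         round(x[vapply(x, is.numeric, logical(1))], 3)),
                   row.names = FALSE)
  invisible(x)
}
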