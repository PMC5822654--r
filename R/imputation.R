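# one Bayesian normal-linear imputation draw: fit y ~ X on observed rows,
# draw (sigma*, beta*) from their posterior under the standard flat prior,
# and return predicted draws for the missing rows
bayes_lm_draw <- function(y_obs, X_obs, X_mis) {
  qx <- qr(X_obs)
  r <- qx$rank
  keep <- qx$pivot[seq_len(r)]
  Xo <- X_obs[, keep, drop = FALSE]
  qo <- qr(Xo)
  beta <- qr.coef(qo, y_obs)
  res <- y_obs - drop(Xo %*% beta)
  df <- max(length(y_obs) - r, 1)
  sigma2_star <- sum(res^2) / rchisq(1, df)
  R <- qr.R(qo)[, order(qo$pivot), drop = FALSE]
  beta_star <- beta + backsolve(R, rnorm(r)) * sqrt(sigma2_star)
  drop(X_mis[, keep, drop = FALSE] %*% beta_star) +
    rnorm(nrow(X_mis), 0, sqrt(sigma2_star))
}

#' Multiple imputation by chained equations (regression switching)
#'
#' Creates `m` completed datasets. Missing cells are initialised by draws
#' from the observed marginals, then `n_cycles` cycles of regression
#' switching impute each variable in a fixed order from a normal-linear
#' regression on all other modelled variables plus school indicators, with
#' draws that propagate both parameter and residual uncertainty. Ordinal
#' items are rounded and bounded to their range; passive variables (the
#' activity participation score) are recomputed as their item sum in every
#' completed dataset, never imputed directly. When a `by` column is given
#' (sex), imputation runs independently within each stratum.
#'
#' @param data data frame containing `school_col`, the modelled variables
#'   and (optionally) the `by` column.
#' @param vars modelled variable names, in imputation order (covariates,
#'   items, outcomes).
#' @param m number of imputed datasets (default 20).
#' @param n_cycles cycles of regression switching per dataset (default 20).
#' @param seed integer seed.
#' @param by optional stratification column name (e.g. `"sex"`).
#' @param school_col school identifier column, entered as categorical
#'   indicators in every imputation model.
#' @param ordinal named list of `c(lower, upper)` ranges for item variables.
#' @param passive named list: `score_name = c(item names)`; the score is
#'   recomputed as the item sum.
#' @return object of class `imputed_stack`: list with `m`, `datasets`,
#'   `n_cycles`, `seed`, `mask` (logical matrix of originally missing
#'   cells over `vars`).
#' @export
chained_imputation <- function(data, vars, m = 20, n_cycles = 20, seed = 1L,
                               by = NULL, school_col = "school_id",
                               ordinal = list(item1 = c(0, 3), item2 = c(0, 3),
                                              item3 = c(0, 3), item4 = c(0, 3)),
                               passive = list(activity_score =
                                                c("item1", "item2", "item3", "item4"))) {
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop_("variables not in data: %s", paste(missing_vars, collapse = ", "))
  mask <- sapply(vars, function(v) is.na(data[[v]]))
  if (any(colSums(!mask) == 0))
    stop_("variable(s) 100%% missing: %s",
          paste(vars[colSums(!mask) == 0], collapse = ", "))
  set.seed(seed)
  datasets <- vector("list", m)
  strata <- if (is.null(by)) list(seq_len(nrow(data)))
            else split(seq_len(nrow(data)), data[[by]])
  for (d in seq_len(m)) {
    comp <- data
    for (rows in strata) {
      sub <- comp[rows, , drop = FALSE]
      smask <- mask[rows, , drop = FALSE]
      if (any(smask)) {
        # initialise from observed marginals within stratum
        for (v in vars[colSums(smask) > 0]) {
          pool <- sub[[v]][!smask[, v]]
          if (!length(pool)) pool <- data[[v]][!mask[, v]]
          sub[[v]][smask[, v]] <- sample(pool, sum(smask[, v]), replace = TRUE)
        }
        sch <- factor(sub[[school_col]])
        Xsch <- if (nlevels(sch) > 1)
          stats::model.matrix(~sch)[, -1, drop = FALSE] else NULL
        impute_vars <- vars[colSums(smask) > 0]
        for (cyc in seq_len(n_cycles)) {
          for (v in impute_vars) {
            others <- setdiff(vars, c(v, names(passive)))
            X <- cbind(1, as.matrix(sub[others]), Xsch)
            mis <- smask[, v]
            imp <- bayes_lm_draw(sub[[v]][!mis], X[!mis, , drop = FALSE],
                                 X[mis, , drop = FALSE])
            if (v %in% names(ordinal)) {
              rng <- ordinal[[v]]
              imp <- pmin(pmax(round(imp), rng[1]), rng[2])
            }
            sub[[v]][mis] <- imp
            for (sc in names(passive))
              if (v %in% passive[[sc]])
                sub[[sc]] <- passive_score(sub[passive[[sc]]],
                                           range = c(0, 3), quiet = TRUE)
          }
        }
      }
      comp[rows, ] <- sub
    }
    datasets[[d]] <- comp
  }
  structure(list(m = m, datasets = datasets, n_cycles = n_cycles,
                 seed = seed, mask = mask, vars = vars),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf("Imputed stack: m = %d datasets, %d cycles, %d of %d cells imputed\n",
              x$m, x$n_cycles, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Passive activity participation score
#'
#' Recomputes the 0-12 activity participation score as the sum of its four
#' 0-3 frequency items. Items outside the valid range (possible after a
#' continuous imputation draw) are clipped to the range, with a message.
#'
#' @param items data frame or matrix of item columns.
#' @param range valid item range (default 0-3).
#' @param quiet suppress the clipping message?
#' @return numeric score vector (item sum).
#' @export
passive_score <- function(items, range = c(0, 3), quiet = FALSE) {
  items <- as.matrix(items)
  out_of_range <- items < range[1] | items > range[2]
  if (any(out_of_range, na.rm = TRUE)) {
    if (!quiet)
      message(sum(out_of_range, na.rm = TRUE),
              " item value(s) outside [", range[1], ",", range[2], "] clipped")
    items <- pmin(pmax(items, range[1]), range[2])
  }
  rowSums(items)
}

# extract (estimate, variance) vectors from a fitted model for pooling
fit_estimates <- function(fit) {
  if (inherits(fit, "network_fit"))
    list(est = c(rho = fit$rho, fit$beta), var = diag(fit$vcov))
  else if (inherits(fit, "ols_fit"))
    list(est = fit$beta, var = diag(fit$vcov_cluster))
  else if (is.list(fit) && all(c("est", "var") %in% names(fit)))
    fit
  else stop_("cannot extract estimates from object of class %s",
             paste(class(fit), collapse = "/"))
}

#' Pool per-imputation fits with Rubin's rules
#'
#' For each parameter: pooled estimate \eqn{\bar q} (mean across
#' imputations), within-imputation variance \eqn{\bar W} (mean of the
#' squared SEs), between-imputation variance B (sample variance of the
#' estimates), total variance \eqn{T = \bar W + (1 + 1/m)B}, Rubin's
#' small-sample degrees of freedom
#' \eqn{\nu = (m-1)\,[1 + \bar W / ((1+1/m)B)]^2}, and a 95% t CI.
#'
#' @param fits list of `m >= 2` fitted models (`ols_fit`, `network_fit`, or
#'   lists with `est`/`var`) sharing a common parameter list.
#' @return object of class `pooled_fit`: data frame with columns
#'   `parameter`, `estimate`, `within`, `between`, `total_var`, `se`, `df`,
#'   `ci_lower`, `ci_upper`; attribute `m`.
#' @export
pool_rubin <- function(fits) {
  stopifnot(length(fits) >= 2)
  ex <- lapply(fits, fit_estimates)
  nm <- names(ex[[1]]$est) %||% paste0("p", seq_along(ex[[1]]$est))
  for (e in ex)
    if (length(e$est) != length(nm) ||
        !identical(names(e$est), names(ex[[1]]$est)))
      stop_("mismatched parameter lists across fits")
  m <- length(fits)
  Q <- do.call(rbind, lapply(ex, `[[`, "est"))
  U <- do.call(rbind, lapply(ex, `[[`, "var"))
  qbar <- colMeans(Q)
  wbar <- colMeans(U)
  B <- apply(Q, 2, var)
  Tv <- wbar + (1 + 1 / m) * B
  df <- ifelse(B > 0, (m - 1) * (1 + wbar / ((1 + 1 / m) * B))^2, Inf)
  tq <- qt(0.975, df)
  out <- data.frame(parameter = nm, estimate = qbar, within = wbar,
                    between = B, total_var = Tv, se = sqrt(Tv), df = df,
                    ci_lower = qbar - tq * sqrt(Tv),
                    ci_upper = qbar + tq * sqrt(Tv),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "m") <- m
  class(out) <- c("pooled_fit", "data.frame")
  out
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat(sprintf("Rubin's-rules pooled estimates (m = %d imputations)\n",
              attr(x, "m")))
  print.data.frame(cbind(parameter = x$parameter,
                         round(x[, c("estimate", "se", "ci_lower",
                                     "ci_upper")], 4)),
                   row.names = FALSE)
  invisible(x)
}
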