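#' Network lag of an outcome vector
#'
#' For a row-standardised weight matrix, entry i of `W x` is the weighted
#' mean of i's friends' values. Rows with no ties (all-zero weights) yield a
#' lag of 0 and their indices are attached as attribute `"zero_rows"`.
#'
#' @param x numeric outcome vector.
#' @param W a [weight_matrix()] (row-standardised).
#' @return numeric lag vector `W x`.
#' @export
spatial_lag <- function(x, W) {
  wm <- as_weight_matrix(W)
  if (length(x) != nrow(wm$W))
    stop_("dimension mismatch: x has %d elements, W is %d x %d",
          length(x), nrow(wm$W), ncol(wm$W))
  if (!all(is.finite(x))) stop_("x must be finite")
  lag <- as.numeric(wm$W %*% x)
  zr <- which(Matrix::rowSums(abs(wm$W)) == 0)
  attr(lag, "zero_rows") <- zr
  lag
}

# triplet representation plus the inclusion subset used by Moran statistics:
# observations with all-zero weight rows are excluded from n, S0 and the mean
moran_prep <- function(x, W) {
  wm <- as_weight_matrix(W)
  if (length(x) != nrow(wm$W)) stop_("dimension mismatch")
  inc <- which(Matrix::rowSums(abs(wm$W)) > 0)
  if (length(inc) == 0) stop_("W has no nonzero entries")
  Wsub <- wm$W[inc, inc, drop = FALSE]
  tr <- Matrix::summary(Wsub)
  list(x = x[inc], i = tr$i, j = tr$j, w = tr$x, n = length(inc),
       S0 = sum(tr$x), ids = wm$ids[inc])
}

moran_stat <- function(z, p) {
  denom <- sum(z^2)
  if (denom < .Machine$double.eps * length(z))
    stop_("Moran's I is undefined: x has zero variance")
  (p$n / p$S0) * sum(p$w * z[p$i] * z[p$j]) / denom
}

#' Moran's I statistic on a friendship weight matrix
#'
#' Computes
#' \deqn{I = \frac{n}{S_0} \frac{\sum_{ij} w_{ij}(x_i-\bar x)(x_j-\bar x)}
#'   {\sum_i (x_i-\bar x)^2}}
#' over the observations with at least one tie (all-zero weight rows are
#' excluded from `n`, `S0` and the mean).
#'
#' @inheritParams spatial_lag
#' @return the Moran's I statistic (dimensionless).
#' @export
morans_i <- function(x, W) {
  p <- moran_prep(x, W)
  moran_stat(p$x - mean(p$x), p)
}

#' Permutation (or analytic) test for positive network autocorrelation
#'
#' One-sided test of Moran's I against the null of no autocorrelation. The
#' permutation p-value is `(1 + #\{permuted I >= observed I\}) / (n_perm + 1)`;
#' the analytic alternative uses the normal approximation under
#' randomisation. The expectation `-1/(n-1)` is reported alongside.
#'
#' @inheritParams spatial_lag
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutation draw.
#' @param method `"permutation"` (default) or `"analytic"`.
#' @return object of class `moran_result`: list with `I`, `expected_I`,
#'   `p_value`, `method`, `n_perm`, `seed`, `n`.
#' @export
morans_i_test <- function(x, W, n_perm = 999, seed = 1L,
                          method = c("permutation", "analytic")) {
  method <- match.arg(method)
  p <- moran_prep(x, W)
  z <- p$x - mean(p$x)
  I_obs <- moran_stat(z, p)
  if (method == "permutation") {
    if (n_perm < 99) stop_("n_perm must be at least 99")
    set.seed(seed)
    denom <- sum(z^2)
    ge <- 0L
    for (b in seq_len(n_perm)) {
      zp <- z[sample.int(p$n)]
      Ib <- (p$n / p$S0) * sum(p$w * zp[p$i] * zp[p$j]) / denom
      if (Ib >= I_obs) ge <- ge + 1L
    }
    pval <- (1 + ge) / (n_perm + 1)
  } else {
    pval <- moran_analytic_p(z, p, I_obs)
    n_perm <- NA_integer_
  }
  structure(list(I = I_obs, expected_I = -1 / (p$n - 1), p_value = pval,
                 method = method, n_perm = n_perm, seed = seed, n = p$n),
            class = "moran_result")
}

# normal approximation under randomisation (one-sided, upper)
moran_analytic_p <- function(z, p, I_obs) {
  n <- p$n
  Wd <- Matrix::sparseMatrix(i = p$i, j = p$j, x = p$w, dims = c(n, n))
  S0 <- p$S0
  S1 <- sum((Wd + Matrix::t(Wd))@x^2) / 2
  S2 <- sum((Matrix::rowSums(Wd) + Matrix::colSums(Wd))^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  EI <- -1 / (n - 1)
  EI2 <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
            b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2)
  v <- EI2 - EI^2
  pnorm((I_obs - EI) / sqrt(v), lower.tail = FALSE)
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expectation %.4f under no autocorrelation)\n",
              x$I, x$expected_I))
  cat(sprintf("  one-sided p = %.4g (%s%s), n = %d\n", x$p_value, x$method,
              if (is.na(x$n_perm)) "" else sprintf(", %d permutations", x$n_perm),
              x$n))
  invisible(x)
}

#' Moran scatter data: centred values against their network lag
#'
#' For row-standardised weights the least-squares slope of the lag on the
#' centred value approximates Moran's I; the scatter shows how similar
#' children are to their immediate friends.
#'
#' @inheritParams spatial_lag
#' @return data frame with columns `id`, `x_centred`, `lag` (one row per
#'   included, non-zero-row observation).
#' @export
moran_scatter <- function(x, W) {
  p <- moran_prep(x, W)
  z <- p$x - mean(p$x)
  Wd <- Matrix::sparseMatrix(i = p$i, j = p$j, x = p$w, dims = c(p$n, p$n))
  data.frame(id = p$ids, x_centred = z, lag = as.numeric(Wd %*% p$x),
             stringsAsFactors = FALSE)
}
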