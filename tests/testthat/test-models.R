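test_that("OLS baseline: mean identity, duplication invariance, rank check", {
  set.seed(71)
  y <- rnorm(40)
  g <- rep(letters[1:8], each = 5)
  f0 <- fit_ols(y, cbind(intercept = rep(1, 40)), g)
  expect_equal(unname(f0$beta), mean(y), tolerance = 1e-12)
  X <- cbind(intercept = 1, x1 = rnorm(40), x2 = rnorm(40))
  f1 <- fit_ols(y, X, g)
  f2 <- fit_ols(c(y, y), rbind(X, X), c(g, g))
  expect_equal(f2$beta, f1$beta, tolerance = 1e-10)
  # residual orthogonality to the design
  expect_lt(max(abs(crossprod(X, f1$residuals))), 1e-8)
  Xbad <- cbind(X, x3 = X[, "x1"] * 2)
  expect_error(fit_ols(y, Xbad, g), "x3")
  expect_error(fit_ols(y, X, rep("a", 40)), "2 clusters")
})

test_that("cluster sandwich matches the reference meat with the stated factor", {
  skip_if_not_installed("sandwich")
  # one observation per cluster: sandwich equals the HC meat up to the factor
  set.seed(72)
  n <- 6
  X <- cbind(intercept = 1, x = rnorm(n))
  y <- rnorm(n)
  g <- letters[1:n]
  f <- fit_ols(y, X, g)
  m <- lm(y ~ 0 + X)
  Vref <- sandwich::vcovCL(m, cluster = g, type = "HC0", cadjust = FALSE)
  k <- ncol(X)
  adj <- n / (n - 1) * (n - 1) / (n - k)
  expect_equal(unname(f$vcov_cluster), unname(adj * Vref), tolerance = 1e-8)
  # many clusters with several observations each
  set.seed(73)
  n2 <- 60; g2 <- rep(letters[1:12], each = 5)
  X2 <- cbind(intercept = 1, a = rnorm(n2), b = rnorm(n2))
  y2 <- rnorm(n2)
  f2 <- fit_ols(y2, X2, g2)
  Vref2 <- sandwich::vcovCL(lm(y2 ~ 0 + X2), cluster = g2, type = "HC0",
                            cadjust = FALSE)
  adj2 <- 12 / 11 * (n2 - 1) / (n2 - 3)
  expect_equal(unname(f2$vcov_cluster), unname(adj2 * Vref2), tolerance = 1e-8)
  # loglik/AIC agree with the standard Gaussian definitions
  expect_equal(f2$loglik, as.numeric(logLik(lm(y2 ~ 0 + X2))), tolerance = 1e-8)
  expect_equal(f2$aic, AIC(lm(y2 ~ 0 + X2)), tolerance = 1e-8)
})

test_that("profile likelihood: rho = 0 equals OLS, dense determinant oracle", {
  st <- make_stratum(seed = 74, n_schools = 2, per_school = 5)
  y <- st$y; X <- st$X; W <- st$W
  n <- length(y)
  # rho = 0: log-det vanishes, equals the OLS Gaussian log-likelihood
  ols <- fit_ols(y, X, st$dat$school_id)
  expect_equal(profile_loglik(0, y, X, W), ols$loglik, tolerance = 1e-10)
  # dense determinant oracle across a rho grid (n = 10, directed W)
  Wd <- as.matrix(W$W)
  for (rho in seq(-0.8, 0.8, by = 0.2)) {
    z <- y - rho * Wd %*% y
    rss <- sum(qr.resid(qr(X), z)^2)
    oracle <- -n / 2 * (log(2 * pi) + 1) - n / 2 * log(rss / n) +
      log(abs(det(diag(n) - rho * Wd)))
    expect_equal(profile_loglik(rho, y, X, W), oracle, tolerance = 1e-9)
  }
  # eigenvalue log-det equals log|det| on a random directed 10-node W
  W10 <- random_weight_matrix(10, seed = 75)
  ev <- weight_eigenvalues(W10)
  for (rho in c(-0.5, 0.3, 0.7))
    expect_equal(sum(log(Mod(1 - rho * ev))),
                 log(abs(det(diag(10) - rho * as.matrix(W10$W)))),
                 tolerance = 1e-9)
  expect_error(profile_loglik(1, y, X, W), "singularity")
})

test_that("network model nests OLS at rho = 0 and AIC differs by exactly 2", {
  st <- make_stratum(seed = 76, n_schools = 6, per_school = 20)
  ols <- fit_ols(st$y, st$X, st$dat$school_id)
  net0 <- fit_network_model(st$y, st$X, st$W, fix_rho = 0)
  expect_equal(net0$beta, ols$beta, tolerance = 1e-8)
  expect_equal(net0$loglik, ols$loglik, tolerance = 1e-10)
  expect_equal(net0$aic - ols$aic, 2, tolerance = 1e-10)
  expect_equal(model_aic(net0), net0$aic)
})

test_that("optimiser's rho matches a fine grid search and maximises the profile", {
  st <- make_stratum(seed = 77, n_schools = 8, per_school = 20)
  fit <- fit_network_model(st$y, st$X, st$W)
  expect_true(fit$converged)
  fi <- fit$feasible_interval
  grid <- seq(fi[1] + 1e-4, fi[2] - 1e-4, by = 1e-4)
  pll <- sapply(grid, function(r) profile_loglik(r, st$y, st$X, st$W))
  expect_lt(abs(grid[which.max(pll)] - fit$rho), 1e-3)
  expect_true(all(profile_loglik(fit$rho, st$y, st$X, st$W) >= pll - 1e-9))
})

test_that("estimates are invariant to node reordering", {
  st <- make_stratum(seed = 78, n_schools = 4, per_school = 15)
  set.seed(79)
  p <- sample(length(st$y))
  Wp <- as_weight_matrix(as.matrix(st$W$W)[p, p], school = st$W$school[p])
  f1 <- fit_network_model(st$y, st$X, st$W)
  f2 <- fit_network_model(st$y[p], st$X[p, ], Wp)
  expect_equal(f2$rho, f1$rho, tolerance = 1e-6)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-6)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
})

test_that("AIC shift-invariance and rho recovery at moderate n", {
  st <- make_stratum(seed = 80, n_schools = 8, per_school = 20)
  X <- st$X
  ols1 <- fit_ols(st$y, X, st$dat$school_id)
  net1 <- fit_network_model(st$y, X, st$W)
  ols2 <- fit_ols(st$y + 100, X, st$dat$school_id)
  net2 <- fit_network_model(st$y + 100, X, st$W)
  # intercept absorbs a constant shift in the AIC comparison
  expect_equal(net2$aic - ols2$aic, net1$aic - ols1$aic, tolerance = 1e-4)
  # the non-convergence flag is honest about boundary solutions
  expect_true(is.logical(net1$converged))
  expect_true(net1$rho > net1$feasible_interval[1] &&
                net1$rho < net1$feasible_interval[2])
})
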