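#' Simulation configuration for a synthetic friendship-network study
#'
#' Defines the data-generating conditions for a synthetic cohort of
#' primary-school children: school structure, friend-nomination behaviour,
#' covariate marginals, the network-autocorrelated outcome model and
#' missingness rates. Defaults emulate a study of ~47 schools and ~1200
#' children aged 8-9, with ~90% same-sex nomination ties, up to four
#' nominations per child, and per-variable missingness between 0.5% and 18%.
#'
#' Outcomes follow the network autocorrelation (spatial lag) model
#' \deqn{y = \rho W y + X\beta + u + \epsilon}
#' with school random intercepts \eqn{u} and iid Gaussian noise
#' \eqn{\epsilon}; `beta` is ordered (intercept, IMD, BMI z-score, activity
#' participation score). Minutes/day of moderate-to-vigorous physical
#' activity (MVPA) is the primary outcome; a second outcome (sedentary
#' minutes/day) is generated from `sedentary`.
#'
#' @param n_schools number of schools.
#' @param children_per_school a single count or a range of counts sampled
#'   uniformly per school.
#' @param p_female probability a child is female.
#' @param max_nominations maximum friend nominations per child.
#' @param n_nominations set of nomination counts sampled uniformly per child
#'   (capped at `max_nominations` and at school size minus one).
#' @param p_same_sex_tie probability each nomination targets a same-sex
#'   schoolmate.
#' @param rho network dependence parameter, `|rho| < 1`.
#' @param beta coefficients (intercept, IMD, BMI z, activity score) for the
#'   primary outcome, in min/day per covariate unit.
#' @param sigma residual SD (min/day) for the primary outcome.
#' @param school_sd SD (min/day) of the school random intercept.
#' @param sedentary list with elements `rho`, `beta`, `sigma` for the
#'   sedentary-time outcome.
#' @param missing_rates named per-variable missingness probabilities (must be
#'   `< 1`).
#' @param seed master integer seed; all generation is a pure function of
#'   (config, seed).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_schools = 47,
                       children_per_school = 20:32,
                       p_female = 0.55,
                       max_nominations = 4,
                       n_nominations = 2:4,
                       p_same_sex_tie = 0.90,
                       rho = 0.20,
                       beta = c(-15, 0, -2.5, 2.5),
                       sigma = 15,
                       school_sd = 5,
                       sedentary = list(rho = 0.12, beta = c(20, 0.15, 2, -3.8), sigma = 40),
                       missing_rates = c(bmi_z = 0.005, imd = 0.02,
                                         item1 = 0.05, item2 = 0.05,
                                         item3 = 0.05, item4 = 0.05,
                                         mean_mvpa = 0.15, mean_sedentary = 0.18),
                       seed = 1L) {
  if (!is.numeric(n_schools) || length(n_schools) != 1 || n_schools < 1)
    stop_("configuration error: n_schools must be a positive count (got %s)",
          paste(n_schools, collapse = ","))
  if (!is_probability(p_female)) stop_("p_female must be a probability in [0,1]")
  if (!is_probability(p_same_sex_tie)) stop_("p_same_sex_tie must be a probability in [0,1]")
  if (max_nominations < 1) stop_("max_nominations must be >= 1")
  if (abs(rho) >= 1) stop_("|rho| must be < 1")
  if (sigma <= 0) stop_("sigma must be positive")
  if (school_sd < 0) stop_("school_sd must be non-negative")
  if (length(beta) != 4) stop_("beta must have 4 elements (intercept, imd, bmi_z, activity_score)")
  if (any(missing_rates < 0) || any(missing_rates > 1))
    stop_("missing_rates must lie in [0,1]")
  cfg <- list(n_schools = as.integer(n_schools),
              children_per_school = as.integer(children_per_school),
              p_female = p_female,
              max_nominations = as.integer(max_nominations),
              n_nominations = pmin(as.integer(n_nominations), as.integer(max_nominations)),
              p_same_sex_tie = p_same_sex_tie,
              rho = rho, beta = beta, sigma = sigma, school_sd = school_sd,
              sedentary = sedentary,
              missing_rates = missing_rates,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d schools, %s children/school, P(female) = %.2f\n",
              x$n_schools,
              if (length(x$children_per_school) > 1)
                sprintf("%d-%d", min(x$children_per_school), max(x$children_per_school))
              else x$children_per_school, x$p_female))
  cat(sprintf("  nominations: %s per child (max %d), P(same-sex tie) = %.2f\n",
              paste(range(x$n_nominations), collapse = "-"),
              x$max_nominations, x$p_same_sex_tie))
  cat(sprintf("  outcome model: rho = %.2f, sigma = %.1f, school SD = %.1f\n",
              x$rho, x$sigma, x$school_sd))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Generate a synthetic roster of children
#'
#' Draws per-child sex, BMI z-score, deprivation (IMD) score and four
#' activity-frequency items (each 0-3); the activity participation score is
#' the item sum, so it always lies in 0-12. IMD is gamma-distributed with
#' mean 15 and SD 10, giving the right skew typical of deprivation indices.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return data frame with columns `child_id`, `school_id`, `sex` ("F"/"M"),
#'   `bmi_z`, `imd`, `item1`..`item4`, `activity_score`.
#' @export
generate_roster <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  sizes <- if (length(config$children_per_school) > 1)
    sample(config$children_per_school, config$n_schools, replace = TRUE)
  else rep(config$children_per_school, config$n_schools)
  school <- rep(sprintf("s%02d", seq_len(config$n_schools)), sizes)
  n <- length(school)
  id <- sprintf("%s_c%03d", school, unlist(lapply(sizes, seq_len)))
  items <- matrix(sample(0:3, 4 * n, replace = TRUE), ncol = 4)
  # gamma with mean 15, SD 10: shape = (15/10)^2, rate = 15/10^2
  roster <- data.frame(
    child_id = id,
    school_id = school,
    sex = ifelse(runif(n) < config$p_female, "F", "M"),
    bmi_z = rnorm(n, 0.3, 1),
    imd = rgamma(n, shape = 2.25, rate = 0.15),
    item1 = items[, 1], item2 = items[, 2],
    item3 = items[, 3], item4 = items[, 4],
    stringsAsFactors = FALSE)
  roster$activity_score <- rowSums(items)
  roster
}

#' Generate friend nominations for a synthetic roster
#'
#' Each child nominates between one and `max_nominations` distinct
#' schoolmates (never themselves), within school only; each tie is same-sex
#' with probability `p_same_sex_tie`. Children in a school of size one emit
#' zero nominations.
#'
#' @inheritParams generate_roster
#' @param roster data frame from [generate_roster()].
#' @return data frame with columns `nominator_id`, `rank`, `nominee_id`.
#' @export
generate_nominations <- function(roster, config, seed = config$seed) {
  stopifnot(nrow(roster) > 0)
  set.seed(derive_seed(seed, 1L))
  by_school <- split(seq_len(nrow(roster)), roster$school_id)
  out <- vector("list", nrow(roster))
  for (i in seq_len(nrow(roster))) {
    mates <- setdiff(by_school[[roster$school_id[i]]], i)
    if (length(mates) == 0) next  # singleton school: no nominations
    k <- min(sample(config$n_nominations, 1), length(mates))
    chosen <- integer(0)
    for (r in seq_len(k)) {
      want_same <- runif(1) < config$p_same_sex_tie
      pool <- setdiff(mates[(roster$sex[mates] == roster$sex[i]) == want_same], chosen)
      if (length(pool) == 0) pool <- setdiff(mates, chosen)
      if (length(pool) == 0) break
      chosen <- c(chosen, pool[sample.int(length(pool), 1)])
    }
    if (length(chosen))
      out[[i]] <- data.frame(nominator_id = roster$child_id[i],
                             rank = seq_along(chosen),
                             nominee_id = roster$child_id[chosen],
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Generate outcomes from the network autocorrelation model
#'
#' Draws \eqn{y = (I - \rho W)^{-1} (X\beta + u + \epsilon)} — the exact
#' reduced form of \eqn{y = \rho W y + X\beta + u + \epsilon} — with school
#' random intercepts \eqn{u \sim N(0, \sigma_s^2)} shared within school and
#' iid \eqn{\epsilon \sim N(0, \sigma^2)}. The linear system is solved
#' exactly (per school block), never truncated.
#'
#' @param W a [weight_matrix()] (row-standardised) or square matrix.
#' @param X covariate matrix with rows matching `W`.
#' @param config a [sim_config()] supplying `rho`, `beta`, `sigma`,
#'   `school_sd` (override any via `...`-style arguments below).
#' @param rho,beta,sigma,school_sd optional overrides of the config values.
#' @param school school membership vector (defaults to the one stored in
#'   `W`); used for the random intercepts.
#' @param seed integer seed.
#' @return numeric outcome vector (min/day).
#' @export
generate_outcomes <- function(W, X, config, seed = config$seed,
                              rho = config$rho, beta = config$beta,
                              sigma = config$sigma, school_sd = config$school_sd,
                              school = NULL) {
  wm <- as_weight_matrix(W)
  if (is.null(school)) school <- wm$school %||% rep("s1", nrow(wm$W))
  X <- as.matrix(X)
  n <- nrow(X)
  if (nrow(wm$W) != n) stop_("dimension mismatch: W is %d x %d but X has %d rows",
                             nrow(wm$W), ncol(wm$W), n)
  if (length(beta) != ncol(X))
    stop_("beta has %d elements but X has %d columns", length(beta), ncol(X))
  fi <- feasible_interval(weight_eigenvalues(wm))
  if (rho <= fi[1] || rho >= fi[2])
    stop_("rho = %.4f lies outside the feasible interval (%.4f, %.4f) for this W",
          rho, fi[1], fi[2])
  set.seed(seed)
  u_school <- setNames(rnorm(length(unique(school)), 0, school_sd), unique(school))
  eta <- drop(X %*% beta) + u_school[school] + rnorm(n, 0, sigma)
  drop(solve_lag_system(wm, rho, eta))
}

# solve (I - rho W) y = eta exactly, per school block when blocks are recorded
solve_lag_system <- function(wm, rho, eta) {
  y <- numeric(length(eta))
  for (idx in school_blocks(wm)) {
    A <- diag(length(idx)) - rho * as.matrix(wm$W[idx, idx, drop = FALSE])
    y[idx] <- solve(A, eta[idx])
  }
  y
}

#' Introduce missing-at-random missingness into an analysis table
#'
#' Sets entries of the variables named in `rates` to `NA` under a MAR
#' mechanism: the missingness probability is logistic in the child's sex and
#' the leave-one-out school mean of the primary outcome, never in the deleted
#' value itself. The logistic intercept is calibrated so the realised
#' marginal rate matches each target rate.
#'
#' @param data analysis data frame containing `sex`, `school_id` and the
#'   variables named in `rates`.
#' @param config a [sim_config()] (supplies `missing_rates` and `seed`), or
#'   pass `rates` directly.
#' @param rates named vector of per-variable missingness probabilities.
#' @param outcome_var variable whose school mean drives the MAR mechanism.
#' @param seed integer seed.
#' @return `data` with `NA`s inserted; the logical missingness mask is
#'   attached as attribute `"miss_mask"`.
#' @export
apply_missingness <- function(data, config = NULL,
                              rates = config$missing_rates,
                              outcome_var = "mean_mvpa",
                              seed = if (is.null(config)) 1L else config$seed) {
  rates <- rates[rates > 0]
  if (length(rates) == 0) return(data)
  if (any(rates >= 1))
    stop_("missingness rate >= 1 for: %s",
          paste(names(rates)[rates >= 1], collapse = ", "))
  missing_vars <- setdiff(names(rates), names(data))
  if (length(missing_vars))
    stop_("variables not in data: %s", paste(missing_vars, collapse = ", "))
  set.seed(derive_seed(seed, 7L))
  n <- nrow(data)
  # MAR driver: sex plus leave-one-out school mean of the outcome
  sex_num <- as.numeric(factor(data$sex))
  y <- data[[outcome_var]]
  y[is.na(y)] <- mean(y, na.rm = TRUE)
  s_sum <- tapply(y, data$school_id, sum)[data$school_id]
  s_n <- tapply(y, data$school_id, length)[data$school_id]
  loo <- ifelse(s_n > 1, (s_sum - y) / (s_n - 1), mean(y))
  driver <- 0.5 * as.numeric(scale(sex_num)) + 0.5 * as.numeric(scale(loo))
  driver[!is.finite(driver)] <- 0
  mask <- matrix(FALSE, n, length(rates), dimnames = list(NULL, names(rates)))
  for (v in names(rates)) {
    a <- uniroot(function(a) mean(plogis(a + driver)) - rates[[v]],
                 c(-30, 30), tol = 1e-10)$root
    mask[, v] <- runif(n) < plogis(a + driver)
    data[[v]][mask[, v]] <- NA
  }
  attr(data, "miss_mask") <- mask
  data
}

#' Generate a per-epoch accelerometer count series for one child
#'
#' Produces non-negative integer counts at 10-s resolution for each day of a
#' wear profile, mixing epochs across the sedentary/light/MVPA intensity
#' bands and planting exact-zero non-wear runs so downstream accelerometry
#' rules (non-wear detection, validity, cut points) are exercised.
#'
#' @param profile list with elements `child_id`, `n_days` (default 5),
#'   `weekend` (logical per day; default last two days), `wear_epochs`
#'   (epochs of wear per day, default 5040 = 14 h), `mix` (probabilities for
#'   sedentary/light/MVPA epochs, default c(0.6, 0.3, 0.1)), and optional
#'   `nonwear_blocks`, a data frame with columns `day`, `start`, `length`
#'   (epochs) of zero runs to plant.
#' @param seed integer seed.
#' @param cutpoints intensity thresholds, see [evenson_cutpoints()].
#' @return data frame with columns `child_id`, `day_id`, `weekend`,
#'   `epoch_index`, `counts`.
#' @export
generate_epoch_series <- function(profile, seed = 1L,
                                  cutpoints = evenson_cutpoints()) {
  n_days <- profile$n_days %||% 5L
  wear_epochs <- profile$wear_epochs %||% 5040L
  mix <- profile$mix %||% c(sedentary = 0.6, light = 0.3, mvpa = 0.1)
  weekend <- profile$weekend %||% c(rep(FALSE, max(0, n_days - 2)),
                                    rep(TRUE, min(2, n_days)))
  thr <- scale_cutpoints(cutpoints, epoch_len = 10)
  set.seed(seed)
  days <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    cls <- sample(1:3, wear_epochs, replace = TRUE, prob = mix)
    counts <- integer(wear_epochs)
    counts[cls == 1] <- sample(0:thr$sedentary_max, sum(cls == 1), replace = TRUE)
    counts[cls == 2] <- sample((thr$sedentary_max + 1):(thr$mvpa_min - 1),
                               sum(cls == 2), replace = TRUE)
    counts[cls == 3] <- sample(thr$mvpa_min:(3 * thr$mvpa_min),
                               sum(cls == 3), replace = TRUE)
    nb <- profile$nonwear_blocks
    if (!is.null(nb)) {
      for (b in which(nb$day == d)) {
        span <- nb$start[b]:(nb$start[b] + nb$length[b] - 1)
        span <- span[span <= wear_epochs]
        counts[span] <- 0L
      }
    }
    days[[d]] <- data.frame(child_id = profile$child_id %||% "c1",
                            day_id = d, weekend = weekend[d],
                            epoch_index = seq_len(wear_epochs),
                            counts = counts, stringsAsFactors = FALSE)
  }
  do.call(rbind, days)
}

#' Synthesise epoch series whose processed summaries match target outcomes
#'
#' Builds count series whose per-day MVPA and sedentary minutes equal the
#' targets up to 10-s epoch rounding, so a model-generated outcome survives a
#' round trip through the accelerometry processing rules.
#'
#' @param child_id child identifier.
#' @param mvpa_min,sedentary_min target mean minutes/day.
#' @param wear_min wear minutes per day (default 540).
#' @param n_days number of days (default 5).
#' @param seed integer seed.
#' @inheritParams generate_epoch_series
#' @return data frame as in [generate_epoch_series()].
#' @export
epochs_from_targets <- function(child_id, mvpa_min, sedentary_min,
                                wear_min = 540, n_days = 5, seed = 1L,
                                cutpoints = evenson_cutpoints()) {
  thr <- scale_cutpoints(cutpoints, epoch_len = 10)
  set.seed(seed)
  wear_e <- round(wear_min * 6)
  mvpa_e <- max(0, round(mvpa_min * 6))
  sed_e <- max(0, round(sedentary_min * 6))
  light_e <- wear_e - mvpa_e - sed_e
  if (light_e < 0) stop_("targets exceed wear time")
  weekend <- c(rep(FALSE, max(0, n_days - 2)), rep(TRUE, min(2, n_days)))
  days <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    cls <- sample(rep(1:3, times = c(sed_e, light_e, mvpa_e)))
    counts <- integer(wear_e)
    counts[cls == 1] <- sample(0:thr$sedentary_max, sum(cls == 1), replace = TRUE)
    counts[cls == 2] <- sample((thr$sedentary_max + 1):(thr$mvpa_min - 1),
                               sum(cls == 2), replace = TRUE)
    counts[cls == 3] <- sample(thr$mvpa_min:(3 * thr$mvpa_min),
                               sum(cls == 3), replace = TRUE)
    days[[d]] <- data.frame(child_id = child_id, day_id = d,
                            weekend = weekend[d],
                            epoch_index = seq_len(wear_e), counts = counts,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, days)
}

#' Simulate a complete synthetic study
#'
#' Generates a roster, friend nominations, per-sex friendship weight
#' matrices, and network-autocorrelated MVPA and sedentary outcomes; then
#' optionally inserts MAR missingness. Outcomes are generated per sex over
#' all children of that sex (children without same-sex ties receive zero
#' weight rows), so every child has an outcome and downstream pruning
#' mirrors a real analysis.
#'
#' @param config a [sim_config()].
#' @param missingness insert missingness at `config$missing_rates`?
#' @param epochs also synthesise per-epoch count series consistent with each
#'   child's outcomes (slow at full study scale; intended for small configs)?
#' @return object of class `synthetic_study`: list with `roster` (including
#'   outcome columns), `nominations`, `epochs` (or `NULL`), and `truth` (the
#'   generating config).
#' @export
simulate_study <- function(config = sim_config(), missingness = TRUE,
                           epochs = FALSE) {
  roster <- generate_roster(config)
  noms <- generate_nominations(roster, config)
  roster$mean_mvpa <- NA_real_
  roster$mean_sedentary <- NA_real_
  net <- match_nominations(noms, roster)
  for (s in c("F", "M")) {
    idx <- which(roster$sex == s)
    sub <- roster[idx, ]
    e <- net$edges
    e <- e[e$from %in% sub$child_id & e$to %in% sub$child_id, , drop = FALSE]
    W <- weight_matrix_from_edges(e, sub$child_id, sub$school_id, stratum = s)
    X <- cbind(intercept = 1, imd = sub$imd, bmi_z = sub$bmi_z,
               activity_score = sub$activity_score)
    roster$mean_mvpa[idx] <- generate_outcomes(
      W, X, config, seed = derive_seed(config$seed, 11L + (s == "F")))
    sed <- config$sedentary
    roster$mean_sedentary[idx] <- generate_outcomes(
      W, X, config, seed = derive_seed(config$seed, 21L + (s == "F")),
      rho = sed$rho, beta = sed$beta, sigma = sed$sigma)
  }
  # keep outcomes on a plausible non-negative scale
  roster$mean_mvpa <- pmax(roster$mean_mvpa + 60, 0)
  roster$mean_sedentary <- pmax(roster$mean_sedentary + 420, 0)
  ep <- NULL
  if (epochs) {
    ep <- do.call(rbind, lapply(seq_len(nrow(roster)), function(i)
      epochs_from_targets(roster$child_id[i], roster$mean_mvpa[i],
                          roster$mean_sedentary[i],
                          wear_min = max(540, ceiling(roster$mean_mvpa[i] +
                                                        roster$mean_sedentary[i]) + 30),
                          seed = derive_seed(config$seed, 1000L + i))))
  }
  if (missingness)
    roster <- apply_missingness(roster, config)
  structure(list(roster = roster, nominations = noms, epochs = ep,
                 truth = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d children in %d schools, %d nominations\n",
              nrow(x$roster), length(unique(x$roster$school_id)),
              nrow(x$nominations)))
  miss <- colMeans(is.na(x$roster[sapply(x$roster, is.numeric)]))
  miss <- miss[miss > 0]
  if (length(miss))
    cat("  missingness:", paste(sprintf("%s %.1f%%", names(miss), 100 * miss),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic study to CSV/JSON files
#'
#' Writes `roster.csv`, `nominations.csv`, `epochs.csv` (if present) and
#' `truth.json` (the generating parameters and seed) into `dir`.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(study$roster, file.path(dir, "roster.csv"), row.names = FALSE)
  write.csv(study$nominations, file.path(dir, "nominations.csv"), row.names = FALSE)
  if (!is.null(study$epochs))
    write.csv(study$epochs, file.path(dir, "epochs.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(study$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
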