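test_that("roster generation respects counts, score range and determinism", {
  cfg <- sim_config(n_schools = 2, children_per_school = 10, seed = 11)
  r1 <- generate_roster(cfg)
  expect_equal(nrow(r1), 20)
  expect_equal(length(unique(r1$school_id)), 2)
  expect_false(anyDuplicated(r1$child_id) > 0)
  expect_true(all(r1$activity_score >= 0 & r1$activity_score <= 12))
  expect_equal(r1$activity_score,
               r1$item1 + r1$item2 + r1$item3 + r1$item4)
  expect_identical(r1, generate_roster(cfg))
  expect_error(sim_config(n_schools = 0), "positive count")
})

test_that("roster covariate marginals match the configured distributions", {
  cfg <- sim_config(n_schools = 40, children_per_school = 50, seed = 12)
  r <- generate_roster(cfg)
  n <- nrow(r)
  expect_lt(abs(mean(r$sex == "F") - 0.55), 4 * sqrt(0.55 * 0.45 / n))
  expect_lt(abs(mean(r$imd) - 15), 4 * 10 / sqrt(n))
  expect_lt(abs(sd(r$imd) - 10), 1)
  expect_gt(mean((r$imd - mean(r$imd))^3) / sd(r$imd)^3, 0.5) # right skew
  expect_lt(abs(mean(r$bmi_z) - 0.3), 4 / sqrt(n))
})

test_that("nominations stay within school, never self, bounded at four", {
  cfg <- sim_config(n_schools = 5, children_per_school = 4:30, seed = 13)
  r <- generate_roster(cfg)
  noms <- generate_nominations(r, cfg)
  school <- setNames(r$school_id, r$child_id)
  expect_true(all(school[noms$nominator_id] == school[noms$nominee_id]))
  expect_false(any(noms$nominator_id == noms$nominee_id))
  expect_true(all(table(noms$nominator_id) <= 4))
  per <- split(noms, noms$nominator_id)
  expect_true(all(vapply(per, function(d) !anyDuplicated(d$nominee_id) &&
                           identical(d$rank, seq_len(nrow(d))), logical(1))))
})

test_that("singleton schools emit zero nominations and p_same_sex_tie = 1 kills cross-sex ties", {
  cfg <- sim_config(n_schools = 3, children_per_school = 1, seed = 14)
  r <- generate_roster(cfg)
  expect_null(generate_nominations(r, cfg))
  cfg2 <- sim_config(n_schools = 4, children_per_school = 20,
                     p_same_sex_tie = 1, seed = 15)
  r2 <- generate_roster(cfg2)
  n2 <- generate_nominations(r2, cfg2)
  sex <- setNames(r2$sex, r2$child_id)
  expect_true(all(sex[n2$nominator_id] == sex[n2$nominee_id]))
})

test_that("same-sex tie fraction approaches the configured probability", {
  cfg <- sim_config(n_schools = 60, children_per_school = 60, seed = 16)
  r <- generate_roster(cfg)
  noms <- generate_nominations(r, cfg)
  sex <- setNames(r$sex, r$child_id)
  frac <- mean(sex[noms$nominator_id] == sex[noms$nominee_id])
  expect_gt(nrow(noms), 1e4)
  # binomial 4 sigma on >= 10^4 ties
  expect_lt(abs(frac - 0.90), 4 * sqrt(0.9 * 0.1 / nrow(noms)))
})

test_that("generated outcomes satisfy the lag-model identity exactly", {
  st <- make_stratum(seed = 17, n_schools = 4, per_school = 15)
  cfg0 <- st$cfg
  # identical seeds give identical (Xb + u + eps), so comparing the rho = 0
  # draw with the rho = 0.2 draw isolates the reduced-form solve:
  # (I - rho W) y_rho must equal y_0 to numerical tolerance
  y0 <- generate_outcomes(st$W, st$X, cfg0, rho = 0, seed = 771)
  yr <- generate_outcomes(st$W, st$X, cfg0, rho = 0.2, seed = 771)
  expect_equal(yr - 0.2 * as.numeric(st$W$W %*% yr), y0, tolerance = 1e-10)
  # with school_sd = 0, the rho = 0 draw is exactly X beta + eps
  eps <- y0 - drop(st$X %*% cfg0$beta)
  expect_equal(sd(eps), cfg0$sigma, tolerance = 0.15 * cfg0$sigma)
  expect_error(generate_outcomes(st$W, st$X, cfg0, rho = 1.2),
               "feasible interval")
})

test_that("missingness hits its target rates, is seed-stable and zero-rate safe", {
  cfg <- sim_config(n_schools = 20, children_per_school = 50, seed = 18)
  st <- simulate_study(cfg, missingness = FALSE)
  d1 <- apply_missingness(st$roster, rates = c(mean_sedentary = 0.18), seed = 5)
  n <- nrow(st$roster)
  n_miss <- sum(is.na(d1$mean_sedentary))
  expect_lt(abs(n_miss / n - 0.18), 3.5 * sqrt(0.18 * 0.82 / n))
  d2 <- apply_missingness(st$roster, rates = c(mean_sedentary = 0.18), seed = 5)
  expect_identical(is.na(d2$mean_sedentary), is.na(d1$mean_sedentary))
  expect_identical(apply_missingness(st$roster, rates = c(bmi_z = 0)),
                   st$roster)
  expect_error(apply_missingness(st$roster, rates = c(bmi_z = 1)), ">= 1")
})

test_that("epoch series generation plants requested structure deterministically", {
  prof <- list(child_id = "c9", n_days = 5, wear_epochs = 3600,
               nonwear_blocks = data.frame(day = 2, start = 100, length = 420))
  ep <- generate_epoch_series(prof, seed = 21)
  expect_equal(length(unique(ep$day_id)), 5)
  expect_true(all(ep$counts >= 0 & ep$counts == round(ep$counts)))
  d2 <- ep$counts[ep$day_id == 2]
  expect_true(all(d2[100:519] == 0))  # planted 70-min block verbatim
  expect_identical(ep, generate_epoch_series(prof, seed = 21))
})

test_that("a full synthetic study is a pure function of config and seed", {
  cfg <- sim_config(n_schools = 3, children_per_school = 12, seed = 22)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$roster, s2$roster)
  expect_identical(s1$nominations, s2$nominations)
  # nominations reference enrolled same-school children only
  school <- setNames(s1$roster$school_id, s1$roster$child_id)
  expect_true(all(s1$nominations$nominee_id %in% s1$roster$child_id))
  expect_true(all(table(s1$nominations$nominator_id) <= cfg$max_nominations))
})

test_that("study files round-trip through CSV/JSON", {
  cfg <- sim_config(n_schools = 2, children_per_school = 6, seed = 23)
  st <- simulate_study(cfg, missingness = FALSE)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(all(file.exists(file.path(dir, c("roster.csv", "nominations.csv",
                                               "truth.json")))))
  back <- read.csv(file.path(dir, "roster.csv"), stringsAsFactors = FALSE)
  expect_equal(back$child_id, st$roster$child_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$rho, cfg$rho)
  expect_equal(truth$seed, cfg$seed)
})
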