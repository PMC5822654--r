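# shared fixtures and independent oracles, all built in code

# random directed weight matrix over one or more school blocks, each node
# nominating up to `max_out` others within its block; row-standardised
random_weight_matrix <- function(n, n_blocks = 1, max_out = 4, seed = 1) {
  set.seed(seed)
  block <- sort(rep_len(seq_len(n_blocks), n))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    mates <- setdiff(which(block == block[i]), i)
    if (!length(mates)) return(NULL)
    k <- sample(seq_len(min(max_out, length(mates))), 1)
    data.frame(from = as.character(i),
               to = as.character(sample(mates, k)))
  }))
  weight_matrix_from_edges(edges, as.character(seq_len(n)),
                           school = paste0("b", block))
}

# brute-force O(n^2) double-sum Moran's I, independent of the package path
brute_moran <- function(x, W) {
  W <- as.matrix(if (inherits(W, "weight_matrix")) W$W else W)
  inc <- rowSums(abs(W)) > 0
  x <- x[inc]; W <- W[inc, inc, drop = FALSE]
  n <- length(x); xb <- mean(x); num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * (x[i] - xb) * (x[j] - xb)
  (n / sum(W)) * num / sum((x - xb)^2)
}

# brute-force non-wear scan: union over all qualifying windows
brute_nonwear <- function(counts, win_e = 360, int_e = 12) {
  n <- length(counts)
  nonwear <- rep(FALSE, n)
  for (s in seq_len(n)) {
    if (counts[s] != 0) next
    run <- 0L; ok <- TRUE
    for (e in s:n) {
      if (counts[e] != 0) {
        run <- run + 1L
        if (run > int_e) break
      } else {
        run <- 0L
        if (e - s + 1 >= win_e) nonwear[s:e] <- TRUE
      }
    }
  }
  nonwear
}

# one single-sex synthetic stratum under correctly-specified conditions:
# roster + network + design + model-generated outcome
make_stratum <- function(seed, n_schools = 24, per_school = 25, rho = 0.20,
                         beta = c(-15, -0.5, -2.5, 2.5), sigma = 15,
                         school_sd = 0) {
  cfg <- sim_config(n_schools = n_schools, children_per_school = per_school,
                    p_female = 1, p_same_sex_tie = 1, rho = rho, beta = beta,
                    sigma = sigma, school_sd = school_sd, seed = seed)
  roster <- generate_roster(cfg)
  noms <- generate_nominations(roster, cfg)
  W <- build_weight_matrix(match_nominations(noms, roster))
  dat <- roster[match(W$ids, roster$child_id), ]
  X <- cbind(intercept = 1, imd = dat$imd, bmi_z = dat$bmi_z,
             activity_score = dat$activity_score)
  y <- generate_outcomes(W, X, cfg, seed = derive_seed_fixture(seed))
  list(cfg = cfg, dat = dat, W = W, X = X, y = y)
}

derive_seed_fixture <- function(seed) (seed * 7919 + 13) %% 2000000000
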