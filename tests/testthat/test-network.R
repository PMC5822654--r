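toy_roster <- function() {
  data.frame(child_id = c("a", "b", "c", "d", "e"),
             school_id = "s1",
             sex = c("F", "F", "F", "M", "M"),
             stringsAsFactors = FALSE)
}

test_that("nomination matching keeps in-study same-school nominees only", {
  noms <- data.frame(nominator_id = c("a", "a", "b", "c", "d"),
                     rank = c(1, 2, 1, 1, 1),
                     nominee_id = c("b", "zz_out", "c", "out2", "e"),
                     stringsAsFactors = FALSE)
  net <- match_nominations(noms, toy_roster())
  expect_equal(net$report$n_nominated, 5)
  expect_equal(net$report$n_matched, 3)  # hand count: a->b, b->c, d->e
  expect_setequal(paste(net$edges$from, net$edges$to),
                  c("a b", "b c", "d e"))
  expect_error(match_nominations(
    data.frame(nominator_id = "ghost", rank = 1, nominee_id = "a"),
    toy_roster()), "ghost")
})

test_that("match rate on synthetic data tracks the enrolment structure", {
  cfg <- sim_config(n_schools = 20, children_per_school = 30, seed = 41)
  r <- generate_roster(cfg)
  noms <- generate_nominations(r, cfg)
  # drop 30% of children to emulate out-of-study friends
  set.seed(42)
  enrolled <- r[runif(nrow(r)) > 0.3, ]
  noms_e <- noms[noms$nominator_id %in% enrolled$child_id, ]
  net <- match_nominations(noms_e, enrolled)
  expect_lt(abs(net$report$n_matched / net$report$n_nominated - 0.7),
            4 * sqrt(0.7 * 0.3 / net$report$n_nominated))
})

test_that("same-sex filtering removes cross-sex ties and reports the fraction", {
  noms <- data.frame(nominator_id = c("a", "b", "d", "d", "e"),
                     rank = c(1, 1, 1, 2, 1),
                     nominee_id = c("b", "d", "b", "e", "d"),
                     stringsAsFactors = FALSE)
  net <- match_nominations(noms, toy_roster())
  fs <- filter_same_sex(net)
  # b->d and d->b form a mixed dyad: both directed edges removed
  expect_equal(fs$report$n_removed, 2)
  expect_equal(fs$report$frac_removed, 2 / 5)
  expect_equal(nrow(fs$networks$F$edges), 1)   # a->b
  expect_equal(nrow(fs$networks$M$edges), 2)   # d->e, e->d
  r2 <- toy_roster(); r2$sex[2] <- NA
  expect_error(filter_same_sex(match_nominations(noms, r2)), "sex missing")
})

test_that("synthetic cross-sex removal fraction is near 1 - p_same_sex_tie", {
  cfg <- sim_config(n_schools = 20, children_per_school = 30, seed = 43)
  r <- generate_roster(cfg)
  net <- match_nominations(generate_nominations(r, cfg), r)
  fs <- filter_same_sex(net)
  n <- net$report$n_matched
  expect_lt(abs(fs$report$frac_removed - 0.10), 4 * sqrt(0.1 * 0.9 / n))
})

test_that("isolate pruning reaches the brute-force fixpoint", {
  # star graph: no removals
  star <- match_nominations(
    data.frame(nominator_id = c("a", "c"), rank = 1, nominee_id = "b"),
    toy_roster()[1:3, ])
  expect_equal(nrow(prune_isolates(star)$nodes), 3)
  # node e's only tie is to d of the opposite sex: e isolated after filtering
  noms <- data.frame(nominator_id = c("a", "b", "e"), rank = 1,
                     nominee_id = c("b", "a", "b"), stringsAsFactors = FALSE)
  fs <- filter_same_sex(match_nominations(noms, toy_roster()))
  prM <- suppressWarnings(prune_isolates(fs$networks$M))
  expect_true("e" %in% prM$report$removed)
  # random networks: pruning agrees with exhaustive recomputation
  set.seed(44)
  for (rep in 1:10) {
    ids <- letters[1:10]
    e <- data.frame(from = sample(ids, 6, TRUE), to = sample(ids, 6, TRUE))
    e <- e[e$from != e$to, ]
    net <- structure(list(nodes = data.frame(child_id = ids, school_id = "s1",
                                             sex = "F"),
                          edges = e, stratum = "F", report = list()),
                     class = "friendship_network")
    keep_oracle <- ids[ids %in% c(e$from, e$to)]
    pruned <- suppressWarnings(prune_isolates(net))
    expect_setequal(pruned$nodes$child_id, keep_oracle)
  }
})

test_that("weight matrix standardisation, ordering and block structure hold", {
  # worked arithmetic case: rows (0,1,1),(1,0,0),(0,0,0)
  e <- data.frame(from = c("a", "a", "b"), to = c("b", "c", "a"))
  wm <- weight_matrix_from_edges(e, c("a", "b", "c"))
  expect_equal(as.matrix(wm$W),
               matrix(c(0, 1, 0, .5, 0, 0, .5, 0, 0), 3, 3),
               ignore_attr = TRUE)
  raw <- weight_matrix_from_edges(e, c("a", "b", "c"), standardise = FALSE)
  expect_equal(Matrix::rowSums(raw$W), c(2, 1, 0), ignore_attr = TRUE)
  # standardised row sums are exactly 0 or 1; zero diagonal
  cfg <- sim_config(n_schools = 6, children_per_school = 15, seed = 45)
  r <- generate_roster(cfg)
  net <- prune_isolates(filter_same_sex(
    match_nominations(generate_nominations(r, cfg), r))$networks$F)
  W <- build_weight_matrix(net)
  rs <- Matrix::rowSums(W$W)
  expect_true(all(abs(rs) < 1e-12 | abs(rs - 1) < 1e-12))
  expect_true(all(Matrix::diag(W$W) == 0))
  # block-diagonal by school: no entry links distinct schools
  tr <- Matrix::summary(W$W)
  expect_true(all(W$school[tr$i] == W$school[tr$j]))
  # degree bound: <= 4 nonzero entries per row pre-standardisation
  Wraw <- build_weight_matrix(net, standardise = FALSE)
  expect_true(all(Matrix::rowSums(Wraw$W > 0) <= 4))
  # spectral radius of standardised W is <= 1
  expect_lte(max(Mod(weight_eigenvalues(W))), 1 + 1e-10)
})

test_that("node permutation permutes the weight matrix consistently", {
  set.seed(46)
  e <- data.frame(from = sample(letters[1:8], 12, TRUE),
                  to = sample(letters[1:8], 12, TRUE))
  e <- unique(e[e$from != e$to, ])
  ids <- letters[1:8]
  perm <- sample(ids)
  W1 <- weight_matrix_from_edges(e, ids)
  W2 <- weight_matrix_from_edges(e, perm)
  p <- match(ids, perm)
  expect_equal(as.matrix(W2$W)[p, p], as.matrix(W1$W), ignore_attr = TRUE)
})
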