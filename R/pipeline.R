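#' Configuration for a full pipeline run
#'
#' @param sim a [sim_config()] used when no `input_dir` is given.
#' @param input_dir optional directory containing `roster.csv`,
#'   `nominations.csv` and (if `use_epochs`) `epochs.csv`.
#' @param strata sexes to analyse.
#' @param outcomes outcome columns to model.
#' @param m,n_cycles multiple-imputation settings (see
#'   [chained_imputation()]).
#' @param n_perm Moran permutation count.
#' @param n_sims impact-interval simulation draws.
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it.
#' @param outdir optional output directory for artefacts.
#' @param overwrite allow writing into an `outdir` that already holds a
#'   manifest?
#' @param use_epochs derive activity outcomes from epoch-level counts via
#'   the accelerometry rules instead of taking roster columns as-is?
#' @param missingness when simulating, insert missingness per the sim
#'   config?
#' @return an object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), input_dir = NULL,
                       strata = c("F", "M"),
                       outcomes = c("mean_mvpa", "mean_sedentary"),
                       m = 20, n_cycles = 20, n_perm = 999, n_sims = 200,
                       seed = 1L, outdir = NULL, overwrite = FALSE,
                       use_epochs = FALSE, missingness = TRUE) {
  structure(list(sim = sim, input_dir = input_dir, strata = strata,
                 outcomes = outcomes, m = m, n_cycles = n_cycles,
                 n_perm = n_perm, n_sims = n_sims, seed = as.integer(seed),
                 outdir = outdir, overwrite = overwrite,
                 use_epochs = use_epochs, missingness = missingness),
            class = "run_config")
}

model_vars <- c("imd", "bmi_z", "item1", "item2", "item3", "item4",
                "mean_mvpa", "mean_sedentary")

# design matrix for the activity models: intercept, IMD, BMI z, activity score
model_design <- function(dat) {
  cbind(intercept = 1, imd = dat$imd, bmi_z = dat$bmi_z,
        activity_score = dat$activity_score)
}

# complete-data analysis of one stratum x outcome
analyse_complete <- function(dat, W, outcome, cfg, seed) {
  y <- dat[[outcome]] - mean(dat[[outcome]])
  X <- model_design(dat)
  moran_raw <- morans_i_test(y, W, n_perm = cfg$n_perm,
                             seed = derive_seed(seed, 31L))
  ols <- fit_ols(y, X, dat$school_id)
  moran_resid <- morans_i_test(ols$residuals, W, n_perm = cfg$n_perm,
                               seed = derive_seed(seed, 32L))
  net <- fit_network_model(y, X, W)
  impacts <- impact_intervals(net, W, n_sims = cfg$n_sims,
                              seed = derive_seed(seed, 33L))
  list(outcome = outcome, moran_raw = moran_raw, ols = ols,
       moran_resid = moran_resid, network = net, impacts = impacts,
       aic = c(ols = ols$aic, network = net$aic,
               difference = net$aic - ols$aic),
       scatter = moran_scatter(dat[[outcome]], W))
}

# multiply-imputed analysis: fit per dataset, pool with Rubin's rules;
# residual Moran's I is summarised by its median and the fraction of
# imputations significant at 0.05; impact draws are stacked across datasets
analyse_imputed <- function(stack, W, outcome, cfg, seed) {
  m <- stack$m
  fits_ols <- vector("list", m); fits_net <- vector("list", m)
  mor_I <- numeric(m); mor_p <- numeric(m)
  imp_list <- vector("list", m)
  for (d in seq_len(m)) {
    dat <- stack$datasets[[d]]
    y <- dat[[outcome]] - mean(dat[[outcome]])
    X <- model_design(dat)
    fits_ols[[d]] <- fit_ols(y, X, dat$school_id)
    mr <- morans_i_test(fits_ols[[d]]$residuals, W, n_perm = cfg$n_perm,
                        seed = derive_seed(seed, 40L + d))
    mor_I[d] <- mr$I; mor_p[d] <- mr$p_value
    fits_net[[d]] <- fit_network_model(y, X, W)
    imp_list[[d]] <- impact_intervals(fits_net[[d]], W, n_sims = cfg$n_sims,
                                      seed = derive_seed(seed, 60L + d),
                                      keep_draws = TRUE)
  }
  draws <- do.call(abind3, lapply(imp_list, attr, "draws"))
  impacts <- imp_list[[1]][, c("covariate", "direct", "indirect", "total")]
  for (mm in c("direct", "indirect", "total")) {
    impacts[[mm]] <- rowMeans(sapply(imp_list, `[[`, mm))
    q <- apply(draws[, mm, , drop = FALSE], 1, quantile,
               probs = c(0.025, 0.975), names = FALSE)
    impacts[[paste0(mm, "_lo")]] <- q[1, ]
    impacts[[paste0(mm, "_hi")]] <- q[2, ]
  }
  aic_ols <- mean(vapply(fits_ols, `[[`, numeric(1), "aic"))
  aic_net <- mean(vapply(fits_net, `[[`, numeric(1), "aic"))
  list(outcome = outcome,
       pooled_ols = pool_rubin(fits_ols),
       pooled_network = pool_rubin(fits_net),
       moran_resid = list(median_I = stats::median(mor_I),
                          frac_significant = mean(mor_p < 0.05)),
       impacts = impacts,
       aic = c(ols = aic_ols, network = aic_net,
               difference = aic_net - aic_ols),
       m = m)
}

abind3 <- function(...) {
  arrs <- list(...)
  array(unlist(arrs), dim = c(dim(arrs[[1]])[1:2],
                              sum(vapply(arrs, function(a) dim(a)[3], 1))),
        dimnames = dimnames(arrs[[1]])[1:2])
}

#' Run the full friendship-network activity analysis
#'
#' Executes, per sex stratum and per outcome: (optional) accelerometry
#' processing, network construction (matching, same-sex restriction,
#' isolate pruning, row-standardised weight matrix), Moran scatter and
#' Moran's I, baseline cluster-robust OLS, residual Moran's I, the network
#' autocorrelation model, impact decomposition with percentile CIs, and —
#' when missing data are present — chained-equations multiple imputation
#' wrapping the fits, pooled by Rubin's rules. Nominations are never
#' imputed, so the network is fixed across imputations.
#'
#' @param config a [run_config()].
#' @return object of class `study_result`: per-stratum list with the pruned
#'   network, weight matrix, removal reports and per-outcome analyses, plus
#'   a `manifest` recording the configuration and seeds. When
#'   `config$outdir` is set, all artefacts are also written to disk.
#' @export
run_study <- function(config = run_config()) {
  cfg <- config
  if (!is.null(cfg$input_dir)) {
    roster <- read.csv(file.path(cfg$input_dir, "roster.csv"),
                       stringsAsFactors = FALSE)
    noms <- read.csv(file.path(cfg$input_dir, "nominations.csv"),
                     stringsAsFactors = FALSE)
    epochs <- if (cfg$use_epochs)
      read.csv(file.path(cfg$input_dir, "epochs.csv"),
               stringsAsFactors = FALSE) else NULL
  } else {
    study <- simulate_study(cfg$sim, missingness = cfg$missingness,
                            epochs = cfg$use_epochs)
    roster <- study$roster
    noms <- study$nominations
    epochs <- study$epochs
  }
  if (!is.null(epochs)) {
    acc <- process_epochs(epochs)
    idx <- match(roster$child_id, acc$children$child_id)
    roster$mean_mvpa <- acc$children$mean_mvpa[idx]
    roster$mean_sedentary <- acc$children$mean_sedentary[idx]
  }
  if (!"activity_score" %in% names(roster))
    roster$activity_score <- passive_score(
      roster[c("item1", "item2", "item3", "item4")], quiet = TRUE)
  net_all <- match_nominations(noms, roster)
  split_nets <- filter_same_sex(net_all)
  result <- list()
  for (s in cfg$strata) {
    net <- prune_isolates(split_nets$networks[[s]])
    if (isTRUE(net$empty)) {
      result[[s]] <- list(empty = TRUE)
      next
    }
    W <- build_weight_matrix(net)
    dat <- roster[match(W$ids, roster$child_id), , drop = FALSE]
    vars_here <- intersect(model_vars, names(dat))
    has_missing <- anyNA(dat[vars_here])
    sseed <- derive_seed(cfg$seed, 100L + match(s, c("F", "M")))
    if (has_missing) {
      stack <- chained_imputation(dat, vars = vars_here, m = cfg$m,
                                  n_cycles = cfg$n_cycles, seed = sseed)
      analyses <- lapply(cfg$outcomes, function(oc)
        analyse_imputed(stack, W, oc, cfg, sseed))
    } else {
      analyses <- lapply(cfg$outcomes, function(oc)
        analyse_complete(dat, W, oc, cfg, sseed))
    }
    names(analyses) <- cfg$outcomes
    result[[s]] <- list(network = net, W = W, data = dat,
                        imputed = has_missing,
                        removal = list(
                          opposite_sex = split_nets$report,
                          isolates = length(net$report$removed)),
                        analyses = analyses)
  }
  out <- structure(list(strata = result,
                        manifest = list(config = serialise_config(cfg),
                                        seed = cfg$seed,
                                        timestamp = format(Sys.time()),
                                        strata = cfg$strata,
                                        outcomes = cfg$outcomes)),
                   class = "study_result")
  if (!is.null(cfg$outdir)) write_study_result(out, roster, cfg)
  out
}

serialise_config <- function(cfg) {
  cl <- unclass(cfg)
  cl$sim <- unclass(cl$sim)
  cl
}

#' @export
print.study_result <- function(x, ...) {
  cat("Friendship-network activity analysis\n")
  for (s in names(x$strata)) {
    st <- x$strata[[s]]
    if (isTRUE(st$empty)) { cat(sprintf("  %s: empty network\n", s)); next }
    cat(sprintf("  stratum %s: %d children, %d ties%s\n", s,
                nrow(st$network$nodes), nrow(st$network$edges),
                if (st$imputed) " (multiply imputed)" else ""))
    for (oc in names(st$analyses)) {
      a <- st$analyses[[oc]]
      rho <- if (st$imputed)
        a$pooled_network$estimate[a$pooled_network$parameter == "rho"]
      else a$network$rho
      cat(sprintf("    %s: rho = %.3f, AIC (network - OLS) = %.1f\n",
                  oc, rho, a$aic["difference"]))
    }
  }
  invisible(x)
}

#' Export a friendship network with activity attributes
#'
#' Writes GraphML (readable by standard graph tools) plus node and edge
#' CSVs, with per-node sex, school and mean MVPA / sedentary minutes for
#' size-scaled network plots. Missing summaries are written as `NA` and
#' counted in a message.
#'
#' @param network a `friendship_network`.
#' @param summaries data frame with `child_id`, `mean_mvpa`,
#'   `mean_sedentary`.
#' @param file base path (without extension) for `<file>.graphml`,
#'   `<file>_nodes.csv`, `<file>_edges.csv`.
#' @return the igraph object, invisibly.
#' @export
export_network <- function(network, summaries, file) {
  nodes <- network$nodes
  idx <- match(nodes$child_id, summaries$child_id)
  nodes$mean_mvpa <- summaries$mean_mvpa[idx]
  nodes$mean_sedentary <- summaries$mean_sedentary[idx]
  n_missing <- sum(is.na(nodes$mean_mvpa) | is.na(nodes$mean_sedentary))
  if (n_missing)
    message(n_missing, " node(s) lack activity summaries; written as NA")
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from", "to")], directed = TRUE, vertices = nodes)
  igraph::write_graph(g, paste0(file, ".graphml"), format = "graphml")
  write.csv(nodes, paste0(file, "_nodes.csv"), row.names = FALSE)
  write.csv(network$edges, paste0(file, "_edges.csv"), row.names = FALSE)
  invisible(g)
}

# write all artefacts of a study result under cfg$outdir
write_study_result <- function(res, roster, cfg) {
  dir <- cfg$outdir
  if (file.exists(file.path(dir, "manifest.json")) && !isTRUE(cfg$overwrite))
    stop_("output directory %s already holds results; set overwrite = TRUE", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fits <- list(); impacts_rows <- list(); fit_rows <- list()
  for (s in names(res$strata)) {
    st <- res$strata[[s]]
    if (isTRUE(st$empty)) next
    export_network(st$network, roster, file.path(dir, paste0("network_", s)))
    wtr <- Matrix::summary(st$W$W)
    write.csv(data.frame(row = st$W$ids[wtr$i], col = st$W$ids[wtr$j],
                         weight = wtr$x),
              file.path(dir, paste0("weight_matrix_", s, ".csv")),
              row.names = FALSE)
    writeLines(st$W$ids, file.path(dir, paste0("node_order_", s, ".txt")))
    for (oc in names(st$analyses)) {
      a <- st$analyses[[oc]]
      key <- paste(s, oc, sep = "_")
      if (!st$imputed)
        write.csv(a$scatter, file.path(dir, paste0("moran_scatter_", key, ".csv")),
                  row.names = FALSE)
      fits[[key]] <- summarise_analysis(a, st$imputed)
      imp <- a$impacts
      imp$stratum <- s; imp$outcome <- oc
      impacts_rows[[key]] <- imp
      fit_rows[[key]] <- fits_table_rows(a, s, oc, st$imputed)
    }
  }
  jsonlite::write_json(fits, file.path(dir, "model_fits.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write.csv(do.call(rbind, impacts_rows), file.path(dir, "impacts_table.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, fit_rows), file.path(dir, "fits_table.csv"),
            row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

summarise_analysis <- function(a, imputed) {
  if (imputed) {
    pn <- a$pooled_network
    list(rho = pn$estimate[pn$parameter == "rho"],
         rho_ci = c(pn$ci_lower[pn$parameter == "rho"],
                    pn$ci_upper[pn$parameter == "rho"]),
         coefficients = setNames(pn$estimate[-1], pn$parameter[-1]),
         aic = as.list(a$aic), residual_moran = a$moran_resid, m = a$m)
  } else {
    list(rho = a$network$rho, rho_ci = unname(a$network$rho_ci),
         coefficients = as.list(a$network$beta),
         aic = as.list(a$aic),
         residual_moran = list(I = a$moran_resid$I,
                               p = a$moran_resid$p_value))
  }
}

fits_table_rows <- function(a, s, oc, imputed) {
  if (imputed) {
    pn <- a$pooled_network
    data.frame(stratum = s, outcome = oc, model = "network",
               parameter = pn$parameter, coefficient = pn$estimate,
               ci_lower = pn$ci_lower, ci_upper = pn$ci_upper,
               stringsAsFactors = FALSE)
  } else {
    nf <- a$network
    data.frame(stratum = s, outcome = oc, model = "network",
               parameter = c("rho", names(nf$beta)),
               coefficient = c(nf$rho, nf$beta),
               ci_lower = nf$ci[, "lower"], ci_upper = nf$ci[, "upper"],
               stringsAsFactors = FALSE)
  }
}
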