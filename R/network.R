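#' Match friend nominations against the study roster
#'
#' Retains only nominations whose nominee is an enrolled roster member of
#' the nominator's school, and reports nominated vs matched counts.
#' Unmatched nominees (out-of-study friends, or an explicit unmatched label)
#' are dropped from the edge set.
#'
#' @param nominations data frame with columns `nominator_id`, `rank`,
#'   `nominee_id`.
#' @param roster data frame with columns `child_id`, `school_id`, `sex`.
#' @return object of class `friendship_network`: list with `nodes` (roster
#'   columns), `edges` (`from`, `to`, `school_id`), `stratum` (`NA` before
#'   sex restriction) and `report` (`n_nominated`, `n_matched`).
#' @export
match_nominations <- function(nominations, roster) {
  if (anyDuplicated(roster$child_id))
    stop_("roster ids are not unique")
  bad <- setdiff(nominations$nominator_id, roster$child_id)
  if (length(bad))
    stop_("nominators absent from roster: %s", paste(bad, collapse = ", "))
  school <- setNames(roster$school_id, roster$child_id)
  keep <- nominations$nominee_id %in% roster$child_id &
    school[nominations$nominator_id] == school[nominations$nominee_id] &
    nominations$nominee_id != nominations$nominator_id
  keep[is.na(keep)] <- FALSE
  edges <- data.frame(from = nominations$nominator_id[keep],
                      to = nominations$nominee_id[keep],
                      school_id = unname(school[nominations$nominator_id[keep]]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = roster[, intersect(c("child_id", "school_id", "sex"),
                                            names(roster))],
                 edges = edges, stratum = NA_character_,
                 report = list(n_nominated = nrow(nominations),
                               n_matched = nrow(edges))),
            class = "friendship_network")
}

#' @export
print.friendship_network <- function(x, ...) {
  cat(sprintf("Friendship network%s: %d children, %d directed ties\n",
              if (is.na(x$stratum)) "" else paste0(" (", x$stratum, ")"),
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Restrict a friendship network to same-sex ties
#'
#' Removes every opposite-sex tie and splits the network into one stratum
#' per sex. The removal report gives the count and fraction of ties removed.
#'
#' @param network a `friendship_network` from [match_nominations()].
#' @return list with `networks` (named list of per-sex `friendship_network`
#'   objects) and `report` (`n_removed`, `frac_removed`).
#' @export
filter_same_sex <- function(network) {
  nodes <- network$nodes
  if (any(is.na(nodes$sex)))
    stop_("sex missing for nodes: %s",
          paste(head(nodes$child_id[is.na(nodes$sex)]), collapse = ", "))
  sex <- setNames(nodes$sex, nodes$child_id)
  e <- network$edges
  same <- sex[e$from] == sex[e$to]
  nets <- lapply(split(nodes, nodes$sex), function(nd) nd)
  out <- lapply(names(nets), function(s) {
    es <- e[same & sex[e$from] == s, , drop = FALSE]
    rownames(es) <- NULL
    structure(list(nodes = nets[[s]], edges = es, stratum = s,
                   report = network$report),
              class = "friendship_network")
  })
  names(out) <- names(nets)
  list(networks = out,
       report = list(n_removed = sum(!same),
                     frac_removed = if (nrow(e)) sum(!same) / nrow(e) else 0))
}

#' Remove children with no in-study same-sex ties
#'
#' Drops nodes with zero in- and out-degree, iterating until no further
#' removals occur (removing an isolate never changes another node's degree,
#' so the fixpoint is reached in one pass, but the iteration guards the
#' invariant). An empty result is signalled explicitly.
#'
#' @param network a per-sex `friendship_network`.
#' @return the pruned network; removed ids are in `$report$removed`, and
#'   `$empty` is `TRUE` when no nodes remain.
#' @export
prune_isolates <- function(network) {
  nodes <- network$nodes
  edges <- network$edges
  removed <- character(0)
  repeat {
    deg <- table(factor(c(edges$from, edges$to), levels = nodes$child_id))
    iso <- nodes$child_id[deg == 0]
    if (length(iso) == 0) break
    removed <- c(removed, iso)
    nodes <- nodes[!nodes$child_id %in% iso, , drop = FALSE]
    edges <- edges[edges$from %in% nodes$child_id &
                     edges$to %in% nodes$child_id, , drop = FALSE]
  }
  network$nodes <- nodes
  network$edges <- edges
  network$report$removed <- removed
  network$empty <- nrow(nodes) == 0
  if (network$empty)
    warning("network is empty after pruning isolates", call. = FALSE)
  network
}

#' Build the (optionally row-standardised) friendship weight matrix
#'
#' Constructs the binary directed contiguity matrix over the network's nodes
#' — entry (i, j) is 1 exactly when i nominated j; reciprocal nominations
#' give two entries and are not symmetrised unless requested — then divides
#' each nonzero row by its sum so that all non-zero rows sum to 1. Nodes are
#' ordered by school then id, making the matrix block-diagonal by school.
#'
#' @param network a `friendship_network`.
#' @param standardise divide each nonzero row by its row sum?
#' @param symmetrise treat ties as undirected before standardising?
#' @return object of class `weight_matrix`: list with `W` (sparse matrix),
#'   `ids`, `school`, `stratum`, `standardised`.
#' @export
build_weight_matrix <- function(network, standardise = TRUE,
                                symmetrise = FALSE) {
  nodes <- network$nodes[order(network$nodes$school_id,
                               network$nodes$child_id), , drop = FALSE]
  wm <- weight_matrix_from_edges(network$edges, nodes$child_id,
                                 nodes$school_id, stratum = network$stratum,
                                 standardise = standardise,
                                 symmetrise = symmetrise)
  wm
}

#' Construct a weight matrix from an edge table
#'
#' Lower-level constructor used by [build_weight_matrix()] and by the
#' synthetic-data generator: takes an explicit node order.
#'
#' @param edges data frame with columns `from`, `to`.
#' @param ids ordered node ids.
#' @param school school id per node (defaults to one school).
#' @param stratum optional stratum label.
#' @inheritParams build_weight_matrix
#' @return a `weight_matrix`.
#' @export
weight_matrix_from_edges <- function(edges, ids, school = NULL,
                                     stratum = NA_character_,
                                     standardise = TRUE, symmetrise = FALSE) {
  n <- length(ids)
  i <- match(edges$from, ids)
  j <- match(edges$to, ids)
  ok <- !is.na(i) & !is.na(j) & i != j
  A <- Matrix::sparseMatrix(i = i[ok], j = j[ok], x = 1, dims = c(n, n))
  A@x[] <- 1  # duplicate nominations collapse to a binary tie
  if (symmetrise) {
    A <- A + Matrix::t(A)
    A@x[] <- 1
  }
  if (standardise) {
    rs <- Matrix::rowSums(A)
    A <- Matrix::Diagonal(n, x = ifelse(rs > 0, 1 / rs, 0)) %*% A
  }
  structure(list(W = methods::as(A, "generalMatrix"), ids = ids,
                 school = school %||% rep("s1", n),
                 stratum = stratum, standardised = standardise,
                 cache = new.env(parent = emptyenv())),
            class = "weight_matrix")
}

#' Coerce a plain matrix to a `weight_matrix`
#'
#' @param W a `weight_matrix`, or a square (possibly sparse) matrix.
#' @param school optional school membership per row.
#' @return a `weight_matrix`.
#' @export
as_weight_matrix <- function(W, school = NULL) {
  if (inherits(W, "weight_matrix")) return(W)
  W <- methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix")
  n <- nrow(W)
  rs <- Matrix::rowSums(W)
  standardised <- all(abs(rs[rs > 1e-12] - 1) < 1e-8)
  structure(list(W = W, ids = rownames(W) %||% as.character(seq_len(n)),
                 school = school %||% rep("s1", n),
                 stratum = NA_character_, standardised = standardised,
                 cache = new.env(parent = emptyenv())),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf(
    "Weight matrix: %d nodes, %d ties, %d school block(s)%s%s\n",
    nrow(x$W), length(x$W@x), length(unique(x$school)),
    if (isTRUE(x$standardised)) ", row-standardised" else "",
    if (is.na(x$stratum)) "" else paste0(", stratum ", x$stratum)))
  invisible(x)
}

# row index sets of the school blocks, in matrix order
school_blocks <- function(wm) {
  unname(split(seq_along(wm$school), wm$school))
}

#' Eigenvalues of a weight matrix
#'
#' Computed per school block (the matrix is block-diagonal by school) and
#' concatenated; cached on the object. Directed matrices can have complex
#' eigenvalues.
#'
#' @param W a `weight_matrix`.
#' @return complex (or numeric) eigenvalue vector of length `nrow(W)`.
#' @export
weight_eigenvalues <- function(W) {
  wm <- as_weight_matrix(W)
  if (!is.null(wm$cache$ev)) return(wm$cache$ev)
  ev <- unlist(lapply(school_blocks(wm), function(idx)
    eigen(as.matrix(wm$W[idx, idx, drop = FALSE]), only.values = TRUE)$values))
  wm$cache$ev <- ev
  ev
}

#' Feasible interval for the network dependence parameter
#'
#' The interval `(1/min real eigenvalue, 1/max real eigenvalue)` of the
#' weight matrix (real eigenvalues only), intersected with (-0.999, 0.999).
#'
#' @param ev eigenvalues from [weight_eigenvalues()], or a `weight_matrix`.
#' @return numeric length-2 vector (lower, upper).
#' @export
feasible_interval <- function(ev) {
  if (inherits(ev, "weight_matrix")) ev <- weight_eigenvalues(ev)
  re <- Re(ev[abs(Im(ev)) < 1e-8])
  lo <- if (any(re < -1e-12)) 1 / min(re) else -0.999
  hi <- if (any(re > 1e-12)) 1 / max(re) else 0.999
  c(max(lo, -0.999), min(hi, 0.999))
}
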