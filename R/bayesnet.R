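## DAG representation: 0/1 adjacency matrix with dimnames; adj[i, j] = 1
## means a directed edge i -> j.

dag_check <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stop_input("DAG adjacency must be a square matrix")
  if (any(diag(adj) != 0)) stop_input("DAG must not contain self-loops")
  if (!is_acyclic(adj)) stop_input("graph contains a directed cycle")
  invisible(adj)
}

#' Test a directed adjacency matrix for acyclicity
#'
#' @param adj square 0/1 matrix; `adj[i, j] = 1` encodes an edge i -> j.
#' @return TRUE when the graph is a DAG.
#' @export
is_acyclic <- function(adj) {
  a <- adj != 0
  indeg <- colSums(a)
  left <- rep(TRUE, nrow(a))
  repeat {
    src <- which(left & indeg == 0)
    if (!length(src)) break
    left[src] <- FALSE
    indeg <- indeg - colSums(a[src, , drop = FALSE])
  }
  !any(left)
}

#' Linear-Gaussian BIC score of a DAG
#'
#' Decomposable network score: each node contributes the maximised
#' Gaussian log-likelihood of its linear regression on its parents (with
#' intercept, residual variance at the MLE) minus `log(n)/2` times its
#' parameter count (coefficients + intercept + variance). Collinear
#' parent sets are scored with a small ridge (1e-8) and a warning.
#'
#' @param data sample x gene numeric matrix, columns standardized.
#' @param dag adjacency matrix over the columns of `data`
#'   (`dag[i, j] = 1` for an edge i -> j).
#' @return total score (numeric scalar) with per-node scores in
#'   attribute `"by_node"`.
#' @export
gaussian_bic <- function(data, dag) {
  data <- as.matrix(data)
  p <- ncol(data)
  n <- nrow(data)
  if (!all(dim(dag) == c(p, p)))
    stop_input("dag must be a %d x %d adjacency matrix", p, p)
  dag_check(dag)
  max_par <- max(colSums(dag != 0))
  if (n <= max_par + 1)
    stop_input("need more samples (%d) than the largest parent set + 1 (%d)",
               n, max_par + 1)
  xc <- sweep(data, 2, colMeans(data))
  G <- crossprod(xc)
  by_node <- vapply(seq_len(p), function(j) {
    pa <- which(dag[, j] != 0)
    k <- length(pa)
    rss <- if (k == 0) G[j, j] else {
      Spp <- G[pa, pa, drop = FALSE]
      spj <- G[pa, j]
      beta <- tryCatch(solve(Spp, spj), error = function(e) {
        warning(sprintf("collinear parents of column %d: ridge applied", j))
        solve(Spp + diag(1e-8, k), spj)
      })
      G[j, j] - sum(spj * beta)
    }
    sigma2 <- max(rss / n, 1e-12)
    -0.5 * n * (log(2 * pi * sigma2) + 1) - 0.5 * log(n) * (k + 2)
  }, numeric(1))
  structure(sum(by_node), by_node = by_node)
}

#' Hill-climbing Bayesian network structure learning
#'
#' Greedy search over single-edge add / delete / reverse moves that keep
#' the graph acyclic, accepting the best strictly-improving move under
#' the linear-Gaussian BIC of [gaussian_bic()]; ties are broken
#' lexicographically by (operation, from, to). The first climb starts
#' from the empty graph; the remaining `restarts - 1` climbs start from
#' seeded random DAGs, and the best-scoring result is returned. Columns
#' are standardized internally.
#'
#' @param data sample x gene matrix (>= 2 genes).
#' @param seed integer seed for the random restarts.
#' @param restarts number of climbs (>= 1; the first is deterministic).
#' @param max_iter move budget per climb; exhausting it returns the
#'   current DAG with `converged = FALSE`.
#' @param max_parents parent-set size cap.
#' @return list with `dag` (named adjacency matrix), `score`,
#'   `converged`, and `trace` (BIC after each accepted move of the best
#'   climb; strictly increasing).
#' @export
hill_climb <- function(data, seed = 1, restarts = 5, max_iter = 10000,
                       max_parents = 5) {
  data <- as.matrix(data)
  if (ncol(data) < 1) stop_input("need at least one gene")
  if (nrow(data) <= max_parents + 1)
    stop_input("need more samples (%d) than max_parents + 1 (%d)",
               nrow(data), max_parents + 1)
  res <- hc_fit(data, as.integer(restarts), as.integer(max_iter),
                as.integer(max_parents), as.integer(seed))
  dag <- res$adj
  dimnames(dag) <- list(colnames(data), colnames(data))
  dag_check(dag)
  if (!res$converged)
    warning("hill climb stopped at max_iter before reaching a local optimum")
  list(dag = dag, score = res$score, converged = res$converged,
       trace = res$trace)
}

#' Bootstrap edge strengths for hill-climbed networks
#'
#' Learns a DAG on each of `R` nonparametric bootstrap resamples of the
#' rows and tallies, per unordered gene pair, the fraction of replicates
#' in which the edge appears in either orientation (`strength`) and,
#' among those, the fraction oriented `from -> to`
#' (`direction_confidence`). Each returned row is oriented along the
#' majority direction (ties broken lexicographically), so
#' `direction_confidence >= 0.5` always.
#'
#' @param data sample x gene matrix.
#' @param R number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param restarts climbs per replicate (single climb by default, as is
#'   conventional for bootstrap model averaging).
#' @param max_iter,max_parents passed to the climber.
#' @param identity_resample use the original rows for every replicate
#'   (diagnostic mode; strengths are then 0 or 1).
#' @return data frame `from`, `to`, `strength`, `direction_confidence`,
#'   one row per pair observed at least once, sorted by decreasing
#'   strength.
#' @export
bootstrap_edge_strength <- function(data, R = 100, seed = 1, restarts = 1,
                                    max_iter = 10000, max_parents = 5,
                                    identity_resample = FALSE) {
  if (R < 1) stop_input("R must be >= 1")
  data <- as.matrix(data)
  genes <- colnames(data) %||% sprintf("g%d", seq_len(ncol(data)))
  cnt <- hc_bootstrap(data, as.integer(R), as.integer(restarts),
                      as.integer(max_iter), as.integer(max_parents),
                      as.integer(seed), isTRUE(identity_resample))
  p <- ncol(data)
  out <- list()
  for (i in seq_len(p - 1)) {
    for (j in seq((i + 1), p)) {
      both <- cnt[i, j] + cnt[j, i]
      if (both == 0) next
      if (cnt[i, j] >= cnt[j, i]) { a <- i; b <- j } else { a <- j; b <- i }
      out[[length(out) + 1]] <- data.frame(
        from = genes[a], to = genes[b], strength = both / R,
        direction_confidence = cnt[a, b] / both, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(from = character(0), to = character(0),
               strength = numeric(0), direction_confidence = numeric(0))
  res[order(-res$strength, res$from, res$to), , drop = FALSE] -> res
  rownames(res) <- NULL
  res
}

#' Filter bootstrap edges by strength and co-expression confirmation
#'
#' Keeps edges whose bootstrap strength is at least `strength_cut`
#' (inclusive: a strength of exactly 0.75 is retained) and whose
#' absolute pairwise correlation is at least `cor_cut`. The orientation
#' is the majority bootstrap direction. Output is sorted by decreasing
#' strength.
#'
#' @param strengths data frame from [bootstrap_edge_strength()].
#' @param cor symmetric correlation matrix with gene dimnames covering
#'   every retained pair.
#' @param strength_cut inclusive strength threshold.
#' @param cor_cut inclusive absolute-correlation threshold.
#' @return data frame `from`, `to`, `strength`, `direction_confidence`,
#'   `cor`.
#' @export
select_directed_edges <- function(strengths, cor, strength_cut = 0.75,
                                  cor_cut = 0.3) {
  keep <- strengths[strengths$strength >= strength_cut, , drop = FALSE]
  if (nrow(keep) == 0) {
    keep$cor <- numeric(0)
    return(keep)
  }
  missing <- !(keep$from %in% rownames(cor)) | !(keep$to %in% colnames(cor))
  if (any(missing))
    stop_input("no correlation available for pair %s - %s",
               keep$from[which(missing)[1]], keep$to[which(missing)[1]])
  keep$cor <- cor[cbind(keep$from, keep$to)]
  keep <- keep[abs(keep$cor) >= cor_cut, , drop = FALSE]
  keep <- keep[order(-keep$strength, keep$from, keep$to), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}
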