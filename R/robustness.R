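#' Edge preservation under random node deletion
#'
#' Repeatedly deletes a fraction of the network's nodes uniformly at
#' random and counts, per edge, the iterations in which both endpoints
#' survive. By default at least one node is removed even when
#' `round(fraction * |V|)` is zero, so small networks still experience
#' perturbation; `remove_at_least_one = FALSE` restores pure rounding.
#'
#' @param network a `regulatory_network` (or any list with `nodes` and
#'   `edges` in the same shape).
#' @param fraction fraction of nodes deleted per iteration, in \[0, 1).
#' @param iterations number of deletion iterations.
#' @param seed integer seed; same seed, same report.
#' @param remove_at_least_one force a minimum deletion of one node.
#' @return object of class `preservation_report`: list with `edges`
#'   (`from`, `to`, `preserved_count`), `preserved_fraction` (per
#'   iteration), `iterations`, and `n_deleted`.
#' @export
node_deletion_bootstrap <- function(network, fraction = 0.02,
                                    iterations = 100, seed = 1,
                                    remove_at_least_one = TRUE) {
  if (fraction < 0 || fraction >= 1)
    stop_input("fraction must be in [0, 1)")
  nodes <- network$nodes$gene_id
  edges <- network$edges
  if (length(nodes) == 0) stop_input("network is empty")
  d <- round(fraction * length(nodes))
  if (remove_at_least_one) d <- max(1L, d)
  ei <- match(edges$from, nodes)
  ej <- match(edges$to, nodes)
  preserved <- integer(nrow(edges))
  frac <- numeric(iterations)
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      alive <- rep(TRUE, length(nodes))
      if (d > 0) alive[sample.int(length(nodes), d)] <- FALSE
      ok <- alive[ei] & alive[ej]
      preserved <- preserved + ok
      frac[it] <- if (nrow(edges)) mean(ok) else 1
    }
  })
  structure(list(edges = data.frame(from = edges$from, to = edges$to,
                                    preserved_count = preserved,
                                    stringsAsFactors = FALSE),
                 preserved_fraction = frac, iterations = iterations,
                 n_deleted = d),
            class = "preservation_report")
}

#' Summarise edge preservation across networks
#'
#' For each threshold `k`, reports per network the fraction of edges
#' preserved in at least `k` iterations, plus the pooled median of that
#' fraction across networks, and each network's median per-iteration
#' preserved rate.
#'
#' @param reports named list of [node_deletion_bootstrap()] reports.
#' @param k_list iteration-count thresholds.
#' @return list with `per_network` (data frame `network`, `k`,
#'   `fraction`, `median_preserved_rate`) and `pooled` (data frame `k`,
#'   `median_fraction`).
#' @export
preservation_summary <- function(reports, k_list = c(70, 80)) {
  if (length(reports) == 0) stop_input("no preservation reports supplied")
  iters <- vapply(reports, function(r) r$iterations, numeric(1))
  if (any(k_list > iters[1]) || length(unique(iters)) > 1) {
    if (length(unique(iters)) > 1)
      stop_input("reports have differing iteration counts")
    stop_input("k (%d) exceeds the number of iterations (%d)",
               max(k_list), iters[1])
  }
  ids <- names(reports) %||% sprintf("network_%d", seq_along(reports))
  rows <- list()
  for (i in seq_along(reports)) {
    r <- reports[[i]]
    for (k in k_list) {
      rows[[length(rows) + 1]] <- data.frame(
        network = ids[i], k = k,
        fraction = if (nrow(r$edges)) mean(r$edges$preserved_count >= k)
                   else NA_real_,
        median_preserved_rate = median(r$preserved_fraction),
        stringsAsFactors = FALSE)
    }
  }
  per_network <- do.call(rbind, rows)
  pooled <- do.call(rbind, lapply(k_list, function(k) {
    fr <- per_network$fraction[per_network$k == k]
    data.frame(k = k, median_fraction = median(fr, na.rm = TRUE))
  }))
  list(per_network = per_network, pooled = pooled)
}
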