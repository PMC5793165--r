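#' Weighted co-expression adjacency
#'
#' Unsigned adjacency `a_ij = |cor(i, j)|^power` with zero diagonal.
#' Signed networks (`(0.5 + 0.5 * cor)^power`) are available behind the
#' `signed` flag; the default is unsigned, so genes with similar or
#' opposite expression patterns are treated alike.
#'
#' @param expr gene x sample matrix (log-scale normalised expression).
#' @param power soft-thresholding exponent.
#' @param signed use a signed network.
#' @return symmetric adjacency matrix with zero diagonal.
#' @export
coexpression_adjacency <- function(expr, power = 6, signed = FALSE) {
  cc <- cor(t(expr))
  a <- if (signed) (0.5 + 0.5 * cc)^power else abs(cc)^power
  diag(a) <- 0
  a
}

#' Choose the soft-thresholding power by scale-free fit
#'
#' For each candidate power the unsigned adjacency and the connectivity
#' `k_i = sum_j a_ij` are computed, the connectivity distribution is
#' binned into equal-count bins and the signed scale-free fit index
#' `-sign(slope) * R^2` of `log10 p(k)` versus `log10 k` is evaluated.
#' The smallest power whose fit reaches `r2_target` is chosen; if none
#' does, the power with the maximal fit is returned with a warning flag.
#' Constant gene rows are excluded with a warning.
#'
#' @param expr gene x sample matrix.
#' @param candidates candidate integer powers.
#' @param r2_target scale-free fit target.
#' @param n_bins number of equal-count connectivity bins.
#' @return list with elements `power`, `fit` (one row per candidate:
#'   `power`, `r_squared`, `slope`, `mean_k`), and `warning` (TRUE when
#'   no candidate reached the target).
#' @export
pick_soft_power <- function(expr, candidates = 1:20, r2_target = 0.8,
                            n_bins = 10) {
  if (nrow(expr) < 3) stop_input("need >= 3 genes to pick a soft power")
  if (ncol(expr) < 4) stop_input("need >= 4 samples to pick a soft power")
  sds <- apply(expr, 1, stats::sd)
  if (all(sds == 0)) stop_input("all gene rows are constant")
  if (any(sds == 0)) {
    warning(sprintf("excluding %d constant gene row(s)", sum(sds == 0)))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  cc <- abs(cor(t(expr)))
  diag(cc) <- 0
  fit <- data.frame(power = candidates, r_squared = NA_real_,
                    slope = NA_real_, mean_k = NA_real_)
  for (i in seq_along(candidates)) {
    a <- cc^candidates[i]
    k <- rowSums(a)
    fit$mean_k[i] <- mean(k)
    sf <- scale_free_fit(k, n_bins)
    fit$r_squared[i] <- sf$r_squared
    fit$slope[i] <- sf$slope
  }
  hit <- which(fit$r_squared >= r2_target)
  if (length(hit)) {
    list(power = candidates[hit[1]], fit = fit, warning = FALSE)
  } else {
    list(power = candidates[which.max(fit$r_squared)], fit = fit,
         warning = TRUE)
  }
}

## signed scale-free topology fit index over equal-count connectivity bins
scale_free_fit <- function(k, n_bins = 10) {
  breaks <- unique(quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 3) return(list(r_squared = 0, slope = 0))
  bins <- cut(k, breaks = breaks, include.lowest = TRUE)
  dk <- tapply(k, bins, mean)
  pk <- tapply(k, bins, length) / length(k)
  keep <- !is.na(dk) & dk > 0 & pk > 0
  if (sum(keep) < 3) return(list(r_squared = 0, slope = 0))
  x <- log10(dk[keep]); y <- log10(pk[keep])
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r_squared = 0, slope = 0))
  slope <- stats::cov(x, y) / stats::var(x)
  r2 <- cor(x, y)^2
  list(r_squared = -sign(slope) * r2, slope = slope)
}

#' Topological overlap from a weighted adjacency
#'
#' Computes the unsigned topological overlap measure
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj`, the shared-neighbour term. The diagonal is
#' defined as 1.
#'
#' @param adjacency symmetric matrix with entries in \[0, 1\] and zero
#'   diagonal.
#' @return TOM matrix (class `TOMMatrix`) with the adjacency and any
#'   soft power stored as attributes.
#' @param power optional soft power to record on the result.
#' @export
tom_from_adjacency <- function(adjacency, power = NA_real_) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a)) stop_input("adjacency must be square")
  if (max(abs(a - t(a))) > 1e-10)
    stop_input("adjacency must be symmetric (tolerance 1e-10)")
  if (any(diag(a) != 0)) stop_input("adjacency diagonal must be zero")
  if (any(a < 0 | a > 1)) stop_input("adjacency entries must be in [0, 1]")
  l <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  structure(tom, adjacency = a, power = power, class = c("TOMMatrix", "matrix"))
}

#' Cut a TOM dendrogram into co-expression modules
#'
#' Average-linkage hierarchical clustering of the dissimilarity
#' `1 - TOM`, cut at a fixed height (a deliberate, deterministic
#' simplification of WGCNA's dynamic tree cut). Clusters smaller than
#' `min_size` are pooled into the `unassigned` group. Modules are
#' labelled `M1, M2, ...` in order of decreasing size (ties broken by
#' the lexicographically smallest member).
#'
#' @param tom a [tom_from_adjacency()] result (or any symmetric
#'   similarity in \[0, 1\] with unit diagonal).
#' @param min_size minimum module size (>= 2).
#' @param cut_height static cut height on the `1 - TOM` dissimilarity.
#' @return object of class `gene_modules`: list with `assignments`
#'   (data frame `gene_id`, `module_id`), `modules` (named list of gene
#'   vectors), `mean_adjacency` (named vector, mean intra-module
#'   adjacency when the adjacency is available) and `tree` (hclust).
#' @export
detect_modules <- function(tom, min_size = 30, cut_height = 0.85) {
  if (min_size < 2) stop_input("min_size must be >= 2")
  tm <- unclass(tom)
  genes <- rownames(tm) %||% sprintf("g%d", seq_len(nrow(tm)))
  tree <- hclust(as.dist(1 - tm), method = "average")
  cl <- cutree(tree, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_size]
  assignments <- data.frame(gene_id = genes, module_id = "unassigned",
                            stringsAsFactors = FALSE)
  modules <- list()
  if (length(big)) {
    firsts <- vapply(big, function(b) min(genes[cl == b]), character(1))
    ord <- order(-as.integer(sizes[big]), firsts)
    for (i in seq_along(ord)) {
      b <- big[ord[i]]
      id <- paste0("M", i)
      members <- genes[cl == b]
      modules[[id]] <- members
      assignments$module_id[assignments$gene_id %in% members] <- id
    }
  }
  adj <- attr(tom, "adjacency")
  mean_adj <- vapply(modules, function(members) {
    if (is.null(adj)) return(NA_real_)
    sub <- adj[members, members, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  structure(list(assignments = assignments, modules = modules,
                 mean_adjacency = mean_adj, tree = tree,
                 cut_height = cut_height, min_size = min_size),
            class = "gene_modules")
}

#' @export
print.gene_modules <- function(x, ...) {
  cat(sprintf("%d co-expression module(s) over %d genes (%d unassigned)\n",
              length(x$modules), nrow(x$assignments),
              sum(x$assignments$module_id == "unassigned")))
  for (id in names(x$modules))
    cat(sprintf("  %s: %d genes\n", id, length(x$modules[[id]])))
  invisible(x)
}
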