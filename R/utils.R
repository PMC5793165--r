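#' @useDynLib lungregnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor cov dhyper median pt quantile rbinom rnorm rpois runif
#'   setNames p.adjust lm coef hclust cutree as.dist
#' @importFrom utils head read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

#' Run code with a temporary RNG seed
#'
#' Saves the current `.Random.seed`, seeds the generator, evaluates `expr`
#' and restores the previous state, so callers' random streams are not
#' perturbed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Welch two-sample t over the rows of two matrices, vectorised.
## Zero-variance rows: p = 0 if the means differ, p = 1 if equal.
row_welch <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  stat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(stat), df)
  degen <- se2 == 0
  if (any(degen)) {
    p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
    stat[degen] <- ifelse(m1[degen] == m2[degen], 0,
                          sign(m2[degen] - m1[degen]) * Inf)
  }
  list(statistic = stat, pvalue = p, mean1 = m1, mean2 = m2)
}

check_conditions <- function(conditions, samples) {
  if (!is.null(names(conditions))) {
    missing <- setdiff(samples, names(conditions))
    if (length(missing))
      stop_input("no condition label for sample(s): %s",
                 paste(utils::head(missing, 3), collapse = ", "))
    conditions <- conditions[samples]
  } else if (length(conditions) != length(samples)) {
    stop_input("`conditions` must be named by sample or match the %d columns",
               length(samples))
  }
  conditions <- as.character(conditions)
  bad <- setdiff(unique(conditions), c("normal", "tumor"))
  if (length(bad))
    stop_input("conditions must be 'normal' or 'tumor', got: %s",
               paste(bad, collapse = ", "))
  for (grp in c("normal", "tumor"))
    if (sum(conditions == grp) < 2)
      stop_input("need >= 2 samples per condition; '%s' has %d",
                 grp, sum(conditions == grp))
  conditions
}

#' Counts-per-million normalisation
#'
#' Scales each sample (column) so its values sum to one million. Used to
#' turn the simulator's raw counts into the normalised matrix every
#' downstream stage consumes.
#'
#' @param counts non-negative gene x sample matrix.
#' @return matrix of the same shape with columns summing to 1e6.
#' @export
cpm <- function(counts) {
  if (any(counts < 0)) stop_input("counts must be non-negative")
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop_input("sample with zero total counts")
  sweep(counts, 2, libsize, "/") * 1e6
}

#' Normalise counts by median-of-ratios size factors
#'
#' Estimates one size factor per sample as the median, over genes
#' expressed in every sample, of the ratio of the gene's count to its
#' geometric mean across samples, then rescales so the average library
#' totals one million. Robust to unbalanced differential expression
#' between sample groups, unlike plain counts-per-million.
#'
#' @param counts non-negative gene x sample count matrix.
#' @return normalised matrix, same shape, CPM-like magnitude.
#' @export
normalize_counts <- function(counts) {
  if (any(counts < 0)) stop_input("counts must be non-negative")
  pos <- rowSums(counts == 0) == 0
  if (sum(pos) < 10) return(cpm(counts))  # too few reference genes
  logg <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2,
              function(col) exp(median(log(col) - logg)))
  norm <- sweep(counts, 2, sf, "/")
  norm * 1e6 / mean(colSums(norm))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to renaming), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_input("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- si * sj / n2
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv_checked <- function(path, required, what = basename(path)) {
  if (!file.exists(path)) stop_input("missing input file: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop_input("%s: missing required column(s): %s", what,
               paste(missing, collapse = ", "))
  df
}

## gene x sample TSV with leading gene_id column -> numeric matrix
read_matrix_tsv <- function(path, what = basename(path)) {
  df <- read_tsv_checked(path, "gene_id", what)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$gene_id
  m
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
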