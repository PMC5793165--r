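## Shared fixtures, generated once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

## the reference simulation at its documented defaults
default_dataset <- function() {
  if (is.null(.fixture_cache$ds))
    .fixture_cache$ds <- generate_dataset(synthetic_config())
  .fixture_cache$ds
}

## small random symmetric adjacency in [0, 1] with zero diagonal
random_adjacency <- function(p) {
  m <- matrix(runif(p * p), p)
  a <- (m + t(m)) / 2
  diag(a) <- 0
  a
}

## naive O(p^3) topological overlap, written independently of the
## matrix-product implementation
tom_naive <- function(a) {
  p <- nrow(a)
  k <- rowSums(a)
  tom <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(p)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

## brute-force BH step-up: q_i = min_{j >= rank(i)} p_(j) * m / j, capped at 1
bh_naive <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(ord == i)  # rank of p[i]
    q[i] <- min(1, min(sort(p)[r:m] * m / (r:m)))
  }
  q
}

## exact two-sided Fisher p by full enumeration over all tables with the
## observed margins, using log-binomial coefficients (independent of dhyper)
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(m, k)
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  pr <- exp(logp)
  obs <- pr[xs == a]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

## enumerate all 25 DAGs on 3 labelled nodes and return the best BIC
exhaustive_best_bic <- function(data) {
  stopifnot(ncol(data) == 3)
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  best <- -Inf
  for (s1 in 0:2) for (s2 in 0:2) for (s3 in 0:2) {
    adj <- matrix(0, 3, 3)
    st <- c(s1, s2, s3)
    for (e in 1:3) {
      if (st[e] == 1) adj[pairs[e, 1], pairs[e, 2]] <- 1
      if (st[e] == 2) adj[pairs[e, 2], pairs[e, 1]] <- 1
    }
    if (!is_acyclic(adj)) next
    best <- max(best, as.numeric(gaussian_bic(data, adj)))
  }
  best
}

## standardize columns (sample sd) the way hill_climb does internally
standardize <- function(x) scale(x)[, , drop = FALSE]
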