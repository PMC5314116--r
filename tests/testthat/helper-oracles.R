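# Independent oracles and small helpers shared across the suite.

# all labelled DAGs on p nodes (pair-state enumeration); p <= 4
enumerate_all_dags <- function(p) {
  pairs <- combn(p, 2)
  np <- ncol(pairs)
  states <- expand.grid(rep(list(0:2), np))
  out <- list()
  for (r in seq_len(nrow(states))) {
    D <- matrix(FALSE, p, p)
    for (k in seq_len(np)) {
      s <- states[r, k]
      if (s == 1) D[pairs[1, k], pairs[2, k]] <- TRUE
      if (s == 2) D[pairs[2, k], pairs[1, k]] <- TRUE
    }
    if (!tastecircuit:::has_directed_cycle(D)) out[[length(out) + 1]] <- D
  }
  out
}

# brute-force: CPDAG adjacency of the globally best-BIC DAG
brute_force_best_cpdag <- function(X, dags) {
  labels <- colnames(X)
  bics <- vapply(dags, function(D) {
    dimnames(D) <- list(labels, labels)
    bic_of_dag(X, D)$bic
  }, numeric(1))
  best <- dags[[which.min(bics)]]
  dimnames(best) <- list(labels, labels)
  tastecircuit:::dag_to_cpdag(best)
}

# hand implementation of the step-up FDR rule (independent of p.adjust)
bh_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(1, q)
  out
}

# brute-force Kruskal-Wallis H with tie correction from first principles
kw_h_oracle <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(v) sum(v)^2 / length(v))) - 3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# histogram-based differential entropy (independent of the package's
# max-entropy approximation)
hist_entropy <- function(u, bins = 64) {
  u <- (u - mean(u)) / sd(u)
  h <- hist(u, breaks = bins, plot = FALSE)
  w <- diff(h$breaks)
  p <- h$counts / sum(h$counts)
  keep <- p > 0
  -sum(p[keep] * log(p[keep] / w[keep]))
}

# oracle orientation decision: entropy of (cause, residual) under both
# orderings, estimated by histogram
orientation_oracle <- function(x, y) {
  res <- function(a, b) b - mean(b) - cov(a, b) / var(a) * (a - mean(a))
  (hist_entropy(y) + hist_entropy(res(y, x))) -
    (hist_entropy(x) + hist_entropy(res(x, y)))
}

# canonical skeleton keys of a coefficient matrix
truth_skeleton <- function(B) {
  t <- which(B != 0, arr.ind = TRUE)
  a <- rownames(B)[t[, 1]]
  b <- colnames(B)[t[, 2]]
  sort(paste(pmin(a, b), pmax(a, b), sep = "|"))
}

truth_edge_keys <- function(B) {
  t <- which(B != 0, arr.ind = TRUE)
  paste(rownames(B)[t[, 1]], colnames(B)[t[, 2]], sep = ">")
}

directed_keys <- function(pattern) {
  D <- pattern$directed
  if (nrow(D)) paste(D[, 1], D[, 2], sep = ">") else character()
}

# draw a random DAG over circuit labels where a chosen edge can be reversed
# without creating a cycle in either version
random_dag_with_reversible_edge <- function(labels, from, to,
                                            edge_prob = 0.3) {
  repeat {
    B1 <- random_dag(labels, edge_prob)
    if (B1[to, from] != 0) {
      B1[from, to] <- B1[to, from]
      B1[to, from] <- 0
    }
    if (B1[from, to] == 0) B1[from, to] <- 0.5
    if (is.null(tastecircuit:::topological_order(B1 != 0))) next
    B2 <- B1
    B2[to, from] <- B1[from, to]
    B2[from, to] <- 0
    if (is.null(tastecircuit:::topological_order(B2 != 0))) next
    return(list(forward = B1, reversed = B2))
  }
}
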