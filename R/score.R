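# Decomposable Gaussian BIC scoring for DAG search.
#
# Score convention: minimized BIC = -2 ln(ML) + k ln(n), with k = number of
# directed edges + number of variables. Constants common to all models (2*pi
# terms) are dropped, so the -2 ln(ML) contribution of node y with parent
# set P reduces to n * ln(sigma2_hat), the ML (1/n) residual variance of y
# regressed on P. With several subjects the per-subject BICs are averaged,
# each subject scored at its own n (the multi-sample score extension).

#' Multi-subject ROI time-series container
#'
#' @param subjects List of numeric matrices (rows = volumes, columns =
#'   regions), all with identical column labels in identical order; or a
#'   single matrix.
#' @param labels Optional region labels overriding the matrices' colnames.
#' @param standardize Z-score each column within each subject (default
#'   `TRUE`); search and orientation always operate on standardized series.
#' @return Object of class `"roi_timeseries_set"`.
#' @export
roi_timeseries_set <- function(subjects, labels = NULL, standardize = TRUE) {
  if (is.matrix(subjects) || is.data.frame(subjects))
    subjects <- list(as.matrix(subjects))
  if (!length(subjects)) stop("at least one subject is required")
  subjects <- lapply(subjects, as.matrix)
  if (is.null(labels)) labels <- colnames(subjects[[1]])
  if (is.null(labels))
    labels <- paste0("V", seq_len(ncol(subjects[[1]])))
  for (i in seq_along(subjects)) {
    X <- subjects[[i]]
    if (!is.null(colnames(X)) && !identical(colnames(X), labels))
      stop("subject ", i, ": region labels differ from the first subject")
    if (ncol(X) != length(labels))
      stop("subject ", i, ": wrong number of columns")
    if (any(!is.finite(X)))
      stop("subject ", i, ": non-finite values in time series")
    if (nrow(X) < ncol(X) + 2)
      stop("subject ", i, ": too few time points (need at least p + 2)")
    colnames(subjects[[i]]) <- labels
  }
  if (standardize)
    subjects <- lapply(subjects, function(X) {
      s <- apply(X, 2, sd)
      if (any(s == 0)) stop("constant column cannot be standardized")
      scale(X)
    })
  structure(list(subjects = subjects, labels = labels,
                 standardized = standardize),
            class = "roi_timeseries_set")
}

#' @export
print.roi_timeseries_set <- function(x, ...) {
  Ts <- vapply(x$subjects, nrow, integer(1))
  cat("ROI time-series set:", length(x$subjects), "subject(s),",
      length(x$labels), "regions, T =",
      paste(range(Ts), collapse = "-"), "\n")
  invisible(x)
}

# internal scorer: per-subject ML covariance of z-scored columns + memoised
# local scores (standardization is applied here so it never depends on how
# the container was built)
make_scorer <- function(set) {
  subs <- lapply(set$subjects, function(X) {
    n <- nrow(X)
    Xc <- scale(X)
    list(S = crossprod(Xc) / n, n = n, logn = log(n))
  })
  env <- new.env(hash = TRUE, parent = emptyenv())
  list(subs = subs, p = length(set$labels), labels = set$labels, cache = env)
}

# ML residual variance of y given parents, from a covariance matrix
conditional_variance <- function(S, y, parents) {
  if (!length(parents)) return(S[y, y])
  Spp <- S[parents, parents, drop = FALSE]
  b <- tryCatch(solve(Spp, S[parents, y]),
                error = function(e)
                  stop("rank-deficient parent design for node ", y,
                       call. = FALSE))
  max(S[y, y] - sum(S[parents, y] * b), 1e-300)
}

# penalized local score: mean over subjects of n*ln(sigma2) + (|P|+1)*ln(n)
local_score_pen <- function(sc, y, parents) {
  parents <- sort(parents)
  key <- paste0(y, "|", paste(parents, collapse = ","))
  v <- sc$cache[[key]]
  if (!is.null(v)) return(v)
  tot <- 0
  for (s in sc$subs)
    tot <- tot + s$n * log(conditional_variance(s$S, y, parents)) +
      (length(parents) + 1) * s$logn
  v <- tot / length(sc$subs)
  assign(key, v, envir = sc$cache)
  v
}

#' Local Gaussian log-likelihood score of one node
#'
#' The -2 ln(ML) contribution of a single node given a parent set:
#' `n * ln(sigma2_hat)` with `sigma2_hat` the ML (1/n denominator) residual
#' variance of the node regressed on its parents. The total model deviance
#' decomposes as the sum of these contributions; constants common to all
#' models are dropped.
#'
#' @param data Numeric matrix (rows = observations); columns should be
#'   standardized (done by default).
#' @param node Column name or index of the scored node.
#' @param parents Column names or indices of the parent set (may be empty).
#' @param standardize Z-score columns first (default `TRUE`).
#' @return Scalar `n * ln(sigma2_hat)`.
#' @export
local_gaussian_score <- function(data, node, parents = NULL,
                                 standardize = TRUE) {
  X <- as.matrix(data)
  if (standardize) X <- scale(X)
  n <- nrow(X)
  idx <- function(v) if (is.character(v)) match(v, colnames(X)) else v
  y <- idx(node); pa <- idx(parents)
  if (anyNA(c(y, pa))) stop("unknown column name")
  if (y %in% pa) stop("parent set must exclude the node itself")
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  n * log(conditional_variance(S, y, pa))
}

#' BIC of a directed acyclic graph
#'
#' Scores a DAG by the minimized Bayes Information Criterion
#' `-2 ln(ML) + k ln(n)`, where the model dimension `k` counts the directed
#' edges plus the number of variables (one residual variance per node).
#' Lower is better; all DAGs in one Markov equivalence class receive the
#' same score.
#'
#' @param data Numeric matrix (one subject) or a
#'   [roi_timeseries_set()]; for a set the per-subject BICs are averaged.
#' @param dag Logical/0-1 adjacency matrix (`dag[i, j]` means `i -> j`) with
#'   dimnames matching the data columns, or a two-column edge matrix.
#' @return Object of class `"ges_score"`: list with `neg2_loglik`, `k`, `n`,
#'   `bic`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(500); y <- 0.7 * x + rnorm(500)
#' d <- cbind(x, y)
#' fwd <- matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2,
#'               dimnames = list(c("x", "y"), c("x", "y")))
#' bic_of_dag(d, fwd)$bic - bic_of_dag(d, t(fwd))$bic  # ~0: score equivalence
bic_of_dag <- function(data, dag) {
  set <- if (inherits(data, "roi_timeseries_set")) data else
    roi_timeseries_set(data)
  p <- length(set$labels)
  D <- as_dag_adjacency(dag, set$labels)
  # every entry of D is a directed edge here, so a 2-cycle is a cycle too
  if (is.null(topological_order(D)))
    stop("graph is cyclic; BIC requires a DAG")
  sc <- make_scorer(set)
  neg2 <- 0; pen_n <- 0
  for (s in sc$subs) pen_n <- pen_n + s$logn
  pen_n <- pen_n / length(sc$subs)
  for (y in seq_len(p)) {
    pa <- which(D[, y])
    tot <- 0
    for (s in sc$subs)
      tot <- tot + s$n * log(conditional_variance(s$S, y, pa))
    neg2 <- neg2 + tot / length(sc$subs)
  }
  k <- sum(D) + p
  n <- if (length(sc$subs) == 1) sc$subs[[1]]$n else
    vapply(sc$subs, `[[`, numeric(1), "n")
  structure(list(neg2_loglik = neg2, k = k, n = n,
                 bic = neg2 + k * pen_n),
            class = "ges_score")
}

#' @export
print.ges_score <- function(x, ...) {
  cat("BIC =", format(x$bic, digits = 6), " (-2lnML =",
      format(x$neg2_loglik, digits = 6), ", k =", x$k, ", n =",
      paste(x$n, collapse = ","), ")\n")
  invisible(x)
}

# accept adjacency matrix (logical/numeric) or 2-column edge matrix
as_dag_adjacency <- function(dag, labels) {
  p <- length(labels)
  if (is.matrix(dag) && ncol(dag) == 2 && (is.character(dag) || !nrow(dag))) {
    D <- matrix(FALSE, p, p, dimnames = list(labels, labels))
    if (nrow(dag)) {
      if (length(setdiff(c(dag), labels))) stop("unknown vertex in edge list")
      D[dag] <- TRUE
    }
    return(D)
  }
  D <- dag != 0
  if (is.null(dimnames(D))) dimnames(D) <- list(labels, labels)
  if (!identical(rownames(D), labels))
    D <- D[labels, labels]
  diag(D) <- FALSE
  D
}
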