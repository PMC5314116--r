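# Model-fitting front end: effective_connectivity() fits a directed
# effective-connectivity graph to multi-subject ROI time series (multi-sample
# greedy equivalence search, then optional non-Gaussian orientation of the
# remaining undirected edges) and returns a classed object with the usual
# methods.

#' Fit an effective-connectivity graph to ROI time series
#'
#' Runs the multi-subject greedy equivalence search ([images_search()]) on
#' per-subject standardized series and, by default, the fixed-structure
#' non-Gaussian orientation post-processor
#' ([ling_orient_fixed_structure()]) on the searched pattern. Edge
#' coefficients are then estimated by pooled least squares of each region on
#' its directed parents.
#'
#' @param data A [roi_timeseries_set()], a single matrix, or a list of
#'   per-subject matrices (rows = volumes, columns = regions).
#' @param orient Apply the non-Gaussian orientation step (default `TRUE`).
#' @return Object of class `"effconn"` with components `pattern`
#'   (the oriented [pattern_graph()]), `search_pattern` (pattern before
#'   orientation), `trace`, `coefficients`, `score` (model [bic_of_dag()]
#'   of the directed part), `data`, `labels`, `call`.
#' @seealso [print.effconn()], [summary.effconn()], [coef.effconn()],
#'   [plot.effconn()], [simulate.effconn()], [residuals.effconn()]
#' @export
#' @examples
#' spec <- sem_spec(chain_dag(c("thalamus", "posterior_insula",
#'                              "ventral_striatum"), beta = 0.7),
#'                  noise = "uniform", n_subjects = 4, n_time = 200)
#' sim <- generate_sem_timeseries(spec, seed = 1)
#' fit <- effective_connectivity(sim$set)
#' fit
#' coef(fit)
effective_connectivity <- function(data, orient = TRUE) {
  set <- if (inherits(data, "roi_timeseries_set")) data else
    roi_timeseries_set(data)
  res <- images_search(set)
  pat <- res$pattern
  if (orient) pat <- ling_orient_fixed_structure(set, pat)
  B <- fit_edge_coefficients(set, pat)
  D <- pattern_to_adj(pat) & !t(pattern_to_adj(pat))
  score <- bic_of_dag(set, D)
  structure(list(pattern = pat, search_pattern = res$pattern,
                 trace = res$trace, coefficients = B, score = score,
                 data = set, labels = set$labels,
                 call = match.call()),
            class = "effconn")
}

# pooled OLS coefficient of each node on its directed parents, on the
# per-subject standardized scale used by search and orientation
fit_edge_coefficients <- function(set, pattern) {
  X <- do.call(rbind, lapply(set$subjects, scale))
  p <- length(set$labels)
  B <- matrix(0, p, p, dimnames = list(set$labels, set$labels))
  A <- pattern_to_adj(pattern)
  D <- A & !t(A)
  for (y in seq_len(p)) {
    pa <- which(D[, y])
    if (!length(pa)) next
    fit <- lm.fit(cbind(1, X[, pa, drop = FALSE]), X[, y])
    B[pa, y] <- fit$coefficients[-1]
  }
  B
}

#' @export
print.effconn <- function(x, ...) {
  cat("Effective-connectivity fit (multi-sample GES",
      if (nrow(x$search_pattern$undirected) != nrow(x$pattern$undirected))
        "+ non-Gaussian orientation" else NULL, ")\n")
  cat("  subjects:", length(x$data$subjects),
      "  regions:", length(x$labels), "\n")
  cat("  edges   :", nrow(x$pattern$directed), "directed,",
      nrow(x$pattern$undirected), "undirected\n")
  cat("  BIC     :", format(x$score$bic, digits = 6), "\n")
  invisible(x)
}

#' Summarise an effective-connectivity fit
#' @param object An `"effconn"` fit.
#' @param ... Unused.
#' @return Object of class `"summary.effconn"`: the edge table with fitted
#'   coefficients and orientation measures, plus the model score.
#' @export
summary.effconn <- function(object, ...) {
  ed <- pattern_edges(object$pattern)
  ed$coefficient <- NA_real_
  if (nrow(ed)) {
    dir <- ed$edge_type == "directed"
    ed$coefficient[dir] <- object$coefficients[cbind(ed$from[dir],
                                                     ed$to[dir])]
  }
  structure(list(edges = ed, score = object$score,
                 n_subjects = length(object$data$subjects),
                 labels = object$labels),
            class = "summary.effconn")
}

#' @export
print.summary.effconn <- function(x, ...) {
  cat("Effective-connectivity fit:", length(x$labels), "regions,",
      x$n_subjects, "subject(s)\n")
  print(x$score)
  if (nrow(x$edges)) {
    cat("\nEdges:\n")
    print(x$edges, row.names = FALSE, digits = 3)
  } else cat("\n(no edges)\n")
  invisible(x)
}

#' @export
coef.effconn <- function(object, ...) object$coefficients

#' Residuals of each region given its fitted parents
#' @param object An `"effconn"` fit.
#' @param ... Unused.
#' @return Pooled residual matrix (rows = pooled volumes, columns = regions).
#' @export
residuals.effconn <- function(object, ...) {
  X <- do.call(rbind, lapply(object$data$subjects, scale))
  X - X %*% object$coefficients
}

#' Simulate new subjects from a fitted effective-connectivity model
#'
#' Draws new ROI time series from the linear structural-equation model
#' defined by the fit's directed edges and coefficients (undirected edges
#' are not simulated), with the chosen noise family scaled to the fitted
#' residual variances.
#'
#' @param object An `"effconn"` fit.
#' @param nsim Number of subjects to simulate.
#' @param seed Integer seed.
#' @param n_time Time points per subject (default: first subject's length).
#' @param noise Noise family, see [sem_spec()].
#' @param ... Unused.
#' @return A [roi_timeseries_set()] (unstandardized).
#' @export
simulate.effconn <- function(object, nsim = 1, seed = NULL,
                             n_time = NULL, noise = "gaussian", ...) {
  if (is.null(n_time)) n_time <- nrow(object$data$subjects[[1]])
  r <- residuals(object)
  scales <- apply(r, 2, function(v) sqrt(mean(v^2)))
  spec <- sem_spec(object$coefficients, noise = noise,
                   noise_scale = scales, n_subjects = nsim, n_time = n_time)
  generate_sem_timeseries(spec, seed = if (is.null(seed)) 1L else seed,
                          standardize = FALSE)$set
}

#' Plot an effective-connectivity graph
#'
#' Draws the fitted pattern with igraph: directed edges with arrows,
#' undirected (reversible) edges without.
#'
#' @param x An `"effconn"` fit or a [pattern_graph()].
#' @param ... Passed on to [igraph::plot.igraph()].
#' @export
plot.effconn <- function(x, ...) {
  g <- x$pattern
  edges <- pattern_edges(g)
  ig <- igraph::make_empty_graph(n = length(g$vertices), directed = TRUE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g$vertices)
  arrow <- numeric(0)
  if (nrow(edges)) {
    ig <- igraph::add_edges(ig, t(as.matrix(edges[, c("from", "to")])))
    arrow <- ifelse(edges$edge_type == "directed", 1, 0)
  }
  igraph::plot.igraph(ig, edge.arrow.mode = arrow,
                      vertex.label.cex = 0.8, ...)
  invisible(x)
}

#' Group-wise effective-connectivity pipeline with cross-group comparison
#'
#' Fits [effective_connectivity()] to each group's (optionally per
#' hemisphere) time-series set and tabulates, for every vertex pair
#' appearing in any fitted graph, whether the edge is shared across groups,
#' unique to one group, direction-reversed between groups, or mixed.
#'
#' @param sets Named list of [roi_timeseries_set()] objects (one per group,
#'   or per group-hemisphere); all over the same regions.
#' @param orient Apply the non-Gaussian orientation step (default `TRUE`).
#' @return List with `fits` (named list of `"effconn"` objects) and
#'   `comparison` (data frame: `region_a`, `region_b`, one status column per
#'   group with values `"absent"`, `"a->b"`, `"b->a"`, `"undirected"`, and
#'   `flag`).
#' @export
run_effective_connectivity <- function(sets, orient = TRUE) {
  if (!is.list(sets) || !length(sets))
    stop("sets must be a non-empty named list of time-series sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every group needs a name")
  labels0 <- NULL
  fits <- lapply(sets, function(s) {
    fit <- effective_connectivity(s, orient = orient)
    if (is.null(labels0)) labels0 <<- fit$labels
    else if (!setequal(labels0, fit$labels))
      stop("groups use different region sets")
    fit
  })
  comparison <- compare_patterns(lapply(fits, function(f) f$pattern))
  list(fits = fits, comparison = comparison)
}

# cross-group edge comparison table
compare_patterns <- function(patterns) {
  groups <- names(patterns)
  all_pairs <- unique(unlist(lapply(patterns, skeleton_keys)))
  if (!length(all_pairs))
    return(data.frame(region_a = character(), region_b = character(),
                      flag = character(), stringsAsFactors = FALSE))
  all_pairs <- sort(all_pairs)
  ab <- do.call(rbind, strsplit(all_pairs, "|", fixed = TRUE))
  status <- sapply(patterns, function(g) {
    A <- pattern_to_adj(g)
    vapply(seq_along(all_pairs), function(k) {
      a <- ab[k, 1]; b <- ab[k, 2]
      if (!a %in% g$vertices || !b %in% g$vertices) return("absent")
      if (A[a, b] && A[b, a]) "undirected"
      else if (A[a, b]) "a->b"
      else if (A[b, a]) "b->a"
      else "absent"
    }, character(1))
  })
  status <- matrix(status, nrow = length(all_pairs),
                   dimnames = list(NULL, groups))
  flag <- apply(status, 1, function(s) {
    present <- s[s != "absent"]
    if (length(present) == 1) "group_unique"
    else if (all(c("a->b", "b->a") %in% present)) "direction_reversed"
    else if (length(present) == length(s) && length(unique(present)) == 1)
      "shared"
    else "mixed"
  })
  out <- data.frame(region_a = ab[, 1], region_b = ab[, 2],
                    stringsAsFactors = FALSE)
  for (g in groups) out[[g]] <- status[, g]
  out$flag <- flag
  out
}
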