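# CPDAG (pattern) machinery: adjacency-matrix representation, Meek
# orientation rules, consistent DAG extension (Dor-Tarsi) and DAG-to-CPDAG
# completion. Internally a graph over p nodes is a logical p x p matrix A:
#   A[i,j] &&  A[j,i]  : undirected edge i - j
#   A[i,j] && !A[j,i]  : directed edge  i -> j

adjacent <- function(A, i, j) A[i, j] || A[j, i]

directed_part <- function(A) A & !t(A)
undirected_part <- function(A) A & t(A)

# TRUE if the directed subgraph of A has a cycle (Kahn's algorithm)
has_directed_cycle <- function(A) {
  D <- directed_part(A)
  active <- rep(TRUE, nrow(D))
  repeat {
    indeg <- colSums(D[active, , drop = FALSE])
    src <- active & indeg == 0
    if (!any(src)) break
    D[src, ] <- FALSE
    active[src] <- FALSE
  }
  any(active)
}

# every pair in U adjacent (any direction)?
is_clique <- function(A, U) {
  if (length(U) < 2) return(TRUE)
  sub <- A[U, U, drop = FALSE] | t(A[U, U, drop = FALSE])
  all(sub[upper.tri(sub)])
}

# can `to` be reached from `from` along a semi-directed path (directed edges
# forward or undirected edges) avoiding nodes in `blocked`?
semidirected_reachable <- function(A, from, to, blocked = integer()) {
  p <- nrow(A)
  seen <- rep(FALSE, p)
  seen[blocked] <- TRUE
  queue <- from
  if (from %in% blocked) return(FALSE)
  seen[from] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nxt <- which(A[v, ] & !seen)
    if (to %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  FALSE
}

# Meek orientation rules R1-R3 applied to closure. R4 only fires under
# background knowledge and cannot trigger on patterns built from
# v-structures, so it is omitted.
meek_closure <- function(A) {
  p <- nrow(A)
  repeat {
    changed <- FALSE
    und <- which(A & t(A), arr.ind = TRUE)
    und <- und[und[, 1] != und[, 2], , drop = FALSE]
    for (k in seq_len(nrow(und))) {
      b <- und[k, 1]; c2 <- und[k, 2]
      if (!(A[b, c2] && A[c2, b])) next  # may have been oriented this sweep
      # R1: a -> b, b - c, a not adjacent to c  =>  b -> c
      aset <- which(A[, b] & !A[b, ])
      if (length(aset) && any(!(A[aset, c2] | A[c2, aset]))) {
        A[c2, b] <- FALSE; changed <- TRUE; next
      }
      # R2: b -> m -> c with b - c  =>  b -> c
      m <- which(A[b, ] & !A[, b] & A[, c2] & !A[c2, ])
      if (length(m)) {
        A[c2, b] <- FALSE; changed <- TRUE; next
      }
      # R3: b - c with b - d1, b - d2, d1 -> c, d2 -> c, d1 !adj d2 => b -> c
      dset <- which(A[b, ] & A[, b] & A[, c2] & !A[c2, ])
      if (length(dset) >= 2) {
        pairs <- combn(dset, 2)
        nonadj <- !(A[cbind(pairs[1, ], pairs[2, ])] |
                    A[cbind(pairs[2, ], pairs[1, ])])
        if (any(nonadj)) {
          A[c2, b] <- FALSE; changed <- TRUE; next
        }
      }
    }
    if (!changed) break
  }
  A
}

# consistent DAG extension of a PDAG (Dor & Tarsi); errors if none exists
pdag_to_dag <- function(A) {
  p <- nrow(A)
  res <- A
  active <- rep(TRUE, p)
  remaining <- p
  while (remaining > 0) {
    found <- FALSE
    for (x in which(active)) {
      # x must be a sink in the directed sense within the active subgraph
      out_dir <- A[x, ] & !A[, x] & active
      if (any(out_dir)) next
      und <- which(A[x, ] & A[, x] & active)
      adj_x <- which((A[x, ] | A[, x]) & active); adj_x <- setdiff(adj_x, x)
      ok <- TRUE
      for (y in und) {
        others <- setdiff(adj_x, y)
        if (length(others) && any(!(A[y, others] | A[others, y]))) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      # orient all undirected edges into x
      if (length(und)) res[x, und] <- FALSE
      active[x] <- FALSE
      remaining <- remaining - 1
      found <- TRUE
      break
    }
    if (!found) stop("PDAG admits no consistent DAG extension")
  }
  res
}

# completed pattern (CPDAG) of a DAG: skeleton + v-structures + Meek closure
dag_to_cpdag <- function(D) {
  p <- nrow(D)
  A <- D | t(D)             # skeleton, all undirected
  for (y in seq_len(p)) {
    pa <- which(D[, y])
    if (length(pa) < 2) next
    pr <- combn(pa, 2)
    for (k in seq_len(ncol(pr))) {
      i <- pr[1, k]; j <- pr[2, k]
      if (!(D[i, j] || D[j, i])) {     # unmarried parents: v-structure
        A[y, i] <- FALSE
        A[y, j] <- FALSE
      }
    }
  }
  meek_closure(A)
}

# re-complete a PDAG produced by an insert/delete operator
complete_pattern <- function(A) dag_to_cpdag(pdag_to_dag(A))

#' Construct a pattern graph (CPDAG with orientation confidences)
#'
#' A pattern graph represents a Markov equivalence class of DAGs: compelled
#' edges are directed, reversible edges undirected. The optional
#' `orientation_measure` stores, per edge `"x->y"`, the signed non-Gaussian
#' orientation confidence assigned by [ling_orient_fixed_structure()].
#'
#' @param vertices Character vector of region labels.
#' @param directed Two-column character matrix (from, to), possibly empty.
#' @param undirected Two-column character matrix of unordered pairs.
#' @param orientation_measure Named numeric vector keyed `"x->y"`, optional.
#' @return Object of class `"pattern_graph"`.
#' @export
pattern_graph <- function(vertices, directed = NULL, undirected = NULL,
                          orientation_measure = numeric()) {
  empty <- matrix(character(), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  if (is.null(directed) || !length(directed)) directed <- empty
  if (is.null(undirected) || !length(undirected)) undirected <- empty
  directed <- matrix(as.character(directed), ncol = 2,
                     dimnames = list(NULL, c("from", "to")))
  undirected <- matrix(as.character(undirected), ncol = 2,
                       dimnames = list(NULL, c("from", "to")))
  used <- unique(c(directed, undirected))
  if (length(setdiff(used, vertices)))
    stop("edge endpoint(s) not in vertex set: ",
         paste(setdiff(used, vertices), collapse = ", "))
  g <- structure(list(vertices = vertices, directed = directed,
                      undirected = undirected,
                      orientation_measure = orientation_measure),
                 class = "pattern_graph")
  pairkey <- function(m) apply(cbind(pmin(m[, 1], m[, 2]),
                                     pmax(m[, 1], m[, 2])), 1,
                               paste, collapse = "|")
  if (nrow(directed) && nrow(undirected) &&
      length(intersect(pairkey(directed), pairkey(undirected))))
    stop("a vertex pair appears both directed and undirected")
  if (has_directed_cycle(pattern_to_adj(g)))
    stop("directed subgraph contains a cycle")
  g
}

# pattern_graph <-> adjacency matrix
pattern_to_adj <- function(g) {
  p <- length(g$vertices)
  A <- matrix(FALSE, p, p, dimnames = list(g$vertices, g$vertices))
  if (nrow(g$directed)) A[g$directed] <- TRUE
  if (nrow(g$undirected)) {
    A[g$undirected] <- TRUE
    A[g$undirected[, 2:1, drop = FALSE]] <- TRUE
  }
  A
}

adj_to_pattern <- function(A, orientation_measure = numeric()) {
  v <- rownames(A)
  D <- which(A & !t(A), arr.ind = TRUE)
  U <- which(A & t(A), arr.ind = TRUE)
  U <- U[U[, 1] < U[, 2], , drop = FALSE]
  pattern_graph(v,
                directed = cbind(v[D[, 1]], v[D[, 2]]),
                undirected = cbind(v[U[, 1]], v[U[, 2]]),
                orientation_measure = orientation_measure)
}

#' @export
print.pattern_graph <- function(x, ...) {
  cat("Pattern graph:", length(x$vertices), "vertices,",
      nrow(x$directed), "directed /", nrow(x$undirected),
      "undirected edges\n")
  if (nrow(x$directed))
    cat(paste0("  ", x$directed[, 1], " -> ", x$directed[, 2],
               collapse = "\n"), "\n")
  if (nrow(x$undirected))
    cat(paste0("  ", x$undirected[, 1], " -- ", x$undirected[, 2],
               collapse = "\n"), "\n")
  invisible(x)
}

#' Edge table of a pattern graph
#' @param g A `"pattern_graph"`.
#' @return Data frame with columns `from`, `to`, `edge_type`,
#'   `orientation_measure`.
#' @export
pattern_edges <- function(g) {
  stopifnot(inherits(g, "pattern_graph"))
  rows <- list()
  if (nrow(g$directed))
    rows[[1]] <- data.frame(from = g$directed[, 1], to = g$directed[, 2],
                            edge_type = "directed", stringsAsFactors = FALSE)
  if (nrow(g$undirected))
    rows[[2]] <- data.frame(from = g$undirected[, 1], to = g$undirected[, 2],
                            edge_type = "undirected",
                            stringsAsFactors = FALSE)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(from = character(), to = character(),
               edge_type = character(), stringsAsFactors = FALSE)
  key <- paste0(out$from, "->", out$to)
  out$orientation_measure <- unname(g$orientation_measure[key])
  rownames(out) <- NULL
  out
}

#' Convert a pattern graph to an igraph object
#' @param g A `"pattern_graph"`.
#' @return An igraph graph; undirected edges are stored as mutual arc pairs.
#' @export
pattern_to_igraph <- function(g) {
  A <- pattern_to_adj(g)
  igraph::graph_from_adjacency_matrix(A * 1, mode = "directed")
}

# skeleton as a canonical set of "a|b" keys (a < b)
skeleton_keys <- function(g) {
  e <- rbind(g$directed, g$undirected)
  if (!nrow(e)) return(character())
  sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "|"))
}
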