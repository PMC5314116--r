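# Greedy equivalence search (GES) over CPDAGs with the minimized BIC score,
# and its multi-subject extension (score averaged over subjects).
#
# Candidate moves are the standard insert/delete operators on the current
# pattern: Insert(x, y, T) adds x -> y and orients T toward y, valid when
# NA(y,x) + T is a clique and blocks every semi-directed y ~> x path;
# Delete(x, y, H) removes the x/y edge and orients y -> h, x -> h for h in H,
# valid when NA(y,x) \ H is a clique. After each accepted move the pattern is
# re-completed (consistent extension, then v-structures + Meek closure).
# Ties between equal-score moves are broken lexicographically on
# (source label, target label, subset) so the search is fully deterministic.

# strict-improvement tolerance guarding against floating-point noise
.ges_tol <- 1e-9

power_set <- function(v) {
  out <- list(integer(0))
  for (x in v) out <- c(out, lapply(out, function(s) c(s, x)))
  out
}

ges_neighbors_und <- function(A, y) which(A[y, ] & A[, y])
ges_parents <- function(A, y) which(A[, y] & !A[y, ])

# best insertion move, or NULL
best_insertion <- function(A, sc) {
  p <- nrow(A)
  labels <- sc$labels
  best <- NULL
  for (y in seq_len(p)) {
    ne_y <- ges_neighbors_und(A, y)
    pa_y <- ges_parents(A, y)
    for (x in seq_len(p)) {
      if (x == y || adjacent(A, x, y)) next
      adj_x <- A[x, ] | A[, x]
      na_yx <- ne_y[adj_x[ne_y]]
      t_pool <- ne_y[!adj_x[ne_y]]
      for (T in power_set(t_pool)) {
        U <- c(na_yx, T)
        if (!is_clique(A, U)) next
        if (semidirected_reachable(A, y, x, blocked = U)) next
        old <- unique(c(pa_y, U))
        d <- local_score_pen(sc, y, c(old, x)) - local_score_pen(sc, y, old)
        cand <- list(x = x, y = y, set = T, delta = d)
        if (is.null(best) || d < best$delta - .ges_tol ||
            (abs(d - best$delta) <= .ges_tol &&
             move_key(cand, labels) < move_key(best, labels)))
          best <- cand
      }
    }
  }
  best
}

# best deletion move, or NULL
best_deletion <- function(A, sc) {
  p <- nrow(A)
  labels <- sc$labels
  best <- NULL
  for (y in seq_len(p)) {
    ne_y <- ges_neighbors_und(A, y)
    pa_y <- ges_parents(A, y)
    for (x in seq_len(p)) {
      if (x == y || !A[x, y]) next   # considers x -> y and x -- y
      adj_x <- A[x, ] | A[, x]
      na_yx <- ne_y[adj_x[ne_y]]
      na_yx <- setdiff(na_yx, x)
      for (H in power_set(na_yx)) {
        R <- setdiff(na_yx, H)
        if (!is_clique(A, R)) next
        base <- unique(c(pa_y, R))
        d <- local_score_pen(sc, y, setdiff(base, x)) -
          local_score_pen(sc, y, unique(c(base, x)))
        cand <- list(x = x, y = y, set = H, delta = d)
        if (is.null(best) || d < best$delta - .ges_tol ||
            (abs(d - best$delta) <= .ges_tol &&
             move_key(cand, labels) < move_key(best, labels)))
          best <- cand
      }
    }
  }
  best
}

move_key <- function(m, labels)
  paste(labels[m$x], labels[m$y],
        paste(sort(labels[m$set]), collapse = ","), sep = "\r")

apply_insertion <- function(A, m) {
  A[m$x, m$y] <- TRUE; A[m$y, m$x] <- FALSE
  for (t in m$set) A[m$y, t] <- FALSE      # orient t -> y
  complete_pattern(A)
}

apply_deletion <- function(A, m) {
  A[m$x, m$y] <- FALSE; A[m$y, m$x] <- FALSE
  for (h in m$set) {
    A[h, m$y] <- FALSE                     # orient y -> h
    if (A[m$x, h] && A[h, m$x]) A[h, m$x] <- FALSE  # orient x -> h
  }
  complete_pattern(A)
}

# best edge-turning move: reverse a directed edge y -> x to x -> y as the
# composite of the best valid Delete(y, x, H) followed, in the resulting
# pattern, by the best valid Insert(x, y, T); the summed deltas equal the
# class-score change exactly. Escapes the single-edge local optima greedy
# insertion can lock into (the turning phase of the reference
# implementations serves the same purpose).
best_turn <- function(A, sc) {
  p <- nrow(A)
  labels <- sc$labels
  best <- NULL
  adj <- which(A | t(A), arr.ind = TRUE)
  adj <- adj[adj[, 1] != adj[, 2], , drop = FALSE]
  for (k in seq_len(nrow(adj))) {
    # candidate: end with the edge (re)inserted as x -> y; covers reversing
    # a directed y -> x and re-classing an undirected pair either way
    y <- adj[k, 1]; x <- adj[k, 2]
    if (A[x, y] && !A[y, x]) next    # already x -> y compelled
    d1 <- best_pair_deletion(A, sc, if (A[y, x]) y else x,
                             if (A[y, x]) x else y)
    if (is.null(d1)) next
    A2 <- apply_deletion(A, d1)
    d2 <- best_pair_insertion(A2, sc, x, y)
    if (is.null(d2)) next
    delta <- d1$delta + d2$delta
    cand <- list(x = x, y = y, del = d1, ins = d2, delta = delta,
                 set = integer(0))
    if (is.null(best) || delta < best$delta - .ges_tol ||
        (abs(delta - best$delta) <= .ges_tol &&
         move_key(cand, labels) < move_key(best, labels)))
      best <- cand
  }
  best
}

# best valid Delete(x, y, H) for one fixed adjacent pair
best_pair_deletion <- function(A, sc, x, y) {
  if (!A[x, y]) return(NULL)
  ne_y <- ges_neighbors_und(A, y)
  pa_y <- ges_parents(A, y)
  adj_x <- A[x, ] | A[, x]
  na_yx <- setdiff(ne_y[adj_x[ne_y]], x)
  best <- NULL
  for (H in power_set(na_yx)) {
    R <- setdiff(na_yx, H)
    if (!is_clique(A, R)) next
    base <- unique(c(pa_y, R))
    d <- local_score_pen(sc, y, setdiff(base, x)) -
      local_score_pen(sc, y, unique(c(base, x)))
    if (is.null(best) || d < best$delta)
      best <- list(x = x, y = y, set = H, delta = d)
  }
  best
}

# best valid Insert(x, y, T) for one fixed non-adjacent pair
best_pair_insertion <- function(A, sc, x, y) {
  if (adjacent(A, x, y)) return(NULL)
  ne_y <- ges_neighbors_und(A, y)
  pa_y <- ges_parents(A, y)
  adj_x <- A[x, ] | A[, x]
  na_yx <- ne_y[adj_x[ne_y]]
  t_pool <- ne_y[!adj_x[ne_y]]
  best <- NULL
  for (T in power_set(t_pool)) {
    U <- c(na_yx, T)
    if (!is_clique(A, U)) next
    if (semidirected_reachable(A, y, x, blocked = U)) next
    old <- unique(c(pa_y, U))
    d <- local_score_pen(sc, y, c(old, x)) - local_score_pen(sc, y, old)
    if (is.null(best) || d < best$delta)
      best <- list(x = x, y = y, set = T, delta = d)
  }
  best
}

ges_core <- function(sc, trace = TRUE) {
  p <- sc$p
  A <- matrix(FALSE, p, p, dimnames = list(sc$labels, sc$labels))
  steps <- list()
  record <- function(phase, op, m)
    steps[[length(steps) + 1L]] <<- data.frame(
      phase = phase, operator = op,
      from = sc$labels[m$x], to = sc$labels[m$y],
      set = paste(sort(sc$labels[m$set]), collapse = ","),
      delta = m$delta, stringsAsFactors = FALSE)
  repeat {
    moved <- FALSE
    repeat {
      m <- best_insertion(A, sc)
      if (is.null(m) || m$delta >= -.ges_tol) break
      A <- apply_insertion(A, m)
      moved <- TRUE
      if (trace) record("forward", "insert", m)
    }
    repeat {
      m <- best_deletion(A, sc)
      if (is.null(m) || m$delta >= -.ges_tol) break
      A <- apply_deletion(A, m)
      moved <- TRUE
      if (trace) record("backward", "delete", m)
    }
    repeat {
      m <- best_turn(A, sc)
      if (is.null(m) || m$delta >= -.ges_tol) break
      A <- apply_insertion(apply_deletion(A, m$del), m$ins)
      moved <- TRUE
      if (trace) record("turning", "turn", m)
    }
    # phases are re-run in alternation until none improves: a turn can
    # expose a better deletion, a deletion a better insertion, and so on
    if (!moved) break
  }
  tr <- if (length(steps)) do.call(rbind, steps) else
    data.frame(phase = character(), operator = character(),
               from = character(), to = character(), set = character(),
               delta = numeric(), stringsAsFactors = FALSE)
  list(adj = A, trace = tr)
}

#' Greedy equivalence search on one dataset
#'
#' Starts from the empty graph and greedily inserts the single edge (over
#' Markov equivalence classes) that most lowers the BIC until no insertion
#' improves it, then greedily deletes; the result is the completed pattern
#' (CPDAG) of the best equivalence class found. Deterministic for fixed
#' input; ties are broken lexicographically.
#'
#' @param data Numeric matrix (rows = observations, columns = variables) or
#'   a single-subject [roi_timeseries_set()]. Columns are standardized.
#' @return List with elements `pattern` (a [pattern_graph()]) and `trace`
#'   (data frame of accepted moves with their score deltas).
#' @export
#' @examples
#' set.seed(7)
#' n <- 2000
#' x <- rnorm(n); y <- 0.7 * x + rnorm(n); z <- 0.7 * y + rnorm(n)
#' ges_search(cbind(x = x, y = y, z = z))$pattern
ges_search <- function(data) {
  set <- if (inherits(data, "roi_timeseries_set")) data else
    roi_timeseries_set(data)
  n_min <- min(vapply(set$subjects, nrow, integer(1)))
  if (n_min <= length(set$labels))
    stop("need more observations than variables")
  sc <- make_scorer(set)
  res <- ges_core(sc)
  list(pattern = adj_to_pattern(res$adj), trace = res$trace)
}

#' Multi-subject greedy equivalence search
#'
#' Identical to [ges_search()] except that every candidate equivalence class
#' is scored by the arithmetic mean of the per-subject BICs, each subject
#' scored at its own sample size; the search returns a single group-level
#' pattern. With one subject (or identical copies of one subject) the result
#' equals [ges_search()] on that subject.
#'
#' @param set A [roi_timeseries_set()] (or a list of matrices, coerced).
#' @return List with `pattern` and `trace`, as [ges_search()].
#' @export
images_search <- function(set) {
  if (!inherits(set, "roi_timeseries_set")) set <- roi_timeseries_set(set)
  sc <- make_scorer(set)
  res <- ges_core(sc)
  list(pattern = adj_to_pattern(res$adj), trace = res$trace)
}
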