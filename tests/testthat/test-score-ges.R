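test_that("local score behaves like a penalised-likelihood building block", {
  set.seed(11)
  n <- 500
  x <- rnorm(n); y <- 0.8 * x + rnorm(n)
  d <- cbind(x = x, y = y)
  # standardized column with no parents: ML variance is (n-1)/n
  expect_equal(local_gaussian_score(d, "x"), n * log((n - 1) / n),
               tolerance = 1e-9)
  # a real parent reduces the contribution
  expect_lt(local_gaussian_score(d, "y", "x"),
            local_gaussian_score(d, "y"))
  expect_error(local_gaussian_score(d, "y", "y"), "exclude")
  # an independent noise parent is not worth its ln(n) penalty on average
  set.seed(12)
  gain <- replicate(200, {
    z <- rnorm(200); w <- rnorm(200)
    dd <- cbind(z = z, w = w)
    local_gaussian_score(dd, "z") - local_gaussian_score(dd, "z", "w")
  })
  expect_lt(mean(gain), log(200))
})

test_that("BIC counts directed edges plus variables and is score equivalent", {
  set.seed(13)
  n <- 800
  x <- rnorm(n); y <- 0.7 * x + rnorm(n)
  d <- cbind(x = x, y = y)
  labels <- c("x", "y")
  empty <- matrix(FALSE, 2, 2, dimnames = list(labels, labels))
  s0 <- bic_of_dag(d, empty)
  expect_equal(s0$k, 2)          # empty graph: k = number of variables
  fwd <- empty; fwd["x", "y"] <- TRUE
  s1 <- bic_of_dag(d, fwd)
  expect_equal(s1$k, 3)
  # Markov-equivalent DAGs x->y and y->x score identically
  expect_equal(s1$bic, bic_of_dag(d, t(fwd))$bic, tolerance = 1e-9)
  cyc <- fwd; cyc["y", "x"] <- TRUE
  expect_error(bic_of_dag(d, cyc), "cyclic")
})

test_that("score equivalence holds exhaustively within equivalence classes", {
  dags <- enumerate_all_dags(4)
  set.seed(14)
  B <- random_dag(4, 0.5)
  sim <- generate_sem_timeseries(sem_spec(B, n_subjects = 1, n_time = 300),
                                 seed = 14)
  X <- sim$set$subjects[[1]]
  bics <- vapply(dags, function(D) {
    dimnames(D) <- dimnames(B); bic_of_dag(X, D)$bic
  }, numeric(1))
  class_key <- vapply(dags, function(D)
    paste(tastecircuit:::dag_to_cpdag(D), collapse = ""), character(1))
  spread <- tapply(bics, class_key, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-9)
})

test_that("BIC ranks the generating chain's class best on strong data", {
  set.seed(15)
  B <- chain_dag(c("x", "y", "z"), beta = 0.7)
  sim <- generate_sem_timeseries(sem_spec(B, n_subjects = 1,
                                          n_time = 2000), seed = 15)
  X <- sim$set$subjects[[1]]
  dags <- enumerate_all_dags(3)
  cp <- brute_force_best_cpdag(X, dags)
  # best class is the chain's class: skeleton x-y, y-z, no collider
  expect_true(cp["x", "y"] && cp["y", "x"])
  expect_true(cp["y", "z"] && cp["z", "y"])
  expect_false(cp["x", "z"] || cp["z", "x"])
})

test_that("ges recovers chain, collider and empty structures", {
  set.seed(7)
  n <- 2000
  x <- rnorm(n); y <- 0.7 * x + rnorm(n); z <- 0.7 * y + rnorm(n)
  g <- ges_search(cbind(x = x, y = y, z = z))$pattern
  expect_equal(nrow(g$undirected), 2)
  expect_equal(nrow(g$directed), 0)
  expect_setequal(tastecircuit:::skeleton_keys(g), c("x|y", "y|z"))

  set.seed(8)
  a <- rnorm(n); b <- rnorm(n); cc <- 0.7 * a + 0.7 * b + rnorm(n)
  g2 <- ges_search(cbind(a = a, b = b, c = cc))$pattern
  expect_setequal(paste(g2$directed[, 1], g2$directed[, 2], sep = ">"),
                  c("a>c", "b>c"))
  expect_equal(nrow(g2$undirected), 0)

  set.seed(9)
  g3 <- ges_search(matrix(rnorm(3 * n), ncol = 3,
                          dimnames = list(NULL, c("u", "v", "w"))))$pattern
  expect_equal(nrow(g3$directed) + nrow(g3$undirected), 0)
})

test_that("ges is deterministic and its trace respects phase semantics", {
  set.seed(16)
  B <- random_dag(5, 0.4)
  sim <- generate_sem_timeseries(sem_spec(B, n_subjects = 1, n_time = 400),
                                 seed = 16)
  X <- sim$set$subjects[[1]]
  r1 <- ges_search(X); r2 <- ges_search(X)
  expect_identical(r1$pattern, r2$pattern)
  expect_identical(r1$trace, r2$trace)
  # every accepted move strictly lowers the class score
  expect_true(all(r1$trace$delta < 0))
  expect_true(all(r1$trace$operator[r1$trace$phase == "forward"] == "insert"))
  expect_true(all(r1$trace$operator[r1$trace$phase == "backward"] == "delete"))
})

test_that("accepted move deltas reproduce the true class-score change", {
  set.seed(17)
  worst <- 0
  for (r in 1:10) {
    B <- random_dag(6, 0.4)
    sim <- generate_sem_timeseries(sem_spec(B, noise = "uniform",
                                            n_subjects = 1, n_time = 400),
                                   seed = r)
    X <- sim$set$subjects[[1]]
    res <- ges_search(X)
    A <- tastecircuit:::pattern_to_adj(res$pattern)
    D <- tastecircuit:::pdag_to_dag(A)
    final <- bic_of_dag(X, D & !t(D))$bic
    empty <- bic_of_dag(X, matrix(FALSE, 6, 6, dimnames = dimnames(B)))$bic
    worst <- max(worst, abs(final - (empty + sum(res$trace$delta))))
  }
  expect_lt(worst, 1e-8)
})

test_that("multi-subject search averages scores and degenerates correctly", {
  set.seed(18)
  B <- chain_dag(c("p", "q", "r"), 0.6)
  sim <- generate_sem_timeseries(sem_spec(B, n_subjects = 1, n_time = 500),
                                 seed = 18)
  X <- sim$set$subjects[[1]]
  single <- ges_search(X)$pattern
  # one subject: identical to ges_search
  expect_identical(images_search(roi_timeseries_set(list(X)))$pattern,
                   single)
  # K identical copies: score averaging leaves the result unchanged
  expect_identical(
    images_search(roi_timeseries_set(list(X, X, X)))$pattern, single)
  # label mismatch across subjects is an input error
  X2 <- X; colnames(X2) <- c("p", "q", "s")
  expect_error(roi_timeseries_set(list(X, X2)), "labels differ")
})

test_that("skeleton recovery does not degrade as T grows", {
  set.seed(19)
  B <- random_dag(6, 0.4)
  recall_at <- function(T) {
    hits <- vapply(1:8, function(r) {
      sim <- generate_sem_timeseries(
        sem_spec(B, noise = "uniform", n_subjects = 1, n_time = T),
        seed = 100 * T + r)
      sk <- tastecircuit:::skeleton_keys(ges_search(sim$set$subjects[[1]])$pattern)
      mean(truth_skeleton(B) %in% sk)
    }, numeric(1))
    mean(hits)
  }
  r100 <- recall_at(100); r400 <- recall_at(400); r1600 <- recall_at(1600)
  expect_gte(r400 + 0.05, r100)   # small slack for Monte-Carlo noise
  expect_gte(r1600 + 0.05, r400)
  expect_gte(r1600, r100)
})

test_that("non-finite data and undersized samples are rejected", {
  X <- matrix(rnorm(40), ncol = 2, dimnames = list(NULL, c("a", "b")))
  X[3, 1] <- NA
  expect_error(roi_timeseries_set(X), "non-finite")
  small <- matrix(rnorm(8), ncol = 4)
  expect_error(roi_timeseries_set(small), "too few")
})
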