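test_that("SEM generator is a pure function of spec and seed", {
  spec <- sem_spec(chain_dag(c("a", "b", "c"), 0.6), noise = "laplace",
                   n_subjects = 3, n_time = 120)
  s1 <- generate_sem_timeseries(spec, seed = 5)
  s2 <- generate_sem_timeseries(spec, seed = 5)
  expect_identical(s1$set$subjects, s2$set$subjects)
  s3 <- generate_sem_timeseries(spec, seed = 6)
  expect_false(identical(s1$set$subjects, s3$set$subjects))
  expect_error(sem_spec(matrix(c(0, 1, 1, 0), 2, 2)), "cyclic")
  expect_error(sem_spec(diag(2)), "zero diagonal")
  expect_error(sem_spec(chain_dag(c("a", "b")), n_time = 5), "at least 10")
})

test_that("empirical covariance matches the closed-form SEM covariance", {
  B <- matrix(0, 4, 4, dimnames = rep(list(paste0("v", 1:4)), 2))
  B["v1", "v2"] <- 0.7; B["v2", "v3"] <- -0.5; B["v1", "v4"] <- 0.4
  B["v3", "v4"] <- 0.6
  spec <- sem_spec(B, noise = "uniform", noise_scale = c(1, 0.8, 1.2, 1),
                   n_subjects = 1, n_time = 50000)
  X <- generate_sem_timeseries(spec, seed = 51)$set$subjects[[1]]
  IB <- solve(diag(4) - t(B))
  D <- diag(c(1, 0.8, 1.2, 1)^2)
  Sigma <- IB %*% D %*% t(IB)
  emp <- cov(X)
  # 2% elementwise, on a scale floored at 1 so near-zero covariances are
  # judged against the sampling noise of the estimator rather than 0
  expect_lt(max(abs(emp - Sigma) / pmax(abs(Sigma), 1)), 0.02)
})

test_that("noise families show the expected tail behaviour", {
  kurt <- function(v) mean((v - mean(v))^4) / var(v)^2 - 3
  spec_of <- function(fam) sem_spec(matrix(0, 1, 1,
                                           dimnames = list("a", "a")),
                                    noise = fam, n_subjects = 1,
                                    n_time = 40000)
  g <- generate_sem_timeseries(spec_of("gaussian"), seed = 1)$set$subjects[[1]]
  u <- generate_sem_timeseries(spec_of("uniform"), seed = 1)$set$subjects[[1]]
  l <- generate_sem_timeseries(spec_of("laplace"), seed = 1)$set$subjects[[1]]
  expect_lt(abs(kurt(g[, 1])), 0.15)
  expect_lt(kurt(u[, 1]), -1)      # uniform: excess kurtosis -1.2
  expect_gt(kurt(l[, 1]), 2)       # Laplace: excess kurtosis +3
  # unit variance in every family
  for (v in list(g, u, l)) expect_equal(var(v[, 1]), 1, tolerance = 0.05)
})

test_that("task schedule satisfies every contingency exactly, for any seed", {
  for (seed in c(1, 7, 99)) {
    s <- generate_task_schedule(seed)
    expect_equal(nrow(s), 280)
    expect_equal(sum(s$cs_type == "sucrose"), 100)
    expect_equal(sum(s$cs_type == "null"), 100)
    expect_equal(sum(s$cs_type == "saliva"), 80)
    # first 10 trials: fixed reinforced sucrose pairings
    expect_true(all(s$cs_type[1:10] == "sucrose"))
    expect_true(all(s$us_delivered[1:10] == "sucrose"))
    # exact 80/20 contingencies, counting the fixed block
    expect_equal(sum(s$cs_type == "sucrose" & s$us_delivered == "sucrose"),
                 80)
    expect_equal(sum(s$cs_type == "sucrose" & s$us_delivered == "none"), 20)
    expect_equal(sum(s$cs_type == "null" & s$us_delivered == "none"), 80)
    expect_equal(sum(s$cs_type == "null" & s$us_delivered == "sucrose"), 20)
    expect_true(all(s$us_delivered[s$cs_type == "saliva"] == "saliva"))
  }
  expect_identical(generate_task_schedule(3), generate_task_schedule(3))
  expect_false(identical(generate_task_schedule(3)$cs_type[11:280],
                         generate_task_schedule(4)$cs_type[11:280]))
})

test_that("streamline generator is seeded and respects group effects", {
  tax <- default_taxonomy()
  d1 <- generate_streamline_dataset(tax, n_subjects = c(g = 2), seed = 8)
  d2 <- generate_streamline_dataset(tax, n_subjects = c(g = 2), seed = 8)
  expect_identical(d1, d2)
  # a +50% effect on one tract raises that tract's strength distinctly
  eff_id <- "left:thalamus->posterior_insula"
  de <- generate_streamline_dataset(
    tax, n_subjects = c(CW = 12, AN = 12),
    group_effects = list(AN = setNames(1.5, eff_id)), seed = 9)
  tab <- pathway_table_for_dataset(de, tax)
  on_tract <- tab$hemisphere == "left" & tab$seed == "thalamus" &
    tab$target == "posterior_insula"
  m_an <- mean(tab$connection_strength[on_tract & tab$group == "AN"])
  m_cw <- mean(tab$connection_strength[on_tract & tab$group == "CW"])
  expect_gt(m_an / m_cw, 1.15)
})

test_that("null streamline data yield calibrated group tests", {
  vols <- c(thalamus = 1000, posterior_insula = 400)
  regions <- data.frame(label = rep(names(vols), 2),
                        hemisphere = rep(c("left", "right"), each = 2),
                        volume = rep(unname(vols), 2))
  tax <- circuit_taxonomy(regions)
  set.seed(52)
  pvals <- vapply(1:200, function(r) {
    d <- generate_streamline_dataset(tax, n_subjects = c(a = 10, b = 10),
                                     seed = 1000 + r)
    tab <- pathway_table_for_dataset(d, tax)
    on <- tab$hemisphere == "left"
    t.test(tab$connection_strength[on & tab$group == "a"],
           tab$connection_strength[on & tab$group == "b"])$p.value
  }, numeric(1))
  expect_gt(mean(pvals < 0.05), 0.005)
  expect_lt(mean(pvals < 0.05), 0.12)
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.001)
})

test_that("behavioral generator reproduces target moments exactly", {
  targets <- behavioral_summary_targets()
  age <- targets[targets$variable == "age_years", ]
  tab <- generate_behavioral_table(age, seed = 10)
  for (g in c("CW", "AN", "BN")) {
    v <- tab$value[tab$group == g]
    expect_equal(length(v), age$n[age$group == g])
    expect_equal(mean(v), age$mean[age$group == g], tolerance = 1e-12)
    expect_equal(sd(v), age$sd[age$group == g], tolerance = 1e-12)
  }
  # round trip: summary ANOVA on the generated data reproduces the target F
  sm <- do.call(rbind, lapply(split(tab$value, tab$group), function(v)
    data.frame(mean = mean(v), sd = sd(v), n = length(v))))
  expect_equal(unname(anova_from_summary(sm)$statistic),
               unname(anova_from_summary(age[c("mean", "sd", "n")])$statistic),
               tolerance = 1e-9)
  expect_identical(generate_behavioral_table(age, seed = 10), tab)
  bad <- age; bad$n[1] <- 1
  expect_error(generate_behavioral_table(bad, seed = 1), "n >= 2")
})

test_that("the full synthetic pipeline recovers ground truth", {
  # default-scale recoverability: skeleton and most orientations at
  # moderate size (scaled-down spot check of the acceptance property)
  set.seed(53)
  hits <- orient_ok <- 0; total_true <- 0
  for (r in 1:5) {
    B <- random_dag(8, 0.3)
    sim <- generate_sem_timeseries(
      sem_spec(B, noise = "uniform", n_subjects = 20, n_time = 200),
      seed = 600 + r)
    fit <- effective_connectivity(sim$set)
    sk <- tastecircuit:::skeleton_keys(fit$pattern)
    hits <- hits + sum(truth_skeleton(B) %in% sk)
    total_true <- total_true + length(truth_skeleton(B))
    orient_ok <- orient_ok + sum(directed_keys(fit$pattern) %in%
                                   truth_edge_keys(B))
  }
  expect_gt(hits / total_true, 0.8)
  expect_gt(orient_ok / total_true, 0.7)
})
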