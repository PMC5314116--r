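fwd_example <- function() {
  streamline_data("thalamus", "left", n_seed_voxels = 2,
                  counts = c(posterior_insula = 500,
                             frontal_operculum = 3500),
                  mean_path_length = c(posterior_insula = 20,
                                       frontal_operculum = 30))
}

test_that("connection probability is count over total samples", {
  d <- fwd_example()
  expect_equal(connection_probability(d, "posterior_insula"), 0.05)
  # path-length weighting multiplies the count by mean length
  expect_equal(connection_probability(d, "posterior_insula",
                                      distance_correct = TRUE), 1.0)
  d0 <- streamline_data("thalamus", "left", 2,
                        counts = c(posterior_insula = 0))
  expect_equal(connection_probability(d0, "posterior_insula"), 0)
  expect_equal(connection_probability(d0, "posterior_insula", TRUE), 0)
  expect_error(connection_probability(d, "hypothalamus"), "not present")
})

test_that("normalization reproduces the hand-computed rescaling", {
  # p_st = 0.05, P_seed = 0.05 + 0.35 = 0.4; reverse gives p_ts = 0.01
  fwd <- fwd_example()
  rev <- streamline_data("posterior_insula", "left", 1,
                         counts = c(thalamus = 50),
                         mean_path_length = c(thalamus = 20))
  got <- normalize_connection_strength(fwd, rev, "posterior_insula",
                                       target_volume = 60)
  expect_equal(got, (0.05 / 0.4) * 0.03 / 60, tolerance = 1e-12)
  expect_equal(got, 6.25e-5, tolerance = 1e-12)
})

test_that("normalization is scale invariant, volume inverse-linear and count monotone", {
  fwd <- fwd_example()
  rev <- streamline_data("posterior_insula", "left", 1,
                         counts = c(thalamus = 50),
                         mean_path_length = c(thalamus = 20))
  base <- normalize_connection_strength(fwd, rev, "posterior_insula", 60)
  # doubling every count and the total samples together changes nothing
  fwd2 <- streamline_data("thalamus", "left", 4,
                          counts = 2 * fwd$counts,
                          mean_path_length = fwd$mean_path_length)
  rev2 <- streamline_data("posterior_insula", "left", 2,
                          counts = 2 * rev$counts,
                          mean_path_length = rev$mean_path_length)
  expect_equal(normalize_connection_strength(fwd2, rev2,
                                             "posterior_insula", 60),
               base, tolerance = 1e-12)
  # doubling target volume exactly halves the strength
  expect_equal(normalize_connection_strength(fwd, rev,
                                             "posterior_insula", 120),
               base / 2, tolerance = 1e-12)
  # monotone in the forward count, all else fixed
  set.seed(1)
  prev <- -Inf
  for (ct in c(0, 10, 100, 400, 900)) {
    f <- streamline_data("thalamus", "left", 2,
                         counts = c(posterior_insula = ct,
                                    frontal_operculum = 3500),
                         mean_path_length = c(posterior_insula = 20,
                                              frontal_operculum = 30))
    s <- normalize_connection_strength(f, rev, "posterior_insula", 60)
    expect_gte(s, prev)
    prev <- s
  }
  # zero forward count gives exactly zero
  f0 <- streamline_data("thalamus", "left", 2,
                        counts = c(posterior_insula = 0,
                                   frontal_operculum = 3500),
                        mean_path_length = c(frontal_operculum = 30))
  expect_equal(normalize_connection_strength(f0, rev, "posterior_insula",
                                             60), 0)
})

test_that("normalization agrees with a straight-line oracle on random inputs", {
  set.seed(42)
  for (r in 1:50) {
    nv <- sample(1:5, 1)
    targets <- paste0("t", 1:3)
    counts <- setNames(sample(0:2000, 3), targets)
    mpl <- setNames(runif(3, 5, 60), targets)
    fwd <- streamline_data("thalamus", "left", nv, counts = counts,
                           mean_path_length = mpl)
    rev <- streamline_data("posterior_insula", "left", 2,
                           counts = c(thalamus = sample(0:500, 1)),
                           mean_path_length = c(thalamus = runif(1, 5, 60)))
    vol <- sample(20:200, 1)
    dc <- sample(c(TRUE, FALSE), 1)
    # oracle: same formula written in a different evaluation order
    tot_f <- nv * 5000
    w <- if (dc) mpl else setNames(rep(1, 3), targets)
    p_st <- counts[["t1"]] * w[["t1"]] / tot_f
    P_seed <- sum(counts * w) / tot_f
    p_ts <- rev$counts[["thalamus"]] *
      (if (dc) rev$mean_path_length[["thalamus"]] else 1) / (2 * 5000)
    oracle <- if (P_seed == 0) 0 else
      p_st * ((p_st + p_ts) / 2) / (P_seed * vol)
    got <- suppressWarnings(
      normalize_connection_strength(fwd, rev, "t1", vol,
                                    distance_correct = dc))
    expect_equal(got, unname(oracle), tolerance = 1e-12)
  }
})

test_that("missing reverse run falls back to the forward probability", {
  fwd <- fwd_example()
  expect_warning(
    s <- normalize_connection_strength(fwd, NULL, "posterior_insula", 60),
    "reverse")
  expect_equal(s, (0.05 / 0.4) * 0.05 / 60, tolerance = 1e-12)
})

test_that("a seed reaching nothing yields zero with a warning", {
  fwd <- streamline_data("thalamus", "left", 2,
                         counts = c(posterior_insula = 0,
                                    frontal_operculum = 0))
  rev <- streamline_data("posterior_insula", "left", 1,
                         counts = c(thalamus = 0))
  expect_warning(s <- normalize_connection_strength(fwd, rev,
                                                    "posterior_insula", 60),
                 "no target")
  expect_equal(s, 0)
})

test_that("pathway mean FA is the visitation-weighted mean", {
  expect_equal(mean_fa_along_tract(c(0.5, 0.5), c(3, 7)), 0.5)
  expect_equal(mean_fa_along_tract(c(0.2, 0.8), c(1, 3)), 0.65)
  expect_error(mean_fa_along_tract(c(0.9), c(0)), "all visitation")
  expect_error(mean_fa_along_tract(c(1.2), c(3)), "\\[0, 1\\]")
})

test_that("pathway table covers every tract and flags missing data", {
  tax <- default_taxonomy()
  ds <- generate_streamline_dataset(tax, n_subjects = c(g = 1), seed = 3)
  tab <- build_pathway_table(ds$subjects[[1]]$runs, tax, subject_id = "s1")
  expect_equal(nrow(tab), 98)
  expect_true(all(tab$status == "ok"))
  expect_true(all(tab$connection_strength >= 0))
  # determinism: identical inputs give identical tables
  tab2 <- build_pathway_table(ds$subjects[[1]]$runs, tax, subject_id = "s1")
  expect_identical(tab, tab2)
  # dropping one seed's runs flags those tracts but keeps 98 rows
  runs <- ds$subjects[[1]]$runs
  keep <- vapply(runs, function(r)
    !(r$seed == "thalamus" && r$hemisphere == "left"), logical(1))
  tab3 <- suppressWarnings(build_pathway_table(runs[keep], tax))
  expect_equal(nrow(tab3), 98)
  miss <- tab3$status == "missing_forward"
  expect_equal(sum(miss), 4)   # the four left thalamic tracts
  expect_true(all(is.na(tab3$connection_strength[miss])))
})
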