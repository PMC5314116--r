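# Synthetic-data generators with known ground truth: linear non-Gaussian
# structural-equation time series over the circuit regions, the
# probabilistic conditioned-taste task schedule, streamline-count datasets
# with injected group effects, and behavioral tables matched to target
# moments. All generators are pure functions of (spec, seed).

#' Specification of a linear structural-equation simulation
#'
#' @param dag Coefficient matrix `B` (zero diagonal, acyclic): `B[i, j]`
#'   is the weight of edge `i -> j`. Row/col names become region labels.
#' @param noise Noise family: `"gaussian"`, `"uniform"`, `"laplace"` or
#'   `"exponential"` (centered). All are scaled to unit variance before
#'   `noise_scale` is applied.
#' @param noise_scale Positive scalar or per-node vector of noise SDs.
#' @param n_subjects Subjects to generate.
#' @param n_time Time points (volumes) per subject; at least 10.
#' @param labels Optional region labels (default: dimnames of `dag`).
#' @param group_effects Optional named list: per-group additive deltas to
#'   edge coefficients, each a matrix like `dag` (used by callers that
#'   simulate several groups from variants of one DAG).
#' @return Object of class `"sem_spec"`.
#' @export
sem_spec <- function(dag, noise = c("gaussian", "uniform", "laplace",
                                    "exponential"),
                     noise_scale = 1, n_subjects = 1, n_time = 200,
                     labels = NULL, group_effects = NULL) {
  noise <- match.arg(noise)
  B <- as.matrix(dag)
  if (nrow(B) != ncol(B)) stop("dag must be square")
  if (any(diag(B) != 0)) stop("dag must have a zero diagonal")
  if (is.null(labels))
    labels <- if (!is.null(rownames(B))) rownames(B) else
      paste0("R", seq_len(nrow(B)))
  dimnames(B) <- list(labels, labels)
  if (is.null(topological_order(B != 0)))
    stop("dag is cyclic")
  if (n_time < 10) stop("n_time must be at least 10")
  if (any(noise_scale <= 0)) stop("noise_scale must be positive")
  noise_scale <- rep_len(noise_scale, nrow(B))
  structure(list(dag = B, noise = noise, noise_scale = noise_scale,
                 n_subjects = n_subjects, n_time = n_time,
                 labels = labels, group_effects = group_effects),
            class = "sem_spec")
}

# topological order of a logical adjacency, or NULL if cyclic
topological_order <- function(D) {
  p <- nrow(D)
  active <- rep(TRUE, p)
  ord <- integer(0)
  while (any(active)) {
    indeg <- colSums(D[active, , drop = FALSE])
    src <- which(active & indeg == 0)
    if (!length(src)) return(NULL)
    ord <- c(ord, src)
    active[src] <- FALSE
    D[src, ] <- FALSE
  }
  ord
}

#' Chain DAG helper
#' @param labels Vertex labels, in causal order.
#' @param beta Edge coefficient (recycled along the chain).
#' @return Coefficient matrix usable as `dag` in [sem_spec()].
#' @export
chain_dag <- function(labels, beta = 0.7) {
  p <- length(labels)
  B <- matrix(0, p, p, dimnames = list(labels, labels))
  if (p > 1)
    B[cbind(seq_len(p - 1), seq(2, p))] <- rep_len(beta, p - 1)
  B
}

#' Random DAG with edge coefficients
#'
#' Draws a random topological order, includes each forward pair with
#' probability `edge_prob`, and assigns each edge a coefficient of random
#' sign with magnitude uniform in `beta_range`. Uses the current RNG state
#' (seed with [set.seed()]).
#'
#' @param labels Vertex labels (or an integer count).
#' @param edge_prob Inclusion probability per ordered pair (default 0.3).
#' @param beta_range Magnitude range of edge coefficients.
#' @return Coefficient matrix.
#' @export
random_dag <- function(labels, edge_prob = 0.3, beta_range = c(0.3, 0.8)) {
  if (length(labels) == 1 && is.numeric(labels))
    labels <- paste0("R", seq_len(labels))
  p <- length(labels)
  ord <- sample(p)
  B <- matrix(0, p, p, dimnames = list(labels, labels))
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
    if (runif(1) < edge_prob) {
      b <- runif(1, beta_range[1], beta_range[2]) * sample(c(-1, 1), 1)
      B[ord[i], ord[j]] <- b
    }
  }
  B
}

# unit-variance noise draws
draw_noise <- function(n, family) {
  switch(family,
         gaussian = rnorm(n),
         uniform = runif(n, -sqrt(3), sqrt(3)),
         laplace = (rexp(n) - rexp(n)) / sqrt(2),
         exponential = rexp(n) - 1,
         stop("unknown noise family: ", family))
}

#' Generate multi-subject SEM time series
#'
#' Each time point is an i.i.d. draw from the linear structural-equation
#' model `x = B' x + e` (solved by topological substitution), with the
#' spec's noise family and per-node scales. An optional double-gamma HRF
#' convolution can be applied per column; it is off by default because the
#' causal search operates on extracted ROI series.
#'
#' @param spec A [sem_spec()].
#' @param seed Integer seed; the generator is a pure function of
#'   `(spec, seed)`.
#' @param standardize Standardize the returned container's columns (default
#'   `FALSE`: raw series are returned; search and orientation standardize
#'   internally regardless).
#' @param hrf Convolve each column with a double-gamma hemodynamic response
#'   (TR = 2 s) before returning.
#' @return List with `set` (a [roi_timeseries_set()]), `dag` (the generating
#'   coefficient matrix) and `spec`.
#' @export
#' @examples
#' sim <- generate_sem_timeseries(
#'   sem_spec(chain_dag(c("a", "b", "c")), noise = "uniform",
#'            n_subjects = 2, n_time = 100), seed = 1)
#' sim$set
generate_sem_timeseries <- function(spec, seed = 1L, standardize = FALSE,
                                    hrf = FALSE) {
  stopifnot(inherits(spec, "sem_spec"))
  B <- spec$dag
  p <- nrow(B)
  ord <- topological_order(B != 0)
  set.seed(seed)
  subjects <- lapply(seq_len(spec$n_subjects), function(s) {
    E <- vapply(seq_len(p),
                function(j) spec$noise_scale[j] *
                  draw_noise(spec$n_time, spec$noise),
                numeric(spec$n_time))
    X <- matrix(0, spec$n_time, p, dimnames = list(NULL, spec$labels))
    for (j in ord) {
      pa <- which(B[, j] != 0)
      X[, j] <- E[, j] +
        if (length(pa)) X[, pa, drop = FALSE] %*% B[pa, j] else 0
    }
    if (hrf) X <- apply(X, 2, convolve_hrf)
    X
  })
  list(set = roi_timeseries_set(subjects, labels = spec$labels,
                                standardize = standardize),
       dag = B, spec = spec)
}

# canonical double-gamma HRF sampled at TR = 2 s
hrf_double_gamma <- function(t, peak = 6, under = 16, ratio = 1 / 6) {
  stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = under, rate = 1)
}

convolve_hrf <- function(x, tr = 2) {
  k <- hrf_double_gamma(seq(0, 30, by = tr))
  k <- k / sum(k)
  y <- stats::filter(c(rep(x[1], length(k) - 1), x), rev(k), sides = 1)
  as.numeric(y[-seq_len(length(k) - 1)])
}

#' Generate the probabilistic conditioned-taste task schedule
#'
#' Builds the 280-trial schedule of the sucrose conditioning task: 100
#' sucrose-CS trials (80 reinforced with sucrose, 20 unreinforced), 100
#' null-CS trials (80 with no solution, 20 with unexpected sucrose), and 80
#' saliva-CS trials always followed by artificial saliva. The first 10
#' trials are fixed reinforced sucrose-CS trials (counted inside the 100/80)
#' to establish the association; all remaining trials are a seeded uniform
#' shuffle. Contingencies are exact counts, not i.i.d. draws, so every
#' schedule satisfies the stated 80/20 proportions exactly.
#'
#' @param seed Integer seed.
#' @return Data frame with columns `trial`, `cs_type`
#'   (`"sucrose"`/`"null"`/`"saliva"`) and `us_delivered`
#'   (`"sucrose"`/`"none"`/`"saliva"`).
#' @export
#' @examples
#' sched <- generate_task_schedule(seed = 1)
#' table(sched$cs_type)
generate_task_schedule <- function(seed = 1L) {
  fixed <- data.frame(cs_type = "sucrose", us_delivered = "sucrose",
                      stringsAsFactors = FALSE)[rep(1, 10), ]
  rest <- rbind(
    data.frame(cs_type = "sucrose", us_delivered = "sucrose")[rep(1, 70), ],
    data.frame(cs_type = "sucrose", us_delivered = "none")[rep(1, 20), ],
    data.frame(cs_type = "null", us_delivered = "none")[rep(1, 80), ],
    data.frame(cs_type = "null", us_delivered = "sucrose")[rep(1, 20), ],
    data.frame(cs_type = "saliva", us_delivered = "saliva")[rep(1, 80), ])
  set.seed(seed)
  rest <- rest[sample(nrow(rest)), ]
  out <- rbind(fixed, rest)
  rownames(out) <- NULL
  out$trial <- seq_len(nrow(out))
  out[c("trial", "cs_type", "us_delivered")]
}

#' Generate a streamline-count dataset with optional group effects
#'
#' For every region participating in the taxonomy's tracts, draws a per-seed
#' streamline run: counts toward each connected partner region (both the
#' tract's forward and reverse directions get runs, so the normalization's
#' bidirectional mean is computable) are negative-binomial around per-tract
#' baseline connection probabilities. Baseline probabilities and mean path
#' lengths are drawn once per call and shared by all subjects and groups;
#' group effects multiply the designated tracts' expected counts.
#'
#' @param taxonomy A `"circuit_taxonomy"`.
#' @param n_subjects Named integer vector: subjects per group (names are
#'   group labels), or a single unnamed count for one group.
#' @param group_effects Optional named list: for each group, a named numeric
#'   vector of multiplicative effects keyed by tract id
#'   (`"hemisphere:seed->target"`), e.g. `list(AN = c("left:thalamus->posterior_insula" = 1.5))`.
#' @param baseline_range Range of per-direction baseline connection
#'   probabilities, sampled log-uniformly (default `c(0.002, 0.05)`).
#' @param dispersion Negative-binomial size parameter (default 20).
#' @param path_length_range Range (mm) of per-pair mean path lengths.
#' @param samples_per_voxel Tracking samples per seed voxel (default 5000).
#' @param seed Integer seed.
#' @return List with `subjects` (list of records: `subject_id`, `group`,
#'   `runs` = list of [streamline_data()]) and `tracts` (the enumerated
#'   tract table).
#' @export
generate_streamline_dataset <- function(taxonomy = default_taxonomy(),
                                        n_subjects = c(group = 10),
                                        group_effects = NULL,
                                        baseline_range = c(0.002, 0.05),
                                        dispersion = 20,
                                        path_length_range = c(10, 80),
                                        samples_per_voxel = 5000,
                                        seed = 1L) {
  if (is.null(names(n_subjects)))
    names(n_subjects) <- paste0("group", seq_along(n_subjects))
  tracts <- enumerate_tracts(taxonomy)
  if (!nrow(tracts)) stop("taxonomy enumerates no tracts")
  set.seed(seed)
  # per-direction baselines and per-pair path lengths, shared across groups
  dir_keys <- c(tract_id(tracts$hemisphere, tracts$seed, tracts$target),
                tract_id(tracts$hemisphere, tracts$target, tracts$seed))
  baseline <- setNames(exp(runif(length(dir_keys),
                                 log(baseline_range[1]),
                                 log(baseline_range[2]))), dir_keys)
  pair_key <- function(h, a, b) paste0(h, ":", pmin(a, b), "|", pmax(a, b))
  pkeys <- unique(pair_key(tracts$hemisphere, tracts$seed, tracts$target))
  plens <- setNames(runif(length(pkeys), path_length_range[1],
                          path_length_range[2]), pkeys)
  # per (hemisphere, region): partners in either tract direction
  partner_table <- unique(rbind(
    data.frame(h = tracts$hemisphere, from = tracts$seed,
               to = tracts$target, stringsAsFactors = FALSE),
    data.frame(h = tracts$hemisphere, from = tracts$target,
               to = tracts$seed, stringsAsFactors = FALSE)))
  subjects <- list()
  for (g in names(n_subjects)) {
    eff <- if (!is.null(group_effects)) group_effects[[g]] else NULL
    for (s in seq_len(n_subjects[[g]])) {
      sid <- paste0(g, "_", s)
      runs <- list()
      for (h in unique(partner_table$h)) {
        regions <- unique(partner_table$from[partner_table$h == h])
        for (r in regions) {
          tg <- partner_table$to[partner_table$h == h &
                                 partner_table$from == r]
          vol <- region_volume(taxonomy, r, h)
          if (is.na(vol)) vol <- 100
          total <- vol * samples_per_voxel
          mu <- baseline[tract_id(h, r, tg)] * total
          if (!is.null(eff)) {
            # multiplier applies to both directions of the designated tract
            mult <- rep(1, length(tg))
            fwd_id <- tract_id(h, r, tg)
            rev_id <- tract_id(h, tg, r)
            mult <- ifelse(fwd_id %in% names(eff), eff[fwd_id], mult)
            mult <- ifelse(rev_id %in% names(eff) & mult == 1,
                           eff[rev_id], mult)
            mu <- mu * mult
          }
          counts <- pmin(rnbinom(length(tg), mu = mu, size = dispersion),
                         total)
          names(counts) <- tg
          mpl <- setNames(plens[pair_key(h, r, tg)], tg)
          runs[[length(runs) + 1L]] <- streamline_data(
            r, h, n_seed_voxels = vol, counts = counts,
            mean_path_length = mpl,
            samples_per_voxel = samples_per_voxel)
        }
      }
      subjects[[length(subjects) + 1L]] <-
        list(subject_id = sid, group = g, runs = runs)
    }
  }
  list(subjects = subjects, tracts = tracts)
}

#' Pathway table for a whole synthetic streamline dataset
#'
#' @param dataset Output of [generate_streamline_dataset()].
#' @param taxonomy The taxonomy used to generate it.
#' @param distance_correct Apply path-length weighting.
#' @return Row-bound [build_pathway_table()] output with a `group` column.
#' @export
pathway_table_for_dataset <- function(dataset, taxonomy = default_taxonomy(),
                                      distance_correct = FALSE) {
  out <- lapply(dataset$subjects, function(s) {
    tab <- build_pathway_table(s$runs, taxonomy, subject_id = s$subject_id,
                               distance_correct = distance_correct)
    tab$group <- s$group
    tab
  })
  do.call(rbind, out)
}

#' Generate a per-subject behavioral table matching target moments
#'
#' Draws per-group normal samples and rescales them affinely so that each
#' group's sample mean and SD reproduce the targets exactly; variables are
#' drawn independently. Useful for turning a printed summary table into raw
#' per-subject data with identical group statistics.
#'
#' @param targets Data frame with columns `variable`, `group`, `mean`, `sd`,
#'   `n`.
#' @param seed Integer seed.
#' @return Tidy data frame: `subject_id`, `group`, `variable`, `value`.
#' @export
generate_behavioral_table <- function(targets, seed = 1L) {
  stopifnot(all(c("variable", "group", "mean", "sd", "n") %in%
                names(targets)))
  if (any(targets$n < 2)) stop("each group needs n >= 2")
  set.seed(seed)
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    tg <- targets[i, ]
    z <- rnorm(tg$n)
    z <- (z - mean(z)) / sd(z)
    data.frame(subject_id = paste0(tg$group, "_", seq_len(tg$n)),
               group = tg$group, variable = tg$variable,
               value = tg$mean + tg$sd * z, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Packaged behavioral summary targets
#'
#' The demographic and behavioral group summary table (mean, SD, n per
#' variable for the control, anorexia and bulimia groups) shipped with the
#' package, in the format [generate_behavioral_table()] and
#' [anova_from_summary()] consume.
#'
#' @return Data frame with columns `variable`, `group`, `mean`, `sd`, `n`.
#' @export
behavioral_summary_targets <- function() {
  path <- system.file("extdata", "behavioral_summaries.tsv",
                      package = "tastecircuit")
  if (!nzchar(path))
    path <- file.path("inst", "extdata", "behavioral_summaries.tsv")
  read.delim(path, stringsAsFactors = FALSE)
}
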