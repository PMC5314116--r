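# Normalized connection strength from probabilistic-tractography streamline
# counts, plus pathway mean FA.
#
# The rescaling for a tract seed->target is
#     ((p_st / P_seed) * pbar) / V_target
# where p_st is the seed->target streamline probability, P_seed the seed's
# total connection probability over its in-circuit targets, pbar the mean of
# the forward (seed->target) and reverse (target->seed) probabilities, and
# V_target the target volume in voxels. Grouping fixed so the result is
# linear in pbar and inverse-linear in target volume. Optional path-length
# correction multiplies each count by the mean path length before forming
# probabilities (distance-correction semantics of probabilistic tracking).

#' Per-seed streamline-count record
#'
#' Holds the output of a probabilistic tracking run from one seed region:
#' streamline counts toward each in-circuit target, with the sampling
#' metadata needed to convert counts to probabilities.
#'
#' @param seed Seed region label (from [region_vocabulary()]).
#' @param hemisphere `"left"` or `"right"`.
#' @param n_seed_voxels Positive voxel count of the seed mask.
#' @param counts Named non-negative vector: streamlines reaching each target.
#' @param mean_path_length Named positive vector (mm), same names as `counts`
#'   (required wherever the count is positive).
#' @param samples_per_voxel Monte-Carlo samples drawn per seed voxel
#'   (default 5000).
#' @return Object of class `"streamline_data"`.
#' @export
#' @examples
#' streamline_data("thalamus", "left", n_seed_voxels = 2,
#'                 counts = c(posterior_insula = 500),
#'                 mean_path_length = c(posterior_insula = 20))
streamline_data <- function(seed, hemisphere, n_seed_voxels, counts,
                            mean_path_length = NULL,
                            samples_per_voxel = 5000) {
  stopifnot(length(seed) == 1, length(n_seed_voxels) == 1,
            n_seed_voxels > 0, samples_per_voxel > 0)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be a named vector of target labels")
  if (any(counts < 0)) stop("streamline counts must be non-negative")
  total <- n_seed_voxels * samples_per_voxel
  if (any(counts > total))
    stop("a streamline count exceeds the total number of samples (",
         total, ")")
  if (is.null(mean_path_length))
    mean_path_length <- setNames(rep(NA_real_, length(counts)), names(counts))
  pos <- names(counts)[counts > 0]
  mpl <- mean_path_length[pos]
  if (any(is.na(mpl) | mpl <= 0))
    stop("mean_path_length must be positive for every target with a ",
         "positive count")
  structure(list(seed = seed, hemisphere = hemisphere,
                 n_seed_voxels = n_seed_voxels,
                 samples_per_voxel = samples_per_voxel,
                 counts = counts, mean_path_length = mean_path_length),
            class = "streamline_data")
}

#' @export
print.streamline_data <- function(x, ...) {
  cat("Streamline run: seed", x$seed, paste0("(", x$hemisphere, ")"),
      "-", x$n_seed_voxels, "voxels x", x$samples_per_voxel, "samples\n")
  print(x$counts)
  invisible(x)
}

#' Streamline connection probability for one target
#'
#' The fraction of Monte-Carlo samples launched from the seed that reached
#' the target: `counts[target] / (n_seed_voxels * samples_per_voxel)`. With
#' `distance_correct = TRUE` each count is first weighted by the tract's mean
#' path length in mm, compensating the drop-off of streamline probability
#' with distance.
#'
#' @param data A [streamline_data()] record.
#' @param target Target region label present in `data$counts`.
#' @param distance_correct Apply path-length weighting? Default `FALSE`.
#' @return Non-negative scalar (probability-like; may exceed 1 when
#'   distance-corrected).
#' @export
#' @examples
#' sd1 <- streamline_data("thalamus", "left", 2,
#'                        counts = c(posterior_insula = 500),
#'                        mean_path_length = c(posterior_insula = 20))
#' connection_probability(sd1, "posterior_insula")         # 0.05
#' connection_probability(sd1, "posterior_insula", TRUE)   # 1.0
connection_probability <- function(data, target, distance_correct = FALSE) {
  stopifnot(inherits(data, "streamline_data"))
  if (!target %in% names(data$counts))
    stop("target '", target, "' not present in streamline counts for seed '",
         data$seed, "'")
  total <- data$n_seed_voxels * data$samples_per_voxel
  if (total <= 0) stop("total number of samples is zero")
  ct <- data$counts[[target]]
  if (ct == 0) return(0)
  if (distance_correct) ct <- ct * data$mean_path_length[[target]]
  ct / total
}

# sum of connection probabilities over every target the seed was tracked to
total_seed_probability <- function(data, distance_correct = FALSE) {
  sum(vapply(names(data$counts), function(tg)
    connection_probability(data, tg, distance_correct), numeric(1)))
}

#' Normalized tract connection strength
#'
#' Rescales the forward seed-to-target streamline probability by the seed's
#' total connection probability, the mean of the forward and reverse
#' probabilities, and the target volume, so that strengths are comparable
#' across seed/target regions of different sizes:
#' `((p_st / P_seed) * mean(p_st, p_ts)) / target_volume`.
#'
#' @param forward [streamline_data()] for the seed region (must contain the
#'   target among its counts).
#' @param reverse [streamline_data()] for the target region tracked back
#'   toward the seed, or `NULL`; when absent the mean probability falls back
#'   to the forward probability alone, with a warning.
#' @param target Target region label.
#' @param target_volume Positive target volume in voxels.
#' @param distance_correct Apply path-length weighting to both directions.
#' @return Non-negative dimensionless scalar; zero iff the forward
#'   probability is zero. A seed that reaches no target at all yields 0 with
#'   a warning.
#' @export
#' @examples
#' fwd <- streamline_data("thalamus", "left", 2,
#'         counts = c(posterior_insula = 500, frontal_operculum = 3500),
#'         mean_path_length = c(posterior_insula = 20, frontal_operculum = 30))
#' rev <- streamline_data("posterior_insula", "left", 1,
#'         counts = c(thalamus = 50), mean_path_length = c(thalamus = 20))
#' normalize_connection_strength(fwd, rev, "posterior_insula", 60)
normalize_connection_strength <- function(forward, reverse, target,
                                          target_volume,
                                          distance_correct = FALSE) {
  stopifnot(inherits(forward, "streamline_data"))
  if (!is.numeric(target_volume) || target_volume <= 0)
    stop("target_volume must be positive")
  p_st <- connection_probability(forward, target, distance_correct)
  P_seed <- total_seed_probability(forward, distance_correct)
  if (P_seed == 0) {
    warning("seed '", forward$seed, "' reaches no target; ",
            "connection strength set to 0")
    return(0)
  }
  if (is.null(reverse)) {
    warning("no reverse run for tract ", forward$seed, "->", target,
            "; using the forward probability alone")
    p_bar <- p_st
  } else {
    stopifnot(inherits(reverse, "streamline_data"))
    p_ts <- connection_probability(reverse, forward$seed, distance_correct)
    p_bar <- (p_st + p_ts) / 2
  }
  ((p_st / P_seed) * p_bar) / target_volume
}

#' Visitation-weighted mean FA along a pathway
#'
#' Mean fractional anisotropy over the voxels a tract visits, weighted by the
#' streamline visitation count of each voxel, so core voxels dominate over
#' rarely-visited fringe voxels.
#'
#' @param fa_values Numeric vector of per-voxel FA values in `[0, 1]`.
#' @param visitation_counts Non-negative integer vector, same length.
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' mean_fa_along_tract(c(0.2, 0.8), c(1, 3))  # 0.65
mean_fa_along_tract <- function(fa_values, visitation_counts) {
  stopifnot(length(fa_values) == length(visitation_counts))
  if (any(fa_values < 0 | fa_values > 1))
    stop("FA values must lie in [0, 1]")
  if (any(visitation_counts < 0))
    stop("visitation counts must be non-negative")
  keep <- visitation_counts > 0
  if (!any(keep))
    stop("pathway undefined: all visitation counts are zero")
  sum(fa_values[keep] * visitation_counts[keep]) / sum(visitation_counts[keep])
}

#' Per-subject pathway table over the enumerated tracts
#'
#' Computes one normalized connection strength per enumerated tract from a
#' subject's streamline runs. Runs are matched by (hemisphere, region); the
#' run from the tract's target region supplies the reverse probability. A
#' missing reverse run falls back to the forward probability (warning); a
#' missing forward run leaves the row's strength `NA` with status
#' `"missing_forward"` and the pipeline continues.
#'
#' @param runs List of [streamline_data()] records covering the subject.
#' @param taxonomy A `"circuit_taxonomy"`; supplies tract list and target
#'   volumes.
#' @param subject_id Identifier copied to the output rows.
#' @param fa Optional named numeric vector of pathway mean FA keyed by tract
#'   id (`"hemisphere:seed->target"`).
#' @param distance_correct Apply path-length weighting.
#' @return Data frame with one row per enumerated tract: `subject_id`,
#'   `hemisphere`, `seed`, `target`, `connection_strength`, `mean_fa`,
#'   `status` (`"ok"`, `"missing_forward"`, `"missing_reverse"`).
#' @export
build_pathway_table <- function(runs, taxonomy = default_taxonomy(),
                                subject_id = "subject", fa = NULL,
                                distance_correct = FALSE) {
  stopifnot(is.list(runs))
  keys <- vapply(runs, function(r) paste0(r$hemisphere, ":", r$seed),
                 character(1))
  names(runs) <- keys
  tracts <- enumerate_tracts(taxonomy)
  n <- nrow(tracts)
  strength <- rep(NA_real_, n)
  mean_fa <- rep(NA_real_, n)
  status <- rep("ok", n)
  for (i in seq_len(n)) {
    hemi <- tracts$hemisphere[i]; s <- tracts$seed[i]; tg <- tracts$target[i]
    fwd <- runs[[paste0(hemi, ":", s)]]
    if (is.null(fwd) || !tg %in% names(fwd$counts)) {
      status[i] <- "missing_forward"
      next
    }
    rev <- runs[[paste0(hemi, ":", tg)]]
    if (!is.null(rev) && !s %in% names(rev$counts)) rev <- NULL
    if (is.null(rev)) status[i] <- "missing_reverse"
    vol <- region_volume(taxonomy, tg, hemi)
    if (is.na(vol)) {
      status[i] <- "missing_volume"
      next
    }
    strength[i] <- withCallingHandlers(
      normalize_connection_strength(fwd, rev, tg, vol, distance_correct),
      warning = function(w) invokeRestart("muffleWarning"))
    id <- tract_id(hemi, s, tg)
    if (!is.null(fa) && id %in% names(fa)) mean_fa[i] <- fa[[id]]
  }
  if (any(status == "missing_reverse"))
    warning(sum(status == "missing_reverse"),
            " tract(s) lacked a reverse run; forward probability used")
  data.frame(subject_id = subject_id, hemisphere = tracts$hemisphere,
             seed = tracts$seed, target = tracts$target,
             connection_strength = strength, mean_fa = mean_fa,
             status = status, stringsAsFactors = FALSE)
}
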