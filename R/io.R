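# Readers and writers for the pipeline's plain-text artifacts: ROI
# time-series TSV, streamline-count TSV, taxonomy JSON, edge-list TSV and
# DOT files. Dialect is fixed (tab-separated, dot decimal, UTF-8, Unix
# newlines) and numeric values are serialized at 17 significant digits so
# write/read round trips are exact.

fmt_num <- function(x)
  ifelse(is.na(x), NA_character_, sprintf("%.17g", as.numeric(x)))

write_tsv_raw <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
}

#' Read a single-subject ROI time-series TSV
#'
#' Expects a header row of region labels followed by numeric rows (one per
#' volume). Non-numeric cells, missing values and infinities are rejected
#' with the offending location.
#'
#' @param path File path.
#' @return Numeric matrix with region-label column names.
#' @export
read_timeseries_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (!nrow(df)) stop("no data rows in ", path)
  M <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(NULL, names(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("non-numeric or non-finite value at row ", bad[1],
           ", column '", names(df)[j], "' in ", path)
    M[, j] <- v
  }
  unknown <- setdiff(colnames(M), region_vocabulary())
  if (length(unknown) && length(unknown) < ncol(M))
    warning("column label(s) outside the region vocabulary: ",
            paste(unknown, collapse = ", "))
  M
}

#' Write a single-subject ROI time-series TSV
#' @param x Numeric matrix (columns = regions).
#' @param path Output path.
#' @export
write_timeseries_tsv <- function(x, path) {
  write_tsv_raw(as.data.frame(x, check.names = FALSE), path)
  invisible(path)
}

#' Read streamline runs from a long-format TSV
#'
#' Columns: `seed_label`, `hemisphere`, `n_seed_voxels`,
#' `samples_per_voxel`, `target_label`, `streamline_count`,
#' `mean_path_length_mm`; one row per seed-target direction.
#'
#' @param path File path.
#' @return List of [streamline_data()] records (one per seed x hemisphere).
#' @export
read_streamlines_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("seed_label", "hemisphere", "n_seed_voxels",
            "samples_per_voxel", "target_label", "streamline_count",
            "mean_path_length_mm")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("streamline TSV is missing column(s): ",
         paste(missing, collapse = ", "))
  key <- paste(df$hemisphere, df$seed_label)
  lapply(split(df, key), function(d) {
    streamline_data(d$seed_label[1], d$hemisphere[1],
                    n_seed_voxels = d$n_seed_voxels[1],
                    counts = setNames(d$streamline_count, d$target_label),
                    mean_path_length = setNames(d$mean_path_length_mm,
                                                d$target_label),
                    samples_per_voxel = d$samples_per_voxel[1])
  })
}

#' Write streamline runs to a long-format TSV
#' @param runs List of [streamline_data()] records.
#' @param path Output path.
#' @export
write_streamlines_tsv <- function(runs, path) {
  rows <- lapply(runs, function(r)
    data.frame(seed_label = r$seed, hemisphere = r$hemisphere,
               n_seed_voxels = r$n_seed_voxels,
               samples_per_voxel = r$samples_per_voxel,
               target_label = names(r$counts),
               streamline_count = unname(r$counts),
               mean_path_length_mm = unname(r$mean_path_length),
               stringsAsFactors = FALSE))
  write_tsv_raw(do.call(rbind, rows), path)
  invisible(path)
}

#' Read a taxonomy from JSON
#' @param path JSON file with fields `regions` (label/hemisphere/volume) and
#'   `pairs`.
#' @return A `"circuit_taxonomy"`.
#' @export
read_taxonomy_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pairs <- lapply(obj$pairs, unlist)
  circuit_taxonomy(as.data.frame(obj$regions), pairs = pairs)
}

#' Write a taxonomy to JSON
#' @param taxonomy A `"circuit_taxonomy"`.
#' @param path Output path.
#' @export
write_taxonomy_json <- function(taxonomy, path) {
  jsonlite::write_json(list(regions = taxonomy$regions,
                            pairs = taxonomy$pairs),
                       path, auto_unbox = FALSE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a pattern graph as a TSV edge list
#' @param g A [pattern_graph()] (or an `"effconn"` fit).
#' @param path Output path.
#' @param group,hemisphere Optional annotation columns.
#' @export
write_edge_tsv <- function(g, path, group = NA, hemisphere = NA) {
  if (inherits(g, "effconn")) g <- g$pattern
  ed <- pattern_edges(g)
  ed <- cbind(data.frame(group = group, hemisphere = hemisphere,
                         stringsAsFactors = FALSE), ed)
  write_tsv_raw(ed, path)
  invisible(path)
}

#' Write a pattern graph in DOT format
#' @param g A [pattern_graph()] (or an `"effconn"` fit).
#' @param path Output path.
#' @param name Graph name in the DOT source.
#' @export
write_dot <- function(g, path, name = "effective_connectivity") {
  if (inherits(g, "effconn")) g <- g$pattern
  lines <- c(paste0("digraph ", name, " {"),
             paste0("  \"", g$vertices, "\";"))
  if (nrow(g$directed))
    lines <- c(lines, paste0("  \"", g$directed[, 1], "\" -> \"",
                             g$directed[, 2], "\";"))
  if (nrow(g$undirected))
    lines <- c(lines, paste0("  \"", g$undirected[, 1], "\" -> \"",
                             g$undirected[, 2], "\" [dir=none];"))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
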