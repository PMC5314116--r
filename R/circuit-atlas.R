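# Region taxonomy of the taste-reward circuit and tract enumeration.
#
# Regions are identified by (label, hemisphere) only; atlas coordinates are
# deliberately out of scope and may travel in a JSON sidecar if a user needs
# them. Only ipsilateral seed->target pairs from the fixed pair table are
# admitted.

#' Controlled vocabulary of circuit region labels
#'
#' The sixteen regions of the taste-reward hierarchy analysed by the package:
#' gustatory thalamus, three insula subregions, frontal operculum, substantia
#' nigra, two amygdala nuclei, four orbitofrontal (OFC) subregions, ventral
#' striatum, medial prefrontal cortex, hypothalamus and anterior cingulate.
#'
#' @return Character vector of the sixteen region labels.
#' @export
#' @examples
#' region_vocabulary()
region_vocabulary <- function() {
  c("thalamus", "dorsal_anterior_insula", "ventral_anterior_insula",
    "posterior_insula", "frontal_operculum", "substantia_nigra",
    "central_nucleus_amygdala", "basolateral_amygdala", "medial_OFC",
    "middle_OFC", "gyrus_rectus", "inferior_OFC", "ventral_striatum",
    "medial_PFC", "hypothalamus", "anterior_cingulate")
}

#' Allowed seed-to-target pairs of the circuit
#'
#' Static pair table defining which ipsilateral tracts are analysed: the
#' thalamus projects to the insula subregions and frontal operculum; each
#' insula subregion to amygdala nuclei, ventral striatum, medial PFC and the
#' four OFC subregions; the substantia nigra to the ventral striatum; each
#' amygdala nucleus to hypothalamus, substantia nigra, ventral striatum and
#' anterior cingulate; each OFC subregion to hypothalamus, ventral striatum
#' and medial PFC. The table has 49 pairs, i.e. 98 tracts over both
#' hemispheres.
#'
#' @return Named list mapping each seed label to a character vector of target
#'   labels.
#' @export
#' @examples
#' allowed_pairs()[["substantia_nigra"]]
#' sum(lengths(allowed_pairs()))  # 49 per hemisphere
allowed_pairs <- function() {
  insula_targets <- c("basolateral_amygdala", "central_nucleus_amygdala",
                      "ventral_striatum", "medial_PFC", "medial_OFC",
                      "middle_OFC", "gyrus_rectus", "inferior_OFC")
  amygdala_targets <- c("hypothalamus", "substantia_nigra",
                        "ventral_striatum", "anterior_cingulate")
  ofc_targets <- c("hypothalamus", "ventral_striatum", "medial_PFC")
  list(
    thalamus = c("dorsal_anterior_insula", "ventral_anterior_insula",
                 "posterior_insula", "frontal_operculum"),
    dorsal_anterior_insula  = insula_targets,
    ventral_anterior_insula = insula_targets,
    posterior_insula        = insula_targets,
    substantia_nigra        = "ventral_striatum",
    central_nucleus_amygdala = amygdala_targets,
    basolateral_amygdala     = amygdala_targets,
    medial_OFC   = ofc_targets,
    middle_OFC   = ofc_targets,
    gyrus_rectus = ofc_targets,
    inferior_OFC = ofc_targets
  )
}

#' Construct a circuit taxonomy
#'
#' A taxonomy holds the regions available for tract enumeration (with
#' hemisphere and optional volume in voxels) together with the allowed-pairs
#' table. Restricting `regions` restricts the enumerated tracts to pairs whose
#' seed and target are both present.
#'
#' @param regions Data frame with columns `label`, `hemisphere`
#'   (`"left"`/`"right"`) and optionally `volume` (positive voxel count).
#' @param pairs Named list mapping seed labels to target labels; defaults to
#'   [allowed_pairs()].
#' @return Object of class `"circuit_taxonomy"`.
#' @export
circuit_taxonomy <- function(regions, pairs = allowed_pairs()) {
  stopifnot(is.data.frame(regions),
            all(c("label", "hemisphere") %in% names(regions)))
  regions$label <- as.character(regions$label)
  regions$hemisphere <- as.character(regions$hemisphere)
  bad <- setdiff(regions$label, region_vocabulary())
  if (length(bad))
    stop("unknown region label(s): ", paste(bad, collapse = ", "))
  if (!all(regions$hemisphere %in% c("left", "right")))
    stop("hemisphere must be 'left' or 'right'")
  if (anyDuplicated(regions[c("label", "hemisphere")]))
    stop("duplicated (label, hemisphere) in taxonomy")
  if (is.null(regions$volume))
    regions$volume <- rep(NA_real_, nrow(regions))
  if (any(!is.na(regions$volume) & regions$volume <= 0))
    stop("region volumes must be positive")
  bad_seed <- setdiff(names(pairs), region_vocabulary())
  bad_tgt <- setdiff(unlist(pairs, use.names = FALSE), region_vocabulary())
  if (length(bad_seed) || length(bad_tgt))
    stop("pair table uses labels outside the region vocabulary: ",
         paste(unique(c(bad_seed, bad_tgt)), collapse = ", "))
  structure(list(regions = regions[order(regions$hemisphere, regions$label), ,
                                   drop = FALSE],
                 pairs = pairs),
            class = "circuit_taxonomy")
}

#' Default taxonomy: all sixteen regions in both hemispheres
#'
#' Volumes are representative voxel counts at 2 mm isotropic resolution,
#' stored with the packaged taxonomy file; they feed the connection-strength
#' volume normalization and the synthetic streamline generator.
#'
#' @return A `"circuit_taxonomy"` covering the full circuit (98 tracts).
#' @export
#' @examples
#' nrow(enumerate_tracts(default_taxonomy()))
default_taxonomy <- function() {
  path <- system.file("extdata", "taste_circuit_taxonomy.json",
                      package = "tastecircuit")
  if (nzchar(path)) return(read_taxonomy_json(path))
  # fallback when called from a source tree (e.g. during development)
  vols <- default_region_volumes()
  regions <- data.frame(
    label = rep(names(vols), times = 2),
    hemisphere = rep(c("left", "right"), each = length(vols)),
    volume = rep(unname(vols), times = 2),
    stringsAsFactors = FALSE)
  circuit_taxonomy(regions)
}

# representative region sizes in voxels (2 mm iso)
default_region_volumes <- function() {
  c(thalamus = 1050, dorsal_anterior_insula = 320,
    ventral_anterior_insula = 280, posterior_insula = 410,
    frontal_operculum = 350, substantia_nigra = 90,
    central_nucleus_amygdala = 60, basolateral_amygdala = 140,
    medial_OFC = 380, middle_OFC = 420, gyrus_rectus = 260,
    inferior_OFC = 340, ventral_striatum = 220, medial_PFC = 520,
    hypothalamus = 80, anterior_cingulate = 640)
}

#' @export
print.circuit_taxonomy <- function(x, ...) {
  cat("Taste-reward circuit taxonomy\n")
  cat("  regions:", nrow(x$regions), "(",
      sum(x$regions$hemisphere == "left"), "left /",
      sum(x$regions$hemisphere == "right"), "right )\n")
  cat("  tracts :", nrow(enumerate_tracts(x)), "\n")
  invisible(x)
}

#' Enumerate the analysed white-matter tracts
#'
#' Produces every allowed ipsilateral seed-to-target pair whose seed and
#' target regions are both present in the taxonomy, ordered deterministically
#' (hemisphere left first, then alphabetical seed, then alphabetical target).
#' The default taxonomy yields 98 tracts, 49 per hemisphere.
#'
#' @param taxonomy A `"circuit_taxonomy"`; defaults to [default_taxonomy()].
#' @return Data frame with columns `hemisphere`, `seed`, `target`.
#' @export
#' @examples
#' tracts <- enumerate_tracts()
#' nrow(tracts)                      # 98
#' table(tracts$hemisphere)          # 49 per hemisphere
enumerate_tracts <- function(taxonomy = default_taxonomy()) {
  stopifnot(inherits(taxonomy, "circuit_taxonomy"))
  out <- list()
  for (hemi in c("left", "right")) {
    present <- taxonomy$regions$label[taxonomy$regions$hemisphere == hemi]
    seeds <- sort(intersect(names(taxonomy$pairs), present))
    for (s in seeds) {
      tg <- sort(intersect(taxonomy$pairs[[s]], present))
      if (length(tg))
        out[[length(out) + 1L]] <- data.frame(
          hemisphere = hemi, seed = s, target = tg, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(hemisphere = character(), seed = character(),
                      target = character(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# canonical tract id used across tables and generator options
tract_id <- function(hemisphere, seed, target) {
  paste0(hemisphere, ":", seed, "->", target)
}

#' Look up a region volume in a taxonomy
#' @param taxonomy A `"circuit_taxonomy"`.
#' @param label Region label.
#' @param hemisphere `"left"` or `"right"`.
#' @return Volume in voxels (may be `NA` if not recorded).
#' @export
region_volume <- function(taxonomy, label, hemisphere) {
  i <- which(taxonomy$regions$label == label &
             taxonomy$regions$hemisphere == hemisphere)
  if (!length(i))
    stop("region not in taxonomy: ", label, " (", hemisphere, ")")
  taxonomy$regions$volume[i]
}
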