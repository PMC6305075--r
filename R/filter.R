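#' Filtering and geometry configuration
#'
#' Collects every tunable threshold of the pipeline with its default. Score
#' thresholds (0.15 for the two hydrogen-bond probes, 0.2 hydrophobic, 0.5
#' for the charged probes), same-type neighbour-count thresholds (30/30/40/5/5)
#' and the 2.5 Angstrom representative-selection radius are the published
#' operating point of the filter; the neighbour-count radius (2.0 A), the
#' probe-scorer constants and the clash factor are this implementation's
#' documented defaults.
#'
#' @param score_threshold named numeric: per-probe minimum score; values
#'   strictly below it are zeroed (boundary survives).
#' @param neighbor_threshold named integer: a point survives only if it has
#'   strictly more same-type nonzero neighbours than this.
#' @param neighbor_radius Angstrom radius for neighbour counting.
#' @param representative_radius non-maximum-suppression radius (Angstrom).
#' @param merge_radius polar pt1/pt2 merge distance (Angstrom, inclusive).
#' @param aromatic_search_radius radius for aromatic-atom counting and
#'   ring-centroid association (Angstrom).
#' @param min_aromatic_atoms minimum aromatic-atom count for upgrading a
#'   hydrophobic point.
#' @param aromatic_max_angle maximum angle (degrees) between ring normal and
#'   the direction to the pocket centroid for the "normal into pocket" test.
#' @param probe_cutoff,probe_sigma,hbond_ideal,charge_ideal,probe_radius,clash_factor
#'   probe-scorer constants (Angstrom; see [build_probe_map()]).
#' @param feature_tolerance default feature-sphere tolerance (Angstrom).
#' @param default_spacing lattice pitch assumed when none is given.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(score_threshold = c(HBD = 0.15, HBA = 0.15,
                                              POS = 0.5, NEG = 0.5,
                                              HYDROPHOBIC = 0.2),
                          neighbor_threshold = c(HBD = 30, HBA = 30,
                                                 POS = 5, NEG = 5,
                                                 HYDROPHOBIC = 40),
                          neighbor_radius = 2.0,
                          representative_radius = 2.5,
                          merge_radius = 3.0,
                          aromatic_search_radius = 4.5,
                          min_aromatic_atoms = 6,
                          aromatic_max_angle = 60,
                          probe_cutoff = 5.0,
                          probe_sigma = 0.8,
                          hbond_ideal = 2.9,
                          charge_ideal = 3.5,
                          probe_radius = 1.6,
                          clash_factor = 0.7,
                          feature_tolerance = 1.5,
                          default_spacing = 0.5) {
  score_threshold <- score_threshold[PROBE_TYPES]
  neighbor_threshold <- neighbor_threshold[PROBE_TYPES]
  if (any(is.na(score_threshold)) || any(score_threshold < 0)) {
    stop("score_threshold must be a named non-negative vector over all probes")
  }
  if (any(is.na(neighbor_threshold)) || any(neighbor_threshold < 0)) {
    stop("neighbor_threshold must be a named non-negative vector over all probes")
  }
  radii <- c(neighbor_radius, representative_radius, merge_radius,
             aromatic_search_radius, probe_cutoff, probe_sigma, probe_radius,
             feature_tolerance, default_spacing)
  if (any(radii <= 0)) stop("all radii must be > 0")
  structure(list(score_threshold = score_threshold,
                 neighbor_threshold = neighbor_threshold,
                 neighbor_radius = neighbor_radius,
                 representative_radius = representative_radius,
                 merge_radius = merge_radius,
                 aromatic_search_radius = aromatic_search_radius,
                 min_aromatic_atoms = min_aromatic_atoms,
                 aromatic_max_angle = aromatic_max_angle,
                 probe_cutoff = probe_cutoff,
                 probe_sigma = probe_sigma,
                 hbond_ideal = hbond_ideal,
                 charge_ideal = charge_ideal,
                 probe_radius = probe_radius,
                 clash_factor = clash_factor,
                 feature_tolerance = feature_tolerance,
                 default_spacing = default_spacing),
            class = "filter_config")
}

#' Read or write a filter configuration as a flat key-value file
#'
#' INI-style `key = value` lines; per-probe entries use `key.PROBE`.
#'
#' @param cfg a `filter_config`.
#' @param file path.
#' @export
write_filter_config <- function(cfg, file) {
  lines <- character(0)
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (length(v) > 1) {
      lines <- c(lines, sprintf("%s.%s = %.6g", nm, names(v), v))
    } else {
      lines <- c(lines, sprintf("%s = %.6g", nm, v))
    }
  }
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_filter_config
#' @export
read_filter_config <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  args <- list()
  for (i in seq_along(keys)) {
    parts <- strsplit(keys[i], ".", fixed = TRUE)[[1]]
    if (length(parts) == 2) {
      v <- args[[parts[1]]]
      if (is.null(v)) v <- numeric(0)
      v[parts[2]] <- vals[i]
      args[[parts[1]]] <- v
    } else {
      args[[keys[i]]] <- vals[i]
    }
  }
  do.call(filter_config, args)
}

#' Zero sub-threshold probe scores
#'
#' Per probe type, scores strictly below the type's threshold are set to
#' zero; boundary values survive.
#'
#' @param map a `probe_map`.
#' @param cfg a [filter_config()].
#' @return the thresholded `probe_map`.
#' @export
threshold_map <- function(map, cfg = filter_config()) {
  for (probe in PROBE_TYPES) {
    s <- map$scores[, probe]
    s[s < cfg$score_threshold[probe]] <- 0
    map$scores[, probe] <- s
  }
  map
}

#' Drop isolated probe points by same-type neighbour count
#'
#' For each nonzero point of a type, the number of other nonzero points of
#' the same type within `neighbor_radius` is counted; the point is kept only
#' if that count is strictly greater than the type's threshold. Counting is
#' simultaneous (all decisions use the pre-filter occupancy).
#'
#' @inheritParams threshold_map
#' @return the filtered `probe_map`.
#' @export
neighbor_filter <- function(map, cfg = filter_config()) {
  pts <- map$grid$points
  for (probe in PROBE_TYPES) {
    s <- map$scores[, probe]
    nz <- which(s > 0)
    if (length(nz) == 0) next
    d <- cross_dist(pts[nz, , drop = FALSE], pts[nz, , drop = FALSE])
    counts <- rowSums(d <= cfg$neighbor_radius + 1e-9) - 1L
    drop <- nz[counts <= cfg$neighbor_threshold[probe]]
    s[drop] <- 0
    map$scores[, probe] <- s
  }
  map
}

# deterministic processing order: score descending, then lexicographic
# (x, y, z), then grid index
nms_order <- function(scores, pts, idx) {
  order(-scores, pts[idx, 1], pts[idx, 2], pts[idx, 3], idx)
}

#' Select representative feature points (non-maximum suppression)
#'
#' Per probe type independently: repeatedly take the surviving point with the
#' highest score, emit it as a pt1 feature point, and suppress all same-type
#' points within `representative_radius` (2.5 Angstrom). Ties are broken by
#' lexicographic coordinates, then grid index, so output is deterministic and
#' independent of point order.
#'
#' @inheritParams threshold_map
#' @return a feature-point data frame (columns type, x, y, z, score, dx, dy,
#'   dz, tol, provenance) with provenance `"PT1"`.
#' @export
select_representatives <- function(map, cfg = filter_config()) {
  pts <- map$grid$points
  out <- list()
  for (probe in PROBE_TYPES) {
    s <- map$scores[, probe]
    nz <- which(s > 0)
    if (length(nz) == 0) next
    ord <- nz[nms_order(s[nz], pts, nz)]
    alive <- rep(TRUE, length(ord))
    pos <- pts[ord, , drop = FALSE]
    for (i in seq_along(ord)) {
      if (!alive[i]) next
      d <- dist_to_point(pos, pos[i, ])
      alive[d <= cfg$representative_radius + 1e-9] <- FALSE
      alive[i] <- NA  # emitted
    }
    keep <- which(is.na(alive))
    for (i in keep) {
      out[[length(out) + 1]] <- feature_row(probe, pos[i, ], score = s[ord[i]],
                                            tol = cfg$feature_tolerance,
                                            provenance = "PT1")
    }
  }
  if (length(out) == 0) return(empty_features())
  rownames_reset(do.call(rbind, out))
}

rownames_reset <- function(df) {
  rownames(df) <- NULL
  df
}

#' Run the full pt1 filter
#'
#' Convenience wrapper: threshold, neighbour filter, then representative
#' selection.
#'
#' @inheritParams threshold_map
#' @return pt1 feature points.
#' @export
extract_pt1 <- function(map, cfg = filter_config()) {
  select_representatives(neighbor_filter(threshold_map(map, cfg), cfg), cfg)
}
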