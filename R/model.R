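#' Merge probe-derived and projection-derived polar points (pt3)
#'
#' A polar pt1 point (HBD, HBA, POS, NEG) survives when some pt2 point of the
#' same type lies within `merge_radius` (3 Angstrom, inclusive). Survivors
#' keep their pt1 coordinates and scores - the probe map carries the energy
#' evidence - and gain the nearest pt2 point's direction - the projection
#' carries the directional evidence. Provenance becomes `"MERGED"`.
#'
#' @param pt1 feature points from [select_representatives()].
#' @param pt2 feature points from [extract_pt2()].
#' @param merge_radius Angstrom, inclusive boundary.
#' @return the merged (pt3) feature-point data frame.
#' @export
merge_pt1_pt2 <- function(pt1, pt2, merge_radius = 3.0) {
  polar <- pt1[pt1$type %in% POLAR_TYPES, , drop = FALSE]
  if (nrow(polar) == 0) return(empty_features())
  keep <- logical(nrow(polar))
  for (i in seq_len(nrow(polar))) {
    cand <- pt2[pt2$type == polar$type[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    d <- dist_to_point(feature_coords(cand), c(polar$x[i], polar$y[i], polar$z[i]))
    j <- which.min(d)
    if (d[j] <= merge_radius + 1e-9) {
      keep[i] <- TRUE
      polar$dx[i] <- cand$dx[j]
      polar$dy[i] <- cand$dy[j]
      polar$dz[i] <- cand$dz[j]
    }
  }
  polar <- polar[keep, , drop = FALSE]
  if (nrow(polar) > 0) polar$provenance <- "MERGED"
  rownames_reset(polar)
}

#' Assemble the final six-type pharmacophore (pt4)
#'
#' pt4 is the union of the merged polar set (pt3), the hydrophobic pt1
#' points (which pass through unfiltered - the 3 Angstrom rule applies only
#' to polar types), and the aromatic features. Features are ordered
#' deterministically by type then coordinates, and the configuration used is
#' embedded in the object.
#'
#' @param pt1 pt1 feature points.
#' @param pt2 pt2 feature points.
#' @param aromatics aromatic feature points.
#' @param cfg a [filter_config()].
#' @param cone a [cone_geometry()].
#' @param source optional list identifying structure/pocket provenance.
#' @return a `pharmacophore` object.
#' @export
build_model <- function(pt1, pt2, aromatics = empty_features(),
                        cfg = filter_config(), cone = cone_geometry(),
                        source = list()) {
  pt3 <- merge_pt1_pt2(pt1, pt2, cfg$merge_radius)
  hydro <- pt1[pt1$type == "HYDROPHOBIC", , drop = FALSE]
  feats <- rbind(pt3, hydro, aromatics)
  if (nrow(feats) == 0) {
    warning("empty pharmacophore model")
  } else {
    feats <- feats[order(match(feats$type, FEATURE_TYPES),
                         feats$x, feats$y, feats$z), , drop = FALSE]
  }
  structure(list(features = rownames_reset(feats), source = source,
                 config = cfg, cone = cone),
            class = "pharmacophore")
}

#' Generate a receptor-based pharmacophore model
#'
#' The top-level fitting function: given an annotated receptor and a pocket
#' grid it runs the full generation pipeline - probe-map scanning, the
#' three-stage pt1 filter (score threshold, same-type neighbour count,
#' 2.5 Angstrom non-maximum suppression), SP2/SP3 hybridization projection of
#' complementary sites (pt2), aromatic-ring upgrading of hydrophobic points,
#' and the 3 Angstrom pt1/pt2 merge - and returns the assembled six-type
#' model.
#'
#' @param structure a `protein` from [parse_pdb()] (roles are assigned if
#'   missing).
#' @param grid a `pocket_grid`.
#' @param config a [filter_config()].
#' @param cone a [cone_geometry()].
#' @return an object of class `pharmacophore` with elements `features` (data
#'   frame: type, x, y, z, score, dx, dy, dz, tol, provenance), `source`,
#'   `config`, `cone`.
#' @examples
#' toy <- make_toy_pocket(seed = 1)
#' model <- pharmacophore(toy$structure, toy$grid)
#' summary(model)
#' @export
pharmacophore <- function(structure, grid, config = filter_config(),
                          cone = cone_geometry()) {
  stopifnot(inherits(grid, "pocket_grid"))
  if (!isTRUE(structure$roles_assigned)) structure <- assign_roles(structure)
  map <- build_probe_map(grid, structure, config)
  pt1 <- extract_pt1(map, config)
  pt2 <- extract_pt2(structure, grid, cone, config)
  arom <- extract_aromatics(pt1, structure, grid, config)
  build_model(pt1, pt2, arom, config, cone,
              source = list(n_atoms = nrow(structure$atoms),
                            n_grid = nrow(grid$points),
                            spacing = grid$spacing))
}

#' @export
print.pharmacophore <- function(x, ...) {
  tab <- table(factor(x$features$type, levels = FEATURE_TYPES))
  cat(sprintf("<pharmacophore> %d features (%s)\n", nrow(x$features),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
summary.pharmacophore <- function(object, ...) {
  print(object)
  if (nrow(object$features) > 0) {
    print(object$features[, c("type", "x", "y", "z", "score", "provenance")],
          digits = 3)
  }
  invisible(object)
}

#' @export
coef.pharmacophore <- function(object, ...) object$features

#' Prune a pharmacophore to its strongest features
#'
#' Reducing the feature count is the practical point of receptor-only
#' generation: screening cost grows with the number of feature triples, and
#' weak features dilute the fit score. Keeps the `max_per_type`
#' highest-scoring features of each type (ties broken by coordinates, so the
#' result is deterministic).
#'
#' @param model a `pharmacophore`.
#' @param max_per_type maximum features kept per type.
#' @return the pruned `pharmacophore`.
#' @export
prune_model <- function(model, max_per_type = 1) {
  f <- model$features
  keep <- unlist(lapply(split(seq_len(nrow(f)), f$type), function(rows) {
    ord <- rows[order(-f$score[rows], f$x[rows], f$y[rows], f$z[rows])]
    ord[seq_len(min(max_per_type, length(ord)))]
  }))
  f <- f[sort(keep), , drop = FALSE]
  model$features <- rownames_reset(f)
  model
}

#' Plot a pharmacophore model
#'
#' Simple base-graphics projection of the feature positions onto a chosen
#' coordinate plane, one colour per feature type.
#'
#' @param x a `pharmacophore`.
#' @param plane which projection, `"xy"`, `"xz"` or `"yz"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pharmacophore <- function(x, plane = c("xy", "xz", "yz"), ...) {
  plane <- match.arg(plane)
  f <- x$features
  if (nrow(f) == 0) {
    graphics::plot(0, 0, type = "n", xlab = "", ylab = "",
                   main = "empty pharmacophore")
    return(invisible(x))
  }
  ax <- strsplit(plane, "")[[1]]
  cols <- c(HBD = "blue", HBA = "red", POS = "purple", NEG = "orange",
            HYDROPHOBIC = "goldenrod", AROMATIC = "darkgreen")
  graphics::plot(f[[ax[1]]], f[[ax[2]]], col = cols[f$type], pch = 19,
                 cex = 1.4, xlab = paste(ax[1], "(A)"),
                 ylab = paste(ax[2], "(A)"), ...)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                   cex = 0.7)
  invisible(x)
}

## ---- serialization ----------------------------------------------------------

MODEL_SCHEMA_VERSION <- "1.0"

#' Serialize or restore a pharmacophore model
#'
#' JSON is the lossless native format (versioned schema, documented in the
#' package vignette): feature table, configuration snapshot and cone
#' parameters; `read_model()` restores an identical object. PML is a
#' LigandScout-style XML export of the feature points (name, position,
#' tolerance, optional target vector) for interoperability; it is
#' write-only.
#'
#' @param model a `pharmacophore`.
#' @param file output path; for `write_model(..., file = NULL)` the character
#'   stream is returned instead.
#' @param format `"JSON"` or `"PML"`.
#' @return the serialized text (invisibly when written to a file);
#'   `read_model()` returns a `pharmacophore`.
#' @export
write_model <- function(model, file = NULL, format = c("JSON", "PML")) {
  format <- match.arg(format)
  txt <- if (format == "JSON") model_to_json(model) else model_to_pml(model)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

model_to_json <- function(model) {
  cfg <- unclass(model$config)
  # named atomic vectors serialize as bare arrays; keep probe names as objects
  cfg$score_threshold <- as.list(cfg$score_threshold)
  cfg$neighbor_threshold <- as.list(cfg$neighbor_threshold)
  payload <- list(
    schema = "apophore-pharmacophore",
    version = MODEL_SCHEMA_VERSION,
    source = model$source,
    config = cfg,
    cone = unclass(model$cone),
    features = model$features
  )
  jsonlite::toJSON(payload, dataframe = "columns", auto_unbox = TRUE,
                   digits = NA, na = "null", pretty = TRUE)
}

pml_feature_name <- c(HBD = "HBD", HBA = "HBA", POS = "PI", NEG = "NI",
                      HYDROPHOBIC = "H", AROMATIC = "AR")

model_to_pml <- function(model) {
  f <- model$features
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             sprintf("<pharmacophore name=\"apophore\" pharmacophoreType=\"LIGAND_SCOUT\">"))
  for (i in seq_len(nrow(f))) {
    nm <- pml_feature_name[[f$type[i]]]
    has_dir <- is.finite(f$dx[i])
    if (f$type[i] %in% c("HBD", "HBA") && has_dir) {
      lines <- c(lines,
        sprintf("  <vector name=\"%s\" featureId=\"f%d\" pointsToLigand=\"%s\" optional=\"false\" disabled=\"false\">",
                nm, i, if (f$type[i] == "HBD") "false" else "true"),
        sprintf("    <origin x3=\"%.4f\" y3=\"%.4f\" z3=\"%.4f\" tolerance=\"%.3f\" />",
                f$x[i], f$y[i], f$z[i], f$tol[i]),
        sprintf("    <target x3=\"%.4f\" y3=\"%.4f\" z3=\"%.4f\" tolerance=\"%.3f\" />",
                f$x[i] + f$dx[i], f$y[i] + f$dy[i], f$z[i] + f$dz[i], f$tol[i]),
        "  </vector>")
    } else if (f$type[i] == "AROMATIC" && has_dir) {
      lines <- c(lines,
        sprintf("  <plane name=\"%s\" featureId=\"f%d\" optional=\"false\" disabled=\"false\">", nm, i),
        sprintf("    <position x3=\"%.4f\" y3=\"%.4f\" z3=\"%.4f\" tolerance=\"%.3f\" />",
                f$x[i], f$y[i], f$z[i], f$tol[i]),
        sprintf("    <normal x3=\"%.4f\" y3=\"%.4f\" z3=\"%.4f\" tolerance=\"%.3f\" />",
                f$dx[i], f$dy[i], f$dz[i], f$tol[i]),
        "  </plane>")
    } else {
      lines <- c(lines,
        sprintf("  <point name=\"%s\" featureId=\"f%d\" optional=\"false\" disabled=\"false\">", nm, i),
        sprintf("    <position x3=\"%.4f\" y3=\"%.4f\" z3=\"%.4f\" tolerance=\"%.3f\" />",
                f$x[i], f$y[i], f$z[i], f$tol[i]),
        "  </point>")
    }
  }
  c(lines, "</pharmacophore>")
}

#' @rdname write_model
#' @export
read_model <- function(file) {
  payload <- jsonlite::fromJSON(file, simplifyVector = TRUE)
  if (is.null(payload$schema) || payload$schema != "apophore-pharmacophore") {
    stop("schema error at $schema: not an apophore pharmacophore JSON")
  }
  feats <- as.data.frame(payload$features, stringsAsFactors = FALSE)
  if (nrow(feats) == 0) feats <- empty_features()
  for (col in c("x", "y", "z", "score", "dx", "dy", "dz", "tol")) {
    if (is.null(feats[[col]])) stop("schema error at $features$", col)
    feats[[col]] <- as.numeric(feats[[col]])
  }
  cfgl <- payload$config
  cfg <- filter_config(
    score_threshold = unlist(cfgl$score_threshold),
    neighbor_threshold = unlist(cfgl$neighbor_threshold),
    neighbor_radius = cfgl$neighbor_radius,
    representative_radius = cfgl$representative_radius,
    merge_radius = cfgl$merge_radius,
    aromatic_search_radius = cfgl$aromatic_search_radius,
    min_aromatic_atoms = cfgl$min_aromatic_atoms,
    aromatic_max_angle = cfgl$aromatic_max_angle,
    probe_cutoff = cfgl$probe_cutoff,
    probe_sigma = cfgl$probe_sigma,
    hbond_ideal = cfgl$hbond_ideal,
    charge_ideal = cfgl$charge_ideal,
    probe_radius = cfgl$probe_radius,
    clash_factor = cfgl$clash_factor,
    feature_tolerance = cfgl$feature_tolerance,
    default_spacing = cfgl$default_spacing)
  cone <- cone_geometry(payload$cone$c, payload$cone$d, payload$cone$e)
  structure(list(features = feats, source = payload$source, config = cfg,
                 cone = cone),
            class = "pharmacophore")
}
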