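#' Find aromatic rings in a structure
#'
#' Phe and Tyr contribute one six-membered ring, His one five-membered ring,
#' and Trp two rings (its fused system is stored as the component five- and
#' six-membered rings). Membership is by template atom names; residues with
#' missing ring atoms are skipped with a warning. Each ring carries its
#' centroid and best-fit plane normal (sign arbitrary at this stage).
#'
#' @param structure a `protein` with roles assigned.
#' @return a list of `ring` objects: `residue`, `reskey`, `atom_indices`,
#'   `centroid`, `normal`.
#' @export
find_rings <- function(structure) {
  if (!isTRUE(structure$roles_assigned)) structure <- assign_roles(structure)
  at <- structure$atoms
  rings <- list()
  for (key in unique(at$reskey)) {
    rows <- which(at$reskey == key)
    res <- at$resname[rows[1]]
    tmpl <- AROMATIC_RING_ATOMS[[res]]
    if (is.null(tmpl)) next
    for (ring_name in names(tmpl)) {
      want <- tmpl[[ring_name]]
      m <- rows[match(want, at$name[rows])]
      if (any(is.na(m))) {
        warning(sprintf("residue %s missing ring atoms; skipped", key))
        next
      }
      coords <- cbind(at$x[m], at$y[m], at$z[m])
      centroid <- colMeans(coords)
      centered <- sweep(coords, 2, centroid)
      sv <- svd(centered)
      normal <- sv$v[, 3]
      rings[[length(rings) + 1]] <- structure(
        list(residue = res, reskey = key, atom_indices = m,
             centroid = centroid, normal = unitv(normal)),
        class = "ring")
    }
  }
  rings
}

#' @export
print.ring <- function(x, ...) {
  cat(sprintf("<ring> %s (%d atoms), centroid (%.2f, %.2f, %.2f)\n",
              x$reskey, length(x$atom_indices), x$centroid[1], x$centroid[2],
              x$centroid[3]))
  invisible(x)
}

#' Count aromatic atoms around a point
#'
#' @param point numeric(3), Angstrom.
#' @param structure a `protein` with roles assigned.
#' @param radius counting radius in Angstrom (boundary inclusive).
#' @return integer count of aromatic ring-member atoms within `radius`.
#' @export
count_aromatic_atoms <- function(point, structure, radius = 4.5) {
  if (!isTRUE(structure$roles_assigned)) structure <- assign_roles(structure)
  at <- structure$atoms
  sel <- which(at$aromatic)
  if (length(sel) == 0) return(0L)
  d <- dist_to_point(cbind(at$x[sel], at$y[sel], at$z[sel]), point)
  sum(d <= radius + 1e-9)
}

#' Does a ring normal point into the pocket?
#'
#' The pocket "inner side" is operationalised as the direction from the ring
#' centroid to the grid centroid; the test passes when either sign of the
#' ring normal lies within `max_angle` of it. A ring whose plane faces the
#' pocket passes; a ring standing edge-on (normal parallel to the pocket
#' wall) fails.
#'
#' @param ring a `ring` from [find_rings()].
#' @param pocket a `pocket_grid`.
#' @param max_angle maximum angle in degrees (default 60).
#' @return logical.
#' @export
normal_into_pocket <- function(ring, pocket, max_angle = 60) {
  v <- pocket$centroid - ring$centroid
  if (vnorm(v) < 1e-9) return(TRUE)
  ang <- vangle(ring$normal, v)
  min(ang, 180 - ang) <= max_angle + 1e-9
}

#' Upgrade hydrophobic points to aromatic features
#'
#' A hydrophobic pt1 point becomes (additionally) an aromatic feature when
#' (1) at least `min_aromatic_atoms` aromatic atoms lie within the search
#' radius of it, and (2) the nearest ring whose centroid is within that
#' radius has its normal oriented into the pocket. The source hydrophobic
#' point is retained alongside: the model keeps a hydrophobic centre that
#' also carries an aromatic feature. The emitted direction is the
#' pocket-facing ring normal.
#'
#' @param pt1_hydrophobic feature-point data frame of hydrophobic pt1 points.
#' @param structure a `protein` with roles assigned.
#' @param pocket a `pocket_grid`.
#' @param cfg a [filter_config()].
#' @return a feature-point data frame of `AROMATIC` features (possibly empty).
#' @export
extract_aromatics <- function(pt1_hydrophobic, structure, pocket,
                              cfg = filter_config()) {
  if (!isTRUE(structure$roles_assigned)) structure <- assign_roles(structure)
  hydro <- pt1_hydrophobic[pt1_hydrophobic$type == "HYDROPHOBIC", , drop = FALSE]
  if (nrow(hydro) == 0) return(empty_features())
  rings <- find_rings(structure)
  if (length(rings) == 0) return(empty_features())
  centroids <- do.call(rbind, lapply(rings, `[[`, "centroid"))

  out <- list()
  for (i in seq_len(nrow(hydro))) {
    p <- c(hydro$x[i], hydro$y[i], hydro$z[i])
    n <- count_aromatic_atoms(p, structure, cfg$aromatic_search_radius)
    if (n < cfg$min_aromatic_atoms) next
    d <- dist_to_point(centroids, p)
    near <- which(d <= cfg$aromatic_search_radius + 1e-9)
    if (length(near) == 0) next
    ring <- rings[[near[which.min(d[near])]]]
    if (!normal_into_pocket(ring, pocket, cfg$aromatic_max_angle)) next
    v <- pocket$centroid - ring$centroid
    normal <- if (sum(ring$normal * v) >= 0) ring$normal else -ring$normal
    out[[length(out) + 1]] <- feature_row("AROMATIC", p,
                                          score = hydro$score[i],
                                          dir = normal,
                                          tol = cfg$feature_tolerance,
                                          provenance = "AROMATIC")
  }
  if (length(out) == 0) return(empty_features())
  rownames_reset(do.call(rbind, out))
}
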