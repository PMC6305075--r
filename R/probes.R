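## Probe-map scoring. Five probe types are scanned over the pocket lattice:
## HBD and HBA (ligand-side hydrogen-bond donor / acceptor probes), POS and
## NEG (charged probes) and HYDROPHOBIC. Each probe scores against the
## complementary receptor atoms: a donor probe sees receptor acceptors, a
## positive probe sees receptor anions, and so on.
##
## The per-pair energy surrogate is a distance-damped Gaussian well centred at
## the ideal contact distance,
##     g(r) = exp(-(r - r_ideal)^2 / (2 sigma^2)),  sigma = 0.8 A,
## with r_ideal = 2.9 A heavy-to-heavy for H bonds, 3.5 A for charge contacts
## and the sum of van der Waals radii for hydrophobic contact. Contributions
## from all complementary atoms within the cutoff are combined as a
## complementary product (noisy-OR), 1 - prod(1 - g_i), which keeps the score
## in [0, 1], reduces to g for a single atom, and is strictly monotone in
## every pair term so the field has no degenerate plateaus. Grid points that
## clash with any receptor heavy atom score zero for every probe. The whole
## function sits behind one interface so a different (e.g. force-field-grade)
## scorer could be substituted.

probe_complement_column <- function(probe) {
  switch(probe,
    HBD = "acceptor",
    HBA = "donor",
    POS = "anionic",
    NEG = "cationic",
    HYDROPHOBIC = "hydrophobic",
    stop("unknown probe type: ", probe)
  )
}

#' Score one probe at one point
#'
#' @param point numeric(3), Angstrom.
#' @param probe one of `"HBD"`, `"HBA"`, `"POS"`, `"NEG"`, `"HYDROPHOBIC"`.
#' @param structure a `protein` with roles assigned.
#' @param cfg a [filter_config()] (supplies cutoff, sigma, clash factor and
#'   probe radius).
#' @return score in `[0, 1]`.
#' @export
score_probe <- function(point, probe, structure, cfg = filter_config()) {
  map <- build_probe_map(pocket_grid(matrix(point, 1, 3),
                                     spacing = cfg$default_spacing),
                         structure, cfg, probes = probe)
  unname(map$scores[1, probe])
}

#' Build the probe map for a pocket grid
#'
#' Applies the probe scorer at every grid point for every probe type. Point
#' order is preserved; scores are deterministic and invariant under rigid
#' motion applied jointly to grid and structure.
#'
#' @param grid a `pocket_grid`.
#' @param structure a `protein` with roles assigned.
#' @param cfg a [filter_config()].
#' @param probes probe types to score (default all five).
#' @return a `probe_map`: list with `grid` and `scores` (n points x 5 matrix).
#' @export
build_probe_map <- function(grid, structure, cfg = filter_config(),
                            probes = PROBE_TYPES) {
  stopifnot(inherits(grid, "pocket_grid"))
  if (!isTRUE(structure$roles_assigned)) structure <- assign_roles(structure)
  bad <- setdiff(probes, PROBE_TYPES)
  if (length(bad) > 0) stop("unknown probe type: ", paste(bad, collapse = ", "))

  pts <- grid$points
  n <- nrow(pts)
  at <- structure$atoms
  scores <- matrix(0, n, length(PROBE_TYPES),
                   dimnames = list(NULL, PROBE_TYPES))
  if (nrow(at) == 0) {
    return(structure(list(grid = grid, scores = scores), class = "probe_map"))
  }

  d <- cross_dist(pts, atom_coords(structure))          # n x n_atoms
  clash <- d < cfg$clash_factor * outer(rep(cfg$probe_radius, n), at$vdw, "+")
  clashed <- rowSums(clash) > 0

  for (probe in probes) {
    col <- probe_complement_column(probe)
    sel <- which(at[[col]])
    if (length(sel) == 0) next
    r_ideal <- switch(probe,
      HBD = , HBA = rep(cfg$hbond_ideal, length(sel)),
      POS = , NEG = rep(cfg$charge_ideal, length(sel)),
      HYDROPHOBIC = at$vdw[sel] + cfg$probe_radius
    )
    ds <- d[, sel, drop = FALSE]
    g <- exp(-sweep(ds, 2, r_ideal, "-")^2 / (2 * cfg$probe_sigma^2))
    g[ds > cfg$probe_cutoff] <- 0
    scores[, probe] <- 1 - apply(1 - g, 1, prod)
  }
  scores[clashed, ] <- 0
  structure(list(grid = grid, scores = scores), class = "probe_map")
}

#' @export
print.probe_map <- function(x, ...) {
  nz <- colSums(x$scores > 0)
  cat(sprintf("<probe_map> %d points; nonzero per probe: %s\n",
              nrow(x$scores),
              paste(sprintf("%s=%d", names(nz), nz), collapse = " ")))
  invisible(x)
}

#' Dump or load a probe map as CSV (debugging aid)
#'
#' @param map a `probe_map`.
#' @param file path.
#' @return `file` invisibly, or the reloaded `probe_map`.
#' @export
write_probe_map <- function(map, file) {
  df <- data.frame(x = map$grid$points[, 1], y = map$grid$points[, 2],
                   z = map$grid$points[, 3], map$scores)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_probe_map
#' @param spacing lattice pitch of the stored grid.
#' @export
read_probe_map <- function(file, spacing = 0.5) {
  df <- utils::read.csv(file)
  grid <- pocket_grid(as.matrix(df[, c("x", "y", "z")]), spacing = spacing)
  scores <- as.matrix(df[, PROBE_TYPES])
  dimnames(scores) <- list(NULL, PROBE_TYPES)
  structure(list(grid = grid, scores = scores), class = "probe_map")
}
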