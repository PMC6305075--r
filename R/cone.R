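#' Hydrogen-bond cone geometry
#'
#' Derives the action-scope cone of a projected hydrogen-bond interaction
#' site. The donor-bound hydrogen sits at the cone apex; the projected site
#' centre P1 sits on the base plane at distance `d + e` from the donor heavy
#' atom, where `d` is the covalent X-H bond length and `e` the empirical
#' H-to-site reach (nominally the sum of the hydrogen and partner van der
#' Waals radii). The base-circle radius `c` bounds the lateral tolerance.
#' Derived quantities: slant `a` with `a^2 = (d + e)^2 + c^2`; apex half-angle
#' `A` with `tan(A) = c / (d + e)`; half-angle `C` seen from the hydrogen,
#' `tan(C) = c / e`; and the minimum acceptable D-H...A angle
#' `B_min = 180 - C` degrees. With the default `c = 1.5` and `e = 2.0` these
#' give `C = 36.87` (about 37 degrees) and `B_min = 143.13` (about 143).
#'
#' @param c base-circle radius, Angstrom (maximum lateral tolerance).
#' @param d covalent donor-hydrogen bond length, Angstrom.
#' @param e hydrogen-to-site distance, Angstrom (> 0).
#' @return a list of class `cone_params`: `c`, `d`, `e`, `a` (slant length),
#'   `angle_A`, `angle_C`, `angle_B_min` (degrees).
#' @export
cone_geometry <- function(c = 1.5, d = 1.0, e = 2.0) {
  if (c < 0 || d < 0 || e <= 0) stop("require c >= 0, d >= 0, e > 0")
  a <- sqrt((d + e)^2 + c^2)
  angle_A <- atan2(c, d + e) * 180 / pi
  angle_C <- atan2(c, e) * 180 / pi
  structure(list(c = c, d = d, e = e, a = a,
                 angle_A = angle_A, angle_C = angle_C,
                 angle_B_min = 180 - angle_C),
            class = "cone_params")
}

#' @export
print.cone_params <- function(x, ...) {
  cat(sprintf(paste0("<cone_params> c=%.2f d=%.2f e=%.2f A: a=%.4f, ",
                     "A=%.2f deg, C=%.2f deg, B_min=%.2f deg\n"),
              x$c, x$d, x$e, x$a, x$angle_A, x$angle_C, x$angle_B_min))
  invisible(x)
}

#' Ideal interaction directions of a receptor atom
#'
#' Returns the unit directions along which an interaction partner (or an
#' implicit hydrogen) would ideally sit, from the atom's hybridization state
#' and its bonded heavy neighbours (resolved by distance, < 1.8 Angstrom, or
#' < 2.0 for sulfur). Hydrogens are never read from the file; their ideal
#' geometry is implied:
#' \itemize{
#'   \item SP2, two neighbours: one in-plane direction bisecting the exterior
#'     angle (e.g. His ring N).
#'   \item SP2, one neighbour: two in-plane directions at 60 degrees either
#'     side of the bond extension (120-degree lone-pair geometry of a
#'     carbonyl or carboxylate oxygen).
#'   \item SP2, three neighbours: the two ring-plane normals (pi directions,
#'     e.g. the guanidinium carbon).
#'   \item SP3, one neighbour: three directions on the tetrahedral cone about
#'     the bond axis (109.47 degrees from the atom-to-neighbour bond vector,
#'     azimuths 0/120/240).
#'   \item SP3, two neighbours: the two remaining tetrahedral directions.
#'   \item SP3, three neighbours: the single remaining tetrahedral direction.
#' }
#'
#' @param structure a `protein` with roles assigned.
#' @param atom_index row index of the atom in `structure$atoms`.
#' @return a list of unit numeric(3) directions (possibly empty, with a
#'   warning, when no bonded neighbour can be resolved).
#' @export
ideal_directions <- function(structure, atom_index) {
  at <- structure$atoms
  a <- c(at$x[atom_index], at$y[atom_index], at$z[atom_index])
  nb <- bonded_neighbors(structure, atom_index)
  if (length(nb) == 0) {
    warning(sprintf("atom %d (%s %s) has no resolvable bonded neighbour",
                    at$serial[atom_index], at$resname[atom_index],
                    at$name[atom_index]))
    return(list())
  }
  bpos <- lapply(nb, function(j) c(at$x[j], at$y[j], at$z[j]))
  u <- lapply(bpos, function(b) unitv(b - a))  # atom -> neighbour bond vectors
  hyb <- at$hybrid[atom_index]

  if (hyb == "SP2") {
    if (length(u) == 1) {
      b <- bpos[[1]]
      others <- setdiff(bonded_neighbors(structure, nb[1]), atom_index)
      normal <- if (length(others) > 0) {
        cpos <- c(at$x[others[1]], at$y[others[1]], at$z[others[1]])
        n <- cross3(a - b, cpos - b)
        if (vnorm(n) < 1e-8) perp_vector(a - b) else unitv(n)
      } else {
        perp_vector(a - b)
      }
      ext <- unitv(a - b)
      return(list(rotate_about(ext, normal, 60),
                  rotate_about(ext, normal, -60)))
    }
    if (length(u) == 2) {
      return(list(unitv(-(u[[1]] + u[[2]]))))
    }
    # >= 3 neighbours: pi directions normal to the substituent plane
    n <- cross3(bpos[[2]] - bpos[[1]], bpos[[3]] - bpos[[1]])
    if (vnorm(n) < 1e-8) return(list())
    n <- unitv(n)
    return(list(n, -n))
  }

  # SP3 (and fallback): tetrahedral geometry
  tet <- 109.471
  if (length(u) == 1) {
    axis <- -u[[1]]
    e1 <- perp_vector(axis)
    e2 <- cross3(axis, e1)
    half <- (180 - tet) * pi / 180  # angle from the extension axis
    lapply(c(0, 120, 240) * pi / 180, function(phi) {
      unitv(cos(half) * axis + sin(half) * (cos(phi) * e1 + sin(phi) * e2))
    })
  } else if (length(u) == 2) {
    axis <- unitv(-(u[[1]] + u[[2]]))
    n <- cross3(u[[1]], u[[2]])
    if (vnorm(n) < 1e-8) n <- perp_vector(axis) else n <- unitv(n)
    half <- (tet / 2) * pi / 180
    list(unitv(cos(half) * axis + sin(half) * n),
         unitv(cos(half) * axis - sin(half) * n))
  } else {
    list(unitv(-(u[[1]] + u[[2]] + u[[3]])))
  }
}

# ligand-side feature type produced by a receptor role
ROLE_COMPLEMENT <- c(donor = "HBA", acceptor = "HBD",
                     anionic = "POS", cationic = "NEG")

#' Project a complementary interaction site from a receptor atom
#'
#' Places a candidate (pt2) feature at `atom + (d + e) * direction`. The
#' emitted type is the ligand-side complement of the receptor role: a
#' receptor donor projects a ligand hydrogen-bond acceptor region (HBA), a
#' receptor acceptor projects an HBD region, an anionic group a positive
#' site, a cationic group a negative site. The stored feature direction
#' points back at the receptor atom; the tolerance is the cone base radius
#' `c`.
#'
#' @param structure a `protein` with roles assigned.
#' @param atom_index atom row index.
#' @param direction unit numeric(3).
#' @param cone a [cone_geometry()].
#' @param role receptor role being projected (`"donor"`, `"acceptor"`,
#'   `"anionic"`, `"cationic"`); defaults to the first role the atom bears.
#' @return a one-row feature-point data frame with provenance `"PT2"`.
#' @export
project_feature <- function(structure, atom_index, direction,
                            cone = cone_geometry(), role = NULL) {
  if (abs(vnorm(direction) - 1) > 1e-6) {
    stop("direction must be a unit vector")
  }
  at <- structure$atoms
  if (is.null(role)) {
    role <- names(ROLE_COMPLEMENT)[vapply(names(ROLE_COMPLEMENT),
                                          function(r) isTRUE(at[[r]][atom_index]),
                                          logical(1))][1]
    if (is.na(role)) stop("atom bears no projectable role")
  }
  pos <- c(at$x[atom_index], at$y[atom_index], at$z[atom_index]) +
    (cone$d + cone$e) * direction
  feature_row(ROLE_COMPLEMENT[[role]], pos, score = 0, dir = -direction,
              tol = cone$c, provenance = "PT2")
}

#' Hydrogen-bond angle acceptability
#'
#' Places the donor hydrogen at `donor + d * hydrogen_dir` and tests whether
#' the implied D-H...A angle meets the minimum (143 degrees with the default
#' cone; boundary inclusive). The geometric floor of 90 degrees, below which
#' the bond is considered broken, is subsumed by this stricter bound.
#'
#' @param donor donor heavy-atom position, numeric(3).
#' @param hydrogen_dir unit direction from donor to hydrogen.
#' @param acceptor_site acceptor position, numeric(3).
#' @param cone a [cone_geometry()].
#' @return logical.
#' @export
angle_ok <- function(donor, hydrogen_dir, acceptor_site,
                     cone = cone_geometry()) {
  h <- donor + cone$d * unitv(hydrogen_dir)
  v1 <- donor - h
  v2 <- acceptor_site - h
  if (vnorm(v2) < 1e-9) return(FALSE)
  vangle(v1, v2) >= cone$angle_B_min - 1e-9
}

#' Extract the hybridization-projected candidate set (pt2)
#'
#' For every role-bearing atom of every pocket residue, interaction sites are
#' projected along the atom's ideal directions and kept when they (i) lie
#' inside the pocket (within one grid spacing of some grid point), (ii) pass
#' the hydrogen-bond angle test for H-bond types, and (iii) do not clash with
#' receptor atoms. Ordering is deterministic (residue, atom, role, direction).
#'
#' @param structure a `protein` with roles assigned.
#' @param pocket a `pocket_grid`. If its residue list is empty, all residues
#'   of the structure are considered pocket-lining (with a warning when that
#'   list was expected).
#' @param cone a [cone_geometry()].
#' @param cfg a [filter_config()] (clash constants).
#' @return a feature-point data frame with provenance `"PT2"`.
#' @export
extract_pt2 <- function(structure, pocket, cone = cone_geometry(),
                        cfg = filter_config()) {
  if (!isTRUE(structure$roles_assigned)) structure <- assign_roles(structure)
  at <- structure$atoms
  if (nrow(pocket$residues) == 0) {
    warning("pocket residue list is empty; no pt2 candidates generated")
    return(empty_features())
  }
  resmatch <- paste(at$chain, at$resseq) %in%
    paste(pocket$residues$chain, pocket$residues$resseq)
  idx <- which(resmatch & (at$donor | at$acceptor | at$anionic | at$cationic))
  if (length(idx) == 0) return(empty_features())

  coords <- atom_coords(structure)
  out <- list()
  for (i in idx) {
    dirs <- ideal_directions(structure, i)
    if (length(dirs) == 0) next
    for (role in names(ROLE_COMPLEMENT)) {
      if (!isTRUE(at[[role]][i])) next
      for (k in seq_along(dirs)) {
        fp <- project_feature(structure, i, dirs[[k]], cone, role = role)
        pos <- c(fp$x, fp$y, fp$z)
        # (i) containment in the pocket
        dmin <- min(dist_to_point(pocket$points, pos))
        if (dmin > pocket$spacing + 1e-9) next
        # (ii) H-bond cone angle for the H-bond types
        if (fp$type %in% c("HBA", "HBD") &&
            !angle_ok(c(at$x[i], at$y[i], at$z[i]), dirs[[k]], pos, cone)) next
        # (iii) receptor clash
        dat <- dist_to_point(coords, pos)
        if (any(dat < cfg$clash_factor * (at$vdw + cfg$probe_radius))) next
        out[[length(out) + 1]] <- fp
      }
    }
  }
  if (length(out) == 0) return(empty_features())
  rownames_reset(do.call(rbind, out))
}
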