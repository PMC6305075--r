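#' Construct a pocket grid object
#'
#' A pocket grid is the lattice of points filling a binding cavity, together
#' with the list of pocket-lining residues. In the intended pipeline both are
#' produced by an external cavity-detection program; here they can also come
#' from [make_toy_pocket()].
#'
#' @param points numeric n x 3 matrix of lattice coordinates (Angstrom).
#' @param spacing lattice pitch in Angstrom (> 0).
#' @param residues data frame with columns `chain` and `resseq` naming the
#'   pocket-lining residues, or `NULL`.
#' @return a `pocket_grid` object (points, spacing, residues, centroid).
#' @export
pocket_grid <- function(points, spacing = 0.5, residues = NULL) {
  points <- as_mat3(points)
  if (nrow(points) < 1) stop("a pocket must have at least one grid point")
  if (!all(is.finite(points))) stop("grid points must be finite")
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  if (is.null(residues)) {
    residues <- data.frame(chain = character(0), resseq = integer(0),
                           stringsAsFactors = FALSE)
  }
  structure(list(points = points, spacing = spacing, residues = residues,
                 centroid = colMeans(points)),
            class = "pocket_grid")
}

#' @export
print.pocket_grid <- function(x, ...) {
  cat(sprintf("<pocket_grid> %d points, spacing %.2f A, centroid (%.2f, %.2f, %.2f)\n",
              nrow(x$points), x$spacing, x$centroid[1], x$centroid[2],
              x$centroid[3]))
  invisible(x)
}

#' Load a pocket grid from plain-text files
#'
#' Reads the two outputs a cavity-detection step provides: a grid file with
#' one `x y z` triple per line (whitespace- or comma-separated, `#` comments)
#' and an optional residue file with `chain resseq` per line.
#'
#' @param grid_file path to the grid-point file.
#' @param residue_file optional path to the pocket-residue file.
#' @param spacing lattice pitch in Angstrom.
#' @return a [pocket_grid()] object with points in file order.
#' @export
load_pocket_grid <- function(grid_file, residue_file = NULL, spacing = 0.5) {
  lines <- readLines(grid_file, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) stop("empty grid file: a pocket must have >= 1 point")
  pts <- matrix(NA_real_, length(rows), 3)
  for (k in seq_along(rows)) {
    i <- rows[k]
    tok <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    val <- suppressWarnings(as.numeric(tok))
    if (length(val) < 3 || any(is.na(val[1:3]))) {
      stop(sprintf("grid parse error at line %d: expected three numbers", i))
    }
    pts[k, ] <- val[1:3]
  }
  residues <- NULL
  if (!is.null(residue_file)) {
    rl <- readLines(residue_file, warn = FALSE)
    rl <- rl[!grepl("^\\s*(#|$)", rl)]
    if (length(rl) > 0) {
      tok <- strsplit(trimws(rl), "[,[:space:]]+")
      residues <- data.frame(
        chain = vapply(tok, `[`, "", 1),
        resseq = as.integer(vapply(tok, `[`, "", 2)),
        stringsAsFactors = FALSE
      )
    }
  }
  pocket_grid(pts, spacing = spacing, residues = residues)
}

#' Write a pocket grid to a plain-text file
#'
#' @param grid a `pocket_grid`.
#' @param file output path (one `x y z` row per point).
#' @return `file`, invisibly.
#' @export
write_grid_file <- function(grid, file) {
  header <- sprintf("# pocket grid: %d points, spacing %.3f A",
                    nrow(grid$points), grid$spacing)
  body <- apply(grid$points, 1, function(p) sprintf("%.4f %.4f %.4f",
                                                    p[1], p[2], p[3]))
  writeLines(c(header, body), file)
  invisible(file)
}

#' @rdname write_grid_file
#' @export
write_residue_file <- function(grid, file) {
  writeLines(sprintf("%s %d", grid$residues$chain, grid$residues$resseq), file)
  invisible(file)
}

## ---- synthetic toy pocket ---------------------------------------------------
## Rigid side-chain templates in a local frame where the pocket centre is the
## origin and the residue's functional group points inward along +z (so it
## sits at negative z). Geometry uses textbook bond lengths/angles; backbone
## atoms are placed outward so they do not reach the cavity. Truth entries are
## the interaction sites the planted group is expected to produce, with the
## tolerance the generator guarantees.

toy_residue_templates <- function() {
  pent <- function(center, angle_deg, r = 1.16) {
    a <- angle_deg * pi / 180
    center + r * c(sin(a), 0, cos(a))
  }
  tmpl <- list()

  # His: imidazole in the xz-plane, NE2 innermost with its in-plane lone-pair
  # bisector pointing straight into the pocket. Donor and acceptor in one.
  c0 <- c(0, 0, -8.36)
  his <- rbind(NE2 = pent(c0, 0), CE1 = pent(c0, 72), CD2 = pent(c0, -72),
               ND1 = pent(c0, 144), CG = pent(c0, -144))
  his <- rbind(his, CB = pent(c0, -144, r = 1.16 + 1.51))
  his <- rbind(his, CA = his["CB", ] + c(0.5, 0.9, -1.1),
               N = his["CB", ] + c(0.5, 0.9, -1.1) + c(1.25, 0, -0.75),
               C = his["CB", ] + c(0.5, 0.9, -1.1) + c(-1.2, 0.4, -0.85),
               O = his["CB", ] + c(0.5, 0.9, -1.1) + c(-1.2, 0.4, -0.85) + c(0, 0.6, -1.07))
  tmpl$HIS <- list(
    resname = "HIS", coords = his,
    truth = data.frame(type = c("HBD", "HBA"),
                       x = 0, y = 0, z = -4.2, tol = 3.5,
                       stringsAsFactors = FALSE))

  # Asp: carboxylate in the xz-plane, O-C-O bisector inward.
  cg <- c(0, 0, -8.1)
  asp <- rbind(CB = cg + c(0, 0, -1.52), CG = cg,
               OD1 = cg + c(1.10, 0, 0.60), OD2 = cg + c(-1.10, 0, 0.60))
  asp <- rbind(asp, CA = asp["CB", ] + c(0.9, 0.6, -1.05),
               N = asp["CB", ] + c(0.9, 0.6, -1.05) + c(1.25, 0, -0.75),
               C = asp["CB", ] + c(0.9, 0.6, -1.05) + c(-1.2, 0.4, -0.85),
               O = asp["CB", ] + c(0.9, 0.6, -1.05) + c(-1.2, 0.4, -0.85) + c(0, 0.6, -1.07))
  tmpl$ASP <- list(
    resname = "ASP", coords = asp,
    truth = data.frame(type = c("POS", "HBD", "HBD"),
                       x = c(0, 1.10, -1.10), y = 0,
                       z = c(-4.2, -4.5, -4.5), tol = 3.5,
                       stringsAsFactors = FALSE))

  # Arg: guanidinium plane perpendicular to the inward axis so the CZ pi
  # normal projects straight into the pocket.
  cz <- c(0, 0, -7.6)
  arg <- rbind(CZ = cz,
               NE = cz + c(0, 1.33, 0),
               NH1 = cz + 1.33 * c(cos(210 * pi / 180), sin(210 * pi / 180), 0),
               NH2 = cz + 1.33 * c(cos(330 * pi / 180), sin(330 * pi / 180), 0))
  arg <- rbind(arg, CD = arg["NE", ] + c(0, 1.0, -1.05))
  arg <- rbind(arg, CG = arg["CD", ] + c(0, 0.65, -1.35),
               CB = arg["CD", ] + c(0, 0.65, -1.35) + c(0.8, 0.5, -1.2))
  tmpl$ARG <- list(
    resname = "ARG", coords = arg,
    truth = data.frame(type = c("NEG", "HBA"),
                       x = c(0, 0), y = c(0, 2.5), z = c(-4.2, -4.8),
                       tol = 3.5, stringsAsFactors = FALSE))

  # Leu: isopropyl fork opening into the pocket.
  cg <- c(0, 0, -7.4)
  leu <- rbind(CG = cg, CD1 = cg + c(1.26, 0, 0.88), CD2 = cg + c(-1.26, 0, 0.88),
               CB = cg + c(0, 0.72, -1.34))
  leu <- rbind(leu, CA = leu["CB", ] + c(0.9, 0.6, -1.05))
  tmpl$LEU <- list(
    resname = "LEU", coords = leu,
    truth = data.frame(type = "HYDROPHOBIC", x = 0, y = 0, z = -4.1,
                       tol = 3.0, stringsAsFactors = FALSE))

  # Phe: ring perpendicular to the inward axis (normal points into the
  # pocket), the configuration that qualifies as an aromatic feature.
  c0 <- c(0, 0, -7.3)
  hexp <- function(az) c0 + 1.39 * c(cos(az * pi / 180), sin(az * pi / 180), 0)
  phe <- rbind(CG = hexp(0), CD1 = hexp(60), CE1 = hexp(120), CZ = hexp(180),
               CE2 = hexp(240), CD2 = hexp(300))
  phe <- rbind(phe, CB = phe["CG", ] + c(1.2, 0, -0.9))
  phe <- rbind(phe, CA = phe["CB", ] + c(0.9, 0.6, -1.05))
  tmpl$PHE <- list(
    resname = "PHE", coords = phe,
    truth = data.frame(type = c("HYDROPHOBIC", "AROMATIC"),
                       x = 0, y = 0, z = -4.3, tol = 3.0,
                       stringsAsFactors = FALSE))

  # Lys: ammonium pointing inward (alternative cationic environment).
  nz <- c(0, 0, -6.3)
  lys <- rbind(NZ = nz, CE = nz + c(0, 0.55, -1.37))
  lys <- rbind(lys, CD = lys["CE", ] + c(0, -0.45, -1.45))
  lys <- rbind(lys, CG = lys["CD", ] + c(0.7, 0.4, -1.3))
  tmpl$LYS <- list(
    resname = "LYS", coords = lys,
    truth = data.frame(type = "NEG", x = 0, y = 0, z = -2.9, tol = 3.5,
                       stringsAsFactors = FALSE))

  tmpl
}

TOY_DIRECTIONS <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

#' Generate a deterministic synthetic pocket with planted feature environments
#'
#' Builds a roughly spherical cavity ringed by side-chain fragments whose
#' functional groups face inward: a His imidazole (H-bond donor and acceptor),
#' an Asp carboxylate (negatively charged receptor group, hence a
#' positive-charge pharmacophore site), an Arg guanidinium (cationic, hence a
#' negative site), a Leu isopropyl group (hydrophobic) and a Phe ring with its
#' normal into the pocket (hydrophobic + aromatic). A Lys ammonium environment
#' is also available. Each planted environment contributes ground-truth
#' entries (expected feature type, approximate position, tolerance) used by
#' recovery tests. Output is deterministic given `seed`.
#'
#' @param environments character vector naming planted residues, a subset of
#'   `c("HIS", "ASP", "ARG", "LEU", "PHE", "LYS")` (at most 6).
#' @param radius pocket radius in Angstrom (grid ball).
#' @param spacing lattice pitch in Angstrom, within `[0.3, 1.5]`.
#' @param seed integer seed controlling the (small) random placement jitter.
#' @param jitter standard deviation (Angstrom) of the rigid per-residue
#'   placement jitter that breaks lattice symmetry; 0 disables it.
#' @return a list of class `toy_pocket`: `structure` (a `protein` with roles
#'   assigned), `grid` (a `pocket_grid` bound to all planted residues), and
#'   `truth` (data frame of expected features: type, x, y, z, tol).
#' @export
make_toy_pocket <- function(environments = c("HIS", "ASP", "ARG", "LEU", "PHE"),
                            radius = 6, spacing = 0.5, seed = 1,
                            jitter = 0.05) {
  if (length(environments) == 0) stop("at least one environment is required")
  if (spacing < 0.3 || spacing > 1.5) stop("spacing must be in [0.3, 1.5] A")
  if (length(environments) > nrow(TOY_DIRECTIONS)) {
    stop("at most ", nrow(TOY_DIRECTIONS), " environments are supported")
  }
  tmpl <- toy_residue_templates()
  bad <- setdiff(environments, names(tmpl))
  if (length(bad) > 0) stop("unknown environment(s): ", paste(bad, collapse = ", "))

  set.seed(seed)
  atoms_list <- list()
  truth_list <- list()
  for (k in seq_along(environments)) {
    tm <- tmpl[[environments[k]]]
    u <- TOY_DIRECTIONS[k, ]
    # rotation taking local +z (inward) to -u, so the template lands on the
    # wall in direction u with its functional group facing the centre
    w <- -u
    e1 <- perp_vector(w)
    e2 <- cross3(w, e1)
    M <- cbind(e1, e2, w)
    shift <- stats::rnorm(3, 0, jitter)
    xyz <- t(M %*% t(tm$coords)) + matrix(shift, nrow(tm$coords), 3, byrow = TRUE)
    atoms_list[[k]] <- data.frame(
      name = rownames(tm$coords),
      element = substr(gsub("[0-9]", "", rownames(tm$coords)), 1, 1),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      resname = tm$resname, resseq = k,
      stringsAsFactors = FALSE
    )
    tp <- as.matrix(tm$truth[, c("x", "y", "z")])
    tp <- t(M %*% t(tp)) + matrix(shift, nrow(tp), 3, byrow = TRUE)
    truth_list[[k]] <- data.frame(type = tm$truth$type, x = tp[, 1],
                                  y = tp[, 2], z = tp[, 3],
                                  tol = tm$truth$tol,
                                  stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, atoms_list)
  atoms <- data.frame(
    serial = seq_len(nrow(at)),
    name = at$name,
    element = at$element,
    x = at$x, y = at$y, z = at$z,
    vdw = vdw_radius(at$element),
    resname = at$resname,
    resseq = at$resseq,
    icode = "",
    chain = "A",
    stringsAsFactors = FALSE
  )
  atoms$reskey <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$resname,
                        sep = "|")
  structure <- assign_roles(new_protein(atoms))

  k <- floor(radius / spacing)
  ax <- (-k:k) * spacing
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  pts <- pts[rowSums(pts^2) <= radius^2, , drop = FALSE]
  dimnames(pts) <- NULL
  grid <- pocket_grid(pts, spacing = spacing,
                      residues = data.frame(chain = "A",
                                            resseq = seq_along(environments),
                                            stringsAsFactors = FALSE))

  structure(list(structure = structure, grid = grid,
                 truth = do.call(rbind, truth_list), seed = seed),
            class = "toy_pocket")
}

#' @export
print.toy_pocket <- function(x, ...) {
  cat(sprintf("<toy_pocket> %d residues, %d grid points, truth: %s\n",
              nrow(x$grid$residues), nrow(x$grid$points),
              paste(sort(unique(x$truth$type)), collapse = ", ")))
  invisible(x)
}
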