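# Shared in-code fixtures and independent brute-force oracles.

# one fixed-column PDB ATOM/HETATM line
pdb_line <- function(serial, name, resname, chain, resseq, x, y, z,
                     elem = substr(name, 1, 1), record = "ATOM") {
  name_field <- if (nchar(name) >= 4) sprintf("%-4s", name) else
    sprintf(" %-3s", name)
  sprintf("%-6s%5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_field, resname, chain, resseq, x, y, z,
          1.0, 0.0, elem)
}

# build a protein from a data frame (name, resname, resseq, x, y, z) through
# the real parser
mk_structure <- function(df, chain = "A", assign = TRUE) {
  lines <- vapply(seq_len(nrow(df)), function(i) {
    pdb_line(i, df$name[i], df$resname[i], chain,
             if (is.null(df$resseq)) 1L else df$resseq[i],
             df$x[i], df$y[i], df$z[i])
  }, character(1))
  s <- parse_pdb(paste(lines, collapse = "\n"))
  if (assign) assign_roles(s) else s
}

# a lone Asp carboxylate fragment centred near the origin
mk_asp_fragment <- function(offset = c(0, 0, 0)) {
  mk_structure(data.frame(
    name = c("CB", "CG", "OD1", "OD2"),
    resname = "ASP",
    x = c(0, 0, 1.10, -1.10) + offset[1],
    y = c(0, 0, 0, 0) + offset[2],
    z = c(-1.52, 0, 0.60, 0.60) + offset[3],
    stringsAsFactors = FALSE))
}

# alanine-like backbone fragment with a well-defined carbonyl plane
mk_carbonyl_fragment <- function() {
  mk_structure(data.frame(
    name = c("N", "CA", "C", "O"),
    resname = "ALA",
    x = c(-1.90, -1.20, 0.30, 0.95),
    y = c(1.05, -0.20, -0.10, 0.95),
    z = c(0, 0, 0, 0),
    stringsAsFactors = FALSE))
}

mk_lys_fragment <- function() {
  mk_structure(data.frame(
    name = c("CD", "CE", "NZ"),
    resname = "LYS",
    x = c(0, 0, 0),
    y = c(-0.4, 0.55, 0.55),
    z = c(-2.75, -1.37, 0.11),
    stringsAsFactors = FALSE))
}

cross3_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

transform_protein <- function(structure, R, tvec) {
  xyz <- cbind(structure$atoms$x, structure$atoms$y, structure$atoms$z)
  xyz <- xyz %*% t(R) + matrix(tvec, nrow(xyz), 3, byrow = TRUE)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

transform_grid <- function(grid, R, tvec) {
  pocket_grid(grid$points %*% t(R) + matrix(tvec, nrow(grid$points), 3,
                                            byrow = TRUE),
              spacing = grid$spacing, residues = grid$residues)
}

## ---- brute-force oracles ----------------------------------------------------

# naive per-point filter pipeline: returns the surviving representative
# feature points per probe type, by explicit loops
oracle_pt1 <- function(points, scores, cfg) {
  out <- list()
  for (probe in colnames(scores)) {
    s <- scores[, probe]
    # stage 1: threshold (strict less-than zeroed)
    for (i in seq_along(s)) if (s[i] < cfg$score_threshold[[probe]]) s[i] <- 0
    # stage 2: neighbour count on the thresholded occupancy
    s2 <- s
    for (i in seq_along(s)) {
      if (s[i] <= 0) next
      count <- 0
      for (j in seq_along(s)) {
        if (j == i || s[j] <= 0) next
        if (sqrt(sum((points[i, ] - points[j, ])^2)) <= cfg$neighbor_radius + 1e-9)
          count <- count + 1
      }
      if (count <= cfg$neighbor_threshold[[probe]]) s2[i] <- 0
    }
    # stage 3: greedy NMS with (score desc, x, y, z, index) priority
    alive <- s2 > 0
    repeat {
      cand <- which(alive)
      if (length(cand) == 0) break
      ord <- cand[order(-s2[cand], points[cand, 1], points[cand, 2],
                        points[cand, 3], cand)]
      top <- ord[1]
      out[[length(out) + 1]] <- data.frame(
        type = probe, x = points[top, 1], y = points[top, 2],
        z = points[top, 3], score = s2[top], stringsAsFactors = FALSE)
      for (j in which(alive)) {
        if (sqrt(sum((points[top, ] - points[j, ])^2)) <=
            cfg$representative_radius + 1e-9) alive[j] <- FALSE
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(type = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), score = numeric(0)))
  }
  do.call(rbind, out)
}

# exact AUC by pair counting
oracle_auc <- function(scores, is_active) {
  act <- scores[as.logical(is_active)]
  dec <- scores[!as.logical(is_active)]
  wins <- 0
  for (a in act) for (d in dec) {
    if (a > d) wins <- wins + 1 else if (a == d) wins <- wins + 0.5
  }
  wins / (length(act) * length(dec))
}

# a probe_map built from raw pieces (tests reach through the public surface
# where possible; this constructor mirrors build_probe_map's output layout)
mk_probe_map <- function(points, scores, spacing = 0.5) {
  grid <- pocket_grid(points, spacing = spacing)
  structure(list(grid = grid, scores = scores), class = "probe_map")
}

# benzene / methanol / acetate SDF text fixtures (V2000)
benzene_sdf <- function() {
  paste(c(
    "benzene", "  fixture", "",
    " 12 12  0  0  0  0  0  0  0  0999 V2000",
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            1.39 * cos(seq(0, 300, 60) * pi / 180),
            1.39 * sin(seq(0, 300, 60) * pi / 180), 0, "C"),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            2.47 * cos(seq(0, 300, 60) * pi / 180),
            2.47 * sin(seq(0, 300, 60) * pi / 180), 0, "H"),
    sprintf("%3d%3d%3d  0", 1:6, c(2:6, 1), 4),
    sprintf("%3d%3d%3d  0", 1:6, 7:12, 1),
    "M  END", "$$$$"), collapse = "\n")
}

methanol_sdf <- function() {
  paste(c(
    "methanol", "  fixture", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.4300    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0",
    "M  END", "$$$$"), collapse = "\n")
}

acetate_sdf <- function() {
  paste(c(
    "acetate", "  fixture", "",
    "  4  3  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.1000    1.1000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.1000   -1.1000    0.0000 O   0  5  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  2  3  2  0", "  2  4  1  0",
    "M  CHG  1   4  -1",
    "M  END", "$$$$"), collapse = "\n")
}

write_tmp <- function(text, ext = ".sdf") {
  f <- tempfile(fileext = ext)
  writeLines(text, f)
  f
}

# features of one type at given coordinates, as a pt-set data frame
mk_features <- function(type, coords, score = 1, provenance = "PT1",
                        dir = NULL) {
  coords <- matrix(coords, ncol = 3)
  do.call(rbind, lapply(seq_len(nrow(coords)), function(i) {
    data.frame(type = type, x = coords[i, 1], y = coords[i, 2],
               z = coords[i, 3], score = score,
               dx = if (is.null(dir)) NA_real_ else dir[1],
               dy = if (is.null(dir)) NA_real_ else dir[2],
               dz = if (is.null(dir)) NA_real_ else dir[3],
               tol = 1.5, provenance = provenance, stringsAsFactors = FALSE)
  }))
}

# cached toy pocket + model for the expensive end-to-end tests
toy_cache <- new.env()
cached_toy_model <- function(seed = 1) {
  key <- paste0("m", seed)
  if (is.null(toy_cache[[key]])) {
    toy <- make_toy_pocket(seed = seed)
    toy_cache[[paste0("t", seed)]] <- toy
    toy_cache[[key]] <- pharmacophore(toy$structure, toy$grid)
  }
  list(toy = toy_cache[[paste0("t", seed)]], model = toy_cache[[key]])
}
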