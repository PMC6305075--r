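## Ligand input and pharmacophore-feature perception.
##
## Molecules arrive as multi-record SDF (V2000), read through ChemmineR. Two
## flavours are supported: ordinary small molecules with real connectivity,
## and the package's own pseudo-ligands - feature-annotated dummy molecules
## written by the screening-fixture generator, which carry their feature
## types in a FEATURE_TYPES data field (one type per atom) and bypass
## chemical perception.

# legacy molfile atom-block charge codes
CHARGE_CODE <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)

#' Read a multi-record SDF into ligand objects
#'
#' @param file path to an SDF (V2000) file.
#' @return a list of `ligand` objects: `id`, `atoms` (data frame: element,
#'   x, y, z, charge), `bonds` (data frame: a1, a2, order), and
#'   `feature_types` (character per-atom annotation, or `NULL`).
#' @export
read_sdf <- function(file) {
  sdfs <- ChemmineR::read.SDFset(file)
  ids <- ChemmineR::sdfid(sdfs)
  out <- vector("list", length(sdfs))
  for (k in seq_along(sdfs)) {
    sdf <- sdfs[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elem <- toupper(gsub("_.*$", "", rownames(ab)))
    # molfile atom-line fields after x/y/z/element: mass difference, then the
    # legacy charge code (ChemmineR exposes them as columns C5 and C6)
    chg_code <- if ("C6" %in% colnames(ab)) as.character(ab[, "C6"]) else
      rep("0", nrow(ab))
    charge <- CHARGE_CODE[chg_code]
    charge[is.na(charge)] <- 0L
    atoms <- data.frame(element = elem, x = ab[, 1], y = ab[, 2], z = ab[, 3],
                        charge = as.integer(charge), stringsAsFactors = FALSE)
    bbm <- as.matrix(bb)
    bonds <- if (length(bbm) == 0 || ncol(bbm) < 3 || nrow(bbm) == 0) {
      data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
    } else {
      data.frame(a1 = as.integer(bbm[, 1]), a2 = as.integer(bbm[, 2]),
                 order = as.integer(bbm[, 3]))
    }
    db <- ChemmineR::datablock(sdf)
    ft <- NULL
    if ("FEATURE_TYPES" %in% names(db)) {
      ft <- strsplit(trimws(db[["FEATURE_TYPES"]]), "\\s+")[[1]]
    }
    id <- if ("LIGAND_ID" %in% names(db)) db[["LIGAND_ID"]] else ids[k]
    out[[k]] <- structure(list(id = id, atoms = rownames_reset(atoms),
                               bonds = bonds, feature_types = ft),
                          class = "ligand")
  }
  out
}

#' Write ligand objects as a multi-record SDF
#'
#' Hand-formatted V2000 records; formal charges are encoded in the legacy
#' atom-block charge column, and pseudo-ligand feature annotations in a
#' FEATURE_TYPES data field. Output reads back identically through
#' [read_sdf()].
#'
#' @param ligands a list of `ligand` objects.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_sdf <- function(ligands, file) {
  code_of <- c(`3` = 1L, `2` = 2L, `1` = 3L, `-1` = 5L, `-2` = 6L, `-3` = 7L)
  recs <- vapply(ligands, function(lig) {
    na <- nrow(lig$atoms); nb <- nrow(lig$bonds)
    lines <- c(lig$id, "  apophore", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
    for (i in seq_len(na)) {
      chg <- code_of[as.character(lig$atoms$charge[i])]
      if (is.na(chg)) chg <- 0L
      lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                                lig$atoms$x[i], lig$atoms$y[i], lig$atoms$z[i],
                                lig$atoms$element[i], chg))
    }
    for (i in seq_len(nb)) {
      lines <- c(lines, sprintf("%3d%3d%3d  0", lig$bonds$a1[i],
                                lig$bonds$a2[i], lig$bonds$order[i]))
    }
    chg_rows <- which(lig$atoms$charge != 0)
    if (length(chg_rows) > 0) {
      lines <- c(lines, paste0(sprintf("M  CHG%3d", length(chg_rows)),
                               paste(sprintf("%4d%4d", chg_rows,
                                             lig$atoms$charge[chg_rows]),
                                     collapse = "")))
    }
    lines <- c(lines, "M  END")
    lines <- c(lines, "> <LIGAND_ID>", lig$id, "")
    if (!is.null(lig$feature_types)) {
      lines <- c(lines, "> <FEATURE_TYPES>",
                 paste(lig$feature_types, collapse = " "), "")
    }
    paste(c(lines, "$$$$"), collapse = "\n")
  }, character(1))
  writeLines(recs, file)
  invisible(file)
}

# all simple rings of size 3..max_size, as sorted atom-index vectors
find_small_rings <- function(bonds, n_atoms, max_size = 6) {
  if (nrow(bonds) == 0) return(list())
  adj <- vector("list", n_atoms)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a1[i]; b <- bonds$a2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  rings <- list()
  seen <- character(0)
  walk <- function(path) {
    last <- path[length(path)]
    for (nxt in adj[[last]]) {
      if (nxt == path[1] && length(path) >= 3) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1]] <<- sort(path)
        }
      } else if (!(nxt %in% path) && length(path) < max_size && nxt > path[1]) {
        walk(c(path, nxt))
      }
    }
  }
  for (start in seq_len(n_atoms)) walk(start)
  # keep only simple rings: every member has exactly two ring neighbours
  Filter(function(r) {
    sub <- bonds[bonds$a1 %in% r & bonds$a2 %in% r, , drop = FALSE]
    nrow(sub) == length(r)
  }, rings)
}

ligand_ring_aromatic <- function(lig, ring) {
  sub <- lig$bonds[lig$bonds$a1 %in% ring & lig$bonds$a2 %in% ring, ,
                   drop = FALSE]
  if (all(sub$order == 4)) return(TRUE)
  # Kekule six-ring: alternating single/double bonds on carbons/nitrogens
  if (length(ring) == 6 && all(lig$atoms$element[ring] %in% c("C", "N")) &&
      sum(sub$order == 2) == 3 && sum(sub$order == 1) == 3) {
    deg2 <- table(c(sub$a1[sub$order == 2], sub$a2[sub$order == 2]))
    return(all(deg2 == 1))
  }
  FALSE
}

#' Perceive pharmacophore features of a ligand
#'
#' For annotated pseudo-ligands the FEATURE_TYPES annotation is authoritative
#' (one feature per atom at the atom position). For real molecules, standard
#' pattern perception on the heavy-atom graph:
#' \itemize{
#'   \item HBD: uncharged or positively charged O/N carrying at least one
#'     hydrogen (explicit, or implied by an unfilled valence);
#'   \item HBA: O or N with a free lone pair (not positively charged, not a
#'     fully substituted amine);
#'   \item NEG: negatively charged atoms; carboxylate oxygens are collapsed
#'     to one feature at the O-O midpoint;
#'   \item POS: positively charged atoms;
#'   \item HYDROPHOBIC: connected clusters of three or more apolar carbons,
#'     one feature per cluster centroid;
#'   \item AROMATIC: aromatic ring centroid with the ring-plane normal.
#' }
#'
#' @param lig a `ligand` from [read_sdf()], or any list with `id`, `atoms`,
#'   `bonds` in the same layout.
#' @return a `ligand_features` object: `id` plus a feature-point data frame.
#' @export
perceive_ligand_features <- function(lig) {
  at <- lig$atoms
  if (nrow(at) == 0 || !all(is.finite(c(at$x, at$y, at$z)))) {
    stop("ligand has no usable 3D coordinates")
  }
  if (!is.null(lig$feature_types)) {
    if (length(lig$feature_types) != nrow(at)) {
      stop("FEATURE_TYPES annotation length does not match atom count")
    }
    feats <- do.call(rbind, lapply(seq_len(nrow(at)), function(i) {
      feature_row(lig$feature_types[i], c(at$x[i], at$y[i], at$z[i]),
                  provenance = "PT2")
    }))
    return(new_ligand_features(lig$id, feats))
  }

  bonds <- lig$bonds
  n <- nrow(at)
  heavy_deg <- integer(n)
  h_count <- integer(n)
  hetero_nb <- logical(n)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a1[i]; b <- bonds$a2[i]
    if (at$element[b] == "H") h_count[a] <- h_count[a] + 1L
    else if (at$element[a] != "H") heavy_deg[a] <- heavy_deg[a] + 1L
    if (at$element[a] == "H") h_count[b] <- h_count[b] + 1L
    else if (at$element[b] != "H") heavy_deg[b] <- heavy_deg[b] + 1L
    if (at$element[a] %in% c("N", "O", "S", "P") || at$charge[a] != 0)
      hetero_nb[b] <- TRUE
    if (at$element[b] %in% c("N", "O", "S", "P") || at$charge[b] != 0)
      hetero_nb[a] <- TRUE
  }
  bond_order_sum <- numeric(n)
  for (i in seq_len(nrow(bonds))) {
    o <- if (bonds$order[i] == 4) 1.5 else bonds$order[i]
    bond_order_sum[bonds$a1[i]] <- bond_order_sum[bonds$a1[i]] + o
    bond_order_sum[bonds$a2[i]] <- bond_order_sum[bonds$a2[i]] + o
  }

  rings <- find_small_rings(bonds, n)
  aromatic_rings <- Filter(function(r) ligand_ring_aromatic(lig, r), rings)
  aromatic_atom <- logical(n)
  for (r in aromatic_rings) aromatic_atom[r] <- TRUE

  feats <- list()
  add <- function(type, pos, dir = c(NA_real_, NA_real_, NA_real_)) {
    feats[[length(feats) + 1]] <<- feature_row(type, pos, dir = dir,
                                               provenance = "PT2")
  }
  coords <- cbind(at$x, at$y, at$z)

  valence <- c(O = 2, N = 3)
  is_on <- at$element %in% c("O", "N")
  implicit_h <- ifelse(is_on,
                       pmax(0, valence[at$element] + at$charge -
                              bond_order_sum),
                       0)
  has_h <- h_count > 0 | implicit_h > 0

  # NEG with carboxylate grouping
  neg_done <- logical(n)
  for (i in which(at$charge < 0)) {
    if (neg_done[i]) next
    partner <- NA_integer_
    if (at$element[i] == "O") {
      cnb <- c(bonds$a2[bonds$a1 == i], bonds$a1[bonds$a2 == i])
      cnb <- cnb[at$element[cnb] == "C"]
      if (length(cnb) == 1) {
        sib <- setdiff(c(bonds$a2[bonds$a1 == cnb], bonds$a1[bonds$a2 == cnb]), i)
        sib <- sib[at$element[sib] == "O"]
        if (length(sib) >= 1) partner <- sib[1]
      }
    }
    if (!is.na(partner)) {
      add("NEG", (coords[i, ] + coords[partner, ]) / 2)
      neg_done[c(i, partner)] <- TRUE
    } else {
      add("NEG", coords[i, ])
      neg_done[i] <- TRUE
    }
  }
  for (i in which(at$charge > 0)) add("POS", coords[i, ])

  for (i in which(is_on & at$charge >= 0 & !neg_done)) {
    if (has_h[i]) add("HBD", coords[i, ])
  }
  for (i in which(is_on & at$charge <= 0)) {
    free_lone_pair <- at$element[i] == "O" ||
      (at$element[i] == "N" && !aromatic_atom[i] && bond_order_sum[i] < 3 + 1e-9 &&
       heavy_deg[i] + h_count[i] + implicit_h[i] < 4) ||
      (at$element[i] == "N" && aromatic_atom[i] && !has_h[i] && heavy_deg[i] == 2)
    if (at$charge[i] < 0 && neg_done[i]) next
    if (free_lone_pair) add("HBA", coords[i, ])
  }

  # hydrophobic clusters: connected apolar-carbon components of size >= 3
  apolar <- at$element == "C" & !hetero_nb & at$charge == 0
  if (any(apolar)) {
    comp <- rep(NA_integer_, n)
    cid <- 0
    for (s in which(apolar)) {
      if (!is.na(comp[s])) next
      cid <- cid + 1
      queue <- s
      comp[s] <- cid
      while (length(queue) > 0) {
        v <- queue[1]; queue <- queue[-1]
        nb <- c(bonds$a2[bonds$a1 == v], bonds$a1[bonds$a2 == v])
        nb <- nb[apolar[nb] & is.na(comp[nb])]
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
    for (k in seq_len(cid)) {
      mem <- which(comp == k)
      if (length(mem) >= 3) {
        add("HYDROPHOBIC", colMeans(coords[mem, , drop = FALSE]))
      }
    }
  }

  for (r in aromatic_rings) {
    centroid <- colMeans(coords[r, , drop = FALSE])
    centered <- sweep(coords[r, , drop = FALSE], 2, centroid)
    normal <- svd(centered)$v[, 3]
    add("AROMATIC", centroid, dir = unitv(normal))
  }

  feats <- if (length(feats) == 0) empty_features() else do.call(rbind, feats)
  new_ligand_features(lig$id, rownames_reset(feats))
}

new_ligand_features <- function(id, features) {
  structure(list(id = id, features = features), class = "ligand_features")
}

#' @export
print.ligand_features <- function(x, ...) {
  cat(sprintf("<ligand_features> %s: %d features (%s)\n", x$id,
              nrow(x$features), paste(x$features$type, collapse = ", ")))
  invisible(x)
}
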