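## Triangle-hash pharmacophore matching. Model feature triples are indexed by
## (sorted type triple, binned side lengths); a ligand triple retrieves
## geometry-compatible model triples, each compatible vertex correspondence
## seeds a rigid least-squares (Kabsch) superposition, the match is extended
## greedily over all features, refined on the matched pairs, and scored as
## the matched fraction of model features. The construction is this package's
## documented reconstruction of a triangular-hashing matcher; bin width and
## match tolerance are exposed parameters.

triangle_key <- function(types, sides, bin_width) {
  bins <- sort(floor(sides / bin_width))
  paste(paste(sort(types), collapse = ","), paste(bins, collapse = ","),
        sep = "|")
}

#' Build a triangle-hash index over a pharmacophore model
#'
#' Indexes every unordered feature triple by sorted type triple and binned
#' side lengths. Collinear (near-zero-area) triples are indexed but flagged
#' and never used to seed a superposition.
#'
#' @param model a `pharmacophore` with at least 3 features (fewer gives an
#'   empty index with a warning).
#' @param bin_width side-length bin width in Angstrom.
#' @return a `triangle_index` object.
#' @export
triangle_index <- function(model, bin_width = 0.5) {
  f <- model$features
  n <- nrow(f)
  index <- new.env(parent = emptyenv())
  triples <- list()
  if (n < 3) {
    warning("model has fewer than 3 features; empty triangle index")
  } else {
    coords <- feature_coords(f)
    combs <- utils::combn(n, 3)
    for (k in seq_len(ncol(combs))) {
      tri <- combs[, k]
      p <- coords[tri, , drop = FALSE]
      sides <- c(vnorm(p[1, ] - p[2, ]), vnorm(p[1, ] - p[3, ]),
                 vnorm(p[2, ] - p[3, ]))
      area <- vnorm(cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])) / 2
      rec <- list(idx = tri, types = f$type[tri], coords = p, sides = sides,
                  degenerate = area < 1e-6)
      triples[[k]] <- rec
      key <- triangle_key(rec$types, sides, bin_width)
      index[[key]] <- c(index[[key]], k)
    }
  }
  structure(list(index = index, triples = triples, model = model,
                 bin_width = bin_width, n_model = n),
            class = "triangle_index")
}

#' @export
print.triangle_index <- function(x, ...) {
  cat(sprintf("<triangle_index> %d features, %d triples, bin %.2f A\n",
              x$n_model, length(x$triples), x$bin_width))
  invisible(x)
}

# optimal rigid transform mapping rows of P onto rows of Q (Kabsch);
# returns list(R, t) with Q ~ P %*% R + t
kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  list(R = R, t = cq - as.vector(cp %*% R))
}

PERM3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
               c(3, 1, 2), c(3, 2, 1))

# side length between vertices i,j of a 3x3 coordinate matrix
tri_side <- function(p, i, j) vnorm(p[i, ] - p[j, ])

#' Match a ligand against an indexed pharmacophore
#'
#' Every non-degenerate ligand feature triple with a type- and
#' geometry-compatible model triple seeds a rigid superposition; matches are
#' extended greedily (a model feature is matched when a same-type transformed
#' ligand feature lies within `tol`), refined by a least-squares refit on the
#' matched pairs, and scored as `n_matched / n_model_features`. The best
#' result is reported (ties: lower RMSD, then enumeration order). A valid
#' match requires at least 3 pairs; otherwise the fit score is 0.
#'
#' @param index a [triangle_index()].
#' @param lig a `ligand_features` object (or a `ligand`, which is perceived
#'   first).
#' @param tol match tolerance in Angstrom.
#' @return a one-row data frame: ligand_id, fit_score, n_matched, rmsd, with
#'   the rigid transform in attribute `"transform"`.
#' @export
match_ligand <- function(index, lig, tol = 1.5) {
  if (inherits(lig, "ligand")) lig <- perceive_ligand_features(lig)
  lf <- lig$features
  mf <- index$model$features
  no_match <- data.frame(ligand_id = lig$id, fit_score = 0, n_matched = 0L,
                         rmsd = NA_real_, stringsAsFactors = FALSE)
  if (nrow(lf) < 3 || index$n_model < 3) return(no_match)

  lcoords <- feature_coords(lf)
  mcoords <- feature_coords(mf)
  bw <- index$bin_width
  best <- list(score = 0, rmsd = Inf, n = 0L, transform = NULL)

  lcomb <- utils::combn(nrow(lf), 3)
  for (k in seq_len(ncol(lcomb))) {
    tri <- lcomb[, k]
    lp <- lcoords[tri, , drop = FALSE]
    area <- vnorm(cross3(lp[2, ] - lp[1, ], lp[3, ] - lp[1, ])) / 2
    if (area < 1e-6) next
    sides <- c(tri_side(lp, 1, 2), tri_side(lp, 1, 3), tri_side(lp, 2, 3))
    # candidate keys: own bin plus or minus one per sorted side
    sb <- sort(floor(sides / bw))
    tkey <- paste(sort(lf$type[tri]), collapse = ",")
    cand <- integer(0)
    for (d1 in -1:1) for (d2 in -1:1) for (d3 in -1:1) {
      key <- paste(tkey, paste(sb + c(d1, d2, d3), collapse = ","), sep = "|")
      cand <- c(cand, index$index[[key]])
    }
    for (ck in unique(cand)) {
      rec <- index$triples[[ck]]
      if (rec$degenerate) next
      for (pi in seq_len(nrow(PERM3))) {
        perm <- PERM3[pi, ]
        if (!identical(lf$type[tri][perm], rec$types)) next
        ok <- TRUE
        for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
          dl <- tri_side(lp, perm[pair[1]], perm[pair[2]])
          dm <- tri_side(rec$coords, pair[1], pair[2])
          if (abs(dl - dm) > 2 * bw) { ok <- FALSE; break }
        }
        if (!ok) next
        tr <- kabsch(lp[perm, , drop = FALSE], rec$coords)
        res <- extend_match(lcoords, lf$type, mcoords, mf$type, tr, tol)
        if (res$n >= 3) {
          tr2 <- kabsch(lcoords[res$lig_idx, , drop = FALSE],
                        mcoords[res$model_idx, , drop = FALSE])
          res2 <- extend_match(lcoords, lf$type, mcoords, mf$type, tr2, tol)
          if (res2$n >= res$n) res <- res2 else tr2 <- tr
          score <- res$n / index$n_model
          if (score > best$score ||
              (score == best$score && res$rmsd < best$rmsd - 1e-12)) {
            best <- list(score = score, rmsd = res$rmsd, n = res$n,
                         transform = tr2)
          }
        }
      }
    }
  }
  if (best$n < 3) return(no_match)
  out <- data.frame(ligand_id = lig$id, fit_score = best$score,
                    n_matched = best$n, rmsd = best$rmsd,
                    stringsAsFactors = FALSE)
  attr(out, "transform") <- best$transform
  out
}

# greedy one-to-one extension of a seeded transform
extend_match <- function(lcoords, ltypes, mcoords, mtypes, tr, tol) {
  moved <- lcoords %*% tr$R + matrix(tr$t, nrow(lcoords), 3, byrow = TRUE)
  d <- cross_dist(mcoords, moved)
  d[outer(mtypes, ltypes, "!=")] <- Inf
  model_idx <- integer(0)
  lig_idx <- integer(0)
  dists <- numeric(0)
  while (TRUE) {
    j <- which.min(d)
    if (!is.finite(d[j])) break
    mi <- (j - 1) %% nrow(d) + 1
    li <- (j - 1) %/% nrow(d) + 1
    if (d[j] > tol) break
    model_idx <- c(model_idx, mi)
    lig_idx <- c(lig_idx, li)
    dists <- c(dists, d[j])
    d[mi, ] <- Inf
    d[, li] <- Inf
  }
  list(n = length(model_idx), model_idx = model_idx, lig_idx = lig_idx,
       rmsd = if (length(dists) > 0) sqrt(mean(dists^2)) else NA_real_)
}

#' Screen a ligand library against a pharmacophore model
#'
#' @param model a `pharmacophore`.
#' @param ligands list of `ligand` or `ligand_features` objects, or a path to
#'   an SDF file.
#' @param tol match tolerance in Angstrom.
#' @param bin_width triangle-hash bin width in Angstrom.
#' @return data frame with one row per ligand: ligand_id, fit_score,
#'   n_matched, rmsd.
#' @export
screen_library <- function(model, ligands, tol = 1.5, bin_width = 0.5) {
  if (is.character(ligands)) ligands <- read_sdf(ligands)
  idx <- triangle_index(model, bin_width)
  rownames_reset(do.call(rbind, lapply(ligands, function(lig) {
    res <- match_ligand(idx, lig, tol)
    attr(res, "transform") <- NULL
    res
  })))
}

#' @rdname screen_library
#' @param object a `pharmacophore`.
#' @param ... passed on to [screen_library()].
#' @export
predict.pharmacophore <- function(object, ligands, ...) {
  screen_library(object, ligands, ...)
}
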