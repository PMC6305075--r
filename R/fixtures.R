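#' Generate a matched active/decoy screening library from a model
#'
#' Desk-scale stand-in for a benchmark decoy set: actives are copies of the
#' model's feature set, jittered by isotropic Gaussian noise and placed in a
#' random rigid frame per ligand, so they remain matchable up to the noise;
#' decoys keep the feature-count statistics but have their types permuted and
#' their positions resampled uniformly inside the model's bounding box, so
#' any match is accidental. All randomness flows from a single seed. Ligands
#' are emitted as annotated pseudo-ligand objects; [write_screening_fixture()]
#' serializes the bundle to SDF plus a labels CSV in the same dialects the
#' screening functions consume.
#'
#' @param model a `pharmacophore` with at least 3 features.
#' @param n_active,n_decoy library composition (each >= 1).
#' @param noise_sd active positional noise, Angstrom (>= 0).
#' @param seed integer seed.
#' @return a `fixture_bundle`: `actives`, `decoys` (lists of `ligand`
#'   objects), `labels` (data frame: ligand_id, is_active), `model`, `seed`.
#' @export
make_screening_fixture <- function(model, n_active = 20, n_decoy = 100,
                                   noise_sd = 0.3, seed = 1) {
  f <- model$features
  if (nrow(f) < 3) stop("model must have at least 3 features")
  if (n_active < 1 || n_decoy < 1) stop("n_active and n_decoy must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)

  coords <- feature_coords(f)
  box_lo <- apply(coords, 2, min) - 1
  box_hi <- apply(coords, 2, max) + 1
  nf <- nrow(f)

  rigid <- function(p) {
    # random rotation via QR of a Gaussian matrix (sign-fixed), then a
    # random translation
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    t <- stats::runif(3, -10, 10)
    p %*% R + matrix(t, nrow(p), 3, byrow = TRUE)
  }
  as_ligand <- function(id, types, pos) {
    n <- nrow(pos)
    structure(list(
      id = id,
      atoms = data.frame(element = "C", x = pos[, 1], y = pos[, 2],
                         z = pos[, 3], charge = 0L, stringsAsFactors = FALSE),
      # a formal chain of single bonds keeps the record a valid molfile;
      # the feature annotation, not the connectivity, drives perception
      bonds = data.frame(a1 = seq_len(n - 1), a2 = seq_len(n - 1) + 1L,
                         order = 1L),
      feature_types = types), class = "ligand")
  }

  actives <- lapply(seq_len(n_active), function(i) {
    pos <- coords + matrix(stats::rnorm(3 * nf, 0, noise_sd), nf, 3)
    as_ligand(sprintf("active_%03d", i), f$type, rigid(pos))
  })
  decoys <- lapply(seq_len(n_decoy), function(i) {
    types <- sample(f$type)
    pos <- cbind(stats::runif(nf, box_lo[1], box_hi[1]),
                 stats::runif(nf, box_lo[2], box_hi[2]),
                 stats::runif(nf, box_lo[3], box_hi[3]))
    as_ligand(sprintf("decoy_%03d", i), types, rigid(pos))
  })
  labels <- data.frame(
    ligand_id = c(vapply(actives, `[[`, "", "id"),
                  vapply(decoys, `[[`, "", "id")),
    is_active = rep(c(TRUE, FALSE), c(n_active, n_decoy)),
    stringsAsFactors = FALSE)
  structure(list(actives = actives, decoys = decoys, labels = labels,
                 model = model, seed = seed),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle> %d actives + %d decoys (seed %d)\n",
              length(x$actives), length(x$decoys), x$seed))
  invisible(x)
}

#' Serialize a screening fixture to disk
#'
#' Writes `ligands.sdf` (actives then decoys, feature-annotated
#' pseudo-ligands) and `labels.csv` (ligand_id, is_active) into `dir`.
#'
#' @param bundle a `fixture_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screening_fixture <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sdf(c(bundle$actives, bundle$decoys), file.path(dir, "ligands.sdf"))
  utils::write.csv(bundle$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Serialize a toy-pocket fixture to disk
#'
#' Writes `receptor.pdb`, `grid.txt` and `residues.txt` in the dialects the
#' generation functions consume.
#'
#' @param toy a `toy_pocket` from [make_toy_pocket()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_toy_pocket <- function(toy, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_pdb(toy$structure, file.path(dir, "receptor.pdb"))
  write_grid_file(toy$grid, file.path(dir, "grid.txt"))
  write_residue_file(toy$grid, file.path(dir, "residues.txt"))
  utils::write.csv(toy$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
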