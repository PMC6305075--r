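test_that("ring templates find Phe, His and the two Trp rings", {
  toy <- make_toy_pocket(environments = c("HIS", "PHE"), seed = 1)
  rings <- find_rings(toy$structure)
  sizes <- sort(vapply(rings, function(r) length(r$atom_indices), integer(1)))
  expect_equal(sizes, c(5, 6))

  # Trp built directly: both component rings are reported
  trp <- mk_structure(data.frame(
    name = c("CG", "CD1", "NE1", "CE2", "CD2", "CE3", "CZ3", "CH2", "CZ2"),
    resname = "TRP",
    x = c(0.00, 1.28, 0.95, -0.43, -0.85, -2.16, -2.56, -1.82, -0.56),
    y = c(0.00, 0.52, 1.82, 1.93, 0.82, 0.53, -0.73, -1.77, -1.52),
    z = 0, stringsAsFactors = FALSE))
  trings <- find_rings(trp)
  expect_length(trings, 2)
  expect_setequal(vapply(trings, function(r) length(r$atom_indices),
                         integer(1)), c(5, 6))
  expect_equal(sum(trp$atoms$aromatic), 9)

  none <- mk_structure(data.frame(name = c("CB", "CG"), resname = "LEU",
                                  x = c(0, 1.5), y = 0, z = 0,
                                  stringsAsFactors = FALSE))
  expect_length(find_rings(none), 0)

  incomplete <- mk_structure(data.frame(
    name = c("CG", "CD1", "CD2"), resname = "PHE",
    x = c(0, 1.2, -1.2), y = c(0, 0.7, 0.7), z = 0, stringsAsFactors = FALSE))
  expect_warning(r0 <- find_rings(incomplete), "missing ring atoms")
  expect_length(r0, 0)
})

test_that("aromatic-atom counting is boundary-inclusive", {
  toy <- make_toy_pocket(environments = "PHE", seed = 1, jitter = 0)
  rings <- find_rings(toy$structure)
  centroid <- rings[[1]]$centroid
  expect_equal(count_aromatic_atoms(centroid, toy$structure), 6)
  expect_equal(count_aromatic_atoms(centroid + c(50, 0, 0), toy$structure), 0)

  # a point exactly 4.5 A from a single aromatic atom counts it
  at <- toy$structure$atoms
  cz <- which(at$name == "CZ")
  away <- c(at$x[cz], at$y[cz], at$z[cz]) + c(0, 0, 4.5) * c(0, 0, 1)
  # move far enough from the other ring atoms by going along +z then offset
  p <- c(at$x[cz], at$y[cz], at$z[cz]) + 4.5 * c(0, -sin(1.2), cos(1.2))
  n_near <- count_aromatic_atoms(p, toy$structure)
  d_all <- sqrt((at$x[at$aromatic] - p[1])^2 + (at$y[at$aromatic] - p[2])^2 +
                (at$z[at$aromatic] - p[3])^2)
  expect_equal(n_near, sum(d_all <= 4.5 + 1e-9))
})

test_that("the inward-normal test accepts facing rings and rejects edge-on rings", {
  ring <- structure(list(residue = "PHE", reskey = "A|1||PHE",
                         atom_indices = 1:6,
                         centroid = c(0, 0, -5), normal = c(0, 0, 1)),
                    class = "ring")
  grid <- pocket_grid(rbind(c(0, 0, 0)), spacing = 0.5)
  expect_true(normal_into_pocket(ring, grid))        # angle 0
  ring$normal <- c(0, 0, -1)
  expect_true(normal_into_pocket(ring, grid))        # sign-insensitive
  ring$normal <- c(1, 0, 0)
  expect_false(normal_into_pocket(ring, grid))       # edge-on, 90 deg
  ring$normal <- c(sin(pi / 4), 0, cos(pi / 4))
  expect_true(normal_into_pocket(ring, grid))        # 45 deg off-normal
  ring$normal <- c(sin(61 * pi / 180), 0, cos(61 * pi / 180))
  expect_false(normal_into_pocket(ring, grid))       # just past the cone
})

test_that("hydrophobic points upgrade to aromatic only for facing rings with enough aromatic atoms", {
  toy <- make_toy_pocket(environments = "PHE", seed = 1, jitter = 0)
  rings <- find_rings(toy$structure)
  centroid <- rings[[1]]$centroid
  inward <- toy$grid$centroid - centroid
  inward <- inward / sqrt(sum(inward^2))
  hpos <- centroid + 3.0 * inward
  hydro <- mk_features("HYDROPHOBIC", hpos, score = 0.9)

  arom <- extract_aromatics(hydro, toy$structure, toy$grid)
  expect_equal(nrow(arom), 1)
  expect_equal(arom$type, "AROMATIC")
  expect_equal(c(arom$x, arom$y, arom$z), hpos)      # same position as source
  expect_equal(arom$provenance, "AROMATIC")
  dirn <- c(arom$dx, arom$dy, arom$dz)
  expect_gt(sum(dirn * inward), 0)                    # pocket-facing normal

  # ring rotated edge-on (normal parallel to the pocket wall): no upgrade.
  # Rotate the ring 90 degrees about an axis perpendicular to its normal.
  at <- toy$structure$atoms
  ringsel <- which(at$aromatic)
  cen <- c(mean(at$x[ringsel]), mean(at$y[ringsel]), mean(at$z[ringsel]))
  axis <- cross3_test(rings[[1]]$normal, c(0, 0, 1))
  if (sqrt(sum(axis^2)) < 1e-6) axis <- cross3_test(rings[[1]]$normal, c(0, 1, 0))
  R <- rotation_matrix(axis, pi / 2)
  rot <- toy$structure
  xyz <- cbind(at$x, at$y, at$z)
  xyz[ringsel, ] <- sweep(sweep(xyz[ringsel, ], 2, cen) %*% t(R), 2, cen, "+")
  rot$atoms$x <- xyz[, 1]; rot$atoms$y <- xyz[, 2]; rot$atoms$z <- xyz[, 3]
  arom2 <- extract_aromatics(hydro, rot, toy$grid)
  expect_equal(nrow(arom2), 0)

  # fewer than six aromatic atoms within range: no upgrade
  weak <- mk_features("HYDROPHOBIC", centroid + 7.5 * inward, score = 0.9)
  expect_equal(nrow(extract_aromatics(weak, toy$structure, toy$grid)), 0)
})

test_that("aromatic features are position-subsets of hydrophobic input under rigid motion", {
  toy <- make_toy_pocket(seed = 8)
  model <- cached_toy_model(8)$model
  hydro <- model$features[model$features$type == "HYDROPHOBIC", ]
  arom <- model$features[model$features$type == "AROMATIC", ]
  if (nrow(arom) > 0) {
    for (i in seq_len(nrow(arom))) {
      d <- sqrt((hydro$x - arom$x[i])^2 + (hydro$y - arom$y[i])^2 +
                (hydro$z - arom$z[i])^2)
      expect_lt(min(d), 1e-9)
    }
  }
})
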