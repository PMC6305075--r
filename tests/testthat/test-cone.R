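test_that("cone geometry reproduces the published operating angles", {
  cp <- cone_geometry(c = 1.5, d = 1.0, e = 2.0)
  expect_equal(round(cp$angle_C), 37)
  expect_equal(round(cp$angle_B_min), 143)
  expect_equal(cp$angle_C, atan(1.5 / 2.0) * 180 / pi, tolerance = 1e-12)
  expect_equal(cp$a, sqrt(3^2 + 1.5^2), tolerance = 1e-12)
  expect_equal(cp$a, 3.3541, tolerance = 1e-4)
  expect_equal(cp$angle_A, 26.565, tolerance = 1e-3)
})

test_that("the degenerate cone and invalid inputs behave", {
  cp0 <- cone_geometry(c = 0, d = 1.3, e = 1.7)
  expect_equal(cp0$angle_A, 0)
  expect_equal(cp0$angle_C, 0)
  expect_equal(cp0$a, 3.0)
  expect_equal(cp0$angle_B_min, 180)
  expect_error(cone_geometry(c = -1), "require")
  expect_error(cone_geometry(e = 0), "require")
})

test_that("slant and apex-angle identities hold to 1e-9 over random cones", {
  set.seed(11)
  for (i in 1:1000) {
    c_ <- runif(1, 0, 3); d_ <- runif(1, 0.5, 1.5); e_ <- runif(1, 0.5, 3)
    cp <- cone_geometry(c_, d_, e_)
    expect_lt(abs(cp$a^2 - ((d_ + e_)^2 + c_^2)), 1e-9)
    expect_lt(abs(tan(cp$angle_A * pi / 180) - c_ / (d_ + e_)), 1e-9)
    expect_lt(abs(tan(cp$angle_C * pi / 180) - c_ / e_), 1e-9)
    expect_equal(cp$angle_B_min, 180 - cp$angle_C, tolerance = 1e-12)
  }
})

test_that("a carbonyl oxygen projects two in-plane lone-pair directions at 120 degrees", {
  frag <- mk_carbonyl_fragment()
  at <- frag$atoms
  oi <- which(at$name == "O")
  ci <- which(at$name == "C")
  dirs <- ideal_directions(frag, oi)
  expect_length(dirs, 2)
  co <- c(at$x[oi] - at$x[ci], at$y[oi] - at$y[ci], at$z[oi] - at$z[ci])
  for (d in dirs) {
    expect_equal(sqrt(sum(d^2)), 1, tolerance = 1e-9)
    ang <- acos(sum(d * co / sqrt(sum(co^2)))) * 180 / pi
    expect_equal(ang, 60, tolerance = 1)       # 120 deg from the C<-O bond
    expect_equal(abs(d[3]), 0, tolerance = 0.02)  # coplanar with the carbonyl
  }
})

test_that("an ammonium nitrogen projects a tetrahedral fan of three directions", {
  frag <- mk_lys_fragment()
  at <- frag$atoms
  ni <- which(at$name == "NZ")
  ce <- which(at$name == "CE")
  dirs <- ideal_directions(frag, ni)
  expect_length(dirs, 3)
  bond <- c(at$x[ce] - at$x[ni], at$y[ce] - at$y[ni], at$z[ce] - at$z[ni])
  bond <- bond / sqrt(sum(bond^2))
  for (d in dirs) {
    ang <- acos(sum(d * bond)) * 180 / pi
    expect_equal(ang, 109.47, tolerance = 0.1)
  }
  # azimuthal spread of 120 degrees between fan members
  expect_equal(acos(sum(dirs[[1]] * dirs[[2]])) * 180 / pi,
               acos(sum(dirs[[2]] * dirs[[3]])) * 180 / pi, tolerance = 1e-6)

  lone <- mk_structure(data.frame(name = "NZ", resname = "LYS",
                                  x = 0, y = 0, z = 0, stringsAsFactors = FALSE))
  expect_warning(d0 <- ideal_directions(lone, 1), "no resolvable")
  expect_length(d0, 0)
})

test_that("projected features sit at d+e along the direction with the complement type", {
  asp <- mk_asp_fragment()
  cp <- cone_geometry()
  od1 <- which(asp$atoms$name == "OD1")
  u <- c(0, 0, 1)
  fp <- project_feature(asp, od1, u, cp, role = "anionic")
  expect_equal(fp$type, "POS")
  src <- c(asp$atoms$x[od1], asp$atoms$y[od1], asp$atoms$z[od1])
  expect_equal(sqrt(sum((c(fp$x, fp$y, fp$z) - src)^2)), cp$d + cp$e,
               tolerance = 1e-9)
  expect_equal(c(fp$dx, fp$dy, fp$dz), -u)
  expect_equal(fp$tol, cp$c)

  fp2 <- project_feature(asp, od1, u, cp, role = "acceptor")
  expect_equal(fp2$type, "HBD")

  gly <- mk_structure(data.frame(
    name = c("N", "CA"), resname = "GLY",
    x = c(0, 1.1), y = c(0, 0.8), z = 0, stringsAsFactors = FALSE))
  ni <- which(gly$atoms$name == "N")
  fp3 <- project_feature(gly, ni, c(0, 0, 1), cp)
  expect_equal(fp3$type, "HBA")  # receptor donor -> ligand acceptor region
  expect_equal(fp3$z, 3.0)

  expect_error(project_feature(asp, od1, c(0, 0, 0.5), cp), "unit vector")
})

test_that("the hydrogen-bond angle test is boundary-inclusive at the cone minimum", {
  cp <- cone_geometry()
  donor <- c(0, 0, 0)
  hdir <- c(0, 0, 1)
  expect_true(angle_ok(donor, hdir, c(0, 0, 3), cp))          # collinear, 180
  # construct an acceptor at exactly the minimum angle from the hydrogen
  build_at_angle <- function(angle_deg) {
    h <- donor + cp$d * hdir
    # direction of H->A making angle_deg with H->D = (0, 0, -1)
    th <- (180 - angle_deg) * pi / 180
    h + 2 * c(sin(th), 0, cos(th))
  }
  expect_true(angle_ok(donor, hdir, build_at_angle(cp$angle_B_min), cp))
  expect_false(angle_ok(donor, hdir, build_at_angle(cp$angle_B_min - 0.1), cp))
  expect_false(angle_ok(donor, hdir, build_at_angle(120), cp))
  expect_false(angle_ok(donor, hdir, build_at_angle(90), cp))
})

test_that("pt2 extraction respects containment and is deterministic", {
  toy <- make_toy_pocket(environments = c("HIS", "ASP"), seed = 2)
  pt2 <- extract_pt2(toy$structure, toy$grid)
  expect_gt(nrow(pt2), 0)
  expect_true("HBD" %in% pt2$type)  # the acceptor-rich walls project donor sites
  expect_true(all(pt2$provenance == "PT2"))
  # every pt2 point is exactly d+e from some role-bearing atom
  at <- toy$structure$atoms
  polar <- at[at$donor | at$acceptor | at$anionic | at$cationic, ]
  for (i in seq_len(nrow(pt2))) {
    d <- sqrt((polar$x - pt2$x[i])^2 + (polar$y - pt2$y[i])^2 +
              (polar$z - pt2$z[i])^2)
    expect_lt(abs(min(d) - 3.0), 1e-9)
  }

  pt2b <- extract_pt2(toy$structure, toy$grid)
  expect_identical(pt2, pt2b)

  far <- pocket_grid(toy$grid$points + 50, spacing = toy$grid$spacing,
                     residues = toy$grid$residues)
  expect_equal(nrow(extract_pt2(toy$structure, far)), 0)

  noresid <- pocket_grid(toy$grid$points, spacing = toy$grid$spacing)
  expect_warning(empty <- extract_pt2(toy$structure, noresid), "residue list")
  expect_equal(nrow(empty), 0)
})

test_that("pt2 transforms covariantly under rigid motion", {
  toy <- make_toy_pocket(environments = c("HIS", "ARG"), seed = 6)
  pt2 <- extract_pt2(toy$structure, toy$grid)
  R <- rotation_matrix(c(0.2, 1, -0.5), 0.9)
  tv <- c(1, -6, 2)
  pt2r <- extract_pt2(transform_protein(toy$structure, R, tv),
                      transform_grid(toy$grid, R, tv))
  expect_equal(nrow(pt2r), nrow(pt2))
  moved <- cbind(pt2$x, pt2$y, pt2$z) %*% t(R) +
    matrix(tv, nrow(pt2), 3, byrow = TRUE)
  expect_equal(cbind(pt2r$x, pt2r$y, pt2r$z), moved, tolerance = 1e-9)
})
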