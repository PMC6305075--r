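# a compact asymmetric 5-feature model used across matching tests
mk_match_model <- function() {
  pt1 <- rbind(mk_features("HBA", c(0, 0, 0), score = 1),
               mk_features("HBD", c(3.1, 0.2, 0), score = 1),
               mk_features("POS", c(1.2, 2.8, 0.5), score = 1),
               mk_features("HYDROPHOBIC", c(0.5, 1.0, 3.0), score = 1),
               mk_features("AROMATIC", c(2.5, 2.0, 2.2), score = 1))
  suppressWarnings(build_model(pt1, rbind(
    mk_features("HBA", c(0, 0, 1), provenance = "PT2", dir = c(0, 0, -1)),
    mk_features("HBD", c(3.1, 0.2, 1), provenance = "PT2", dir = c(0, 0, -1)),
    mk_features("POS", c(1.2, 2.8, 1.5), provenance = "PT2", dir = c(0, 0, -1))),
    mk_features("AROMATIC", c(2.5, 2.0, 2.2), provenance = "AROMATIC",
                dir = c(0, 0, 1))))
}

model_as_ligand <- function(model, id = "self") {
  structure(list(id = id, features = model$features), class = "ligand_features")
}

test_that("triangle indexing enumerates feature triples and flags degenerate ones", {
  m3 <- suppressWarnings(build_model(
    rbind(mk_features("HBA", c(0, 0, 0), score = 1),
          mk_features("HBD", c(2, 0, 0), score = 1),
          mk_features("HYDROPHOBIC", c(0, 2, 0), score = 1)),
    rbind(mk_features("HBA", c(0, 0, 1), provenance = "PT2"),
          mk_features("HBD", c(2, 0, 1), provenance = "PT2"))))
  idx3 <- triangle_index(m3)
  expect_length(idx3$triples, 1)

  m5 <- mk_match_model()
  idx5 <- triangle_index(m5)
  expect_length(idx5$triples, choose(5, 3))

  collinear <- suppressWarnings(build_model(
    rbind(mk_features("HYDROPHOBIC", rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                      score = 1)),
    mk_features("HBA", c(0, 0, 0))[0, ]))
  idxc <- triangle_index(collinear)
  expect_true(idxc$triples[[1]]$degenerate)

  too_small <- suppressWarnings(build_model(
    mk_features("HBA", c(0, 0, 0), score = 1),
    mk_features("HBA", c(0, 0, 1), provenance = "PT2")))
  expect_warning(idx1 <- triangle_index(too_small), "fewer than 3")
  expect_length(idx1$triples, 0)
})

test_that("a ligand identical to the model matches perfectly", {
  m <- mk_match_model()
  idx <- triangle_index(m)
  res <- match_ligand(idx, model_as_ligand(m))
  expect_equal(res$fit_score, 1.0)
  expect_equal(res$n_matched, nrow(m$features))
  expect_lt(res$rmsd, 1e-9)
})

test_that("matching is invariant to rigid motion of the ligand", {
  m <- mk_match_model()
  idx <- triangle_index(m)
  lig <- model_as_ligand(m, "moved")
  R <- rotation_matrix(c(0, 1, 0), pi / 2)
  tv <- c(12, -3, 4)
  xyz <- cbind(lig$features$x, lig$features$y, lig$features$z) %*% t(R) +
    matrix(tv, nrow(lig$features), 3, byrow = TRUE)
  lig$features$x <- xyz[, 1]; lig$features$y <- xyz[, 2]
  lig$features$z <- xyz[, 3]
  res <- match_ligand(idx, lig)
  expect_equal(res$fit_score, 1.0)
  expect_lt(res$rmsd, 1e-6)

  set.seed(21)
  for (i in 1:5) {
    R <- rotation_matrix(rnorm(3), runif(1, 0, 2 * pi))
    tv <- runif(3, -20, 20)
    lig2 <- model_as_ligand(m, "r")
    xyz <- cbind(lig2$features$x, lig2$features$y, lig2$features$z) %*% t(R) +
      matrix(tv, nrow(lig2$features), 3, byrow = TRUE)
    lig2$features$x <- xyz[, 1]; lig2$features$y <- xyz[, 2]
    lig2$features$z <- xyz[, 3]
    res2 <- match_ligand(idx, lig2)
    expect_equal(res2$fit_score, 1.0)
    expect_lt(res2$rmsd, 1e-6)
  }
})

test_that("partial and impossible matches score accordingly", {
  m <- mk_match_model()
  idx <- triangle_index(m)

  # drop two features: fit score is normalised by the model feature count
  part <- model_as_ligand(m, "partial")
  part$features <- part$features[1:3, ]
  resp <- match_ligand(idx, part)
  expect_equal(resp$fit_score, 3 / 5)

  alien <- structure(list(id = "alien", features =
    mk_features("NEG", rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)), score = 1)),
    class = "ligand_features")
  resa <- match_ligand(idx, alien)
  expect_equal(resa$fit_score, 0)
  expect_equal(resa$n_matched, 0)

  two <- structure(list(id = "two", features =
    m$features[1:2, ]), class = "ligand_features")
  expect_equal(match_ligand(idx, two)$fit_score, 0)
})

test_that("screen_library and predict() return one scored row per ligand", {
  m <- mk_match_model()
  ligs <- list(model_as_ligand(m, "a"), model_as_ligand(m, "b"))
  ligs[[2]]$features <- ligs[[2]]$features[1:3, ]
  sc <- screen_library(m, ligs)
  expect_equal(sc$ligand_id, c("a", "b"))
  expect_equal(sc$fit_score, c(1, 0.6))
  sc2 <- predict(m, ligs)
  expect_equal(sc2, sc)
})
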