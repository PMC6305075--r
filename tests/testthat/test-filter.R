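cfg <- filter_config()

test_that("score thresholding zeroes strictly-below values and keeps boundaries", {
  pts <- matrix(runif(15), 5, 3)
  scores <- matrix(0, 5, 5, dimnames = list(NULL, c("HBD", "HBA", "POS",
                                                    "NEG", "HYDROPHOBIC")))
  scores[, "HBD"] <- c(0.15, 0.149, 0.5, 0.14, 1)
  scores[, "POS"] <- c(0.4, 0.5, 0.6, 0.49, 0.51)
  scores[, "NEG"] <- c(0.6, 0.4, 0.5, 0, 1)
  scores[, "HYDROPHOBIC"] <- c(0.2, 0.199, 0.3, 0.1, 0.25)
  thr <- threshold_map(mk_probe_map(pts, scores), cfg)
  expect_equal(thr$scores[, "HBD"], c(0.15, 0, 0.5, 0, 1))
  expect_equal(thr$scores[, "POS"], c(0, 0.5, 0.6, 0, 0.51))
  expect_equal(thr$scores[, "NEG"], c(0.6, 0, 0.5, 0, 1))
  expect_equal(thr$scores[, "HYDROPHOBIC"], c(0.2, 0, 0.3, 0, 0.25))
})

test_that("neighbour filtering needs strictly more same-type neighbours than the threshold", {
  # an isolated HBD point dies against the threshold of 30
  pts <- matrix(c(0, 0, 0), 1, 3)
  scores <- matrix(0, 1, 5, dimnames = list(NULL, PROBE_NAMES <- c("HBD",
    "HBA", "POS", "NEG", "HYDROPHOBIC")))
  scores[1, "HBD"] <- 0.9
  nf <- neighbor_filter(mk_probe_map(pts, scores), cfg)
  expect_equal(unname(nf$scores[1, "HBD"]), 0)

  # POS blob on a 0.5 A lattice: centre with exactly 5 neighbours dies,
  # with 6 survives (strictly-greater-than-5 rule)
  mk_blob <- function(n_neighbors) {
    offsets <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(-0.5, 0, 0), c(0, 0.5, 0),
                     c(0, -0.5, 0), c(0, 0, 0.5), c(0, 0, -0.5))
    pts <- offsets[seq_len(n_neighbors + 1), , drop = FALSE]
    scores <- matrix(0, nrow(pts), 5,
                     dimnames = list(NULL, c("HBD", "HBA", "POS", "NEG",
                                             "HYDROPHOBIC")))
    scores[, "POS"] <- 0.9
    mk_probe_map(pts, scores)
  }
  five <- neighbor_filter(mk_blob(5), cfg)
  expect_equal(unname(five$scores[1, "POS"]), 0)
  six <- neighbor_filter(mk_blob(6), cfg)
  expect_equal(unname(six$scores[1, "POS"]), 0.9)
  # brute-force count agrees on the kept blob
  expect_equal(sum(six$scores[, "POS"] > 0), 7)
})

test_that("representative selection is greedy non-maximum suppression", {
  sc <- function(pts, val) {
    m <- matrix(0, nrow(pts), 5, dimnames = list(NULL, c("HBD", "HBA", "POS",
                                                         "NEG", "HYDROPHOBIC")))
    m[, "HBD"] <- val
    m
  }
  one <- matrix(c(1, 2, 3), 1, 3)
  r1 <- select_representatives(mk_probe_map(one, sc(one, 0.8)), cfg)
  expect_equal(nrow(r1), 1)
  expect_equal(c(r1$x, r1$y, r1$z), c(1, 2, 3))

  close2 <- rbind(c(0, 0, 0), c(0, 0, 2))
  r2 <- select_representatives(mk_probe_map(close2, sc(close2, c(0.9, 0.8))), cfg)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$score, 0.9)

  far2 <- rbind(c(0, 0, 0), c(0, 0, 3))
  r3 <- select_representatives(mk_probe_map(far2, sc(far2, c(0.9, 0.8))), cfg)
  expect_equal(nrow(r3), 2)
})

random_map <- function(n, seed, planted_boundaries = TRUE) {
  set.seed(seed)
  pts <- matrix(runif(3 * n, 0, 3.5), n, 3)
  scores <- matrix(0, n, 5, dimnames = list(NULL, c("HBD", "HBA", "POS",
                                                    "NEG", "HYDROPHOBIC")))
  for (p in colnames(scores)) {
    nz <- runif(n) < 0.6
    scores[nz, p] <- round(runif(sum(nz)), 3)
  }
  if (planted_boundaries && n >= 6) {
    scores[1, "HBD"] <- 0.15; scores[2, "HBA"] <- 0.149
    scores[3, "HYDROPHOBIC"] <- 0.2; scores[4, "POS"] <- 0.5
    scores[5, "NEG"] <- 0.5; scores[6, "POS"] <- 0.499
  }
  mk_probe_map(pts, scores)
}

test_that("the full filter pipeline matches the brute-force oracle on random maps", {
  for (seed in 1:25) {
    n <- sample(20:120, 1)
    map <- random_map(n, seed)
    got <- extract_pt1(map, cfg)
    want <- oracle_pt1(map$grid$points, map$scores, cfg)
    got <- got[order(got$type, got$x, got$y, got$z), ]
    want <- want[order(want$type, want$x, want$y, want$z), ]
    expect_equal(got$type, want$type)
    expect_equal(got$x, want$x)
    expect_equal(got$score, want$score)
  }
})

test_that("pipeline output is invariant to grid-point input order", {
  map <- random_map(80, 99)
  base <- extract_pt1(map, cfg)
  set.seed(1)
  perm <- sample(nrow(map$grid$points))
  shuffled <- mk_probe_map(map$grid$points[perm, ], map$scores[perm, ])
  again <- extract_pt1(shuffled, cfg)
  o1 <- base[order(base$type, base$x, base$y, base$z), ]
  o2 <- again[order(again$type, again$x, again$y, again$z), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("emitted representatives dominate their neighbourhood and are well separated", {
  loose <- filter_config(neighbor_threshold = c(HBD = 1, HBA = 1, POS = 1,
                                                NEG = 1, HYDROPHOBIC = 1))
  for (seed in 26:35) {
    map <- random_map(100, seed)
    filtered <- neighbor_filter(threshold_map(map, loose), loose)
    reps <- select_representatives(filtered, loose)
    for (p in unique(reps$type)) {
      sel <- reps[reps$type == p, , drop = FALSE]
      if (nrow(sel) > 1) {
        d <- as.matrix(dist(cbind(sel$x, sel$y, sel$z)))
        expect_gt(min(d[upper.tri(d)]), 2.5)
      }
      # every suppressed point lies within 2.5 A of some representative
      # whose score is at least its own (greedy-NMS domination)
      nzpts <- filtered$grid$points[filtered$scores[, p] > 0, , drop = FALSE]
      nzsc <- filtered$scores[filtered$scores[, p] > 0, p]
      for (j in seq_along(nzsc)) {
        d <- sqrt((sel$x - nzpts[j, 1])^2 + (sel$y - nzpts[j, 2])^2 +
                  (sel$z - nzpts[j, 3])^2)
        expect_true(any(d <= 2.5 + 1e-9 & sel$score >= nzsc[j] - 1e-12))
      }
    }
  }
})

test_that("filter configuration round-trips through the key-value file", {
  f <- tempfile(fileext = ".cfg")
  write_filter_config(cfg, f)
  back <- read_filter_config(f)
  expect_equal(back$score_threshold, cfg$score_threshold)
  expect_equal(back$neighbor_threshold, cfg$neighbor_threshold)
  expect_equal(back$representative_radius, cfg$representative_radius)
  expect_equal(back$merge_radius, cfg$merge_radius)
  expect_error(filter_config(representative_radius = -1), "radii")
})
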