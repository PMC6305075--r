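# Small vector-geometry helpers shared across modules. All coordinates are in
# Angstrom; direction vectors are unit-norm numeric(3).

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# angle between two vectors, degrees
vangle <- function(a, b) {
  ca <- sum(unitv(a) * unitv(b))
  ca <- max(-1, min(1, ca))
  acos(ca) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# deterministic vector perpendicular to u (unit input not required)
perp_vector <- function(u) {
  u <- unitv(u)
  ref <- if (abs(u[1]) <= abs(u[2]) && abs(u[1]) <= abs(u[3])) {
    c(1, 0, 0)
  } else if (abs(u[2]) <= abs(u[3])) c(0, 1, 0) else c(0, 0, 1)
  unitv(cross3(u, ref))
}

# rotate vector v about unit axis k by angle degrees (Rodrigues)
rotate_about <- function(v, k, angle_deg) {
  k <- unitv(k)
  th <- angle_deg * pi / 180
  v * cos(th) + cross3(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

# n x 3 matrix of squared distances ... returns distances from each row of m
# (n x 3) to point p (length 3)
dist_to_point <- function(m, p) {
  sqrt((m[, 1] - p[1])^2 + (m[, 2] - p[2])^2 + (m[, 3] - p[3])^2)
}

# pairwise distances between rows of a (n x 3) and rows of b (m x 3)
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

as_mat3 <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  stopifnot(ncol(m) == 3)
  dimnames(m) <- NULL
  m
}

# empty feature-point data frame; the common currency of the pipeline
empty_features <- function() {
  data.frame(type = character(0), x = numeric(0), y = numeric(0),
             z = numeric(0), score = numeric(0),
             dx = numeric(0), dy = numeric(0), dz = numeric(0),
             tol = numeric(0), provenance = character(0),
             stringsAsFactors = FALSE)
}

feature_row <- function(type, pos, score = 0, dir = c(NA_real_, NA_real_, NA_real_),
                        tol = 1.5, provenance = "PT1") {
  pos <- pos + 0  # normalize IEEE negative zeros for stable serialization
  dir <- dir + 0
  data.frame(type = type, x = pos[1], y = pos[2], z = pos[3], score = score,
             dx = dir[1], dy = dir[2], dz = dir[3], tol = tol,
             provenance = provenance, stringsAsFactors = FALSE)
}

feature_coords <- function(features) {
  cbind(features$x, features$y, features$z)
}

FEATURE_TYPES <- c("HBD", "HBA", "POS", "NEG", "HYDROPHOBIC", "AROMATIC")
POLAR_TYPES <- c("HBD", "HBA", "POS", "NEG")
PROBE_TYPES <- c("HBD", "HBA", "POS", "NEG", "HYDROPHOBIC")
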