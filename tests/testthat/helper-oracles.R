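# Independent oracles and geometric fixtures. Everything here deliberately
# avoids the package's own code paths for the quantity being checked.

# direct per-point summation of the inertia tensor (loop, no linear algebra)
oracle_inertia <- function(points) {
  ctr <- unname(colMeans(points))
  tensor <- matrix(0, 3, 3)
  for (i in seq_len(nrow(points))) {
    r <- as.numeric(points[i, ]) - ctr
    tensor <- tensor + sum(r^2) * diag(3) - r %*% t(r)
  }
  list(tensor = tensor, centroid = ctr)
}

mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(n^2))) / 2
}

# single tetrahedron mesh
tetra_mesh <- function() {
  tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
}

# open cylinder (no caps), axis +z, base at z = 0
cylinder_mesh <- function(radius = 5, height = 100, n_seg = 48,
                          n_ring = 80) {
  phi <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  z <- seq(0, height, length.out = n_ring)
  verts <- do.call(rbind, lapply(z, function(zz) {
    cbind(radius * cos(phi), radius * sin(phi), zz)
  }))
  idx <- function(i, j) (i - 1) * n_seg + ((j - 1) %% n_seg) + 1
  js <- seq_len(n_seg)
  faces <- do.call(rbind, lapply(seq_len(n_ring - 1), function(i) {
    rbind(cbind(idx(i, js), idx(i, js + 1), idx(i + 1, js + 1)),
          cbind(idx(i, js), idx(i + 1, js + 1), idx(i + 1, js)))
  }))
  tri_mesh(verts, faces)
}

icosahedron_points <- function() {
  p <- (1 + sqrt(5)) / 2
  rbind(c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
        c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
        c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
}

# uniform random rotation from a random quaternion (independent of the
# package's rotation code)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# rotation moving the z-axis by at most max_deg (for equivariance sampling)
random_small_rotation <- function(max_deg = 60) {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, max_deg * pi / 180)
  k <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(ang) * k + (1 - cos(ang)) * k %*% k
}

# exhaustive-enumeration two-sided p for a two-sample linear rank statistic;
# statistic(xs) = sum of per-observation scores over the first-sample subset
oracle_exact_rank_p <- function(scores, na, observed) {
  splits <- utils::combn(length(scores), na)
  dist <- apply(splits, 2, function(ix) sum(scores[ix]))
  p_lo <- mean(dist <= observed + 1e-9)
  p_hi <- mean(dist >= observed - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

oracle_mw_u <- function(a, b) {
  sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
}

oracle_ab_scores <- function(pooled) {
  r <- rank(pooled)
  pmin(r, length(pooled) + 1 - r)
}

# ICC(A,1) via an explicit aov() ANOVA decomposition
oracle_icc_a1 <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# consistency (non-absolute) ICC from the same mean squares
oracle_icc_consistency <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][, "Mean Sq"]
  (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3])
}

axis_angle_deg <- function(rot) {
  acos(max(-1, min(1, (sum(diag(rot)) - 1) / 2))) * 180 / pi
}
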