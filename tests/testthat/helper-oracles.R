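# Independent oracles used across tests. These deliberately re-derive
# quantities with different code paths than the package implementation.

# Benjamini-Hochberg step-up, written longhand from the definition.
bh_brute_force <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Partial correlation via explicit projection-matrix residualization.
partial_r_brute_force <- function(x, y, C) {
  M <- cbind(1, C)
  P <- diag(length(x)) - M %*% solve(crossprod(M)) %*% t(M)
  as.numeric(stats::cor(P %*% x, P %*% y))
}

# Point-in-cylinder voxel count by explicit per-voxel geometry (point-to-line
# distance via cross product, independent of the generator's projection math).
cylinder_count_brute_force <- function(dim3, voxel_size, start, end, radius) {
  u <- (end - start) / sqrt(sum((end - start)^2))
  L <- sqrt(sum((end - start)^2))
  count <- 0L
  for (i in seq_len(dim3[1])) for (j in seq_len(dim3[2])) for (k in seq_len(dim3[3])) {
    p <- (c(i, j, k) - 1) * voxel_size - start
    t_ax <- sum(p * u)
    cr <- c(p[2] * u[3] - p[3] * u[2],
            p[3] * u[1] - p[1] * u[3],
            p[1] * u[2] - p[2] * u[1])
    if (t_ax >= 0 && t_ax <= L && sum(cr^2) <= radius^2 + 1e-12) count <- count + 1L
  }
  count
}

# Two-way mean squares for the agreement ICC, via aov() rather than closed
#-form row/column means.
icc_oracle <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(
    y = as.vector(ratings),
    subj = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

dice_coefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Minimal 6-direction scheme containing the coordinate axes, for hand checks.
axis_scheme <- function(n_b0 = 1L, bvalue = 1000) {
  s <- 1 / sqrt(2)
  dirs <- cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(s, s, 0), c(s, 0, s), c(0, s, s))
  list(bvalues = c(rep(0, n_b0), rep(bvalue, 6)),
       bvecs = cbind(matrix(0, 3, n_b0), dirs))
}
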