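# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# Two well-separated Gaussian blobs with the given per-class counts.
make_blobs <- function(counts, separation = 8, sd = 0.5, d = 2, seed = 1) {
  generate_feature_dataset(counts, separation = separation, noise_sd = sd,
                           n_features = max(d, length(counts)),
                           rng = rng_handle(seed))
}

# Brute-force k nearest neighbours of row i among `pool` rows of X
# (Euclidean), excluding i itself. Independent of the package's knn code.
brute_knn <- function(X, i, pool, k) {
  pool <- setdiff(pool, i)
  d <- sqrt(colSums((t(X[pool, , drop = FALSE]) - X[i, ])^2))
  pool[order(d)][seq_len(min(k, length(pool)))]
}

# Does `p` lie on the closed segment between `a` and `b` (within tol)?
on_segment <- function(p, a, b, tol = 1e-9) {
  ab <- b - a
  denom <- sum(ab^2)
  if (denom == 0) return(sqrt(sum((p - a)^2)) <= tol)
  t <- sum((p - a) * ab) / denom
  t >= -tol && t <= 1 + tol && sqrt(sum((p - (a + t * ab))^2)) <= tol
}

# Is `p` inside the closed triangle (a, b, c)? Solved via least squares in
# barycentric coordinates; degenerate triangles fall back to segment tests.
in_triangle <- function(p, a, b, c, tol = 1e-8) {
  M <- cbind(b - a, c - a)
  sol <- tryCatch(qr.solve(M, p - a, tol = 1e-12), error = function(e) NULL)
  if (!is.null(sol) && sqrt(sum((M %*% sol - (p - a))^2)) <= tol) {
    u <- sol[1]; v <- sol[2]
    return(u >= -tol && v >= -tol && u + v <= 1 + tol)
  }
  on_segment(p, a, b, tol) || on_segment(p, a, c, tol) ||
    on_segment(p, b, c, tol)
}
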