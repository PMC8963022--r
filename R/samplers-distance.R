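# Pairwise-distance and k-nearest-neighbour helpers shared by all samplers.
# Datasets here are small (hundreds of windows), so exact O(n^2) search via
# stats::dist is both simplest and fastest.

dist_matrix <- function(X) {
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  D
}

# k nearest rows of `pool_idx` (indices into X) for each row of `query_idx`,
# excluding the query row itself. Returns a list of integer vectors of
# indices into X. Ties broken by row order (stable).
knn_lists <- function(X, query_idx, pool_idx, k) {
  lapply(query_idx, function(i) {
    cand <- setdiff(pool_idx, i)
    if (length(cand) == 0L) return(integer(0))
    d <- sqrt(colSums((t(X[cand, , drop = FALSE]) - X[i, ])^2))
    cand[order(d)][seq_len(min(k, length(cand)))]
  })
}

# Shared interpolation core. Given seed row indices (into X) and a
# per-row list of candidate neighbours, draws one neighbour uniformly and an
# interpolation coefficient u in [0,1), and emits
#   x_new = x_seed + u * (x_neighbour - x_seed).
# Seeds with no candidate neighbour duplicate themselves (neighbour -1,
# u recorded as NA). RNG call sequence: one uniform vector for neighbour
# selection, one for u — identical across every method that routes through
# this core, which is what makes SMOTE and all-safe MSMOTE bit-identical
# under a shared seed.
interp_core <- function(X, seed_rows, nbr_lists_of, rng, method) {
  n_syn <- length(seed_rows)
  d <- ncol(X)
  if (n_syn == 0L) return(empty_batch(d, method))
  usel <- rng_uniform(rng, n_syn)
  u <- rng_uniform(rng, n_syn)
  nbr <- integer(n_syn)
  for (s in seq_len(n_syn)) {
    cand <- nbr_lists_of(seed_rows[s])
    if (length(cand) == 0L) {
      nbr[s] <- -1L
    } else {
      nbr[s] <- cand[pmin(length(cand), floor(usel[s] * length(cand)) + 1L)]
    }
  }
  X_syn <- X[seed_rows, , drop = FALSE]
  has_nbr <- nbr > 0L
  if (any(has_nbr)) {
    i <- which(has_nbr)
    X_syn[i, ] <- X_syn[i, , drop = FALSE] +
      u[i] * (X[nbr[i], , drop = FALSE] - X_syn[i, , drop = FALSE])
  }
  u[!has_nbr] <- NA_real_
  prov <- data.frame(method = method, seed_index = seed_rows,
                     neighbor_index = nbr, u = u)
  list(X_syn = X_syn, nbr = nbr, u = u, prov = prov)
}

#' SMOTE: synthetic minority oversampling by k-NN interpolation
#'
#' For each synthetic row, a seed is drawn uniformly (with replacement) from
#' the minority set, one of its `k` nearest same-class neighbours (Euclidean
#' metric) is drawn uniformly, and the synthetic point is placed at
#' `seed + u * (neighbour - seed)` with `u ~ Uniform[0, 1)` — on the closed
#' segment between the two points, never beyond it.
#'
#' @param minority_X numeric matrix of minority-class rows (`>= 1` row; a
#'   single row degenerates to duplicating that row).
#' @param k neighbourhood size; capped at `nrow(minority_X) - 1`.
#' @param n_synth number of synthetic rows to generate.
#' @param rng an [rng_handle()].
#' @return a `synthetic_batch` whose provenance records the seed row, the
#'   chosen neighbour row (`-1` if none exists) and the interpolation draw.
#' @export
smote_generate <- function(minority_X, k, n_synth, rng) {
  minority_X <- as.matrix(minority_X)
  n_min <- nrow(minority_X)
  if (n_min == 0L) stop("minority class is empty")
  if (n_synth == 0L) return(empty_batch(ncol(minority_X), "SMOTE"))
  nbrs <- knn_lists(minority_X, seq_len(n_min), seq_len(n_min), k)
  seeds <- rng_integers(rng, n_synth, n_min)
  core <- interp_core(minority_X, seeds, function(i) nbrs[[i]], rng, "SMOTE")
  synthetic_batch(core$X_syn, rep(NA_integer_, n_synth), core$prov, "SMOTE")
}

#' Random-SMOTE: interpolation inside minority triangles
#'
#' For each synthetic row, a seed `x` is drawn uniformly from the minority
#' set and two further distinct minority rows `x1`, `x2` (both different
#' from `x`) are drawn uniformly. A temporary point
#' `x_tmp = x1 + u1 (x2 - x1)` is placed on the segment between `x1` and
#' `x2`, and the synthetic point `x + u2 (x_tmp - x)` on the segment between
#' `x` and `x_tmp` — hence inside the closed triangle `(x, x1, x2)`. This
#' opens a 2-D region for synthesis instead of SMOTE's 1-D segments.
#'
#' With fewer than 3 minority rows the method falls back to
#' [smote_generate()] with `k = 1` (documented degenerate behaviour; the
#' provenance `method` column records the fallback).
#'
#' @param minority_X numeric matrix of minority-class rows.
#' @param n_synth number of synthetic rows.
#' @param rng an [rng_handle()].
#' @return a `synthetic_batch`; provenance columns `x1_index`, `x2_index`,
#'   `u1`, `u2` record the triangle and the two draws.
#' @export
random_smote_generate <- function(minority_X, n_synth, rng) {
  minority_X <- as.matrix(minority_X)
  n_min <- nrow(minority_X)
  if (n_min == 0L) stop("minority class is empty")
  if (n_synth == 0L) return(empty_batch(ncol(minority_X), "RANDOM_SMOTE"))
  if (n_min < 3L) {
    b <- smote_generate(minority_X, 1L, n_synth, rng)
    b$method <- "RANDOM_SMOTE"
    b$provenance$method <- "RANDOM_SMOTE(smote_fallback)"
    return(b)
  }
  seeds <- rng_integers(rng, n_synth, n_min)
  x1 <- integer(n_synth); x2 <- integer(n_synth)
  for (s in seq_len(n_synth)) {
    pair <- with_rng(rng, sample(setdiff(seq_len(n_min), seeds[s]), 2L))
    x1[s] <- pair[1L]; x2[s] <- pair[2L]
  }
  u1 <- rng_uniform(rng, n_synth)
  u2 <- rng_uniform(rng, n_synth)
  X_tmp <- minority_X[x1, , drop = FALSE] +
    u1 * (minority_X[x2, , drop = FALSE] - minority_X[x1, , drop = FALSE])
  X_syn <- minority_X[seeds, , drop = FALSE] +
    u2 * (X_tmp - minority_X[seeds, , drop = FALSE])
  prov <- data.frame(method = "RANDOM_SMOTE", seed_index = seeds,
                     neighbor_index = -1L, u = u2,
                     x1_index = x1, x2_index = x2, u1 = u1, u2 = u2)
  synthetic_batch(X_syn, rep(NA_integer_, n_synth), prov, "RANDOM_SMOTE")
}
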