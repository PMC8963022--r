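#' Agglomerative clustering of a minority class (CBSO step 1)
#'
#' Average-linkage agglomerative clustering of the minority rows, cut at the
#' height `T = cluster_threshold_factor * mean(nearest-minority-neighbour
#' distance)`. Singleton clusters are permitted; a one-row input forms one
#' singleton cluster.
#'
#' @param minority_X numeric matrix of minority-class rows.
#' @param cluster_threshold_factor multiplier on the mean nearest-neighbour
#'   distance (default 3).
#' @return list with `cluster` (integer id per row) and `threshold` (the cut
#'   height used; `0` for a single row).
#' @export
cbso_cluster <- function(minority_X, cluster_threshold_factor = 3) {
  minority_X <- as.matrix(minority_X)
  n <- nrow(minority_X)
  stopifnot(n >= 1L)
  if (n == 1L) return(list(cluster = 1L, threshold = 0))
  d_obj <- stats::dist(minority_X)
  D <- as.matrix(d_obj)
  diag(D) <- Inf
  threshold <- cluster_threshold_factor * mean(apply(D, 1L, min))
  hc <- stats::hclust(d_obj, method = "average")
  cl <- stats::cutree(hc, h = threshold)
  list(cluster = as.integer(cl), threshold = threshold)
}

# CBSO generation for one minority class: seeds are drawn with probability
# proportional to their border weight (the fraction of other-class points
# among their k all-class nearest neighbours; uniform when all weights are
# zero), the interpolation partner is drawn uniformly from the seed's own
# cluster, so no synthetic point ever crosses a cluster boundary. Singleton
# cluster seeds duplicate themselves.
cbso_generate_class <- function(ds, class_idx, n_synth, k,
                                cluster_threshold_factor, rng) {
  rows <- which(ds$y == class_idx)
  minX <- ds$X[rows, , drop = FALSE]
  n_min <- nrow(minX)
  clus <- cbso_cluster(minX, cluster_threshold_factor)
  nbrs_all <- knn_lists(ds$X, rows, seq_len(nrow(ds$X)),
                        min(k, nrow(ds$X) - 1L))
  w <- vapply(seq_len(n_min), function(j) {
    mean(ds$y[nbrs_all[[j]]] != class_idx)
  }, numeric(1))
  if (sum(w) == 0) w <- rep(1, n_min)
  mates <- lapply(seq_len(n_min), function(j) {
    setdiff(which(clus$cluster == clus$cluster[j]), j)
  })
  seeds <- with_rng(rng, sample.int(n_min, n_synth, replace = TRUE,
                                    prob = w / sum(w)))
  core <- interp_core(minX, seeds, function(i) mates[[i]], rng, "CBSO")
  core$prov$cluster <- clus$cluster[core$prov$seed_index]
  list(X_syn = core$X_syn, prov = core$prov, rows = rows, clustering = clus)
}

#' Proximity-level partition of a minority class (ProWSyn step 1)
#'
#' Iterative peeling from the class boundary: level `l` collects every
#' not-yet-assigned minority row that appears among the `k` nearest
#' remaining minority neighbours of any other-class row; assigned rows are
#' removed and the peel repeats. After `max_levels - 1` peels, all remaining
#' rows receive level `max_levels`. Level weights decay exponentially with
#' distance from the boundary, `w(l) = exp(-theta * (l - 1))` (normalised),
#' and the per-level synthetic allocation is proportional to the total row
#' weight of the level, rounded with largest-remainder correction so
#' allocations sum exactly to `n_synth`.
#'
#' @param ds a [feature_dataset()] containing minority and other classes.
#' @param class minority class name to partition.
#' @param k neighbourhood size for the peel.
#' @param max_levels maximum proximity level.
#' @param theta weight decay rate (`>= 0`).
#' @param n_synth if supplied, per-level allocations are computed.
#' @return list with `rows` (minority row indices into `ds`), `level`
#'   (integer per minority row), `weights` (per-level, normalised over
#'   `max_levels` levels) and `allocation` (per-level counts, or `NULL`).
#' @export
prowsyn_partition <- function(ds, class, k = 5L, max_levels = 5L, theta = 1,
                              n_synth = NULL) {
  validate_dataset(ds)
  class_idx <- match(class, ds$class_names)
  stopifnot(!is.na(class_idx))
  max_levels <- as.integer(max_levels)
  k <- as.integer(k)
  rows <- which(ds$y == class_idx)
  others <- which(ds$y != class_idx)
  stopifnot(length(rows) >= 1L, length(others) >= 1L)
  level <- rep(NA_integer_, length(rows))
  remaining <- seq_along(rows)
  for (l in seq_len(max_levels - 1L)) {
    if (length(remaining) == 0L) break
    hit <- integer(0)
    for (m in others) {
      cand <- rows[remaining]
      d <- sqrt(colSums((t(ds$X[cand, , drop = FALSE]) - ds$X[m, ])^2))
      hit <- union(hit, remaining[order(d)][seq_len(min(k, length(cand)))])
    }
    level[hit] <- l
    remaining <- setdiff(remaining, hit)
  }
  level[remaining] <- max_levels
  w <- exp(-theta * (seq_len(max_levels) - 1))
  w <- w / sum(w)
  allocation <- NULL
  if (!is.null(n_synth)) {
    allocation <- allocate_largest_remainder(
      vapply(seq_len(max_levels), function(l) sum(level == l) * w[l],
             numeric(1)),
      n_synth
    )
  }
  list(rows = rows, level = level, weights = w, allocation = allocation)
}

# Distribute n_total over groups proportionally to `shares`, flooring and
# then topping up by largest fractional remainder (ties -> earlier group),
# so the result sums exactly to n_total.
allocate_largest_remainder <- function(shares, n_total) {
  if (sum(shares) == 0) shares <- rep(1, length(shares))
  exact <- n_total * shares / sum(shares)
  base <- floor(exact)
  short <- n_total - sum(base)
  if (short > 0) {
    frac <- exact - base
    top <- order(-frac, seq_along(frac))[seq_len(short)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}

# ProWSyn generation for one minority class: each level generates its
# allocated count by SMOTE-style interpolation between members of the same
# level (k nearest same-level neighbours; a singleton level duplicates its
# member). Levels closer to the boundary carry larger weights and therefore
# larger allocations.
prowsyn_generate_class <- function(ds, class_idx, n_synth, k, max_levels,
                                   theta, rng) {
  part <- prowsyn_partition(ds, ds$class_names[class_idx], k = k,
                            max_levels = max_levels, theta = theta,
                            n_synth = n_synth)
  rows <- part$rows
  minX <- ds$X[rows, , drop = FALSE]
  pieces <- list()
  for (l in seq_len(max_levels)) {
    n_l <- part$allocation[l]
    if (n_l == 0L) next
    members <- which(part$level == l)
    if (length(members) == 0L) next
    nbrs <- knn_lists(minX, members, members, k)
    lookup <- integer(nrow(minX)); lookup[members] <- seq_along(members)
    seeds <- members[rng_integers(rng, n_l, length(members))]
    core <- interp_core(minX, seeds, function(i) nbrs[[lookup[i]]], rng,
                        "PROWSYN")
    core$prov$level <- l
    pieces[[length(pieces) + 1L]] <- core
  }
  X_syn <- do.call(rbind, c(list(matrix(numeric(0), 0L, ncol(minX))),
                            lapply(pieces, `[[`, "X_syn")))
  prov <- do.call(rbind, lapply(pieces, `[[`, "prov"))
  if (is.null(prov)) {
    prov <- data.frame(method = character(0), seed_index = integer(0),
                       neighbor_index = integer(0), u = numeric(0),
                       level = integer(0))
  }
  list(X_syn = X_syn, prov = prov, rows = rows, partition = part)
}
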