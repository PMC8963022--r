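#' Find Tomek links in a labelled dataset
#'
#' A Tomek link is a pair of points `(a, b)` with different class labels such
#' that no third point `z` satisfies `d(a, z) < d(a, b)` or
#' `d(b, z) < d(a, b)` — i.e. the two points are each other's nearest
#' neighbours under the Euclidean metric. Such pairs sit on the class
#' boundary or are label noise.
#'
#' @param X numeric matrix, `n >= 2` rows.
#' @param y per-row labels (any atomic type).
#' @return data.frame with columns `a`, `b` (row indices, `a < b`), one row
#'   per link; zero rows when no link exists.
#' @export
find_tomek_links <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 2L, length(y) == n)
  D <- dist_matrix(X)
  nnd <- apply(D, 1L, min)
  y <- as.character(y)
  link <- upper.tri(D) & outer(y, y, "!=") &
    D <= matrix(nnd, n, n) & D <= matrix(nnd, n, n, byrow = TRUE)
  hits <- which(link, arr.ind = TRUE)
  if (nrow(hits) == 0L) {
    return(data.frame(a = integer(0), b = integer(0)))
  }
  ord <- order(hits[, 1L], hits[, 2L])
  data.frame(a = as.integer(hits[ord, 1L]), b = as.integer(hits[ord, 2L]))
}

# SMOTE oversampling of every minority class followed by Tomek-link
# cleaning of the augmented set; both endpoints of every link are removed
# (original or synthetic alike). Used as the first NDBM constituent and as
# the SMOTE_TOMEKLINKS method of oversample(). Returns the cleaned batch,
# the indices of removed *original* rows, and a cleaning log.
smote_tomeklinks_core <- function(ds, spec, rng) {
  n_orig <- nrow(ds$X)
  batch <- dataset_smote_batch(ds, spec, rng, method = "SMOTE_TOMEKLINKS")
  aug_X <- rbind(ds$X, batch$X_syn)
  aug_y <- c(ds$y, batch$y_syn)
  links <- find_tomek_links(aug_X, ds$class_names[aug_y])
  removed <- sort(unique(c(links$a, links$b)))
  removed_orig <- removed[removed <= n_orig]
  removed_syn <- removed[removed > n_orig] - n_orig
  if (length(removed_syn)) {
    keep <- setdiff(seq_len(nrow(batch$X_syn)), removed_syn)
    batch <- synthetic_batch(batch$X_syn[keep, , drop = FALSE],
                             batch$y_syn[keep],
                             batch$provenance[keep, , drop = FALSE],
                             batch$method)
  }
  list(batch = batch, removed = removed_orig,
       log = list(links = links, removed_original = removed_orig,
                  removed_synthetic = removed_syn,
                  removed_classes = ds$class_names[aug_y[removed]]))
}

#' Type minority samples as safe, border or noise (MSMOTE)
#'
#' Each row of every non-majority class is typed by the class composition of
#' its `k` nearest neighbours in the full training set (all classes,
#' excluding the row itself): `safe` when all `k` neighbour labels equal the
#' row's class, `noise` when none do, `border` otherwise.
#'
#' @param ds a [feature_dataset()].
#' @param k neighbourhood size; clipped to `n - 1` when fewer other points
#'   exist (the clip is recorded in the `k_used` attribute).
#' @return data.frame with columns `row` (index into `ds`), `class`, and
#'   `type` (factor safe/border/noise); one row per minority sample.
#' @export
msmote_type <- function(ds, k = 5L) {
  validate_dataset(ds)
  cc <- class_counts(ds)
  maj <- match(cc$majority, ds$class_names)
  min_rows <- which(ds$y != maj)
  n <- nrow(ds$X)
  k_used <- min(k, n - 1L)
  nbrs <- knn_lists(ds$X, min_rows, seq_len(n), k_used)
  same <- vapply(seq_along(min_rows), function(j) {
    sum(ds$y[nbrs[[j]]] == ds$y[min_rows[j]])
  }, integer(1))
  type <- ifelse(same == k_used, "safe", ifelse(same == 0L, "noise", "border"))
  out <- data.frame(row = min_rows,
                    class = ds$class_names[ds$y[min_rows]],
                    type = factor(type, levels = c("safe", "border", "noise")))
  attr(out, "k_used") <- k_used
  out
}

# MSMOTE generation for one minority class. Noise-typed rows are excluded
# both as seeds and from the neighbour candidate pool; safe seeds
# interpolate toward one of their k nearest same-class (non-noise)
# neighbours, border seeds only toward their single nearest one. When every
# row is safe this reduces exactly to smote_generate on the class rows (same
# RNG call sequence through interp_core).
msmote_generate_class <- function(ds, class_idx, n_synth, k, rng) {
  rows <- which(ds$y == class_idx)
  typing <- msmote_type(ds, k)
  typing <- typing[typing$row %in% rows, , drop = FALSE]
  pool_local <- which(typing$type != "noise")   # positions within `rows`
  if (length(pool_local) == 0L) {
    stop("no eligible seeds: all minority rows of class '",
         ds$class_names[class_idx], "' typed as noise")
  }
  minX <- ds$X[rows, , drop = FALSE]
  nbrs <- knn_lists(minX, pool_local, pool_local, k)
  kk <- ifelse(typing$type[pool_local] == "border", 1L, k)
  nbrs <- lapply(seq_along(nbrs), function(j) {
    utils::head(nbrs[[j]], kk[j])
  })
  seeds_pos <- rng_integers(rng, n_synth, length(pool_local))
  seeds <- pool_local[seeds_pos]
  lookup <- integer(nrow(minX)); lookup[pool_local] <- seq_along(pool_local)
  core <- interp_core(minX, seeds, function(i) nbrs[[lookup[i]]], rng,
                      "MSMOTE")
  core$prov$type <- as.character(typing$type[core$prov$seed_index])
  list(X_syn = core$X_syn, prov = core$prov, rows = rows, typing = typing)
}
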