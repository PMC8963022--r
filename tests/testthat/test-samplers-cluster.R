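# Single-threshold clustering oracle: connected components of the graph
# linking points closer than the cut height. For well-separated blobs this
# coincides with average-linkage clustering cut at the same height.
oracle_components <- function(X, h) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (D[i, j] <= h && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

test_that("agglomerative clustering separates distant minority blobs", {
  # two compact quintets far apart: every within-blob distance is well
  # below the cut height, the between-blob distance far above it, so
  # average linkage and the single-threshold component oracle coincide
  quintet <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(0.1, 0.1), c(0.05, 0.05))
  minX <- rbind(quintet, quintet + 100)
  cl <- cbso_cluster(minX, cluster_threshold_factor = 3)
  expect_identical(length(unique(cl$cluster)), 2L)
  expect_identical(length(unique(cl$cluster[1:5])), 1L)
  expect_identical(length(unique(cl$cluster[6:10])), 1L)
  canon <- function(v) match(v, unique(v))
  expect_identical(canon(cl$cluster),
                   canon(oracle_components(minX, cl$threshold)))

  same <- matrix(1, 5, 2)
  expect_identical(length(unique(cbso_cluster(same)$cluster)), 1L)
  expect_identical(cbso_cluster(matrix(c(1, 2), 1, 2))$cluster, 1L)
})

test_that("CBSO synthetics never cross cluster boundaries", {
  rng <- rng_handle(7)
  blob1 <- with_rng(rng, matrix(rnorm(16, sd = 0.3), 8, 2))
  blob2 <- with_rng(rng, matrix(rnorm(16, sd = 0.3), 8, 2)) + 60
  majority <- with_rng(rng, matrix(rnorm(120, sd = 0.5), 60, 2)) + 20
  ds <- feature_dataset(rbind(majority, blob1, blob2),
                        rep(c("A", "B"), c(60, 16)))
  res <- oversample(ds, sampler_spec("CBSO"), rng_handle(4))
  prov <- res$batches[[1]]$provenance
  minority_rows <- which(dataset_labels(ds) == "B")
  side <- function(r) ifelse(match(r, minority_rows) <= 8, 1L, 2L)
  has_nbr <- prov$neighbor_index > 0
  expect_gt(sum(has_nbr), 0)
  expect_true(all(side(prov$seed_index[has_nbr]) ==
                    side(prov$neighbor_index[has_nbr])))
  # synthetics sit on within-cluster segments
  for (i in which(has_nbr)) {
    expect_true(on_segment(res$batches[[1]]$X_syn[i, ],
                           ds$X[prov$seed_index[i], ],
                           ds$X[prov$neighbor_index[i], ]))
  }
})

test_that("a singleton cluster seed duplicates itself", {
  rng <- rng_handle(3)
  blob <- with_rng(rng, matrix(rnorm(10, sd = 0.1), 5, 2))
  lone <- c(500, 500)
  maj <- with_rng(rng, matrix(rnorm(40, sd = 1), 20, 2)) + 50
  ds <- feature_dataset(rbind(maj, blob, lone), rep(c("A", "B"), c(20, 6)))
  res <- oversample(ds, sampler_spec("CBSO"), rng_handle(8))
  prov <- res$batches[[1]]$provenance
  lone_rows <- which(prov$seed_index == 26L)
  expect_true(all(prov$neighbor_index[lone_rows] == -1L))
  if (length(lone_rows)) {
    expect_true(all(res$batches[[1]]$X_syn[lone_rows, 1] == 500))
  }
})

test_that("proximity levels peel minority rows boundary-first", {
  # 1-D: majority at 0, minority at -1, -2, -3; k = 1 peels one row per pass
  ds <- feature_dataset(matrix(c(0, -1, -2, -3), 4, 1),
                        c("A", "B", "B", "B"))
  part <- prowsyn_partition(ds, "B", k = 1, max_levels = 3)
  expect_identical(part$level, c(1L, 2L, 3L))
  w <- part$weights
  expect_equal(w, exp(-(0:2)) / sum(exp(-(0:2))))
  expect_true(all(diff(w) < 0))

  part1 <- prowsyn_partition(ds, "B", k = 1, max_levels = 1)
  expect_identical(part1$level, c(1L, 1L, 1L))
  expect_equal(part1$weights, 1)
})

test_that("level allocations use largest-remainder rounding and sum exactly", {
  ds <- feature_dataset(matrix(c(0, -1, -2, -3), 4, 1),
                        c("A", "B", "B", "B"))
  for (n_s in c(1L, 5L, 7L, 100L)) {
    part <- prowsyn_partition(ds, "B", k = 1, max_levels = 3, n_synth = n_s)
    expect_identical(sum(part$allocation), n_s)
    expect_true(all(part$allocation >= 0))
  }
  # weights proportional to exp(-theta (l-1)): lower levels get at least as
  # many synthetics when level sizes are equal
  part <- prowsyn_partition(ds, "B", k = 1, max_levels = 3, n_synth = 30)
  expect_true(all(diff(part$allocation) <= 0))
})

test_that("ProWSyn collapses to within-class SMOTE when one level holds all rows", {
  ds <- make_blobs(c(A = 20L, B = 8L), separation = 12, seed = 5)
  # k >= minority size puts every minority row at level 1
  spec <- sampler_spec("PROWSYN", k_neighbors = 10)
  part <- prowsyn_partition(ds, "B", k = 10, max_levels = 5)
  expect_true(all(part$level == 1L))
  r_pw <- oversample(ds, spec, rng_handle(23))
  minority_rows <- which(dataset_labels(ds) == "B")
  r_sm <- smote_generate(ds$X[minority_rows, ], k = 10, n_synth = 12,
                         rng = rng_handle(23))
  # identical RNG call sequence: the level-1 generator IS within-class SMOTE
  expect_identical(unname(r_pw$batches[[1]]$X_syn), unname(r_sm$X_syn))
})

test_that("a steep weight decay concentrates synthesis at level 1", {
  rng <- rng_handle(19)
  minor <- with_rng(rng, matrix(rnorm(40, sd = 0.6), 20, 2))
  major <- with_rng(rng, matrix(rnorm(80, sd = 0.6), 40, 2)) +
    matrix(c(4, 0), 40, 2, byrow = TRUE)
  ds <- feature_dataset(rbind(major, minor), rep(c("A", "B"), c(40, 20)))
  spec <- sampler_spec("PROWSYN", k_neighbors = 3, theta = 50)
  res <- oversample(ds, spec, rng_handle(6))
  expect_true(all(res$batches[[1]]$provenance$level == 1L))
})
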