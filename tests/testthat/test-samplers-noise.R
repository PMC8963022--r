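# Verbatim-condition Tomek oracle: (a,b) is a link iff the classes differ
# and no z has d(a,z) < d(a,b) or d(b,z) < d(a,b).
oracle_tomek <- function(X, y) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  out <- data.frame(a = integer(0), b = integer(0))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (y[a] == y[b]) next
    z <- setdiff(seq_len(n), c(a, b))
    if (!any(D[a, z] < D[a, b] | D[b, z] < D[a, b])) {
      out <- rbind(out, data.frame(a = a, b = b))
    }
  }
  out
}

test_that("Tomek links are exactly the cross-class mutual nearest neighbours", {
  # two tight same-class clusters far apart: no cross-class nearest pairs
  X <- rbind(matrix(rnorm(20, sd = 0.1), 10, 2),
             matrix(rnorm(20, sd = 0.1) + 50, 10, 2))
  y <- rep(c("A", "B"), each = 10)
  expect_identical(nrow(find_tomek_links(X, y)), 0L)

  # 1-D worked case: A at 0.0 and 1.0, B at 1.1 and 5.0
  X1 <- matrix(c(0, 1, 1.1, 5), 4, 1)
  y1 <- c("A", "A", "B", "B")
  links <- find_tomek_links(X1, y1)
  expect_identical(links, data.frame(a = 2L, b = 3L))

  set.seed(42)
  for (i in 1:5) {
    Xr <- matrix(rnorm(60), 30, 2)
    yr <- sample(c("A", "B", "C"), 30, replace = TRUE)
    expect_identical(find_tomek_links(Xr, yr), oracle_tomek(Xr, yr))
  }
})

test_that("SMOTE+Tomek leaves separable data untouched by cleaning", {
  ds <- make_blobs(c(A = 20L, B = 8L), separation = 20, sd = 0.3, seed = 3)
  res <- oversample(ds, sampler_spec("SMOTE_TOMEKLINKS"), rng_handle(2))
  expect_identical(nrow(res$log$links), 0L)
  expect_length(res$removed, 0)
  expect_true(all(class_counts(res$dataset)$counts == 20L))
})

test_that("SMOTE+Tomek removes a mislabelled point and its partner", {
  rng <- rng_handle(17)
  minor <- with_rng(rng, matrix(rnorm(24, sd = 0.4), 12, 2))
  major <- with_rng(rng, matrix(rnorm(58, sd = 0.4) + 30, 29, 2))
  intruder <- minor[1, ] + c(0.01, 0.01)  # majority point inside the minority cloud
  X <- rbind(major, intruder, minor)
  y <- c(rep("A", 30), rep("B", 12))
  ds <- feature_dataset(X, y)
  res <- oversample(ds, sampler_spec("SMOTE_TOMEKLINKS"), rng_handle(5))
  expect_true(30L %in% unlist(res$log$links))  # the intruder is row 30
  expect_true(30L %in% res$log$removed_original)
  # no links remain in the cleaned output
  out <- res$dataset
  expect_identical(nrow(find_tomek_links(out$X, dataset_labels(out))), 0L)
})

test_that("balanced input with no links is returned unchanged", {
  ds <- make_blobs(c(A = 10L, B = 10L), separation = 20, seed = 9)
  res <- oversample(ds, sampler_spec("SMOTE_TOMEKLINKS"), rng_handle(1))
  expect_identical(res$dataset$X, ds$X)
  expect_identical(res$dataset$y, ds$y)
})

test_that("MSMOTE typing partitions minority rows into safe/border/noise", {
  # 1-D geometry, k = 2: a deep minority pair (safe), one minority point
  # between the classes (border), one lone minority point inside the
  # majority cluster (noise)
  X <- matrix(c(0, 0.1, 9.0, 10, 10.05, 10.1, 10.15, 9.9), ncol = 1)
  y <- c("B", "B", "B", "B", "A", "A", "A", "A")
  ds <- feature_dataset(X, y)
  typing <- msmote_type(ds, k = 2)
  expect_identical(nrow(typing), 4L)  # exactly the minority rows
  tt <- setNames(as.character(typing$type), typing$row)
  expect_identical(tt[["1"]], "safe")
  expect_identical(tt[["2"]], "safe")
  expect_identical(tt[["3"]], "border")
  expect_identical(tt[["4"]], "noise")
  expect_identical(sum(table(typing$type)), 4L)
})

test_that("all-safe MSMOTE is bit-identical to SMOTE under a shared seed", {
  ds <- make_blobs(c(A = 30L, B = 12L), separation = 25, sd = 0.3, seed = 8)
  typing <- msmote_type(ds, k = 5)
  expect_true(all(typing$type == "safe"))
  r_ms <- oversample(ds, sampler_spec("MSMOTE"), rng_handle(55))
  r_sm <- oversample(ds, sampler_spec("SMOTE"), rng_handle(55))
  expect_identical(r_ms$batches[[1]]$X_syn, r_sm$batches[[1]]$X_syn)
})

test_that("noise rows generate nothing and border rows use their nearest neighbour", {
  # class B: a tight cluster of 6, one border point near class A, one noise
  # point deep inside class A
  set.seed(5)
  clusterB <- matrix(rnorm(12, sd = 0.05), 6, 2)
  border <- c(1.8, 0)
  noise <- c(4, 0)
  clusterA <- matrix(rnorm(40, sd = 0.12), 20, 2) + matrix(c(4, 0), 20, 2,
                                                           byrow = TRUE)
  clusterA[1, ] <- c(2.0, 0)  # an A point pulling `border` to border status
  X <- rbind(clusterA, clusterB, border, noise)
  y <- rep(c("A", "B"), c(20, 8))
  ds <- feature_dataset(X, y)
  typing <- msmote_type(ds, k = 5)
  tt <- setNames(as.character(typing$type), typing$row)
  expect_identical(tt[["27"]], "border")
  expect_identical(tt[["28"]], "noise")

  res <- oversample(ds, sampler_spec("MSMOTE"), rng_handle(20))
  prov <- res$batches[[1]]$provenance
  expect_gt(nrow(prov), 0)
  expect_false(28L %in% prov$seed_index)     # noise never seeds
  expect_false(28L %in% prov$neighbor_index) # ... nor serves as a neighbour
  # border seeds interpolate only toward their nearest eligible minority row
  minority_rows <- which(dataset_labels(ds) == "B")
  eligible <- setdiff(minority_rows, c(27L, 28L))  # not the seed, not noise
  border_rows <- prov[prov$seed_index == 27L, ]
  if (nrow(border_rows) > 0) {
    nn <- eligible[which.min(sqrt(colSums(
      (t(ds$X[eligible, , drop = FALSE]) - ds$X[27L, ])^2)))]
    expect_true(all(border_rows$neighbor_index == nn))
  }
})

test_that("an all-noise minority class raises a clear error", {
  X <- rbind(matrix(rnorm(40, sd = 0.1), 20, 2),
             matrix(c(0.01, 0.01), 1, 2))
  y <- c(rep("A", 20), "B")
  ds <- feature_dataset(X, y)
  expect_error(oversample(ds, sampler_spec("MSMOTE"), rng_handle(1)),
               "no eligible seeds")
})
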