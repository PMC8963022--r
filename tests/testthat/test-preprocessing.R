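test_that("magnitude matches the elementwise Euclidean norm", {
  rec <- triaxial_recording(3, 4, 0, "a", 10)
  expect_equal(magnitude(rec), 5)
  rec0 <- triaxial_recording(0, 0, 0, "a", 10)
  expect_equal(magnitude(rec0), 0)

  set.seed(11)
  x <- rnorm(100); y <- rnorm(100); z <- rnorm(100)
  rec <- triaxial_recording(x, y, z, rep("a", 100), 50)
  oracle <- vapply(1:100, function(i) sqrt(x[i]^2 + y[i]^2 + z[i]^2),
                   numeric(1))
  expect_equal(magnitude(rec), oracle, tolerance = 1e-14)
})

test_that("magnitude is invariant under 3-D rotations", {
  set.seed(21)
  V <- matrix(rnorm(300), 100, 3)
  for (i in 1:5) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))  # random orthogonal matrix
    W <- V %*% t(Q)
    m1 <- magnitude(triaxial_recording(V[, 1], V[, 2], V[, 3],
                                       rep("a", 100), 1))
    m2 <- magnitude(triaxial_recording(W[, 1], W[, 2], W[, 3],
                                       rep("a", 100), 1))
    expect_true(max(abs(m1 - m2)) < 1e-9)
  }
})

test_that("segmentation drops the trailing partial window and labels modally", {
  s <- 1:10
  seg <- segment_windows(s, rep("A", 10), window_seconds = 3, sample_rate = 1)
  expect_length(seg$windows, 3)           # floor(10 / 3), sample 10 dropped
  expect_identical(seg$windows[[2]], 4:6)
  expect_identical(seg$labels, rep("A", 3))

  seg2 <- segment_windows(1:3, c("A", "A", "B"), 3, 1,
                          class_names = c("A", "B"))
  expect_identical(seg2$labels, "A")      # modal rule
  seg3 <- segment_windows(1:3, c("B", "A", "B"), 3, 1,
                          class_names = c("A", "B"))
  expect_identical(seg3$labels, "B")
  # modal tie breaks toward the earlier class name
  seg4 <- segment_windows(1:4, c("B", "B", "A", "A"), 4, 1,
                          class_names = c("A", "B"))
  expect_identical(seg4$labels, "A")

  expect_length(segment_windows(1:2, c("A", "A"), 3, 1)$windows, 0)
})

test_that("null-labelled windows are removed before feature extraction", {
  labs <- c(rep("walk", 6), rep("null", 6))
  seg <- segment_windows(1:12, labs, 3, 1, class_names = "walk")
  expect_identical(seg$labels, c("walk", "walk"))
  expect_length(seg$windows, 2)
})

test_that("the six time-domain features satisfy their defining identities", {
  f <- extract_features(c(5, 5, 5))
  expect_equal(unname(f[c("mean", "min", "max", "median")]), rep(5, 4))
  expect_equal(unname(f["std"]), 0)
  expect_equal(unname(f["range"]), 0)

  f2 <- extract_features(c(1, 2, 3, 4))
  expect_equal(unname(f2["mean"]), 2.5)
  expect_equal(unname(f2["std"]), sqrt(1.25))  # population formula
  expect_equal(unname(f2["min"]), 1)
  expect_equal(unname(f2["max"]), 4)
  expect_equal(unname(f2["median"]), 2.5)
  expect_equal(unname(f2["range"]), 3)

  set.seed(31)
  for (i in 1:20) {
    w <- rnorm(sample(3:50, 1))
    f <- extract_features(w)
    expect_equal(unname(f["range"]), max(w) - min(w))
    expect_true(f["min"] <= f["median"] && f["median"] <= f["max"])
    expect_true(f["std"] >= 0)
    # all six are order statistics or moments: permutation invariant
    expect_identical(extract_features(sample(w)), f)
  }
  expect_error(extract_features(numeric(0)), "empty")
})

test_that("the full chain yields one row per non-null window", {
  spec <- scenario_spec(data.frame(
    name = c("walk", "jump"), duration_s = c(60, 12),
    amplitude = c(1, 3), frequency_hz = c(2, 3.2),
    noise_sd = c(0.2, 0.4)), sample_rate = 50)
  rec <- generate_recording(spec, rng_handle(8))
  fds <- features_from_recording(rec, window_seconds = 2)
  expect_identical(ncol(fds$X), 6L)
  cc <- class_counts(fds)$counts
  expect_true(abs(cc[["walk"]] - 30) <= 1)   # 60 s / 2 s windows
  expect_true(abs(cc[["jump"]] - 6) <= 1)
})
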