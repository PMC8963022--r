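#' Feature dataset: matrix of features plus class labels
#'
#' The unit every sampler and classifier in the package consumes: an
#' `n x d` numeric matrix `X`, integer labels `y` indexing into the ordered
#' character vector `class_names`. Labels are stored as indices so that class
#' ordering (used for majority tie-breaks and for score/rank tables) is
#' stable.
#'
#' @param X numeric matrix (or data.frame of numerics), one row per sample.
#' @param labels per-row class labels; character, factor, or integer indices
#'   into `class_names`.
#' @param class_names ordered class names. Defaults to the sorted unique
#'   labels (or factor levels when `labels` is a factor).
#' @return object of class `feature_dataset` with fields `X`, `y`,
#'   `class_names`.
#' @examples
#' ds <- feature_dataset(matrix(rnorm(8), 4, 2), c("A", "A", "B", "B"))
#' class_counts(ds)
#' @export
feature_dataset <- function(X, labels, class_names = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  storage.mode(X) <- "double"
  if (is.null(class_names)) {
    class_names <- if (is.factor(labels)) levels(labels) else
      as.character(sort(unique(as.character(labels))))
  }
  if (is.numeric(labels) && !is.factor(labels)) {
    y <- as.integer(labels)
  } else {
    y <- match(as.character(labels), class_names)
  }
  ds <- structure(
    list(X = X, y = y, class_names = as.character(class_names)),
    class = "feature_dataset"
  )
  validate_dataset(ds)
}

#' Validate a feature dataset's invariants
#'
#' Checks that the matrix has no missing values, every label resolves to a
#' known class name, and dimensions agree. Returns the dataset unchanged if
#' all invariants hold.
#'
#' @param ds a [feature_dataset()].
#' @return `ds`, invisibly unchanged.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "feature_dataset"))
  if (nrow(ds$X) < 1L || ncol(ds$X) < 1L) {
    stop("feature dataset must have at least one row and one feature column")
  }
  if (length(ds$y) != nrow(ds$X)) {
    stop("label vector length (", length(ds$y), ") does not match rows (",
         nrow(ds$X), ")")
  }
  bad <- which(!stats::complete.cases(ds$X) | !is.finite(rowSums(ds$X)))
  if (length(bad)) {
    stop("missing or non-finite feature values in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (anyNA(ds$y) || any(ds$y < 1L) || any(ds$y > length(ds$class_names))) {
    off <- which(is.na(ds$y) | ds$y < 1L | ds$y > length(ds$class_names))
    stop("label(s) in row(s) ", paste(utils::head(off, 5L), collapse = ", "),
         " not found in class_names")
  }
  empty <- setdiff(seq_along(ds$class_names), unique(ds$y))
  if (length(empty)) {
    stop("class(es) with no samples: ",
         paste(ds$class_names[empty], collapse = ", "))
  }
  ds
}

#' Per-class counts and majority class
#'
#' @param ds a [feature_dataset()].
#' @return list with `counts` (named integer vector in `class_names` order,
#'   absent classes counted as zero) and `majority` (class name; ties broken
#'   by `class_names` order).
#' @export
class_counts <- function(ds) {
  stopifnot(inherits(ds, "feature_dataset"))
  counts <- tabulate(ds$y, nbins = length(ds$class_names))
  names(counts) <- ds$class_names
  list(counts = counts, majority = ds$class_names[which.max(counts)])
}

#' Character labels of a feature dataset
#' @param ds a [feature_dataset()].
#' @return character vector of per-row class names.
#' @export
dataset_labels <- function(ds) ds$class_names[ds$y]

#' @export
print.feature_dataset <- function(x, ...) {
  cc <- class_counts(x)
  cat("feature_dataset:", nrow(x$X), "samples x", ncol(x$X), "features\n")
  cat("classes:", paste(sprintf("%s=%d", names(cc$counts), cc$counts),
                        collapse = ", "),
      sprintf("(majority: %s)\n", cc$majority))
  invisible(x)
}

# Subset rows of a feature dataset, keeping the class dictionary.
dataset_subset <- function(ds, idx) {
  structure(
    list(X = ds$X[idx, , drop = FALSE], y = ds$y[idx],
         class_names = ds$class_names),
    class = "feature_dataset"
  )
}

# Append rows (matrix + integer labels) to a feature dataset.
dataset_rbind <- function(ds, X_new, y_new) {
  if (length(y_new) == 0L) return(ds)
  structure(
    list(X = rbind(ds$X, X_new), y = c(ds$y, as.integer(y_new)),
         class_names = ds$class_names),
    class = "feature_dataset"
  )
}

#' Tri-axial accelerometer recording
#'
#' Raw labelled acceleration stream from a single body-worn 3-axis
#' accelerometer, the input of the preprocessing chain. Labels are per-sample
#' activity names and may include an explicit null/background class.
#'
#' @param x,y,z numeric acceleration series of equal length.
#' @param labels per-sample activity labels (character or factor).
#' @param sample_rate sampling rate in Hz, positive.
#' @param t optional time stamps; defaults to `(0:(n-1)) / sample_rate`.
#' @return object of class `triaxial_recording`.
#' @export
triaxial_recording <- function(x, y, z, labels, sample_rate, t = NULL) {
  n <- length(x)
  if (length(y) != n || length(z) != n || length(labels) != n) {
    stop("x, y, z and labels must have equal length")
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be positive")
  }
  if (is.null(t)) t <- (seq_len(n) - 1L) / sample_rate
  structure(
    list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
         z = as.numeric(z), labels = as.character(labels),
         sample_rate = as.numeric(sample_rate)),
    class = "triaxial_recording"
  )
}

#' @export
print.triaxial_recording <- function(x, ...) {
  cat("triaxial_recording:", length(x$x), "samples @", x$sample_rate, "Hz,",
      length(unique(x$labels)), "label(s)\n")
  invisible(x)
}

#' Sampler specification
#'
#' Bundles a sampling method identifier with its hyperparameters. `alpha` is
#' the sampling percentage: the fraction of the majority-minority count gap
#' filled by synthesis for each minority class (`1` = full parity, the
#' "100%" setting).
#'
#' @param method one of `"SMOTE"`, `"RANDOM_SMOTE"`, `"SMOTE_TOMEKLINKS"`,
#'   `"MSMOTE"`, `"CBSO"`, `"PROWSYN"`, `"DBM"`, `"NDBM"`, `"CBM"`
#'   (case-insensitive; `-` and `_` interchangeable).
#' @param k_neighbors neighbourhood size for nearest-neighbour steps.
#' @param alpha sampling percentage as a fraction, `> 0`.
#' @param max_levels maximum number of proximity levels (ProWSyn).
#' @param theta proximity-weight decay rate (ProWSyn), `w(l) ∝ exp(-theta (l-1))`.
#' @param cluster_threshold_factor multiplier on the mean nearest-minority
#'   -neighbour distance giving the agglomerative cut height (CBSO).
#' @return object of class `sampler_spec`.
#' @export
sampler_spec <- function(method, k_neighbors = 5L, alpha = 1,
                         max_levels = 5L, theta = 1,
                         cluster_threshold_factor = 3) {
  method <- toupper(gsub("-", "_", as.character(method)))
  methods <- c("SMOTE", "RANDOM_SMOTE", "SMOTE_TOMEKLINKS", "MSMOTE",
               "CBSO", "PROWSYN", "DBM", "NDBM", "CBM")
  method <- match.arg(method, methods)
  stopifnot(alpha > 0, k_neighbors >= 1L, max_levels >= 1L, theta >= 0,
            cluster_threshold_factor > 0)
  structure(
    list(method = method, k_neighbors = as.integer(k_neighbors),
         alpha = alpha, max_levels = as.integer(max_levels), theta = theta,
         cluster_threshold_factor = cluster_threshold_factor),
    class = "sampler_spec"
  )
}

#' @export
print.sampler_spec <- function(x, ...) {
  cat(sprintf("sampler_spec: %s (k=%d, alpha=%g)\n",
              x$method, x$k_neighbors, x$alpha))
  invisible(x)
}

# Construct a synthetic batch record: synthetic rows plus per-row provenance.
# neighbor_index is -1 where no distinct neighbour exists (degenerate seeds);
# extra columns (u draws, cluster/level ids, pair indices) vary by method.
synthetic_batch <- function(X_syn, y_syn, provenance, method) {
  stopifnot(nrow(X_syn) == length(y_syn), nrow(X_syn) == nrow(provenance))
  structure(
    list(X_syn = X_syn, y_syn = as.integer(y_syn),
         provenance = provenance, method = method),
    class = "synthetic_batch"
  )
}

empty_batch <- function(d, method, extra_cols = character()) {
  prov <- data.frame(method = character(0), seed_index = integer(0),
                     neighbor_index = integer(0), u = numeric(0))
  for (cl in extra_cols) prov[[cl]] <- numeric(0)
  synthetic_batch(matrix(numeric(0), 0L, d), integer(0), prov, method)
}

#' @export
print.synthetic_batch <- function(x, ...) {
  cat("synthetic_batch:", nrow(x$X_syn), "rows via", x$method, "\n")
  invisible(x)
}

#' Read / write the CSV feature-table dialect
#'
#' Header row, feature columns first, final `label` column, UTF-8, `.`
#' decimal separator.
#'
#' @param path file path.
#' @return [feature_dataset()] for the reader.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"label" %in% names(df)) stop("feature CSV must have a 'label' column")
  lab <- as.character(df$label)
  X <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  feature_dataset(X, lab)
}

#' @rdname read_feature_csv
#' @param ds a [feature_dataset()] to write.
#' @export
write_feature_csv <- function(ds, path) {
  df <- as.data.frame(ds$X)
  if (is.null(colnames(ds$X))) {
    names(df) <- paste0("f", seq_len(ncol(ds$X)))
  }
  df$label <- dataset_labels(ds)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write the raw-recording CSV dialect (`t,x,y,z,label`)
#'
#' @param path file path.
#' @param sample_rate sampling rate in Hz; if `NULL`, inferred from the
#'   median spacing of the `t` column.
#' @return [triaxial_recording()] for the reader.
#' @export
read_recording_csv <- function(path, sample_rate = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "x", "y", "z", "label")
  if (!all(need %in% names(df))) {
    stop("recording CSV must have columns ", paste(need, collapse = ","))
  }
  if (is.null(sample_rate)) {
    dt <- stats::median(diff(df$t))
    if (!is.finite(dt) || dt <= 0) stop("cannot infer sample rate from t")
    sample_rate <- 1 / dt
  }
  triaxial_recording(df$x, df$y, df$z, df$label, sample_rate, t = df$t)
}

#' @rdname read_recording_csv
#' @param rec a [triaxial_recording()] to write.
#' @export
write_recording_csv <- function(rec, path) {
  utils::write.csv(
    data.frame(t = rec$t, x = rec$x, y = rec$y, z = rec$z,
               label = rec$labels),
    path, row.names = FALSE
  )
  invisible(path)
}
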