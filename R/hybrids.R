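#' Hybrid oversampling: DBM, NDBM and CBM
#'
#' Each hybrid runs two constituent samplers independently on the same
#' training split with the same sampling percentage `alpha`, but with
#' independent RNG substreams, and concatenates both synthetic batches over
#' a *single* shared copy of the original rows:
#'
#' * `DBM` (distance-based): SMOTE + Random-SMOTE
#' * `NDBM` (noise-detection-based): SMOTE with Tomek-link cleaning + MSMOTE
#' * `CBM` (cluster-based): ProWSyn + CBSO
#'
#' Because both constituents each fill the full majority-minority gap at
#' `alpha = 1`, hybrid minority classes deliberately overshoot the majority
#' count (e.g. counts `{A:20, B:5}` give `B = 5 + 15 + 15 = 35` under DBM);
#' no rebalancing is applied. For NDBM, original rows deleted by the
#' Tomek-link step are removed from the shared copy; MSMOTE's noise-typed
#' rows are merely unused as seeds, never deleted.
#'
#' @param train a [feature_dataset()] with at least 2 classes (the training
#'   split only).
#' @param method `"DBM"`, `"NDBM"` or `"CBM"`.
#' @param alpha sampling percentage passed to both constituents.
#' @param rng an [rng_handle()]; two child streams are spawned from it.
#' @param k_neighbors,max_levels,theta,cluster_threshold_factor constituent
#'   hyperparameters, see [sampler_spec()].
#' @return an `oversample_result` whose `batches` holds the two constituent
#'   `synthetic_batch`es (in the order listed above) and whose `removed`
#'   holds indices of original rows deleted by cleaning (always empty for
#'   DBM and CBM).
#' @export
hybrid_oversample <- function(train, method = c("DBM", "NDBM", "CBM"),
                              alpha = 1, rng, k_neighbors = 5L,
                              max_levels = 5L, theta = 1,
                              cluster_threshold_factor = 3) {
  method <- match.arg(method)
  validate_dataset(train)
  if (length(unique(train$y)) < 2L) {
    stop("hybrid oversampling needs at least 2 classes")
  }
  constituents <- switch(method,
    DBM  = c("SMOTE", "RANDOM_SMOTE"),
    NDBM = c("SMOTE_TOMEKLINKS", "MSMOTE"),
    CBM  = c("PROWSYN", "CBSO")
  )
  streams <- rng_spawn(rng, 2L)
  parts <- vector("list", 2L)
  for (i in 1:2) {
    spec_i <- sampler_spec(constituents[i], k_neighbors = k_neighbors,
                           alpha = alpha, max_levels = max_levels,
                           theta = theta,
                           cluster_threshold_factor = cluster_threshold_factor)
    parts[[i]] <- tryCatch(
      oversample(train, spec_i, streams[[i]]),
      error = function(e) {
        stop("hybrid constituent ", constituents[i], " failed: ",
             conditionMessage(e))
      }
    )
  }
  removed <- parts[[1]]$removed  # only a cleaning constituent removes rows
  keep <- setdiff(seq_len(nrow(train$X)), removed)
  batches <- list(parts[[1]]$batches[[1]], parts[[2]]$batches[[1]])
  out <- dataset_subset(train, keep)
  for (b in batches) out <- dataset_rbind(out, b$X_syn, b$y_syn)
  structure(
    list(dataset = out, batches = batches, removed = removed,
         spec = sampler_spec(method, k_neighbors = k_neighbors,
                             alpha = alpha, max_levels = max_levels,
                             theta = theta,
                             cluster_threshold_factor =
                               cluster_threshold_factor),
         log = parts[[1]]$log,
         counts = class_counts(out)$counts),
    class = "oversample_result"
  )
}

#' Audit an oversampling result for train/test leakage
#'
#' Verifies that synthetic rows were derived only from training rows
#' (provenance audit: every recorded seed/neighbour index must point inside
#' the training split) and that no test row appears in the augmented
#' training set. An augmented row that exactly equals a test row but also
#' equals an original training row is reported as a coincidence note, not a
#' failure (this can legitimately happen when an interpolation draw of 0
#' duplicates a training row that happens to equal a test row).
#'
#' Failures are reported, never raised.
#'
#' @param train,test disjoint [feature_dataset()] splits.
#' @param result an `oversample_result` produced from `train`.
#' @return object of class `leakage_report`: list with `pass` (logical),
#'   `violations` (data.frame of type/detail) and `notes` (character).
#' @export
leakage_guard <- function(train, test, result) {
  n_train <- nrow(train$X)
  violations <- data.frame(type = character(0), detail = character(0))
  notes <- character(0)
  key <- function(M) apply(M, 1L, function(r) paste(signif(r, 12), collapse = "|"))
  train_keys <- key(train$X)
  test_keys <- key(test$X)
  for (b in result$batches) {
    prov <- b$provenance
    idx_cols <- intersect(c("seed_index", "neighbor_index"), names(prov))
    for (cl in idx_cols) {
      bad <- which(prov[[cl]] > n_train)
      if (length(bad)) {
        violations <- rbind(violations, data.frame(
          type = "synthetic_from_outside_train",
          detail = sprintf("%s batch row %d: %s=%d exceeds train size %d",
                           b$method, bad, cl, prov[[cl]][bad], n_train)))
      }
    }
  }
  aug_keys <- key(result$dataset$X)
  in_test <- which(aug_keys %in% test_keys)
  for (i in in_test) {
    if (aug_keys[i] %in% train_keys) {
      notes <- c(notes, sprintf(
        "augmented row %d equals a test row but also equals a training row (coincidence)", i))
    } else {
      violations <- rbind(violations, data.frame(
        type = "test_row_in_augmented_train",
        detail = sprintf("augmented row %d matches a test row", i)))
    }
  }
  structure(list(pass = nrow(violations) == 0L, violations = violations,
                 notes = notes),
            class = "leakage_report")
}

#' @export
print.leakage_report <- function(x, ...) {
  cat("leakage_guard:", if (x$pass) "PASS" else "FAIL", "\n")
  if (nrow(x$violations)) {
    cat(sprintf(" %d violation(s), e.g. %s\n", nrow(x$violations),
                x$violations$detail[1]))
  }
  for (n in x$notes) cat(" note:", n, "\n")
  invisible(x)
}
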