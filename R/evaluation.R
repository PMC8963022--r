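#' Weighted F1, recall and precision for multi-class predictions
#'
#' Per-class precision and recall are computed from the confusion matrix;
#' class weights are the true-label proportions `w_i = n_i / N`. The
#' weighted F1 is `sum_i 2 w_i P_i R_i / (P_i + R_i)`, with a class's term
#' taken as 0 when `P_i + R_i = 0`; a class with no predicted positives gets
#' precision 0. Under these weights the weighted recall equals the overall
#' accuracy.
#'
#' @param y_true,y_pred equal-length label vectors (character or factor).
#' @param class_names class universe; defaults to the union of both vectors,
#'   sorted.
#' @return list with `f1`, `recall`, `precision` (weighted scalars in
#'   `[0, 1]`) and `per_class` (data.frame of class, n, weight, precision,
#'   recall, f1).
#' @examples
#' weighted_scores(c("A", "A", "A", "B"), c("A", "A", "B", "B"))$f1  # 0.7667
#' @export
weighted_scores <- function(y_true, y_pred, class_names = NULL) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0L)
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (is.null(class_names)) class_names <- sort(unique(c(y_true, y_pred)))
  tf <- factor(y_true, levels = class_names)
  pf <- factor(y_pred, levels = class_names)
  cm <- table(truth = tf, pred = pf)
  tp <- diag(cm)
  pred_n <- colSums(cm)
  true_n <- rowSums(cm)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(true_n > 0, tp / true_n, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- true_n / sum(true_n)
  list(
    f1 = sum(w * f1), recall = sum(w * recall),
    precision = sum(w * precision),
    per_class = data.frame(class = class_names, n = as.integer(true_n),
                           weight = as.numeric(w),
                           precision = as.numeric(precision),
                           recall = as.numeric(recall),
                           f1 = as.numeric(f1))
  )
}

#' Stratified cross-validation folds
#'
#' Shuffles each class separately and deals its rows round-robin across the
#' folds, so every test fold holds roughly `1/n_folds` of each class. Test
#' sets are pairwise disjoint and cover all rows.
#'
#' @param ds a [feature_dataset()].
#' @param n_folds number of folds (`>= 2`).
#' @param rng an [rng_handle()].
#' @return list of `n_folds` lists with integer `train` and `test` indices.
#' @export
make_folds <- function(ds, n_folds = 3L, rng) {
  validate_dataset(ds)
  stopifnot(n_folds >= 2L)
  cc <- class_counts(ds)
  small <- names(cc$counts)[cc$counts < n_folds]
  if (length(small)) {
    stop("class(es) too small for ", n_folds, "-fold stratification: ",
         paste(small, collapse = ", "))
  }
  fold_of <- integer(nrow(ds$X))
  for (ci in seq_along(ds$class_names)) {
    rows <- which(ds$y == ci)
    rows <- with_rng(rng, sample(rows))
    fold_of[rows] <- rep_len(seq_len(n_folds), length(rows))
  }
  lapply(seq_len(n_folds), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

#' Experiment configuration
#'
#' @param dataset a [feature_dataset()].
#' @param samplers character vector of method names (see [sampler_spec()]);
#'   `"baseline"` means no resampling. Alternatively a named list of
#'   [sampler_spec()]s.
#' @param classifiers list of classifier objects (see [classifiers]).
#' @param n_folds folds per repetition (default 3).
#' @param n_repetitions repetitions with different random fold selections
#'   (default 30).
#' @param alpha sampling percentage applied to every method.
#' @param seed master seed; every source of randomness derives from it.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(dataset, samplers = c("baseline", "SMOTE",
                                                    "RANDOM_SMOTE",
                                                    "SMOTE_TOMEKLINKS",
                                                    "MSMOTE", "CBSO",
                                                    "PROWSYN", "DBM", "NDBM",
                                                    "CBM"),
                              classifiers = default_classifiers(),
                              n_folds = 3L, n_repetitions = 30L, alpha = 1,
                              seed = 1L) {
  stopifnot(n_folds >= 2L, n_repetitions >= 1L)
  if (is.character(samplers)) {
    nm <- samplers
    samplers <- lapply(samplers, function(s) {
      if (identical(tolower(s), "baseline")) NULL else
        sampler_spec(s, alpha = alpha)
    })
    names(samplers) <- nm
  }
  structure(
    list(dataset = validate_dataset(dataset), samplers = samplers,
         classifiers = classifiers, n_folds = as.integer(n_folds),
         n_repetitions = as.integer(n_repetitions), seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Run a leakage-safe resampling-versus-classifier experiment
#'
#' For each repetition (seeded from the master seed): fold the pooled data
#' with stratification, oversample each *training* fold only, fit each
#' classifier on the augmented fold, and score on the untouched test fold.
#' [leakage_guard()] is run on every oversampled fold and its verdict
#' recorded; a guard failure stops the experiment. Per-cell scores are the
#' mean over folds, then mean/sd over repetitions.
#'
#' @param cfg an [experiment_config()].
#' @return object of class `experiment_result`: list with matrices
#'   `f1_mean`, `f1_sd`, `recall_mean`, `precision_mean` (classifiers x
#'   samplers), array `raw` (classifier x sampler x repetition mean-F1),
#'   array `per_class_f1` (classifier x sampler x class, mean over
#'   repetitions and folds), `leakage_pass` (logical), `n_leakage_checks`,
#'   and `config`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  ds <- cfg$dataset
  clf_names <- vapply(cfg$classifiers, `[[`, character(1), "name")
  smp_names <- names(cfg$samplers)
  n_c <- length(clf_names); n_s <- length(smp_names)
  n_rep <- cfg$n_repetitions
  raw <- array(NA_real_, c(n_c, n_s, n_rep),
               dimnames = list(clf_names, smp_names, NULL))
  raw_rec <- raw; raw_prec <- raw
  pc <- array(0, c(n_c, n_s, length(ds$class_names)),
              dimnames = list(clf_names, smp_names, ds$class_names))
  pc_n <- 0L
  leakage_pass <- TRUE; n_checks <- 0L
  master <- rng_handle(cfg$seed)
  rep_rngs <- rng_spawn(master, n_rep)
  for (r in seq_len(n_rep)) {
    rng <- rep_rngs[[r]]
    folds <- make_folds(ds, cfg$n_folds, rng)
    acc <- array(0, c(n_c, n_s, 3L))
    pc_fold <- array(0, c(n_c, n_s, length(ds$class_names)))
    for (fold in folds) {
      train <- dataset_subset(ds, fold$train)
      test <- dataset_subset(ds, fold$test)
      for (s in seq_len(n_s)) {
        spec <- cfg$samplers[[s]]
        if (is.null(spec)) {
          aug <- train
        } else {
          res <- oversample(train, spec, rng)
          guard <- leakage_guard(train, test, res)
          n_checks <- n_checks + 1L
          if (!guard$pass) {
            leakage_pass <- FALSE
            stop("leakage guard failed for sampler ", smp_names[s],
                 " in repetition ", r)
          }
          aug <- res$dataset
        }
        for (ci in seq_len(n_c)) {
          clf <- cfg$classifiers[[ci]]
          pred <- tryCatch({
            model <- clf$fit(aug$X, dataset_labels(aug), rng)
            with_rng(rng, clf$predict(model, test$X))
          }, error = function(e) NULL)
          if (is.null(pred)) next  # cell recorded as missing
          sc <- weighted_scores(dataset_labels(test), pred,
                                class_names = ds$class_names)
          acc[ci, s, ] <- acc[ci, s, ] + c(sc$f1, sc$recall, sc$precision)
          pc_fold[ci, s, ] <- pc_fold[ci, s, ] + sc$per_class$f1
        }
      }
    }
    raw[, , r] <- acc[, , 1L] / cfg$n_folds
    raw_rec[, , r] <- acc[, , 2L] / cfg$n_folds
    raw_prec[, , r] <- acc[, , 3L] / cfg$n_folds
    pc <- pc + pc_fold / cfg$n_folds
    pc_n <- pc_n + 1L
  }
  structure(
    list(
      f1_mean = apply(raw, c(1L, 2L), mean, na.rm = TRUE),
      f1_sd = apply(raw, c(1L, 2L), stats::sd, na.rm = TRUE),
      recall_mean = apply(raw_rec, c(1L, 2L), mean, na.rm = TRUE),
      precision_mean = apply(raw_prec, c(1L, 2L), mean, na.rm = TRUE),
      raw = raw,
      per_class_f1 = pc / pc_n,
      leakage_pass = leakage_pass,
      n_leakage_checks = n_checks,
      config = cfg
    ),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result:", dim(x$raw)[3], "repetitions x",
      x$config$n_folds, "folds; leakage checks:",
      x$n_leakage_checks, if (x$leakage_pass) "(all passed)" else "(FAILED)",
      "\nmean weighted F1:\n")
  print(round(x$f1_mean, 4))
  invisible(x)
}
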