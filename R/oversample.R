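# Per-class synthesis budget: alpha is the fraction of the majority-minority
# gap to fill, so alpha = 1 brings every class to parity with the majority.
synthesis_targets <- function(ds, alpha) {
  cc <- class_counts(ds)
  n_maj <- max(cc$counts)
  targets <- round(alpha * (n_maj - cc$counts))
  targets[names(cc$counts) == cc$majority] <- 0L
  as.integer(targets)
}

# Run a per-class generator over every class needing synthesis and assemble
# one dataset-level synthetic_batch with provenance indices mapped to global
# rows of `ds`. `gen` is called as gen(class_idx, n_synth, rng) and must
# return list(X_syn, prov, rows) with local seed/neighbour indices into
# `rows`.
dataset_batch <- function(ds, method, gen, rng, alpha = 1) {
  targets <- synthesis_targets(ds, alpha)
  Xs <- list(); ys <- list(); provs <- list()
  for (ci in seq_along(ds$class_names)) {
    if (targets[ci] <= 0L) next
    piece <- gen(ci, targets[ci], rng)
    prov <- piece$prov
    prov$seed_index <- piece$rows[prov$seed_index]
    has_nbr <- prov$neighbor_index > 0L
    prov$neighbor_index[has_nbr] <- piece$rows[prov$neighbor_index[has_nbr]]
    for (col in intersect(c("x1_index", "x2_index"), names(prov))) {
      prov[[col]] <- piece$rows[prov[[col]]]
    }
    prov$class <- ds$class_names[ci]
    Xs[[length(Xs) + 1L]] <- piece$X_syn
    ys[[length(ys) + 1L]] <- rep(ci, nrow(piece$X_syn))
    provs[[length(provs) + 1L]] <- prov
  }
  if (length(Xs) == 0L) return(empty_batch(ncol(ds$X), method))
  prov <- do.call(rbind, lapply(provs, function(p) {
    p[, c("method", "seed_index", "neighbor_index", "u", "class")]
  }))
  prov_full <- provs
  b <- synthetic_batch(do.call(rbind, Xs), unlist(ys), prov, method)
  b$provenance_extra <- prov_full
  b
}

# Dataset-level SMOTE batch (also the first stage of SMOTE_TOMEKLINKS).
dataset_smote_batch <- function(ds, spec, rng, method = "SMOTE") {
  dataset_batch(ds, method, function(ci, n, r) {
    rows <- which(ds$y == ci)
    b <- smote_generate(ds$X[rows, , drop = FALSE], spec$k_neighbors, n, r)
    list(X_syn = b$X_syn, prov = b$provenance, rows = rows)
  }, rng, alpha = spec$alpha)
}

#' Oversample a feature dataset with any supported method
#'
#' The shared sampler interface: every minority class (any class smaller
#' than the majority) is brought toward parity according to
#' `spec$alpha`, using the method named in `spec`. Single methods produce
#' one synthetic batch; the hybrid methods `DBM`, `NDBM` and `CBM` run their
#' two constituents independently on the same data (with independent RNG
#' substreams) and concatenate both batches over a single copy of the
#' original rows — see [hybrid_oversample()].
#'
#' @param ds a [feature_dataset()] (training split only — never oversample
#'   before splitting).
#' @param spec a [sampler_spec()].
#' @param rng an [rng_handle()].
#' @return an object of class `oversample_result`: list with `dataset` (the
#'   augmented [feature_dataset()]), `batches` (list of `synthetic_batch`,
#'   length 1 for single methods, 2 for hybrids), `removed` (indices of
#'   original rows deleted by cleaning; empty except for Tomek-link
#'   methods), `spec` and `log`.
#' @examples
#' rng <- rng_handle(7)
#' ds <- generate_feature_dataset(c(A = 20, B = 5), rng = rng)
#' res <- oversample(ds, sampler_spec("SMOTE"), rng)
#' class_counts(res$dataset)$counts
#' @export
oversample <- function(ds, spec, rng) {
  validate_dataset(ds)
  stopifnot(inherits(spec, "sampler_spec"), inherits(rng, "rng_handle"))
  if (spec$method %in% c("DBM", "NDBM", "CBM")) {
    return(hybrid_oversample(ds, spec$method, alpha = spec$alpha, rng = rng,
                             k_neighbors = spec$k_neighbors,
                             max_levels = spec$max_levels, theta = spec$theta,
                             cluster_threshold_factor =
                               spec$cluster_threshold_factor))
  }
  removed <- integer(0)
  log <- list()
  if (spec$method == "SMOTE_TOMEKLINKS") {
    st <- smote_tomeklinks_core(ds, spec, rng)
    batch <- st$batch
    removed <- st$removed
    log <- st$log
  } else {
    batch <- switch(
      spec$method,
      SMOTE = dataset_smote_batch(ds, spec, rng),
      RANDOM_SMOTE = dataset_batch(ds, "RANDOM_SMOTE", function(ci, n, r) {
        rows <- which(ds$y == ci)
        b <- random_smote_generate(ds$X[rows, , drop = FALSE], n, r)
        list(X_syn = b$X_syn, prov = b$provenance, rows = rows)
      }, rng, alpha = spec$alpha),
      MSMOTE = dataset_batch(ds, "MSMOTE", function(ci, n, r) {
        msmote_generate_class(ds, ci, n, spec$k_neighbors, r)
      }, rng, alpha = spec$alpha),
      CBSO = dataset_batch(ds, "CBSO", function(ci, n, r) {
        cbso_generate_class(ds, ci, n, spec$k_neighbors,
                            spec$cluster_threshold_factor, r)
      }, rng, alpha = spec$alpha),
      PROWSYN = dataset_batch(ds, "PROWSYN", function(ci, n, r) {
        prowsyn_generate_class(ds, ci, n, spec$k_neighbors, spec$max_levels,
                               spec$theta, r)
      }, rng, alpha = spec$alpha),
      stop("unknown method ", spec$method)
    )
  }
  keep <- setdiff(seq_len(nrow(ds$X)), removed)
  out <- dataset_rbind(dataset_subset(ds, keep), batch$X_syn, batch$y_syn)
  structure(
    list(dataset = out, batches = list(batch), removed = removed,
         spec = spec, log = log),
    class = "oversample_result"
  )
}

#' @export
print.oversample_result <- function(x, ...) {
  cat("oversample_result:", x$spec$method, "->",
      nrow(x$dataset$X), "rows (",
      sum(vapply(x$batches, function(b) nrow(b$X_syn), integer(1))),
      "synthetic,", length(x$removed), "removed )\n")
  invisible(x)
}
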