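#' Magnitude (Euclidean norm) of a tri-axial recording
#'
#' Collapses the three axes to `sqrt(x^2 + y^2 + z^2)`, which is invariant to
#' sensor orientation: any 3-D rotation of the axes leaves the magnitude
#' unchanged.
#'
#' @param rec a [triaxial_recording()].
#' @return numeric series of the same length, all values `>= 0`.
#' @export
magnitude <- function(rec) {
  stopifnot(inherits(rec, "triaxial_recording"))
  if (length(rec$x) == 0L) stop("recording is empty")
  sqrt(rec$x^2 + rec$y^2 + rec$z^2)
}

#' Segment a labelled series into non-overlapping windows
#'
#' Cuts the series into consecutive disjoint windows of
#' `floor(window_seconds * sample_rate)` samples; the trailing partial window
#' is discarded. Each window is labelled with its modal per-sample label
#' (ties broken toward the earlier entry of `class_names`); windows whose
#' modal label equals `null_label` are dropped.
#'
#' @param series numeric series (typically the [magnitude()] signal).
#' @param labels per-sample labels, same length as `series`.
#' @param window_seconds window length in seconds.
#' @param sample_rate sampling rate in Hz.
#' @param class_names ordering used for modal tie-breaks; defaults to sorted
#'   unique labels.
#' @param null_label label treated as background and dropped (`"null"`).
#' @return list with `windows` (list of numeric vectors) and `labels`
#'   (character vector, one per kept window). A series shorter than one
#'   window yields zero windows.
#' @export
segment_windows <- function(series, labels, window_seconds, sample_rate,
                            class_names = NULL, null_label = "null") {
  stopifnot(length(series) == length(labels), window_seconds > 0,
            sample_rate > 0)
  len <- floor(window_seconds * sample_rate)
  if (len < 1L) stop("window shorter than one sample")
  labels <- as.character(labels)
  if (is.null(class_names)) class_names <- sort(unique(labels))
  n_win <- floor(length(series) / len)
  windows <- vector("list", n_win)
  win_labels <- character(n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1L) * len + 1L):(w * len)
    windows[[w]] <- series[idx]
    win_labels[w] <- modal_label(labels[idx], class_names)
  }
  keep <- win_labels != null_label
  list(windows = windows[keep], labels = win_labels[keep])
}

# Modal label with ties broken by class_names order; labels outside
# class_names (e.g. an explicit null class) rank after all known classes.
modal_label <- function(lab, class_names) {
  u <- unique(lab)
  cnt <- vapply(u, function(l) sum(lab == l), integer(1))
  ord <- match(u, class_names)
  ord[is.na(ord)] <- length(class_names) + 1L
  u[order(-cnt, ord)][1L]
}

#' Six time-domain features of one window
#'
#' Mean, standard deviation (population form, divide by `n`), minimum,
#' maximum, median (even length: mean of the two central order statistics)
#' and range (`max - min`) of the window's magnitude samples.
#'
#' @param window non-empty numeric vector.
#' @return named numeric vector
#'   `c(mean, std, min, max, median, range)`.
#' @export
extract_features <- function(window) {
  if (length(window) == 0L) stop("empty window")
  mn <- min(window); mx <- max(window)
  c(mean = mean(window),
    std = sqrt(mean((window - mean(window))^2)),
    min = mn,
    max = mx,
    median = stats::median(window),
    range = mx - mn)
}

#' Full preprocessing chain: recording to feature dataset
#'
#' Computes the magnitude signal, segments it into non-overlapping windows,
#' and extracts the six time-domain features per window, yielding the
#' `d = 6` feature table the samplers and classifiers consume.
#'
#' @inheritParams segment_windows
#' @param rec a [triaxial_recording()].
#' @return a [feature_dataset()] with six feature columns.
#' @examples
#' rec <- triaxial_recording(x = sin(1:200), y = cos(1:200),
#'                           z = 9.81 + 0 * (1:200),
#'                           labels = rep(c("walk", "run"), each = 100),
#'                           sample_rate = 20)
#' features_from_recording(rec, window_seconds = 1)
#' @export
features_from_recording <- function(rec, window_seconds,
                                    null_label = "null",
                                    class_names = NULL) {
  mag <- magnitude(rec)
  if (is.null(class_names)) {
    class_names <- sort(setdiff(unique(rec$labels), null_label))
  }
  seg <- segment_windows(mag, rec$labels, window_seconds, rec$sample_rate,
                         class_names = class_names, null_label = null_label)
  if (length(seg$windows) == 0L) stop("recording shorter than one window")
  X <- t(vapply(seg$windows, extract_features, numeric(6)))
  feature_dataset(X, seg$labels, class_names = sort(unique(seg$labels)))
}
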