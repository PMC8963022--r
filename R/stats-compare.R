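#' Anderson-Darling normality test (estimated parameters)
#'
#' Tests a sample against the normal distribution with mean and variance
#' estimated from the data. The statistic is
#' `A^2 = -n - (1/n) sum (2i - 1) (log F(z_(i)) + log(1 - F(z_(n+1-i))))`
#' with `F` the standard normal CDF of the standardised order statistics;
#' the small-sample corrected statistic `A*^2 = A^2 (1 + 4/n - 25/n^2)` is
#' mapped to a p-value through the standard piecewise exponential
#' approximation.
#'
#' @param values numeric sample, `n >= 8`, non-constant.
#' @return object of class `test_result` with `statistic` (the corrected
#'   `A*^2`), `statistic_uncorrected` (`A^2`), `df` (`NA`), `p_value` and
#'   `test`.
#' @export
anderson_darling_normal <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 8L) stop("Anderson-Darling test needs n >= 8")
  s <- stats::sd(values)
  if (s == 0) stop("constant input: normality test undefined")
  z <- sort((values - mean(values)) / s)
  logF <- stats::pnorm(z, log.p = TRUE)
  logS <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (logF + rev(logS)))
  A2c <- A2 * (1 + 4 / n - 25 / n^2)
  p <- if (A2c < 0.2) {
    1 - exp(-13.436 + 101.14 * A2c - 223.73 * A2c^2)
  } else if (A2c < 0.34) {
    1 - exp(-8.318 + 42.796 * A2c - 59.938 * A2c^2)
  } else if (A2c < 0.6) {
    exp(0.9177 - 4.279 * A2c - 1.38 * A2c^2)
  } else {
    exp(1.2937 - 5.709 * A2c + 0.0186 * A2c^2)
  }
  test_result("Anderson-Darling normality", A2c, NA_real_,
              min(max(p, 0), 1), statistic_uncorrected = A2)
}

test_result <- function(test, statistic, df, p_value, ...) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, ...),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4f\n", x$test,
              x$statistic, ifelse(is.na(x$df), "-", format(x$df)),
              x$p_value))
  invisible(x)
}

#' One-way analysis of variance across groups
#'
#' Standard between/within decomposition (`SS_total = SS_between +
#' SS_within`), fitted via [stats::lm()]. With `k` groups the between-groups
#' degrees of freedom are `k - 1`.
#'
#' @param groups list of numeric vectors, `>= 2` groups of `>= 2` values.
#' @return a `test_result` with fields `table` (data.frame of df, sum_sq,
#'   mean_sq per source) plus the F `statistic`, `df` (between, within) and
#'   `p_value`. When both between and within variance are zero the F ratio
#'   is undefined and reported as `NA`.
#' @export
oneway_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 2L))
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  at <- suppressWarnings(stats::anova(stats::lm(values ~ g)))
  tab <- data.frame(source = c("between", "within"),
                    df = at$Df, sum_sq = at$`Sum Sq`,
                    mean_sq = at$`Mean Sq`)
  f <- at$`F value`[1]
  p <- at$`Pr(>F)`[1]
  # zero between- and within-variance: 0/0, the F ratio is undefined
  if (!is.finite(f) ||
      sum(at$`Sum Sq`) <= 1e-12 * (1 + mean(values)^2)) {
    f <- NA_real_; p <- NA_real_
  }
  out <- test_result("one-way ANOVA", f, at$Df, p)
  out$table <- tab
  out
}

#' Rank a score matrix within blocks
#'
#' Each row (block; here: one classifier) is ranked across treatments
#' (sampling methods) from 1 (lowest score) to `k` (highest); ties receive
#' average ranks. Row rank sums are `k (k + 1) / 2` by construction.
#'
#' @param score_matrix numeric matrix, blocks x treatments.
#' @return object of class `rank_table`: list with `ranks` (matrix) and
#'   `rank_sums` (named column sums).
#' @export
rank_table <- function(score_matrix) {
  m <- as.matrix(score_matrix)
  ranks <- t(apply(m, 1L, rank, ties.method = "average"))
  dimnames(ranks) <- dimnames(m)
  structure(list(ranks = ranks, rank_sums = colSums(ranks)),
            class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  print(x$ranks)
  cat("Sum of ranks:\n")
  print(x$rank_sums)
  invisible(x)
}

#' Friedman test on a blocks-by-treatments score matrix
#'
#' Ranks each block's scores 1..k (average ranks on ties) and computes
#' `chi2 = 12 / (n k (k + 1)) * sum_j R_j^2 - 3 n (k + 1)` over the column
#' rank sums `R_j`, referred to the chi-squared distribution with `k - 1`
#' degrees of freedom. A matrix that already contains ranks is unchanged by
#' the ranking step.
#'
#' @param score_matrix numeric matrix with `n >= 2` rows (blocks) and
#'   `k >= 2` complete columns (treatments).
#' @return a `test_result` with `statistic` (chi-squared), `df`, `p_value`
#'   and `rank_table` (see [rank_table()]).
#' @examples
#' m <- rbind(c(1, 2, 3), c(1, 3, 2), c(1, 2, 3))
#' friedman_test(m)
#' @export
friedman_test <- function(score_matrix) {
  m <- as.matrix(score_matrix)
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 2L, k >= 2L)
  if (anyNA(m)) stop("score matrix has missing cells")
  rt <- rank_table(m)
  chi2 <- 12 / (n * k * (k + 1)) * sum(rt$rank_sums^2) - 3 * n * (k + 1)
  out <- test_result("Friedman", chi2, k - 1L,
                     stats::pchisq(chi2, k - 1L, lower.tail = FALSE))
  out$rank_table <- rt
  out
}

#' Compare sampling methods across classifiers
#'
#' The routing used to analyse a classifiers-by-methods score matrix: the
#' flattened cells are first screened with the Anderson-Darling normality
#' test; if normality is not rejected (p > 0.05) a one-way ANOVA across
#' methods is run, otherwise the non-parametric Friedman test with its rank
#' table.
#'
#' @param score_matrix numeric matrix, classifiers x sampling methods, of
#'   mean scores.
#' @param alpha_level significance threshold for the normality screen
#'   (default 0.05).
#' @return object of class `sampler_comparison`: list with `normality`
#'   (`test_result`), `route` (`"anova"` or `"friedman"`), `test`
#'   (`test_result`), `rank_table` (Friedman route only) and `summary`
#'   (one-line text verdict).
#' @export
compare_samplers <- function(score_matrix, alpha_level = 0.05) {
  m <- as.matrix(score_matrix)
  if (anyNA(m)) stop("score matrix has missing cells")
  normality <- anderson_darling_normal(as.numeric(m))
  if (normality$p_value > alpha_level) {
    route <- "anova"
    test <- oneway_anova(lapply(seq_len(ncol(m)), function(j) m[, j]))
    rt <- NULL
  } else {
    route <- "friedman"
    test <- friedman_test(m)
    rt <- test$rank_table
  }
  sig <- !is.na(test$p_value) && test$p_value <= alpha_level
  summary <- sprintf(
    "normality p = %.4f -> %s; %s p = %.4f: %s difference between methods%s",
    normality$p_value, route, test$test, test$p_value,
    if (sig) "significant" else "no significant",
    if (!is.null(rt) && sig) {
      top <- which.max(rt$rank_sums)
      sprintf(" (top-ranked: %s)",
              if (is.null(names(rt$rank_sums))) top else names(top))
    } else ""
  )
  structure(list(normality = normality, route = route, test = test,
                 rank_table = rt, summary = summary),
            class = "sampler_comparison")
}

#' @export
print.sampler_comparison <- function(x, ...) {
  cat(x$summary, "\n")
  invisible(x)
}
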