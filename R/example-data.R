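#' Published benchmark rank tables
#'
#' Classifier-by-sampling-method rank matrices (five classifiers, nine
#' methods, ranks 1 = lowest F1 to 9 = highest per classifier row) from a
#' published benchmark comparison of these sampling strategies on the ADL
#' and Opportunity activity-recognition datasets. Shipped as worked examples
#' for [friedman_test()] and [rank_table()]: feeding them to
#' `friedman_test` reproduces the published chi-squared statistics (21.8133
#' for ADL, 24.2133 for Opportunity, df = 8) and column rank sums.
#'
#' @return named list of two numeric matrices (`adl`, `opportunity`), rows =
#'   classifiers, columns = sampling methods.
#' @examples
#' friedman_test(example_rank_matrices()$adl)
#' @export
example_rank_matrices <- function() {
  read_one <- function(file) {
    df <- utils::read.csv(system.file("extdata", file, package = "harsmote",
                                      mustWork = TRUE),
                          check.names = FALSE)
    m <- as.matrix(df[, -1L])
    rownames(m) <- df$classifier
    m
  }
  list(adl = read_one("rank_adl.csv"),
       opportunity = read_one("rank_opportunity.csv"))
}
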