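#' Tidy a synteny summary into a per-bin tibble
#' @param x A [synteny_summary()] object.
#' @param ... Unused.
#' @return A tibble with one row per deletion bin.
#' @exportS3Method generics::tidy
tidy.synteny_summary <- function(x, ...) {
  x$per_bin %||% tibble(bin = character(), n_syntenic = integer(),
                        n_other = integer(), pct_syntenic = numeric())
}

#' One-row summary of a synteny summary
#' @param x A [synteny_summary()] object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.synteny_summary <- function(x, ...) x$overall

#' Tidy a collinearity summary into a per-bin tibble
#' @param x A [collinearity_summary()] object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.collinearity_summary <- function(x, ...) x$per_bin

#' One-row summary of a collinearity summary
#' @param x A [collinearity_summary()] object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.collinearity_summary <- function(x, ...) x$overall

#' Tidy a uniformity test: observed and expected per bin
#' @param x A [chisq_uniformity()] object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.uniformity_test <- function(x, ...) {
  tibble(bin = seq_along(x$observed), observed = x$observed, expected = x$expected)
}

#' One-row summary of a uniformity test
#' @param x A [chisq_uniformity()] object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.uniformity_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         proportion = x$proportion)
}

#' One-row summary of a Pearson correlation test
#' @param x A [pearson_test()] object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.pearson_test <- function(x, ...) {
  tibble(r = x$r, df = x$df, p_value = x$p_value, n = x$n)
}

#' One-row summary of a Welch t-test
#' @param x A [welch_t_test()] object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.welch_t_test <- function(x, ...) {
  tibble(t = x$t, df = x$df, p_value = x$p_value,
         mean_a = x$mean_a, mean_b = x$mean_b)
}

#' One-row summary of the bias tests
#' @param x A [bias_tests()] object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.bias_tests <- function(x, ...) {
  tibble(chisq_statistic = x$chisq$statistic, chisq_df = x$chisq$df,
         chisq_p_value = x$chisq$p_value,
         pearson_r = x$pearson$r, pearson_p_value = x$pearson$p_value)
}

#' @export
print.uniformity_test <- function(x, ...) {
  cat("Chi-square uniformity: X2 = ", signif(x$statistic, 4), ", df = ", x$df,
      ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' @export
print.pearson_test <- function(x, ...) {
  cat("Pearson correlation: r = ", signif(x$r, 4), ", p = ",
      signif(x$p_value, 3), " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @export
print.welch_t_test <- function(x, ...) {
  cat("Welch t-test: t = ", signif(x$t, 4), ", df = ", signif(x$df, 4),
      ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}
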