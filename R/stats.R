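#' Coefficient of variation
#'
#' `Cv = sigma / |mu| * 100` (percent): a unit-free spread measure used to
#' compare variability across environmental factors on different scales. The
#' absolute mean keeps the coefficient positive for below-zero temperature
#' variables.
#'
#' @param mean Sample mean (non-zero).
#' @param sd Standard deviation (>= 0).
#' @return Cv in percent.
#' @export
#' @examples
#' coefficient_of_variation(3630, sd_from_se(44, 206))  # ~17.4
coefficient_of_variation <- function(mean, sd) {
  if (any(mean == 0))
    hs_stop("habsim_undefined_cv_error", "Cv is undefined for mean = 0")
  if (any(sd < 0)) hs_stop("habsim_value_error", "sd must be >= 0")
  sd / abs(mean) * 100
}

#' Recover a standard deviation from a standard error
#'
#' Bridges "mean +/- SE" summary tables to the Cv formula's sigma:
#' `sd = se * sqrt(n)`.
#'
#' @param se Standard error of the mean (>= 0).
#' @param n Sample size (>= 2).
#' @return The standard deviation.
#' @export
sd_from_se <- function(se, n) {
  if (any(n < 2)) hs_stop("habsim_value_error", "n must be >= 2")
  if (any(se < 0)) hs_stop("habsim_value_error", "se must be >= 0")
  se * sqrt(n)
}

#' One-way ANOVA across habitat groups
#'
#' Classical fixed-effects one-way analysis of variance: F is the ratio of
#' the between-group to the within-group mean square, with p from the F
#' distribution on (groups - 1, n - groups) degrees of freedom. Used to ask
#' whether an environmental factor differs among native habitats (counties or
#' towns).
#'
#' @param values Numeric vector.
#' @param groups Parallel vector of group labels (>= 2 groups, each with >= 2
#'   values).
#' @return A list of class `eco_anova`: `f_value`, `p_value`, `df_between`,
#'   `df_within`, `stars` (`"***"` for p < 0.001, `"**"` < 0.01, `"*"` < 0.05,
#'   `""` otherwise).
#' @export
one_way_anova <- function(values, groups) {
  if (length(values) != length(groups))
    hs_stop("habsim_value_error", "values and groups must have equal length")
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(as.character(groups[keep]))
  counts <- table(groups)
  if (length(counts) < 2L)
    hs_stop("habsim_value_error", "at least 2 groups required")
  small <- names(counts)[counts < 2]
  if (length(small))
    hs_stop("habsim_value_error", "group(s) with fewer than 2 values: %s",
            paste(small, collapse = ", "))
  ot <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  structure(list(f_value = unname(ot$statistic),
                 p_value = unname(ot$p.value),
                 df_between = as.integer(unname(ot$parameter["num df"])),
                 df_within = as.integer(unname(ot$parameter["denom df"])),
                 stars = if (ot$p.value < 0.001) "***" else if (ot$p.value < 0.01)
                   "**" else if (ot$p.value < 0.05) "*" else ""),
            class = "eco_anova")
}

#' @export
print.eco_anova <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g%s, p = %.3g\n",
              x$df_between, x$df_within, x$f_value, x$stars, x$p_value))
  invisible(x)
}

#' PCA variance contributions of environmental variables
#'
#' Eigen-decomposition of the correlation (default) or covariance matrix of
#' the plot-by-variable matrix, reporting per-component percentages of total
#' variance and signed loadings. Eigenvector sign is arbitrary, so each
#' component is oriented to make its largest-magnitude loading positive --
#' a fixed convention that keeps results deterministic.
#'
#' @param x Numeric matrix or data.frame (samples x variables), no missing
#'   values.
#' @param standardize Logical; `TRUE` (default) uses the correlation matrix.
#' @return A list of class `eco_pca`: `variance_pct` (non-increasing, sums to
#'   100) and `loadings` (variables x components, each column unit norm).
#' @export
pca_contributions <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (anyNA(x)) hs_stop("habsim_value_error", "PCA input contains missing values")
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      const <- if (is.null(colnames(x))) which(sds == 0) else colnames(x)[sds == 0]
      hs_stop("habsim_value_error",
              "constant column(s) cannot be standardized: %s",
              paste(const, collapse = ", "))
    }
  }
  p <- stats::prcomp(x, center = TRUE, scale. = standardize)
  var_pct <- 100 * p$sdev^2 / sum(p$sdev^2)
  load <- p$rotation
  for (j in seq_len(ncol(load))) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) load[, j] <- -load[, j]
  }
  structure(list(variance_pct = var_pct, loadings = load), class = "eco_pca")
}

#' @export
print.eco_pca <- function(x, ...) {
  cat("<eco_pca> variance contributions (%):",
      paste(render_num(x$variance_pct, 1), collapse = ", "), "\n")
  invisible(x)
}

#' Per-variable ANOVA report in summary-table form
#'
#' Convenience wrapper running [one_way_anova()] for every continuous column
#' of a plot-sample table against its `habitat_group` labels.
#'
#' @param samples Output of [sample_at_points()].
#' @param exclude Columns to skip besides `plot_id`/`habitat_group` (e.g. the
#'   soil layer).
#' @return data.frame `variable, f_value, p_value, df_between, df_within,
#'   stars`.
#' @export
anova_report <- function(samples, exclude = NULL) {
  vars <- setdiff(names(samples), c("plot_id", "habitat_group", exclude))
  rows <- lapply(vars, function(nm) {
    a <- one_way_anova(samples[[nm]], samples$habitat_group)
    data.frame(variable = nm, f_value = a$f_value, p_value = a$p_value,
               df_between = a$df_between, df_within = a$df_within,
               stars = a$stars, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
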