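#' Three-way overlap decomposition of prediction vs survey
#'
#' Model-quality assessment by set arithmetic over region ids: the
#' intersection of the predicted and the surveyed region sets is the
#' *congruent* part; predicted-but-not-surveyed regions suggest potential
#' (undiscovered or unoccupied) habitat; surveyed-but-not-predicted regions
#' are prediction misses. Percentages use the bases that make them
#' interpretable: survey coverage and survey-only use the survey size as
#' denominator, prediction-only uses the prediction size. Raw percentages are
#' retained; rendering rounds half-up to one decimal only at print time.
#'
#' @param predicted Character vector (or set) of predicted region ids.
#' @param survey Non-empty character vector of surveyed region ids.
#' @return A list of class `eco_overlap`: `n_predicted`, `n_survey`,
#'   `n_union`, `n_congruent`, `n_prediction_only`, `n_survey_only`,
#'   `pct_survey_covered`, `pct_prediction_only`, `pct_survey_only`.
#' @export
#' @examples
#' r <- overlap_report(paste0("c", 1:6), paste0("c", 4:8))
#' r$n_congruent  # 3
overlap_report <- function(predicted, survey) {
  predicted <- unique(as.character(predicted))
  survey <- unique(as.character(survey))
  if (length(survey) == 0L)
    hs_stop("habsim_empty_survey_error",
            "survey set is empty: overlap percentages are undefined")
  n_p <- length(predicted); n_s <- length(survey)
  n_c <- length(intersect(predicted, survey))
  out <- list(
    n_predicted = n_p, n_survey = n_s,
    n_union = n_p + n_s - n_c,
    n_congruent = n_c,
    n_prediction_only = n_p - n_c,
    n_survey_only = n_s - n_c,
    pct_survey_covered = 100 * n_c / n_s,
    pct_prediction_only = if (n_p > 0) 100 * (n_p - n_c) / n_p else NA_real_,
    pct_survey_only = 100 * (n_s - n_c) / n_s
  )
  structure(out, class = "eco_overlap")
}

#' @export
print.eco_overlap <- function(x, ...) {
  cat("<eco_overlap> prediction vs survey decomposition\n")
  cat(sprintf("  regions listed by either source (union): %d\n", x$n_union))
  cat(sprintf("  congruent (predicted and surveyed):      %d  (%s%% of survey covered)\n",
              x$n_congruent, render_num(x$pct_survey_covered, 1)))
  cat(sprintf("  prediction only (potential habitat):     %d  (%s%% of prediction)\n",
              x$n_prediction_only, render_num(x$pct_prediction_only, 1)))
  cat(sprintf("  survey only (prediction misses):         %d  (%s%% of survey)\n",
              x$n_survey_only, render_num(x$pct_survey_only, 1)))
  invisible(x)
}

#' Render an overlap report as a data.frame
#'
#' @param report An [overlap_report()] result.
#' @return One-row data.frame with the six counts and the three percentages
#'   rendered half-up to one decimal (`*_pct` columns as numbers).
#' @export
overlap_table <- function(report) {
  data.frame(
    n_predicted = report$n_predicted, n_survey = report$n_survey,
    n_union = report$n_union, n_congruent = report$n_congruent,
    n_prediction_only = report$n_prediction_only,
    n_survey_only = report$n_survey_only,
    pct_survey_covered = round_half_up(report$pct_survey_covered, 1),
    pct_prediction_only = round_half_up(report$pct_prediction_only, 1),
    pct_survey_only = round_half_up(report$pct_survey_only, 1)
  )
}

#' Read a survey region list
#'
#' CSV with a `region_id` column and optionally a `species` column; when
#' `species` is given the rows are filtered to it. Duplicated ids collapse to
#' a set.
#'
#' @param path CSV path.
#' @param species Optional species name to filter on.
#' @return Character vector of region ids.
#' @export
read_survey <- function(path, species = NULL) {
  if (!file.exists(path)) hs_stop("habsim_io_error", "survey file does not exist: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"region_id" %in% names(df))
    hs_stop("habsim_parse_error", "%s: survey CSV needs a region_id column", path)
  if (!is.null(species)) {
    if (!"species" %in% names(df))
      hs_stop("habsim_parse_error", "%s: no species column to filter on", path)
    df <- df[df$species == species, , drop = FALSE]
  }
  unique(as.character(df$region_id))
}
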