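#' Build the native-habitat target envelope
#'
#' The envelope is the multivariate summary of conditions at the native-range
#' plots: per continuous variable the sample count, extrema, mean, standard
#' deviation (n - 1 denominator), standard error of the mean (sd / sqrt(n))
#' and mean absolute deviation about the mean (denominator n) -- the scale
#' used to normalise layers before the Minkowski distance -- plus the set of
#' soil codes observed at the plots. Missing values (plots on nodata cells)
#' are excluded variable-wise and `n` is reported per variable. Variables with
#' zero spread are flagged (`zero_spread`); the similarity step excludes them
#' from the distance.
#'
#' @param samples Output of [sample_at_points()]: `plot_id`, `habitat_group`
#'   and one column per layer.
#' @param soil_layer Name of the categorical soil column in `samples`, or
#'   `NULL` if no soil layer was sampled.
#' @param soil_taxonomy Optional data.frame `code,path` translating raster
#'   soil codes to taxonomic paths; when absent, raw codes are kept as
#'   single-level soil codes.
#' @return An object of class `eco_envelope` with elements `variables` (a
#'   data.frame `name,n,min,max,mean,sd,se,mad,zero_spread`), `soils`
#'   (character vector of soil code paths) and `n_plots`.
#' @export
build_envelope <- function(samples, soil_layer = NULL, soil_taxonomy = NULL) {
  varnames <- setdiff(names(samples), c("plot_id", "habitat_group", soil_layer))
  if (length(varnames) == 0L)
    hs_stop("habsim_value_error", "no continuous variables in samples")
  rows <- lapply(varnames, function(nm) {
    v <- samples[[nm]]
    v <- v[!is.na(v)]
    n <- length(v)
    if (n < 2L)
      hs_stop("habsim_insufficient_data_error",
              "variable '%s' has %d non-missing value(s); at least 2 required", nm, n)
    m <- mean(v)
    s <- stats::sd(v)                    # n - 1 denominator
    data.frame(name = nm, n = n, min = min(v), max = max(v), mean = m,
               sd = s, se = s / sqrt(n), mad = mean(abs(v - m)),
               zero_spread = s == 0, stringsAsFactors = FALSE)
  })
  variables <- do.call(rbind, rows)
  soils <- character(0)
  if (!is.null(soil_layer)) {
    if (!soil_layer %in% names(samples))
      hs_stop("habsim_value_error", "soil column '%s' not in samples", soil_layer)
    codes <- unique(samples[[soil_layer]])
    codes <- codes[!is.na(codes)]
    soils <- if (!is.null(soil_taxonomy)) {
      i <- match(codes, soil_taxonomy$code)
      if (anyNA(i))
        hs_stop("habsim_value_error", "soil code(s) %s missing from taxonomy",
                paste(codes[is.na(i)], collapse = ", "))
      as.character(soil_taxonomy$path[i])
    } else as.character(codes)
    soils <- sort(unique(soils))
  }
  structure(list(variables = variables, soils = soils, n_plots = nrow(samples)),
            class = "eco_envelope")
}

#' @export
print.eco_envelope <- function(x, ...) {
  cat(sprintf("<eco_envelope> %d variables from %d plots; %d soil type(s)\n",
              nrow(x$variables), x$n_plots, length(x$soils)))
  print(x$variables, row.names = FALSE)
  invisible(x)
}

#' Render the envelope as a summary table
#'
#' One row per variable with the columns of a conventional habitat-factor
#' table: range, mean +/- SE and the coefficient of variation (delegated to
#' [coefficient_of_variation()], rendered half-up to one decimal; `"0.0"` for
#' zero-spread variables).
#'
#' @param env An [build_envelope()] result.
#' @param units Optional named character vector of per-variable units.
#' @return A data.frame with columns `variable`, `unit`, `range`,
#'   `mean_se`, `cv_pct`.
#' @export
envelope_report <- function(env, units = NULL) {
  v <- env$variables
  cv <- vapply(seq_len(nrow(v)), function(i) {
    if (v$sd[i] == 0) 0 else coefficient_of_variation(v$mean[i], v$sd[i])
  }, numeric(1))
  data.frame(
    variable = v$name,
    unit = if (is.null(units)) "" else unname(units[v$name]),
    range = sprintf("%s, %s", format(v$min, trim = TRUE), format(v$max, trim = TRUE)),
    mean_se = sprintf("%s ± %s", format(v$mean, trim = TRUE),
                      format(signif(v$se, 3), trim = TRUE)),
    cv_pct = render_num(cv, 1),
    stringsAsFactors = FALSE
  )
}

#' Serialize / restore an envelope
#'
#' Two on-disk forms: a CSV of the per-variable table (report-friendly) and a
#' structured `key: value` config text that captures the variables, the soil
#' set and the plot count, so a prediction run can be reproduced from the
#' envelope file alone without the original plots. [read_envelope()] reads
#' the config form.
#'
#' @param env An `eco_envelope`.
#' @param path Output path.
#' @param format `"config"` (full, default) or `"csv"` (variables table only).
#' @return Invisibly, `path`.
#' @export
write_envelope <- function(env, path, format = c("config", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(env$variables, path, row.names = FALSE)
    return(invisible(path))
  }
  v <- env$variables
  lines <- c("# habitat envelope", sprintf("n_plots: %d", env$n_plots),
             sprintf("soils: %s", paste(env$soils, collapse = " ")),
             sprintf("variables: %d", nrow(v)))
  for (i in seq_len(nrow(v)))
    lines <- c(lines, sprintf(
      "var: %s n=%d min=%.17g max=%.17g mean=%.17g sd=%.17g mad=%.17g",
      v$name[i], v$n[i], v$min[i], v$max[i], v$mean[i], v$sd[i], v$mad[i]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_envelope
#' @export
read_envelope <- function(path) {
  if (!file.exists(path)) hs_stop("habsim_io_error", "envelope file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  get1 <- function(key) {
    ln <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (!length(ln)) hs_stop("habsim_parse_error", "%s: missing '%s:'", path, key)
    trimws(sub(paste0("^", key, ":"), "", ln[1]))
  }
  n_plots <- as.integer(get1("n_plots"))
  soils_raw <- get1("soils")
  soils <- if (nzchar(soils_raw)) strsplit(soils_raw, "\\s+")[[1]] else character(0)
  vlines <- grep("^var: ", lines, value = TRUE)
  rows <- lapply(vlines, function(ln) {
    tok <- strsplit(sub("^var: ", "", ln), "\\s+")[[1]]
    kv <- strsplit(tok[-1], "=", fixed = TRUE)
    vals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                            vapply(kv, `[`, "", 1))
    data.frame(name = tok[1], n = as.integer(vals["n"]), min = vals["min"],
               max = vals["max"], mean = vals["mean"], sd = vals["sd"],
               se = vals["sd"] / sqrt(vals["n"]), mad = vals["mad"],
               zero_spread = vals["sd"] == 0, stringsAsFactors = FALSE)
  })
  variables <- do.call(rbind, rows)
  rownames(variables) <- NULL
  structure(list(variables = variables, soils = soils, n_plots = n_plots),
            class = "eco_envelope")
}
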