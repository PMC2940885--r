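#' Parameters of the similarity analysis
#'
#' Collects the tunables of the envelope-distance method in one validated
#' object.
#'
#' * `q` — Minkowski exponent (>= 1): 1 is the Manhattan distance, 2 (the
#'   default) the Euclidean distance.
#' * `soil_mode` — how the categorical soil score is combined with the
#'   climate similarity: `"weighted"` (default) blends them,
#'   `(1 - w) * s_climate + w * s_soil`; `"mask"` zeroes cells with no soil
#'   affinity; `"off"` ignores soil.
#' * `soil_weight` — w above, in `[0, 1]`. The default `NULL` resolves at run
#'   time to `1 / (k + 1)` where k is the number of continuous variables
#'   used, i.e. soil counts as one factor among k + 1.
#' * `variable_weights` — optional named positive weights per continuous
#'   variable (default: all 1).
#' * `d_ref_policy` — the reference distance mapping distance to the 0-100
#'   similarity scale: `"max"` (default; the largest finite distance over the
#'   analysis extent scores 0), `"percentile:P"` (the P-th percentile, larger
#'   distances clipped to 0), or `"fixed:v"` (a fixed distance in normalized
#'   units). The distance-to-similarity mapping is an interpretation layer of
#'   this package, not a property of the Minkowski distance itself; see the
#'   methods vignette.
#'
#' @param q Minkowski exponent, default 2.
#' @param soil_mode `"weighted"`, `"mask"` or `"off"`.
#' @param soil_weight Numeric in `[0, 1]` or `NULL` (auto `1/(k+1)`).
#' @param variable_weights Named numeric vector or `NULL`.
#' @param d_ref_policy Character policy string.
#' @return An object of class `eco_sim_params`.
#' @export
similarity_params <- function(q = 2, soil_mode = c("weighted", "mask", "off"),
                              soil_weight = NULL, variable_weights = NULL,
                              d_ref_policy = "max") {
  soil_mode <- match.arg(soil_mode)
  if (!is.numeric(q) || length(q) != 1L || q < 1)
    hs_stop("habsim_value_error", "q must be a single number >= 1 (q < 1 is not a metric)")
  if (!is.null(soil_weight) &&
      (!is.numeric(soil_weight) || soil_weight < 0 || soil_weight > 1))
    hs_stop("habsim_value_error", "soil_weight must be in [0, 1]")
  if (!is.null(variable_weights) && any(variable_weights <= 0))
    hs_stop("habsim_value_error", "variable weights must be positive")
  if (!grepl("^(max|percentile:[0-9.]+|fixed:[0-9.eE+-]+)$", d_ref_policy))
    hs_stop("habsim_value_error",
            "d_ref_policy must be 'max', 'percentile:P' or 'fixed:v'")
  structure(list(q = q, soil_mode = soil_mode, soil_weight = soil_weight,
                 variable_weights = variable_weights,
                 d_ref_policy = d_ref_policy),
            class = "eco_sim_params")
}

#' Weighted Minkowski distance
#'
#' `d(x, y; q) = (sum_i w_i |x_i - y_i|^q)^(1/q)` for `q >= 1`; `q = 1` is
#' the Manhattan distance and `q = 2` the Euclidean distance.
#'
#' @param x,y Numeric vectors of equal length.
#' @param q Exponent >= 1.
#' @param weights Optional positive weights (default all 1).
#' @return A non-negative scalar.
#' @export
#' @examples
#' minkowski_distance(c(0, 0), c(3, 4), q = 2)  # 5
#' minkowski_distance(c(0, 0), c(3, 4), q = 1)  # 7
minkowski_distance <- function(x, y, q = 2, weights = NULL) {
  if (length(x) != length(y))
    hs_stop("habsim_value_error", "x and y must have equal length")
  if (q < 1) hs_stop("habsim_value_error", "q must be >= 1 (q < 1 is not a metric)")
  w <- if (is.null(weights)) rep(1, length(x)) else weights
  if (length(w) != length(x))
    hs_stop("habsim_value_error", "weights must match the vector length")
  if (any(w <= 0)) hs_stop("habsim_value_error", "weights must be positive")
  sum(w * abs(x - y)^q)^(1 / q)
}

#' Normalize a stack against an envelope
#'
#' Per-variable standardization by the envelope's mean absolute deviation:
#' each continuous cell value x becomes `(x - mean_env) / mad_env`, so a cell
#' exactly at the native mean maps to 0 and a deviation of one mad maps to 1.
#' This is the classic pre-step that puts heterogeneous factors (metres,
#' millimetres, degrees) on a common scale before a Minkowski distance.
#' Zero-mad (spread-free) variables carry no distance information under this
#' scheme and are excluded with a warning (`strict = TRUE` errors instead).
#'
#' @param stack An [eco_stack()].
#' @param env An [build_envelope()] result covering every continuous layer.
#' @param strict Error on zero-mad variables instead of dropping them.
#' @return An `eco_stack` of the normalized continuous layers (soil layer
#'   dropped).
#' @export
normalize_stack <- function(stack, env, strict = FALSE) {
  cont <- continuous_layers(stack)
  missing <- setdiff(cont, env$variables$name)
  if (length(missing))
    hs_stop("habsim_value_error", "layer(s) missing from the envelope: %s",
            paste(missing, collapse = ", "))
  v <- env$variables
  zero <- cont[v$mad[match(cont, v$name)] == 0]
  if (length(zero)) {
    if (strict)
      hs_stop("habsim_value_error", "zero-spread variable(s): %s",
              paste(zero, collapse = ", "))
    hs_warn("excluding zero-spread variable(s) from the distance: %s",
            paste(zero, collapse = ", "))
    cont <- setdiff(cont, zero)
  }
  if (!length(cont))
    hs_stop("habsim_value_error", "no continuous variables with positive spread")
  layers <- lapply(cont, function(nm) {
    g <- stack$layers[[nm]]
    i <- match(nm, v$name)
    g$values <- (g$values - v$mean[i]) / v$mad[i]
    g
  })
  eco_stack(layers)
}

#' Soil similarity by grade division
#'
#' Scores a soil code against the envelope's observed soil set on the
#' hierarchical taxonomy order < suborder < group < subgroup < family: the
#' score is the deepest shared level divided by 5, maximised over the
#' envelope codes. An exact family match scores 1; codes sharing nothing at
#' the order level score 0.
#'
#' @param code A soil code path (string, see [soil_code()]).
#' @param env_soils Non-empty character vector of envelope soil code paths.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' soil_similarity("O1/S1/G1/U1/F1", c("O1/S1/G1/U1/F1"))  # 1
#' soil_similarity("O1/S2", c("O1/S1/G1"))                 # 0.2
soil_similarity <- function(code, env_soils) {
  if (length(env_soils) == 0L)
    hs_stop("habsim_value_error", "envelope soil set is empty")
  a <- strsplit(as.character(soil_code(code)), "/", fixed = TRUE)[[1]]
  depth <- vapply(env_soils, function(s) {
    b <- strsplit(as.character(s), "/", fixed = TRUE)[[1]]
    k <- min(length(a), length(b))
    same <- a[seq_len(k)] == b[seq_len(k)]
    if (!same[1]) 0L else {
      mis <- which(!same)
      if (length(mis)) mis[1] - 1L else k
    }
  }, integer(1))
  max(depth) / 5
}

# vectorised soil score for a categorical grid: unique codes scored once
soil_score_grid <- function(soil_grid, taxonomy, env_soils) {
  codes <- soil_grid$values
  ucodes <- unique(as.vector(codes))
  ucodes <- ucodes[!is.na(ucodes)]
  paths <- if (!is.null(taxonomy)) {
    i <- match(ucodes, taxonomy$code)
    if (anyNA(i))
      hs_stop("habsim_value_error", "soil raster code(s) missing from taxonomy: %s",
              paste(ucodes[is.na(i)], collapse = ", "))
    as.character(taxonomy$path[i])
  } else as.character(ucodes)
  score <- vapply(paths, soil_similarity, numeric(1), env_soils = env_soils)
  out <- matrix(NA_real_, nrow(codes), ncol(codes))
  out[] <- score[match(as.vector(codes), ucodes)]
  out
}

#' Compute the per-cell similarity map
#'
#' The core of the method. For every cell the continuous layers are
#' normalized against the envelope ([normalize_stack()]), the Minkowski
#' distance d from the cell's normalized vector to the envelope centre (the
#' zero vector) is computed, and distance becomes a climate similarity
#' `s_c = 100 * max(0, 1 - d / d_ref)` where `d_ref` follows
#' `params$d_ref_policy`. The soil grade score `s_s = 100 * soil_similarity`
#' is combined per `params$soil_mode`. Cells with nodata in any used layer
#' are nodata in the result.
#'
#' @param stack An [eco_stack()] (continuous layers plus optional soil
#'   layer).
#' @param env The target envelope.
#' @param params A [similarity_params()] object.
#' @return An object of class `eco_similarity`: an [eco_grid()] of similarity
#'   rates in `[0, 100]` with attributes `d_ref` (the reference distance
#'   used) and `params`.
#' @export
similarity_map <- function(stack, env, params = similarity_params()) {
  norm <- normalize_stack(stack, env)
  cont <- names(norm$layers)
  k <- length(cont)
  w <- if (is.null(params$variable_weights)) stats::setNames(rep(1, k), cont)
       else {
         miss <- setdiff(cont, names(params$variable_weights))
         if (length(miss))
           hs_stop("habsim_value_error", "variable_weights missing for: %s",
                   paste(miss, collapse = ", "))
         params$variable_weights[cont]
       }
  ref <- norm$layers[[1]]
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (nm in cont) acc <- acc + w[[nm]] * abs(norm$layers[[nm]]$values)^params$q
  d <- acc^(1 / params$q)

  pol <- params$d_ref_policy
  finite_d <- d[is.finite(d)]
  if (!length(finite_d))
    hs_stop("habsim_value_error", "no finite distances over the analysis extent")
  d_ref <- if (pol == "max") max(finite_d)
  else if (startsWith(pol, "percentile:"))
    stats::quantile(finite_d, as.numeric(sub("percentile:", "", pol)) / 100,
                    names = FALSE)
  else as.numeric(sub("fixed:", "", pol))
  if (!is.finite(d_ref) || d_ref <= 0)
    hs_stop("habsim_value_error",
            "reference distance must be positive (got %s); is every cell at the envelope mean?",
            format(d_ref))

  s_c <- 100 * pmax(0, 1 - d / d_ref)
  dim(s_c) <- dim(d)                    # pmax drops the matrix shape

  use_soil <- params$soil_mode != "off" && !is.null(stack$soil_layer)
  if (use_soil) {
    if (length(env$soils) == 0L)
      hs_stop("habsim_value_error",
              "soil_mode '%s' requires a non-empty envelope soil set", params$soil_mode)
    s_s <- 100 * soil_score_grid(stack$layers[[stack$soil_layer]],
                                 stack$soil_taxonomy, env$soils)
    if (params$soil_mode == "weighted") {
      wgt <- params$soil_weight %||% (1 / (k + 1))
      s <- (1 - wgt) * s_c + wgt * s_s
    } else {                                  # mask
      s <- ifelse(s_s > 0, s_c, 0)
    }
    s[is.na(s_s) | is.na(s_c)] <- NA_real_
  } else s <- s_c

  out <- eco_grid(s, name = "similarity", cell_size = ref$cell_size,
                  origin = ref$origin, nodata = ref$nodata)
  attr(out, "d_ref") <- d_ref
  attr(out, "params") <- params
  class(out) <- c("eco_similarity", class(out))
  out
}

#' Classify a similarity map into suitability zones
#'
#' Pure thresholding of the similarity rate: `s >= favorable_min` is
#' favorable, `suitable_min <= s < favorable_min` suitable, `s <
#' suitable_min` slightly appropriate. Both boundaries are inclusive at the
#' lower end of their class (a cell at exactly 95 is favorable; exactly 90 is
#' suitable).
#'
#' @param sim An [similarity_map()] result (or any `eco_grid` of rates in
#'   `[0, 100]`).
#' @param favorable_min Lower bound of the favorable class, default 95.
#' @param suitable_min Lower bound of the suitable class, default 90.
#' @return An object of class `eco_class_map`: an `eco_grid` of integer codes
#'   1 = favorable, 2 = suitable, 3 = slightly_appropriate, `NA` = nodata,
#'   with attribute `thresholds`.
#' @export
classify <- function(sim, favorable_min = 95, suitable_min = 90) {
  if (!(suitable_min >= 0 && suitable_min < favorable_min && favorable_min <= 100))
    hs_stop("habsim_threshold_error",
            "need 0 <= suitable_min < favorable_min <= 100 (got %s, %s)",
            format(suitable_min), format(favorable_min))
  s <- sim$values
  cls <- matrix(NA_real_, nrow(s), ncol(s))
  cls[s < suitable_min] <- 3
  cls[s >= suitable_min & s < favorable_min] <- 2
  cls[s >= favorable_min] <- 1
  out <- eco_grid(cls, name = "class", cell_size = sim$cell_size,
                  origin = sim$origin, nodata = 0, categorical = TRUE)
  attr(out, "thresholds") <- c(favorable_min = favorable_min,
                               suitable_min = suitable_min)
  attr(out, "levels") <- c("favorable", "suitable", "slightly_appropriate")
  class(out) <- c("eco_class_map", class(out))
  out
}

#' @export
print.eco_class_map <- function(x, ...) {
  tab <- table(factor(x$values, levels = 1:3,
                      labels = attr(x, "levels")), useNA = "ifany")
  cat("<eco_class_map> cell counts:\n")
  print(tab)
  invisible(x)
}
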