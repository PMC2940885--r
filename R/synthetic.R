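#' Default continuous variables of the synthetic landscape
#'
#' Eleven climate/terrain variables whose centres and native half-ranges
#' mirror the native-habitat envelope of an alpine-plateau species (see the
#' reference table shipped in `inst/extdata/`): high elevation, abundant
#' sunshine, cool temperatures, moderate precipitation.
#'
#' @return data.frame `name, center, native_half` (11 rows).
#' @export
default_variables <- function() {
  data.frame(
    name = c("elevation", "relative_humidity", "sunshine_duration",
             "annual_precipitation", "accumulated_temperature",
             "mean_annual_temperature", "mean_march_temperature",
             "minimum_temperature", "maximum_temperature",
             "mean_minimum_temperature", "mean_maximum_temperature"),
    center = c(3630, 63.7, 2450, 574, 9517, 8.6, -4.5, -19.1, 17.2, -11.2, 10.4),
    native_half = c(1285, 7.1, 403.5, 254, 9629, 4, 3, 7.1, 5.75, 5.25, 6.1),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic landscape
#'
#' Fixes every knob of the generator so that a `(spec, seed)` pair fully
#' determines the fixture. Continuous layers are linear gradients in evenly
#' rotated directions plus seeded Gaussian noise; the layer amplitude is
#' `amplitude_mult` times the variable's native half-range, so the landscape
#' spans a region several times wider than the native envelope, and the noise
#' standard deviation is `noise_frac` of the amplitude (smooth interpolated
#' national surfaces). The planted "truth" zone is the set of cells whose
#' value is within `truth_frac * amplitude` of the variable centre on every
#' layer; with evenly rotated gradients that is a regular 2k-gon around the
#' landscape centre whose boundary sits at the default suitable-similarity
#' contour (see the methods vignette for the geometry). Soil is a Voronoi
#' mosaic of hierarchical taxonomy codes; counties are a rectangular tiling
#' grouped into provinces.
#'
#' @param seed Integer master seed; per-stage substreams are derived from it
#'   by fixed offsets so stages are independently reproducible.
#' @param shape `c(rows, cols)`, default `c(200, 200)`.
#' @param cell_size Cell edge in km, default 1.
#' @param variables data.frame `name, center, native_half`
#'   (default [default_variables()]).
#' @param amplitude_mult Gradient half-amplitude in native half-ranges,
#'   default 3.
#' @param noise_frac Noise sd as a fraction of the amplitude, default 0.005.
#' @param truth_frac Truth-zone half-width as a fraction of the amplitude,
#'   default 0.105.
#' @param counties `c(n_rows, n_cols)` of the county tiling, default
#'   `c(10, 10)`.
#' @param provinces `c(n_rows, n_cols)` of province blocks, default
#'   `c(2, 2)`.
#' @param n_soil_patches Number of Voronoi soil patches, default 30.
#' @param soil_levels Taxonomy sizes `c(orders, suborders, groups, subgroups,
#'   families)`, default `c(4, 8, 16, 28, 40)` (a national taxonomy scaled
#'   down about 10-20x).
#' @return A list of class `eco_landscape_spec`.
#' @export
landscape_spec <- function(seed = 1L, shape = c(200, 200), cell_size = 1,
                           variables = default_variables(),
                           amplitude_mult = 3, noise_frac = 0.005,
                           truth_frac = 0.105,
                           counties = c(10, 10), provinces = c(2, 2),
                           n_soil_patches = 30,
                           soil_levels = c(4, 8, 16, 28, 40)) {
  if (any(shape < 2)) hs_stop("habsim_value_error", "degenerate landscape shape")
  if (truth_frac <= 0 || truth_frac >= 1)
    hs_stop("habsim_value_error", "truth_frac must be in (0, 1)")
  if (any(diff(soil_levels) < 0))
    hs_stop("habsim_value_error", "soil taxonomy sizes must be non-decreasing")
  structure(list(seed = as.integer(seed), shape = as.integer(shape),
                 cell_size = cell_size, variables = variables,
                 amplitude_mult = amplitude_mult, noise_frac = noise_frac,
                 truth_frac = truth_frac, counties = as.integer(counties),
                 provinces = as.integer(provinces),
                 n_soil_patches = as.integer(n_soil_patches),
                 soil_levels = as.integer(soil_levels)),
            class = "eco_landscape_spec")
}

# seed substreams: one master seed fans out by fixed offsets per stage
stage_seed <- function(seed, stage)
  (as.integer(seed) + 7919L * switch(stage, layers = 1L, soil = 2L,
                                     plots = 3L, survey = 4L)) %% .Machine$integer.max

# build the rectangular county tiling as polygon-mode regions
county_tiling <- function(spec) {
  nr <- spec$shape[1]; nc <- spec$shape[2]; cs <- spec$cell_size
  H <- nr * cs; W <- nc * cs
  cty <- spec$counties; prv <- spec$provinces
  h <- H / cty[1]; w <- W / cty[2]
  ids <- character(0); provs <- character(0); geom <- list()
  for (i in seq_len(cty[1])) for (j in seq_len(cty[2])) {
    x0 <- (j - 1) * w; y1 <- H - (i - 1) * h
    ring <- rbind(c(x0, y1 - h), c(x0 + w, y1 - h), c(x0 + w, y1), c(x0, y1))
    geom[[length(geom) + 1L]] <- list(ring)
    ids <- c(ids, sprintf("C%03d", (i - 1) * cty[2] + j))
    pi_ <- ceiling(i / (cty[1] / prv[1])); pj <- ceiling(j / (cty[2] / prv[2]))
    provs <- c(provs, sprintf("P%02d", (pi_ - 1) * prv[2] + pj))
  }
  eco_regions(data.frame(region_id = ids, province_id = provs,
                         stringsAsFactors = FALSE), geometry = geom)
}

# hierarchical soil taxonomy: each level's members get a parent in the level
# above; returns data.frame code (1..n_families), path ("Ox/Sx/Gx/Ux/Fx")
make_soil_taxonomy <- function(soil_levels, seed) {
  set.seed(seed)
  prefix <- c("O", "S", "G", "U", "F")
  parent <- vector("list", 5)
  for (lev in 2:5)
    parent[[lev]] <- sample.int(soil_levels[lev - 1], soil_levels[lev], replace = TRUE)
  path_of <- function(fam) {
    u <- parent[[5]][fam]; g <- parent[[4]][u]; s <- parent[[3]][g]; o <- parent[[2]][s]
    sprintf("O%d/S%d/G%d/U%d/F%d", o, s, g, u, fam)
  }
  data.frame(code = seq_len(soil_levels[5]),
             path = vapply(seq_len(soil_levels[5]), path_of, character(1)),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic landscape with known ground truth
#'
#' Builds the full fixture bundle: a variable stack (continuous gradients
#' plus a Voronoi soil mosaic), the planted truth zone, and the county
#' tiling. Identical `spec` (including its seed) reproduces the landscape
#' exactly.
#'
#' @param spec A [landscape_spec()].
#' @return A list of class `eco_landscape`: `stack` (an [eco_stack()] with
#'   soil layer and taxonomy), `truth` (an [eco_grid()] of 0/1, 1 = planted
#'   suitable zone), `regions` (an [eco_regions()] county tiling) and `spec`.
#' @export
make_landscape <- function(spec = landscape_spec()) {
  nr <- spec$shape[1]; nc <- spec$shape[2]; cs <- spec$cell_size
  vars <- spec$variables
  k <- nrow(vars)
  origin <- c(0, nr * cs)
  cx <- nc * cs / 2; cy <- nr * cs / 2
  xs <- (seq_len(nc) - 0.5) * cs
  ys <- origin[2] - (seq_len(nr) - 0.5) * cs
  dx <- matrix(rep(xs - cx, each = nr), nr, nc)
  dy <- matrix(rep(ys - cy, times = nc), nr, nc)
  r_max <- sqrt(max(dx)^2 + max(dy)^2)

  set.seed(stage_seed(spec$seed, "layers"))
  layers <- vector("list", k)
  truth <- matrix(TRUE, nr, nc)
  for (l in seq_len(k)) {
    theta <- 2 * pi * (l - 1) / k
    amp <- spec$amplitude_mult * vars$native_half[l]
    proj <- (cos(theta) * dx + sin(theta) * dy) / r_max
    v <- vars$center[l] + amp * proj +
      matrix(stats::rnorm(nr * nc, sd = spec$noise_frac * amp), nr, nc)
    truth <- truth & (abs(v - vars$center[l]) <= spec$truth_frac * amp)
    layers[[l]] <- eco_grid(v, name = vars$name[l], cell_size = cs, origin = origin)
  }
  if (!any(truth))
    hs_stop("habsim_value_error", "planted truth zone is empty; widen truth_frac")

  set.seed(stage_seed(spec$seed, "soil"))
  taxonomy <- make_soil_taxonomy(spec$soil_levels, stage_seed(spec$seed, "soil"))
  sx <- stats::runif(spec$n_soil_patches, 0, nc * cs)
  sy <- stats::runif(spec$n_soil_patches, 0, nr * cs)
  fam <- sample.int(spec$soil_levels[5], spec$n_soil_patches, replace = TRUE)
  # nearest Voronoi site per cell
  px <- as.vector(matrix(rep(xs, each = nr), nr, nc))
  py <- as.vector(matrix(rep(ys, times = nc), nr, nc))
  nearest <- max.col(-outer(px, sx, function(a, b) (a - b)^2) -
                      outer(py, sy, function(a, b) (a - b)^2))
  soil <- eco_grid(matrix(fam[nearest], nr, nc), name = "soil_type",
                   cell_size = cs, origin = origin, categorical = TRUE)
  stack <- eco_stack(c(layers, list(soil)), soil_layer = "soil_type",
                     soil_taxonomy = taxonomy)
  truth_grid <- eco_grid(matrix(as.numeric(truth), nr, nc), name = "truth",
                         cell_size = cs, origin = origin, categorical = TRUE)
  structure(list(stack = stack, truth = truth_grid,
                 regions = county_tiling(spec), spec = spec),
            class = "eco_landscape")
}

#' @export
print.eco_landscape <- function(x, ...) {
  cat(sprintf("<eco_landscape> %d x %d cells, %d layers, truth zone %d cells (%.2f%%)\n",
              x$spec$shape[1], x$spec$shape[2], length(x$stack$layers),
              sum(x$truth$values == 1), 100 * mean(x$truth$values == 1)))
  invisible(x)
}

#' Sample native-habitat plots from the truth zone
#'
#' Draws `n` cells uniformly without replacement from the planted truth zone
#' and places one plot at each cell centre; `habitat_group` is the county
#' containing the plot.
#'
#' @param landscape A [make_landscape()] result.
#' @param n Number of plots, default 206.
#' @param seed Optional seed override (default: the landscape's plot
#'   substream).
#' @return An `eco_plots` table (see [plot_table()]).
#' @export
make_plots <- function(landscape, n = 206, seed = NULL) {
  truth <- landscape$truth
  cells <- which(truth$values == 1)
  if (length(cells) < n)
    hs_stop("habsim_value_error",
            "truth zone has %d cells, fewer than the %d plots requested",
            length(cells), n)
  set.seed(seed %||% stage_seed(landscape$spec$seed, "plots"))
  pick <- sample(cells, n)
  nr <- nrow(truth$values)
  rows <- (pick - 1) %% nr + 1
  cols <- (pick - 1) %/% nr + 1
  x <- grid_cell_x(truth, cols)
  y <- grid_cell_y(truth, rows)
  idx <- region_cell_index(landscape$regions, truth)
  group <- landscape$regions$table$region_id[idx[cbind(rows, cols)]]
  plot_table(sprintf("plot_%03d", seq_len(n)), x, y, group)
}

#' Region-level ground truth
#'
#' The set of counties that genuinely hold the species: counties where at
#' least a fraction `tau` of cells lie in the planted truth zone (the same
#' coverage rule [region_class()] applies to predictions).
#'
#' @param landscape A [make_landscape()] result.
#' @param tau Coverage fraction, default 0.05.
#' @return Character vector of region ids.
#' @export
truth_region_set <- function(landscape, tau = 0.05) {
  idx <- region_cell_index(landscape$regions, landscape$truth)
  tv <- landscape$truth$values
  n_reg <- nrow(landscape$regions$table)
  keep <- !is.na(idx)
  ri <- factor(idx[keep], levels = seq_len(n_reg))
  n_cells <- as.integer(table(ri))
  n_truth <- as.integer(table(ri[tv[keep] == 1]))
  landscape$regions$table$region_id[n_cells > 0 & n_truth / pmax(n_cells, 1) >= tau]
}

#' Derive a survey record set from the regional truth
#'
#' Emulates an imperfect field survey: each truth region is dropped with
#' probability `omission` (unsurveyed or missed occurrences) and each
#' non-truth region is added with probability `commission` (records of
#' related species or misidentifications).
#'
#' @param truth_regions Character vector of true region ids.
#' @param all_regions Character vector of every region id (for commission).
#' @param omission,commission Rates in `[0, 1]`.
#' @param seed Integer seed.
#' @return Character vector of surveyed region ids (possibly empty).
#' @export
make_survey <- function(truth_regions, all_regions, omission = 0,
                        commission = 0, seed = 1L) {
  if (omission < 0 || omission > 1 || commission < 0 || commission > 1)
    hs_stop("habsim_value_error", "omission and commission must be in [0, 1]")
  set.seed(seed)
  kept <- truth_regions[stats::runif(length(truth_regions)) >= omission]
  extra_pool <- setdiff(all_regions, truth_regions)
  extra <- extra_pool[stats::runif(length(extra_pool)) < commission]
  sort(unique(c(kept, extra)))
}
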