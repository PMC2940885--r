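# Shared fixture builders. Everything is generated in code under fixed seeds.

# a small landscape that exercises the full pipeline quickly
tiny_spec <- function(seed = 1L, shape = c(50, 50), counties = c(5, 5),
                      n_soil_patches = 8, ...) {
  landscape_spec(seed = seed, shape = shape, counties = counties,
                 n_soil_patches = n_soil_patches, ...)
}

# plain 2-layer congruent stack from matrices
stack_of <- function(..., cell_size = 1) {
  mats <- list(...)
  layers <- lapply(seq_along(mats), function(i)
    eco_grid(mats[[i]], name = names(mats)[i] %||% paste0("v", i),
             cell_size = cell_size))
  eco_stack(layers)
}

# a small pool of valid soil taxonomy paths for enumeration tests
make_soil_taxonomy_for_test <- function() {
  c("O1/S1/G1/U1/F1", "O1/S1/G1/U1/F2", "O1/S1/G2/U3/F5", "O1/S2/G3/U4/F6",
    "O1/S2", "O2/S4/G6/U8/F9", "O2/S4/G6", "O2/S5", "O3/S6/G7/U9/F10",
    "O3/S6/G8", "O4/S7/G9/U10/F11", "O4/S8")
}

# full pipeline on one seed; returns the quantities the recovery tests assert
pipeline_metrics <- function(seed, spec = landscape_spec(seed = seed),
                             omission = 0, commission = 0,
                             n_plots = if (all(spec$shape >= 200)) 206 else 30) {
  land <- make_landscape(spec)
  plots <- make_plots(land, n = n_plots)
  samples <- sample_at_points(land$stack, plots)
  env <- build_envelope(samples, soil_layer = "soil_type",
                        soil_taxonomy = land$stack$soil_taxonomy)
  sim <- similarity_map(land$stack, env)
  cls <- classify(sim)
  pred_cells <- cls$values <= 2
  truth_cells <- land$truth$values == 1
  assignments <- region_class(cls, land$regions)
  truth_reg <- truth_region_set(land)
  survey <- make_survey(truth_reg, land$regions$table$region_id,
                        omission = omission, commission = commission,
                        seed = seed + 31657L)
  rep <- overlap_report(predicted_regions(assignments), survey)
  list(land = land, plots = plots, env = env, sim = sim, cls = cls,
       jaccard = sum(pred_cells & truth_cells) / sum(pred_cells | truth_cells),
       survey_coverage = rep$pct_survey_covered, report = rep)
}

# simulate plot samples with a planted two-factor structure: a dominant
# temperature axis and an orthogonal moisture axis driving disjoint variable
# blocks, with small independent noise
planted_factor_samples <- function(n = 206, noise_sd = 0.2, seed = 42) {
  set.seed(seed)
  temp <- rnorm(n); moist <- rnorm(n)
  temp_vars <- c("maximum_temperature", "mean_maximum_temperature",
                 "mean_annual_temperature", "accumulated_temperature",
                 "minimum_temperature", "mean_minimum_temperature")
  moist_vars <- c("annual_precipitation", "relative_humidity",
                  "mean_march_humidity")
  out <- sapply(temp_vars, function(v) temp + rnorm(n, sd = noise_sd))
  out <- cbind(out, sapply(moist_vars, function(v) moist + rnorm(n, sd = noise_sd)))
  out
}
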