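# the core: normalization, Minkowski distance, soil grading, similarity map

test_that("normalization maps envelope mean to 0 and mean + mad to 1", {
  samples <- data.frame(plot_id = as.character(1:4), habitat_group = "g",
                        v = c(2, 4, 6, 8))
  env <- build_envelope(samples)       # mean 5, mad 2
  st <- stack_of(v = matrix(c(5, 7, 3, 5), 2, 2))
  nm <- normalize_stack(st, env)
  expect_equal(nm$layers$v$values, matrix(c(0, 1, -1, 0), 2, 2))
})

test_that("self-normalization: plot samples get mean 0 and mad 1", {
  land <- make_landscape(tiny_spec(6))
  plots <- make_plots(land, n = 25)
  samples <- sample_at_points(land$stack, plots)
  env <- build_envelope(samples, soil_layer = "soil_type")
  nm <- normalize_stack(land$stack, env)
  for (nmname in names(nm$layers)) {
    g <- nm$layers[[nmname]]
    rc <- point_to_cell(g, plots$x, plots$y)
    z <- g$values[cbind(rc$row, rc$col)]
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(mean(abs(z - mean(z))) - 1), 1e-9)
  }
})

test_that("zero-spread variables are dropped with a warning (or error in strict mode)", {
  samples <- data.frame(plot_id = as.character(1:3), habitat_group = "g",
                        ok = c(1, 2, 3), flat = c(5, 5, 5))
  env <- build_envelope(samples)
  st <- stack_of(ok = matrix(rnorm(4), 2, 2), flat = matrix(5, 2, 2))
  expect_warning(nm <- normalize_stack(st, env), "flat")
  expect_named(nm$layers, "ok")
  expect_error(normalize_stack(st, env, strict = TRUE), class = "habsim_value_error")
  st2 <- stack_of(extra = matrix(0, 2, 2))
  expect_error(normalize_stack(st2, env), class = "habsim_value_error")
})

test_that("Minkowski distance reproduces hand values and validates input", {
  expect_equal(minkowski_distance(c(0, 0), c(3, 4), q = 2), 5)
  expect_equal(minkowski_distance(c(0, 0), c(3, 4), q = 1), 7)
  for (q in c(1, 1.5, 2, 4)) expect_equal(minkowski_distance(1:5, 1:5, q), 0)
  expect_equal(minkowski_distance(0, 2, q = 2, weights = 9), 6)
  expect_error(minkowski_distance(1:3, 1:4), class = "habsim_value_error")
  expect_error(minkowski_distance(1:3, 4:6, q = 0.5), class = "habsim_value_error")
  expect_error(similarity_params(q = 0.5), class = "habsim_value_error")
})

test_that("metric properties hold on 1000 seeded random triples", {
  set.seed(1000)
  for (i in 1:1000) {
    n <- sample(2:6, 1)
    x <- rnorm(n); y <- rnorm(n); z <- rnorm(n)
    q <- sample(c(1, 1.5, 2, 3), 1)
    dxy <- minkowski_distance(x, y, q)
    expect_identical(dxy, minkowski_distance(y, x, q))          # symmetry
    expect_gte(dxy, 0)
    expect_lte(dxy, minkowski_distance(x, z, q) +
                    minkowski_distance(z, y, q) + 1e-12)        # triangle
  }
})

test_that("distance is non-increasing in q for fixed vectors", {
  set.seed(77)
  qs <- c(1, 1.5, 2, 3, 5, 10)
  for (i in 1:50) {
    x <- rnorm(6); y <- rnorm(6)
    d <- vapply(qs, function(q) minkowski_distance(x, y, q), numeric(1))
    expect_true(all(diff(d) <= 1e-12))
  }
})

test_that("soil grade division scores shared taxonomy depth out of 5", {
  expect_equal(soil_similarity("O1/S1/G1/U1/F1", "O1/S1/G1/U1/F1"), 1)
  expect_equal(soil_similarity("O1/S2", "O1/S1/G1"), 0.2)
  expect_equal(soil_similarity("O2/S9", "O1/S1"), 0)
  # max over the envelope set: shares a subgroup with one code, nothing with
  # the other
  envs <- c("O1/S1/G1/U1/F9", "O7/S7/G7/U7/F7")
  expect_equal(soil_similarity("O1/S1/G1/U1/F1", envs), 0.8)
  # enumeration oracle over a random envelope set
  set.seed(14)
  tax <- make_soil_taxonomy_for_test()
  for (i in 1:20) {
    code <- sample(tax, 1)
    env_soils <- sample(tax, 4)
    oracle <- max(vapply(env_soils, function(s) {
      a <- strsplit(code, "/")[[1]]; b <- strsplit(s, "/")[[1]]
      d <- 0L
      for (k in seq_len(min(length(a), length(b)))) {
        if (a[k] == b[k]) d <- k else break
      }
      d / 5
    }, numeric(1)))
    expect_equal(soil_similarity(code, env_soils), oracle)
  }
  expect_error(soil_similarity("O1", character(0)), class = "habsim_value_error")
})

test_that("similarity map equals a cell-by-cell scalar-loop oracle to 1e-9", {
  land <- make_landscape(tiny_spec(2))
  plots <- make_plots(land, n = 35)
  env <- build_envelope(sample_at_points(land$stack, plots),
                        soil_layer = "soil_type",
                        soil_taxonomy = land$stack$soil_taxonomy)
  params <- similarity_params(q = 2)
  sim <- similarity_map(land$stack, env, params)

  # oracle: per-cell scalar loop through the published formulas
  cont <- setdiff(names(land$stack$layers), "soil_type")
  v <- env$variables
  nr <- nrow(sim$values); nc <- ncol(sim$values)
  d <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    z <- vapply(cont, function(nm) {
      i <- match(nm, v$name)
      (land$stack$layers[[nm]]$values[r, c] - v$mean[i]) / v$mad[i]
    }, numeric(1))
    d[r, c] <- minkowski_distance(z, rep(0, length(z)), q = 2)
  }
  d_ref <- max(d)
  expect_equal(attr(sim, "d_ref"), d_ref, tolerance = 1e-12)
  w <- 1 / (length(cont) + 1)
  s_or <- matrix(NA_real_, nr, nc)
  tax <- land$stack$soil_taxonomy
  soil <- land$stack$layers$soil_type$values
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    s_c <- 100 * max(0, 1 - d[r, c] / d_ref)
    s_s <- 100 * soil_similarity(tax$path[match(soil[r, c], tax$code)], env$soils)
    s_or[r, c] <- (1 - w) * s_c + w * s_s
  }
  expect_lt(max(abs(sim$values - s_or)), 1e-9)
})

test_that("similarity endpoints: envelope centre scores 100, d_ref scores 0", {
  samples <- data.frame(plot_id = as.character(1:4), habitat_group = "g",
                        a = c(9, 11, 10, 10), b = c(0, 2, 1, 1))
  env <- build_envelope(samples)       # means 10, 1
  st <- stack_of(a = matrix(c(10, 12, 14, 10), 2, 2),
                 b = matrix(c(1, 3, 5, 1), 2, 2))
  sim <- similarity_map(st, env, similarity_params(soil_mode = "off"))
  expect_equal(sim$values[1, 1], 100)   # exactly at the envelope means
  far <- which.max(abs(st$layers$a$values - 10) + abs(st$layers$b$values - 1))
  expect_equal(sim$values[far], 0)      # the reference-distance cell
  expect_true(all(sim$values >= 0 & sim$values <= 100))
})

test_that("soil modes combine as documented and nodata propagates", {
  samples <- data.frame(plot_id = as.character(1:3), habitat_group = "g",
                        a = c(-1, 0, 1), soil = c(1, 1, 1))
  tax <- data.frame(code = 1:2, path = c("O1/S1/G1/U1/F1", "O2/S2"))
  env <- build_envelope(samples, soil_layer = "soil", soil_taxonomy = tax)
  a <- matrix(c(0, 1, NA, 0), 2, 2)
  soil <- eco_grid(matrix(c(1, 2, 1, 1), 2, 2), name = "soil", categorical = TRUE)
  st <- eco_stack(list(eco_grid(a, name = "a"), soil), soil_layer = "soil",
                  soil_taxonomy = tax)
  w <- 1 / 2                                        # one variable -> w = 1/(1+1)
  sim_w <- similarity_map(st, env, similarity_params(soil_mode = "weighted"))
  d_ref <- attr(sim_w, "d_ref")
  s_c <- 100 * (1 - abs(a) / (2 / 3) / d_ref)       # mad = 2/3; all d <= d_ref
  expect_equal(sim_w$values[1, 1], (1 - w) * s_c[1, 1] + w * 100)
  expect_equal(sim_w$values[2, 1], (1 - w) * s_c[2, 1] + w * 0)  # disjoint order
  expect_true(is.na(sim_w$values[1, 2]))            # nodata in a layer
  sim_m <- similarity_map(st, env, similarity_params(soil_mode = "mask"))
  expect_equal(sim_m$values[2, 1], 0)               # no soil affinity -> 0
  expect_equal(sim_m$values[1, 1], s_c[1, 1])
  sim_o <- similarity_map(st, env, similarity_params(soil_mode = "off"))
  expect_equal(sim_o$values[2, 1], s_c[2, 1])
})

test_that("shrinking any coordinate deviation never lowers similarity", {
  set.seed(55)
  for (i in 1:100) {
    x <- rnorm(5); q <- sample(c(1, 2, 3), 1)
    j <- sample(5, 1)
    x2 <- x; x2[j] <- x2[j] * runif(1)       # shrink |x_j - 0|
    d_ref <- 10
    s1 <- 100 * max(0, 1 - minkowski_distance(x, rep(0, 5), q) / d_ref)
    s2 <- 100 * max(0, 1 - minkowski_distance(x2, rep(0, 5), q) / d_ref)
    expect_gte(s2, s1 - 1e-12)
  }
})

test_that("classification thresholds are inclusive at class lower bounds", {
  s <- eco_grid(matrix(c(95, 90, 89.999, 100, 94.999, NA), 2, 3))
  cls <- classify(s)
  expect_equal(cls$values[1, 1], 1)   # 95.0 is favorable
  expect_equal(cls$values[2, 1], 2)   # 90.0 is suitable
  expect_equal(cls$values[1, 2], 3)   # 89.999 is slightly appropriate
  expect_equal(cls$values[2, 2], 1)
  expect_equal(cls$values[1, 3], 2)   # 94.999 stays suitable
  expect_true(is.na(cls$values[2, 3]))
  expect_error(classify(s, favorable_min = 80, suitable_min = 90),
               class = "habsim_threshold_error")
})

test_that("native plots score at or above the landscape median similarity", {
  m <- pipeline_metrics(3, spec = tiny_spec(3))
  rc <- point_to_cell(m$sim, m$plots$x, m$plots$y)
  plot_scores <- m$sim$values[cbind(rc$row, rc$col)]
  expect_true(all(plot_scores >= median(m$sim$values, na.rm = TRUE)))
})
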