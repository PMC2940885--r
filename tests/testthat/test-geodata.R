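# rasters, stacks, point sampling, regions, plots

test_that("congruent layers stack; misaligned layers raise a named error", {
  a <- eco_grid(matrix(1:100, 10, 10), name = "a")
  b <- eco_grid(matrix(runif(100), 10, 10), name = "b")
  s <- eco_stack(list(a, b))
  expect_length(s$layers, 2)

  wide <- eco_grid(matrix(0, 10, 11), name = "wide")
  err <- expect_error(eco_stack(list(a, wide)), class = "habsim_alignment_error")
  expect_match(conditionMessage(err), "wide")

  shifted <- eco_grid(matrix(0, 10, 10), name = "shifted", origin = c(1, 10))
  expect_error(eco_stack(list(a, shifted)), class = "habsim_alignment_error")
  expect_error(eco_stack(list(a, eco_grid(matrix(0, 10, 10), name = "a"))),
               class = "habsim_value_error")
})

test_that("ASCII grid write/read round-trips continuous values to double precision", {
  withr::local_seed(7)
  g <- eco_grid(matrix(rnorm(120) * 1e3, 10, 12), name = "elev",
                cell_size = 0.5, origin = c(3.25, 10.75))
  g$values[c(5, 40)] <- NA
  p <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, p)
  h <- read_ascii_grid(p, name = "elev")
  expect_equal(h$values, g$values, tolerance = 1e-12)
  expect_equal(h$cell_size, g$cell_size)
  expect_equal(h$origin, g$origin)
  # a 12-layer synthetic stack round-trips bit for bit
  land <- make_landscape(tiny_spec(3))
  dir <- withr::local_tempdir()
  write_stack(land$stack, dir)
  back <- read_stack(sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE)),
                     soil_layer = "soil_type",
                     soil_taxonomy_path = file.path(dir, "soil_taxonomy.csv"))
  for (nm in names(land$stack$layers))
    expect_identical(back$layers[[nm]]$values, land$stack$layers[[nm]]$values)
})

test_that("categorical grids round-trip exactly and reject nodata as a code", {
  g <- eco_grid(matrix(sample(1:9, 64, TRUE), 8, 8), name = "soil",
                categorical = TRUE)
  p <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, p)
  expect_identical(read_ascii_grid(p, categorical = TRUE)$values, g$values)
  expect_error(eco_grid(matrix(c(1, -9999), 1, 2), categorical = TRUE),
               class = "habsim_value_error")
})

test_that("points map to containing cells with deterministic edge ties", {
  g <- eco_grid(matrix(seq_len(20), 4, 5), cell_size = 2, origin = c(10, 8))
  # centre of cell (2, 3): x = 10 + 2.5*2 = 15, y = 8 - 1.5*2 = 5
  expect_equal(point_to_cell(g, 15, 5), data.frame(row = 2L, col = 3L))
  # interior shared edge belongs to the east/south cell
  expect_equal(point_to_cell(g, 12, 5)$col, 2L)   # x on edge between cols 1|2
  expect_equal(point_to_cell(g, 15, 4)$row, 3L)   # y on edge between rows 2|3
  # extent maximum edges belong to the last row/column
  expect_equal(point_to_cell(g, 20, 0), data.frame(row = 4L, col = 5L))
  expect_true(is.na(point_to_cell(g, 20.01, 5)$col))
})

test_that("sampling returns cell values; a linear gradient is recovered exactly", {
  nr <- 40; nc <- 40
  xs <- (seq_len(nc) - 0.5); ys <- nr - (seq_len(nr) - 0.5)
  grad <- outer(ys, xs, function(y, x) 3 * x + 7 * y + 1)   # closed form
  st <- stack_of(grad = grad)
  set.seed(11)
  n <- 206
  px <- runif(n, 0, nc); py <- runif(n, 0, nr)
  plots <- plot_table(sprintf("p%03d", 1:n), px, py, "g")
  got <- sample_at_points(st, plots)
  rc <- point_to_cell(st$layers[[1]], px, py)
  expected <- 3 * (rc$col - 0.5) + 7 * (nr - (rc$row - 0.5)) + 1
  expect_equal(got$grad, expected)
})

test_that("sampling is invariant to plot and layer order; nodata yields NA", {
  land <- make_landscape(tiny_spec(5))
  plots <- make_plots(land, n = 25)
  a <- sample_at_points(land$stack, plots)
  perm <- sample(nrow(plots))
  b <- sample_at_points(land$stack, plots[perm, ])
  expect_equal(b[order(b$plot_id), ], a[order(a$plot_id), ],
               ignore_attr = TRUE)
  rev_stack <- eco_stack(rev(land$stack$layers), soil_layer = "soil_type",
                         soil_taxonomy = land$stack$soil_taxonomy)
  c_ <- sample_at_points(rev_stack, plots)
  expect_equal(c_[, names(a)], a, ignore_attr = TRUE)

  st <- stack_of(v = matrix(c(NA, 1, 2, 3), 2, 2))
  got <- sample_at_points(st, plot_table("p1", 0.5, 1.5, "g"))
  expect_true(is.na(got$v))
})

test_that("out-of-extent plots error by default and drop with a warning on request", {
  st <- stack_of(v = matrix(1:4, 2, 2))
  plots <- plot_table(c("in", "out"), c(0.5, 9), c(0.5, 0.5), "g")
  expect_error(sample_at_points(st, plots), class = "habsim_extent_error")
  expect_warning(got <- sample_at_points(st, plots, out_of_extent = "drop"),
                 "1 out-of-extent")
  expect_equal(got$plot_id, "in")
  all_out <- plot_table("far", 99, 99, "g")
  expect_error(suppressWarnings(sample_at_points(st, all_out, "drop")),
               class = "habsim_extent_error")
})

test_that("region GeoJSON round-trips ids and areas; squares have exact areas", {
  sq <- function(x0, y0, w) list(rbind(c(x0, y0), c(x0 + w, y0),
                                       c(x0 + w, y0 + w), c(x0, y0 + w)))
  regions <- eco_regions(
    data.frame(region_id = c("A", "B", "C", "D"),
               province_id = c("P1", "P1", "P2", "P2")),
    geometry = list(sq(0, 0, 10), sq(10, 0, 10), sq(0, 10, 10), sq(10, 10, 10)))
  expect_equal(regions$table$area_km2, rep(100, 4))  # 10 km x 10 km counties
  p <- withr::local_tempfile(fileext = ".geojson")
  write_regions(regions, p)
  back <- read_regions(p)
  expect_identical(back$table$region_id, regions$table$region_id)
  expect_equal(back$table$area_km2, regions$table$area_km2)
})

test_that("duplicate identifiers are validation errors", {
  expect_error(plot_table(c("p1", "p1"), 1:2, 1:2, "g"),
               class = "habsim_validation_error")
  pcsv <- withr::local_tempfile(fileext = ".csv")
  writeLines("plot_id,x,y,habitat_group\np1,1,1,a\np1,2,2,a", pcsv)
  expect_error(read_plots(pcsv), class = "habsim_validation_error")
  expect_error(
    eco_regions(data.frame(region_id = c("A", "A"), province_id = "P"),
                geometry = list(list(rbind(c(0, 0), c(1, 0), c(1, 1))),
                                list(rbind(c(0, 0), c(1, 0), c(1, 1))))),
    class = "habsim_validation_error")
})

test_that("soil codes validate top-down filling", {
  expect_equal(unclass(soil_code("O1/S2/G3")), "O1/S2/G3")
  expect_error(soil_code("O1//G3"), class = "habsim_validation_error")
  expect_error(soil_code(""), class = "habsim_validation_error")
})
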