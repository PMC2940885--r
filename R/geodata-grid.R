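#' Create a single raster layer
#'
#' A grid is the raster primitive of the package: a rectangular matrix of cell
#' values on a regular square-cell lattice. Row 1 is the northernmost row; the
#' `origin` is the outer (north-west) corner of cell `[1, 1]`. Coordinates are
#' in ground units, by convention kilometres so that the default
#' `cell_size = 1` reproduces the 1.0 x 1.0 km analysis grid the method was
#' designed around. Missing cells are stored as `NA`; `nodata` is only the
#' sentinel used on disk.
#'
#' @param values Numeric matrix (rows x cols). Integer codes for categorical
#'   layers.
#' @param name Layer name.
#' @param cell_size Edge length of a cell in ground units (> 0), default 1
#'   (km).
#' @param origin Length-2 numeric `c(x, y)`: the outer corner of cell
#'   `[1, 1]`, i.e. `(xmin, ymax)` of the extent.
#' @param nodata Sentinel written to / recognised in files (default -9999).
#' @param categorical Logical; `TRUE` for integer-coded class layers (e.g.
#'   soil types), which are round-tripped exactly.
#' @return An object of class `eco_grid`.
#' @seealso [read_ascii_grid()], [write_ascii_grid()], [eco_stack()]
#' @export
eco_grid <- function(values, name = "layer", cell_size = 1,
                     origin = c(0, nrow(values) * cell_size),
                     nodata = -9999, categorical = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    hs_stop("habsim_shape_error", "grid '%s' must have at least one row and column", name)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    hs_stop("habsim_shape_error", "cell_size must be a single positive number")
  if (length(origin) != 2L)
    hs_stop("habsim_shape_error", "origin must be c(x, y)")
  if (categorical && any(values == nodata, na.rm = TRUE))
    hs_stop("habsim_value_error",
            "categorical grid '%s' uses the nodata sentinel %s as a category code",
            name, format(nodata))
  if (categorical) storage.mode(values) <- "integer"
  structure(
    list(name = name, values = values, cell_size = cell_size,
         origin = as.numeric(origin), nodata = nodata,
         categorical = isTRUE(categorical)),
    class = "eco_grid"
  )
}

#' @export
print.eco_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<eco_grid> '%s': %d x %d cells of %g ground units%s\n",
              x$name, nrow(v), ncol(v), x$cell_size,
              if (x$categorical) " (categorical)" else ""))
  cat(sprintf("  origin (NW corner): (%g, %g); NA cells: %d\n",
              x$origin[1], x$origin[2], sum(is.na(v))))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  if (is.finite(rng[1])) cat(sprintf("  value range: [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.eco_grid <- function(x) dim(x$values)

# x-coordinates of cell centres for columns, y for rows
grid_cell_x <- function(grid, cols = seq_len(ncol(grid$values)))
  grid$origin[1] + (cols - 0.5) * grid$cell_size
grid_cell_y <- function(grid, rows = seq_len(nrow(grid$values)))
  grid$origin[2] - (rows - 0.5) * grid$cell_size

#' Map points to the grid cells containing them
#'
#' Deterministic point-to-cell rule: cell `[r, c]` (1-based) covers the
#' half-open square `[x0+(c-1)s, x0+cs) x (y0-rs, y0-(r-1)s]`, so a point on a
#' shared interior edge belongs to the cell east/south of the edge, and points
#' on the extent's maximum edges belong to the last row/column (the extent is
#' closed). Points outside the extent map to `NA`.
#'
#' @param grid An [eco_grid()].
#' @param x,y Numeric vectors of point coordinates in ground units.
#' @return A data.frame with integer columns `row`, `col` (`NA` when outside
#'   the extent).
#' @export
point_to_cell <- function(grid, x, y) {
  s <- grid$cell_size
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col0 <- floor((x - grid$origin[1]) / s)
  row0 <- floor((grid$origin[2] - y) / s)
  # closed maximum edges: x == xmax / y == ymin still belong to the last cell
  col0[x == grid$origin[1] + nc * s] <- nc - 1
  row0[y == grid$origin[2] - nr * s] <- nr - 1
  bad <- col0 < 0 | col0 >= nc | row0 < 0 | row0 >= nr
  col0[bad] <- NA_real_; row0[bad] <- NA_real_
  data.frame(row = as.integer(row0 + 1), col = as.integer(col0 + 1))
}

#' Read an ESRI ASCII grid
#'
#' Parses the plain-text Arc/Info ASCII raster format (`ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' `NODATA_value` header followed by rows north to south). Cells equal to the
#' nodata sentinel become `NA`.
#'
#' @param path File path.
#' @inheritParams eco_grid
#' @return An [eco_grid()].
#' @export
read_ascii_grid <- function(path, name = sub("\\.[^.]*$", "", basename(path)),
                            categorical = FALSE) {
  if (!file.exists(path))
    hs_stop("habsim_io_error", "raster file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2L && tolower(tok[1]) %in%
        c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter", "yllcenter",
          "cellsize", "nodata_value")) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      i <- i + 1L
    } else break
  }
  for (key in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[key]]))
      hs_stop("habsim_io_error", "ASCII grid %s: missing '%s' header", path, key)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  nodata <- hdr$nodata_value %||% -9999
  xll <- hdr$xllcorner %||% (if (!is.null(hdr$xllcenter)) hdr$xllcenter - cs / 2 else 0)
  yll <- hdr$yllcorner %||% (if (!is.null(hdr$yllcenter)) hdr$yllcenter - cs / 2 else 0)
  body <- paste(lines[(i + 1L):length(lines)], collapse = " ")
  vals <- scan(text = body, what = numeric(), quiet = TRUE)
  if (length(vals) != nr * nc)
    hs_stop("habsim_io_error", "ASCII grid %s: expected %d values, found %d",
            path, nr * nc, length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  eco_grid(m, name = name, cell_size = cs,
           origin = c(xll, yll + nr * cs), nodata = nodata,
           categorical = categorical)
}

#' Write an ESRI ASCII grid
#'
#' Inverse of [read_ascii_grid()]. Continuous layers are written with 17
#' significant digits so a write/read round trip reproduces values to
#' double precision; categorical layers are written as integers and round-trip
#' exactly.
#'
#' @param grid An [eco_grid()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ascii_grid <- function(grid, path) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  v[is.na(v)] <- grid$nodata
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10f", grid$origin[1]),
    sprintf("yllcorner %.10f", grid$origin[2] - nr * grid$cell_size),
    sprintf("cellsize %.10f", grid$cell_size),
    sprintf("NODATA_value %s", format(grid$nodata, scientific = FALSE))
  )
  fmt <- if (grid$categorical) function(x) format(x, scientific = FALSE)
         else function(x) formatC(x, format = "g", digits = 17)
  rows <- apply(v, 1, function(r) paste(fmt(r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
write_raster <- write_ascii_grid

#' Assemble aligned layers into a variable stack
#'
#' A stack is the multi-layer environmental database of a study area: an
#' ordered set of congruent grids (identical shape, origin and cell size),
#' containing any number of continuous layers (climate, terrain) and at most
#' one categorical soil layer whose integer codes index a soil-taxonomy table.
#' Misaligned layers are an error: the package never resamples silently.
#'
#' @param layers A list of [eco_grid()] objects with unique names.
#' @param soil_layer Name of the single categorical layer, or `NULL`.
#' @param soil_taxonomy Optional data.frame with columns `code` (integer, the
#'   raster codes of the soil layer) and `path` (a soil code string, see
#'   [soil_code()]).
#' @return An object of class `eco_stack`.
#' @export
eco_stack <- function(layers, soil_layer = NULL, soil_taxonomy = NULL) {
  if (length(layers) < 1L) hs_stop("habsim_shape_error", "a stack needs at least one layer")
  nms <- vapply(layers, function(g) g$name, character(1))
  if (anyDuplicated(nms))
    hs_stop("habsim_value_error", "duplicate layer names: %s",
            paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(layers) <- nms
  ref <- layers[[1]]
  for (g in layers[-1]) {
    if (!identical(dim(g$values), dim(ref$values)))
      hs_stop("habsim_alignment_error",
              "layer '%s' has shape %dx%d, expected %dx%d (layer '%s')",
              g$name, nrow(g$values), ncol(g$values),
              nrow(ref$values), ncol(ref$values), ref$name)
    if (!isTRUE(all.equal(g$origin, ref$origin)) ||
        !isTRUE(all.equal(g$cell_size, ref$cell_size)))
      hs_stop("habsim_alignment_error",
              "layer '%s' origin/cell_size differs from layer '%s'",
              g$name, ref$name)
  }
  if (!is.null(soil_layer)) {
    if (!soil_layer %in% nms)
      hs_stop("habsim_value_error", "soil layer '%s' not among layers", soil_layer)
    layers[[soil_layer]]$categorical <- TRUE
  }
  n_cat <- sum(vapply(layers, function(g) g$categorical, logical(1)))
  if (n_cat > 1L)
    hs_stop("habsim_value_error", "at most one categorical (soil) layer is allowed")
  structure(list(layers = layers, soil_layer = soil_layer,
                 soil_taxonomy = soil_taxonomy),
            class = "eco_stack")
}

#' @export
print.eco_stack <- function(x, ...) {
  ref <- x$layers[[1]]
  cat(sprintf("<eco_stack> %d layers, %d x %d cells of %g units\n",
              length(x$layers), nrow(ref$values), ncol(ref$values), ref$cell_size))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  if (!is.null(x$soil_layer)) cat("  soil layer:", x$soil_layer, "\n")
  invisible(x)
}

# names of the continuous layers of a stack
continuous_layers <- function(stack)
  names(stack$layers)[!vapply(stack$layers, function(g) g$categorical, logical(1))]

#' Read a stack of raster files
#'
#' Reads each path with [read_ascii_grid()] and assembles the result with
#' [eco_stack()]; alignment errors name the offending layer.
#'
#' @param paths Character vector of ESRI ASCII grid paths. Layer names are the
#'   file names without extension.
#' @inheritParams eco_stack
#' @param soil_taxonomy_path Optional CSV (`code,path`) describing the soil
#'   layer's codes.
#' @return An `eco_stack`.
#' @export
read_stack <- function(paths, soil_layer = NULL, soil_taxonomy_path = NULL) {
  layers <- lapply(paths, function(p)
    read_ascii_grid(p, categorical = identical(
      sub("\\.[^.]*$", "", basename(p)), soil_layer)))
  tax <- NULL
  if (!is.null(soil_taxonomy_path)) {
    tax <- utils::read.csv(soil_taxonomy_path, stringsAsFactors = FALSE)
    if (!all(c("code", "path") %in% names(tax)))
      hs_stop("habsim_io_error", "soil taxonomy CSV needs columns 'code' and 'path'")
  }
  eco_stack(layers, soil_layer = soil_layer, soil_taxonomy = tax)
}

#' Write every layer of a stack as ASCII grids
#'
#' @param stack An `eco_stack`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_stack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(stack$layers, function(g) {
    p <- file.path(dir, paste0(g$name, ".asc"))
    write_ascii_grid(g, p)
    p
  }, character(1))
  if (!is.null(stack$soil_taxonomy))
    utils::write.csv(stack$soil_taxonomy,
                     file.path(dir, "soil_taxonomy.csv"), row.names = FALSE)
  invisible(paths)
}

#' Extract layer values at plot locations
#'
#' Each plot receives the value of the cell containing it (nearest-cell
#' lookup, no interpolation; ties broken by the deterministic rule of
#' [point_to_cell()]). `NA` (nodata) cells yield missing values. This is the
#' extraction step that turns field plots into envelope samples.
#'
#' @param stack An [eco_stack()].
#' @param plots A plot table from [read_plots()] or [plot_table()].
#' @param out_of_extent `"error"` (default) rejects any out-of-extent plot;
#'   `"drop"` removes them with a warning reporting the count.
#' @return A data.frame with `plot_id`, `habitat_group` and one column per
#'   layer.
#' @export
sample_at_points <- function(stack, plots, out_of_extent = c("error", "drop")) {
  out_of_extent <- match.arg(out_of_extent)
  ref <- stack$layers[[1]]
  rc <- point_to_cell(ref, plots$x, plots$y)
  outside <- is.na(rc$row)
  if (any(outside)) {
    if (out_of_extent == "error")
      hs_stop("habsim_extent_error",
              "%d plot(s) fall outside the stack extent (first: '%s'); use out_of_extent='drop' to discard them",
              sum(outside), plots$plot_id[which(outside)[1]])
    hs_warn("dropping %d out-of-extent plot(s)", sum(outside))
    plots <- plots[!outside, , drop = FALSE]
    rc <- rc[!outside, , drop = FALSE]
  }
  if (nrow(plots) == 0L)
    hs_stop("habsim_extent_error", "all plots fall outside the stack extent")
  idx <- cbind(rc$row, rc$col)
  out <- data.frame(plot_id = plots$plot_id,
                    habitat_group = plots$habitat_group,
                    stringsAsFactors = FALSE)
  for (nm in names(stack$layers)) out[[nm]] <- stack$layers[[nm]]$values[idx]
  out
}
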