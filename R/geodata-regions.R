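#' Administrative region set
#'
#' Regions (counties grouped into provinces) carry the zoning tallies and the
#' survey validation. Two representations are supported: `polygon` mode, where
#' each region is a polygon (outer ring plus optional holes) in the same
#' ground coordinates as the rasters, and `grid` mode, where a congruent
#' categorical grid holds a region index per cell. Polygon mode is the
#' default throughout.
#'
#' @param table data.frame with columns `region_id` (unique), `province_id`
#'   and optionally `area_km2` (filled from the polygon geometry when absent).
#' @param geometry For polygon mode: a list (one element per region) of lists
#'   of rings, each ring a 2-column matrix of x,y vertices (first ring outer,
#'   further rings holes). For grid mode: `NULL`.
#' @param grid For grid mode: an [eco_grid()] of integer region indices
#'   (1-based row numbers of `table`), `NA` where unassigned.
#' @return An object of class `eco_regions`.
#' @export
eco_regions <- function(table, geometry = NULL, grid = NULL) {
  if (anyDuplicated(table$region_id))
    hs_stop("habsim_validation_error", "duplicate region_id: %s",
            paste(unique(table$region_id[duplicated(table$region_id)]), collapse = ", "))
  mode <- if (!is.null(geometry)) "polygon" else if (!is.null(grid)) "grid" else
    hs_stop("habsim_validation_error", "regions need either polygon geometry or a label grid")
  if (mode == "polygon") {
    if (length(geometry) != nrow(table))
      hs_stop("habsim_validation_error", "geometry length != number of regions")
    if (is.null(table$area_km2))
      table$area_km2 <- vapply(geometry, polygon_area, numeric(1))
  }
  if (!is.null(table$area_km2) && any(table$area_km2 < 0))
    hs_stop("habsim_validation_error", "negative region area")
  structure(list(mode = mode, table = table, geometry = geometry, grid = grid),
            class = "eco_regions")
}

#' @export
print.eco_regions <- function(x, ...) {
  cat(sprintf("<eco_regions> %d regions in %d provinces (%s mode)\n",
              nrow(x$table), length(unique(x$table$province_id)), x$mode))
  invisible(x)
}

# shoelace area of a polygon (list of rings; holes subtract), in ground units^2
polygon_area <- function(rings) {
  ring_area <- function(r) {
    x <- r[, 1]; y <- r[, 2]
    n <- length(x)
    j <- c(n, seq_len(n - 1))
    abs(sum(x[j] * y - x * y[j])) / 2
  }
  a <- ring_area(rings[[1]])
  if (length(rings) > 1)
    a <- a - sum(vapply(rings[-1], ring_area, numeric(1)))
  a
}

# even-odd ray casting: are points (px, py) inside the polygon (list of rings)?
# Vectorised over points; a point inside a hole is outside.
points_in_polygon <- function(rings, px, py) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- nrow(ring)
    # drop explicit closing vertex if present
    if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
    crossed <- rep(FALSE, length(px))
    j <- n
    for (i in seq_len(n)) {
      cond <- ((y[i] > py) != (y[j] > py)) &
        (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
      crossed <- xor(crossed, cond & !is.na(cond))
      j <- i
    }
    inside <- xor(inside, crossed)
  }
  inside
}

# per-cell region index (integer matrix, NA = unassigned): a cell belongs to
# the region whose polygon contains its centre (first match in table order)
region_cell_index <- function(regions, grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  if (regions$mode == "grid") {
    g <- regions$grid
    if (!identical(dim(g$values), c(nr, nc)))
      hs_stop("habsim_alignment_error", "region label grid is not congruent with the raster")
    return(matrix(as.integer(g$values), nr, nc))
  }
  cx <- grid_cell_x(grid); cy <- grid_cell_y(grid)
  px <- rep(cx, each = nr); py <- rep(cy, times = nc)  # column-major order
  idx <- rep(NA_integer_, nr * nc)
  for (k in seq_along(regions$geometry)) {
    rings <- regions$geometry[[k]]
    xs <- unlist(lapply(rings, function(r) r[, 1]))
    ys <- unlist(lapply(rings, function(r) r[, 2]))
    cand <- which(is.na(idx) & px >= min(xs) & px <= max(xs) &
                    py >= min(ys) & py <= max(ys))
    if (!length(cand)) next
    hit <- points_in_polygon(rings, px[cand], py[cand])
    idx[cand[hit]] <- k
  }
  matrix(idx, nr, nc)
}

#' Read regions from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon (or single-polygon MultiPolygon)
#' features whose properties include `region_id` and `province_id`
#' (`area_km2` optional; computed from the geometry otherwise). Coordinates
#' must be in the same ground units as the rasters.
#'
#' @param path GeoJSON file path.
#' @return An [eco_regions()] in polygon mode.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) hs_stop("habsim_io_error", "region file does not exist: %s", path)
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    hs_stop("habsim_parse_error", "%s: expected a GeoJSON FeatureCollection", path)
  feats <- gj$features
  parse_ring <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    if (!is.matrix(m) || ncol(m) != 2 || nrow(m) < 3)
      hs_stop("habsim_parse_error", "%s: malformed polygon ring", path)
    m
  }
  geometry <- vector("list", length(feats))
  tab <- data.frame(region_id = character(length(feats)),
                    province_id = character(length(feats)),
                    stringsAsFactors = FALSE)
  areas <- rep(NA_real_, length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    g <- f$geometry
    coords <- switch(g$type %||% "",
      Polygon = g$coordinates,
      MultiPolygon = {
        if (length(g$coordinates) != 1)
          hs_stop("habsim_parse_error", "%s: MultiPolygon with >1 part unsupported", path)
        g$coordinates[[1]]
      },
      hs_stop("habsim_parse_error", "%s: unsupported geometry type '%s'",
              path, g$type %||% "NULL"))
    geometry[[i]] <- lapply(coords, parse_ring)
    tab$region_id[i] <- as.character(f$properties$region_id %||%
      hs_stop("habsim_parse_error", "%s: feature %d lacks region_id", path, i))
    tab$province_id[i] <- as.character(f$properties$province_id %||% NA_character_)
    if (!is.null(f$properties$area_km2)) areas[i] <- as.numeric(f$properties$area_km2)
  }
  if (!all(is.na(areas))) tab$area_km2 <- areas
  eco_regions(tab, geometry = geometry)
}

#' Write regions to GeoJSON
#'
#' @param regions An [eco_regions()] in polygon mode.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_regions <- function(regions, path) {
  if (regions$mode != "polygon")
    hs_stop("habsim_validation_error", "only polygon-mode regions can be written to GeoJSON")
  feats <- lapply(seq_len(nrow(regions$table)), function(i) {
    rings <- lapply(regions$geometry[[i]], function(r) {
      # close the ring
      if (!(r[1, 1] == r[nrow(r), 1] && r[1, 2] == r[nrow(r), 2]))
        r <- rbind(r, r[1, ])
      lapply(seq_len(nrow(r)), function(j) c(r[j, 1], r[j, 2]))
    })
    list(type = "Feature",
         properties = list(region_id = regions$table$region_id[i],
                           province_id = regions$table$province_id[i],
                           area_km2 = regions$table$area_km2[i]),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Create a plot table
#'
#' Field plots: georeferenced sampling points in the species' native range,
#' each labelled with a habitat group (the county or town it belongs to) used
#' as the grouping factor of the across-habitat ANOVA.
#'
#' @param plot_id Character vector of unique plot identifiers.
#' @param x,y Coordinates in ground units.
#' @param habitat_group Character labels.
#' @return A data.frame of class `eco_plots`.
#' @export
plot_table <- function(plot_id, x, y, habitat_group) {
  if (anyDuplicated(plot_id))
    hs_stop("habsim_validation_error", "duplicate plot_id: %s",
            paste(unique(plot_id[duplicated(plot_id)]), collapse = ", "))
  out <- data.frame(plot_id = as.character(plot_id), x = as.numeric(x),
                    y = as.numeric(y), habitat_group = as.character(habitat_group),
                    stringsAsFactors = FALSE)
  class(out) <- c("eco_plots", "data.frame")
  out
}

#' Read / write a plot CSV
#'
#' CSV with header `plot_id,x,y,habitat_group` (UTF-8). Duplicate plot ids
#' are a validation error.
#'
#' @param path CSV path.
#' @return [read_plots()]: an `eco_plots` data.frame.
#' @export
read_plots <- function(path) {
  if (!file.exists(path)) hs_stop("habsim_io_error", "plot file does not exist: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "x", "y", "habitat_group")
  if (!all(need %in% names(df)))
    hs_stop("habsim_parse_error", "%s: plot CSV needs columns %s", path,
            paste(need, collapse = ", "))
  plot_table(df$plot_id, df$x, df$y, df$habitat_group)
}

#' @rdname read_plots
#' @param plots An `eco_plots` table.
#' @export
write_plots <- function(plots, path) {
  utils::write.csv(as.data.frame(plots)[, c("plot_id", "x", "y", "habitat_group")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Parse and compare hierarchical soil codes
#'
#' Soil types are identified by a taxonomic path
#' `order/suborder/group/subgroup/family`; any suffix may be absent but levels
#' must be filled from the top down. `soil_code()` validates and normalises a
#' path string; [soil_similarity()] scores two codes by grade division.
#'
#' @param path A string such as `"O2/S5/G12/U20/F31"`.
#' @return The validated path string (class `soil_code`).
#' @export
soil_code <- function(path) {
  parts <- strsplit(as.character(path), "/", fixed = TRUE)[[1]]
  if (length(parts) < 1L || length(parts) > 5L || any(!nzchar(trimws(parts))))
    hs_stop("habsim_validation_error",
            "soil code '%s' must have 1-5 non-empty levels filled top-down", path)
  structure(paste(trimws(parts), collapse = "/"), class = "soil_code")
}
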