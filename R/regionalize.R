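#' Assign suitability classes to administrative regions
#'
#' Aggregates the cell-level classification to regions by a coverage-fraction
#' rule: a region is *favorable* when at least a fraction `tau` of its
#' non-nodata cells are favorable, otherwise *suitable* when at least `tau`
#' are favorable or suitable, otherwise *slightly_appropriate*. Per-class
#' membership flags use the same rule class-wise (`member_favorable`:
#' fraction of favorable cells >= tau; `member_suitable`: fraction of
#' suitable cells >= tau), so a region can legitimately appear in both the
#' favorable and the suitable list — county lists of this kind overlap in
#' practice. Regions with zero covered cells are flagged unassigned.
#'
#' @param class_map An [classify()] result.
#' @param regions An [eco_regions()] sharing the ground coordinate frame.
#' @param tau Coverage fraction in (0, 1], default 0.05.
#' @return A data.frame (one row per region): `region_id`, `province_id`,
#'   `n_cells` (covered, non-nodata), `frac_favorable`, `frac_suitable`,
#'   `frac_slight`, `member_favorable`, `member_suitable`, `assigned_class`
#'   (`"favorable"`, `"suitable"`, `"slightly_appropriate"` or `NA` when
#'   uncovered).
#' @export
region_class <- function(class_map, regions, tau = 0.05) {
  if (!is.numeric(tau) || tau <= 0 || tau > 1)
    hs_stop("habsim_value_error", "tau must be in (0, 1]")
  idx <- region_cell_index(regions, class_map)
  cls <- class_map$values
  n_reg <- nrow(regions$table)
  covered <- !is.na(idx) & !is.na(cls)
  ri <- factor(idx[covered], levels = seq_len(n_reg))
  n_cells <- as.integer(table(ri))
  n_fav   <- as.integer(table(ri[cls[covered] == 1]))
  n_suit  <- as.integer(table(ri[cls[covered] == 2]))
  n_slight <- as.integer(table(ri[cls[covered] == 3]))
  frac <- function(num) ifelse(n_cells > 0, num / n_cells, NA_real_)
  f_fav <- frac(n_fav); f_suit <- frac(n_suit); f_slight <- frac(n_slight)
  member_fav <- !is.na(f_fav) & f_fav >= tau
  member_suit <- !is.na(f_suit) & f_suit >= tau
  assigned <- ifelse(n_cells == 0, NA_character_,
              ifelse(f_fav >= tau, "favorable",
              ifelse(f_fav + f_suit >= tau, "suitable", "slightly_appropriate")))
  if (any(n_cells == 0))
    hs_warn("%d region(s) with zero covered cells left unassigned", sum(n_cells == 0))
  data.frame(region_id = regions$table$region_id,
             province_id = regions$table$province_id,
             n_cells = n_cells,
             frac_favorable = f_fav, frac_suitable = f_suit,
             frac_slight = f_slight,
             member_favorable = member_fav, member_suitable = member_suit,
             assigned_class = assigned, stringsAsFactors = FALSE)
}

#' Tally the zoning by class, region and province
#'
#' Summarises a [region_class()] table (and optionally the underlying cell
#' classification for areas): per class the number of member regions, the
#' number of distinct provinces containing them, and the land area as cell
#' count times cell area. The combined "tested suitable" count — regions in
#' the favorable or the suitable list — is computed by inclusion–exclusion,
#' `n_union = n_favorable + n_suitable - n_overlap`.
#'
#' @param assignments Output of [region_class()].
#' @param class_map Optional [classify()] result for cell-based areas.
#' @return A list of class `eco_tally`: `classes` (data.frame `class,
#'   n_regions, n_provinces, area_km2`), `n_favorable`, `n_suitable`,
#'   `n_overlap`, `n_union`, `area_union_km2` (favorable + suitable cell
#'   area; cell classes are exclusive so no double counting) and
#'   `n_unassigned`.
#' @export
tally <- function(assignments, class_map = NULL) {
  a <- assignments
  n_fav <- sum(a$member_favorable, na.rm = TRUE)
  n_suit <- sum(a$member_suitable, na.rm = TRUE)
  n_both <- sum(a$member_favorable & a$member_suitable, na.rm = TRUE)
  prov <- function(flag) length(unique(a$province_id[flag & !is.na(flag)]))
  cell_area <- function(code) {
    if (is.null(class_map)) return(NA_real_)
    sum(class_map$values == code, na.rm = TRUE) * class_map$cell_size^2
  }
  classes <- data.frame(
    class = c("favorable", "suitable", "slightly_appropriate"),
    n_regions = c(n_fav, n_suit,
                  sum(a$assigned_class == "slightly_appropriate", na.rm = TRUE)),
    n_provinces = c(prov(a$member_favorable), prov(a$member_suitable),
                    prov(a$assigned_class == "slightly_appropriate")),
    area_km2 = c(cell_area(1), cell_area(2), cell_area(3)),
    stringsAsFactors = FALSE
  )
  structure(list(classes = classes,
                 n_favorable = n_fav, n_suitable = n_suit,
                 n_overlap = n_both,
                 n_union = n_fav + n_suit - n_both,
                 area_union_km2 = if (is.null(class_map)) NA_real_
                                  else cell_area(1) + cell_area(2),
                 n_unassigned = sum(is.na(a$assigned_class))),
            class = "eco_tally")
}

#' @export
print.eco_tally <- function(x, ...) {
  cat("<eco_tally>\n")
  print(x$classes, row.names = FALSE)
  cat(sprintf("favorable %d + suitable %d - overlap %d = %d regions tested suitable\n",
              x$n_favorable, x$n_suitable, x$n_overlap, x$n_union))
  if (!is.na(x$area_union_km2))
    cat(sprintf("combined favorable+suitable area: %g km^2\n", x$area_union_km2))
  invisible(x)
}

#' The set of predicted regions
#'
#' Convenience accessor: region ids in the favorable or suitable list of a
#' [region_class()] table — the prediction set handed to [overlap_report()].
#'
#' @param assignments Output of [region_class()].
#' @return Character vector of region ids.
#' @export
predicted_regions <- function(assignments) {
  keep <- (assignments$member_favorable | assignments$member_suitable)
  assignments$region_id[keep & !is.na(keep)]
}
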