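# Per-region immune-cell composition: counts, densities, proportions,
# Treg/CD8 ratio.

region_filter <- function(cells, region) {
  region <- toupper(region)
  if (region == "ALL") return(cells)
  if (region %in% c("TUMOUR", "STROMA")) {
    if (!"compartment" %in% names(cells)) {
      tme_error("cells carry no compartment labels; run annotate_regions() first",
                class = "tme_schema_error")
    }
    return(cells[cells$compartment == tolower(region), , drop = FALSE])
  }
  if (region %in% c("IM_T", "IM_S")) {
    if (!"im_label" %in% names(cells)) {
      tme_error("cells carry no invasive-margin labels; run annotate_regions() first",
                class = "tme_schema_error")
    }
    return(cells[cells$im_label == region, , drop = FALSE])
  }
  tme_config_error("region", "must be one of ALL, TUMOUR, STROMA, IM_T, IM_S")
}

#' Proportion of a population among all retained cells of a region
#'
#' The denominator is every retained (DAPI+) cell in the region, tumour
#' cells included; an immune-cells-only denominator is available via
#' `denominator = "immune"`.
#'
#' @param cells Phenotyped (and, for compartment/margin regions,
#'   region-annotated) cell table.
#' @param population Population name (see [tme_populations()]).
#' @param region One of `"ALL"`, `"TUMOUR"`, `"STROMA"`, `"IM_T"`, `"IM_S"`.
#' @param denominator `"all"` (default) or `"immune"` (non-tumour cells).
#' @return Fraction in \[0, 1\], or `NA` with a warning when the region is
#'   empty.
#' @export
population_proportion <- function(cells, population, region = "ALL",
                                  denominator = c("all", "immune")) {
  denominator <- match.arg(denominator)
  sub <- region_filter(cells, region)
  if (denominator == "immune") sub <- sub[!as.logical(sub$TUMOUR_CELL), , drop = FALSE]
  if (nrow(sub) == 0L) {
    warning(sprintf("region %s empty; proportion undefined", region))
    return(NA_real_)
  }
  sum(as.logical(sub[[population]])) / nrow(sub)
}

#' Density of a population in a region
#'
#' Cell count divided by the region's area (from geometry), in cells per
#' square millimetre. Areas are summed over the supplied geometries
#' (patient-level pooling of ROIs).
#'
#' @inheritParams population_proportion
#' @param geometries A single [region_geometry()] or a list of them
#'   covering the ROIs present in `cells`; `NULL` omits the density.
#' @param config A [region_config()] for invasive-margin areas.
#' @return Cells per mm^2, or `NA` with a warning when no geometry is
#'   available or the region area is zero.
#' @export
population_density <- function(cells, population, region = "ALL",
                               geometries = NULL, config = region_config()) {
  if (is.null(geometries)) {
    warning("no geometry; density omitted")
    return(NA_real_)
  }
  if (inherits(geometries, "region_geometry")) geometries <- list(geometries)
  area <- sum(vapply(geometries, region_area, numeric(1),
                     region = toupper(region), config = config))
  if (area <= 0) {
    warning(sprintf("region %s has zero area; density undefined", region))
    return(NA_real_)
  }
  sub <- region_filter(cells, region)
  sum(as.logical(sub[[population]])) / area
}

#' Treg/CD8 ratio in a region
#'
#' Number of regulatory T cells divided by the number of CD8 T cells.
#'
#' @inheritParams population_proportion
#' @return Ratio, or `NA` with a warning when the region has no CD8 T cell
#'   (the patient is excluded from that comparison).
#' @export
treg_cd8_ratio <- function(cells, region = "ALL") {
  sub <- region_filter(cells, region)
  n_cd8 <- sum(as.logical(sub$CD8_T))
  if (n_cd8 == 0L) {
    warning(sprintf("region %s has no CD8 T cells; Treg/CD8 ratio undefined", region))
    return(NA_real_)
  }
  sum(as.logical(sub$TREG)) / n_cd8
}

#' Cohort composition table
#'
#' Per patient, region and population: cell count, density (when geometry
#' is available) and proportion of all retained cells in the region. ROIs
#' are pooled per patient.
#'
#' @param cells Phenotyped, region-annotated cohort cell table.
#' @param geometries Named list of [region_geometry()] keyed by `roi_id`,
#'   or `NULL` to skip densities.
#' @param populations Population names to tabulate.
#' @param regions Regions to tabulate.
#' @param config A [region_config()].
#' @return Data frame with columns `patient_id`, `region`, `population`,
#'   `count`, `n_region_cells`, `density_mm2`, `proportion`.
#' @export
cohort_composition <- function(cells, geometries = NULL,
                               populations = setdiff(tme_populations(), "OTHER"),
                               regions = c("ALL", "TUMOUR", "STROMA", "IM_T", "IM_S"),
                               config = region_config()) {
  rows <- list()
  # cache per-ROI region areas, classifying each ROI's grid once
  area_cache <- NULL
  if (!is.null(geometries)) {
    area_cache <- t(vapply(geometries, function(g) {
      region_areas(g, config)
    }, numeric(5)))[, regions, drop = FALSE]
  }
  for (pid in unique(cells$patient_id)) {
    sub <- cells[cells$patient_id == pid, , drop = FALSE]
    rois <- unique(as.character(sub$roi_id))
    for (rg in regions) {
      reg_cells <- tryCatch(region_filter(sub, rg), tme_schema_error = function(e) NULL)
      if (is.null(reg_cells)) next
      n_reg <- nrow(reg_cells)
      area <- if (!is.null(area_cache)) {
        sum(area_cache[intersect(rois, rownames(area_cache)), rg])
      } else NA_real_
      for (pop in populations) {
        cnt <- sum(as.logical(reg_cells[[pop]]))
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, region = rg, population = pop,
          count = cnt, n_region_cells = n_reg,
          density_mm2 = if (!is.na(area) && area > 0) cnt / area else NA_real_,
          proportion = if (n_reg > 0) cnt / n_reg else NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
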