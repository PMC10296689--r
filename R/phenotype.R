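# Marker panels and phenotyping of segmented cells into major populations.

#' Marker panels
#'
#' The two six-marker staining panels used on sequential sections. Panel 1
#' resolves the T-cell compartment (CD4, CD8, FOXP3, PD-1), Panel 2 the
#' broader leukocyte lineages (CD3, CD20, CD56, CD68). Both carry
#' pancytokeratin (PANCK) to flag tumour cells and DAPI as the
#' nucleated-cell gate.
#'
#' @param name One of `"Panel1"`, `"Panel2"` or `"both"`. `"both"` is a
#'   convenience for synthetic tables that carry all markers in one export;
#'   real sequential-section data should be analysed per panel.
#' @return An object of class `marker_panel`: a list with `name` and the
#'   ordered `markers` character vector.
#' @examples
#' marker_panel("Panel1")$markers
#' @export
marker_panel <- function(name = c("both", "Panel1", "Panel2")) {
  name <- match.arg(name)
  markers <- switch(name,
    Panel1 = c("PANCK", "CD4", "CD8", "FOXP3", "PD1", "DAPI"),
    Panel2 = c("PANCK", "CD3", "CD20", "CD56", "CD68", "DAPI"),
    both   = c("PANCK", "CD4", "CD8", "FOXP3", "PD1",
               "CD3", "CD20", "CD56", "CD68", "DAPI")
  )
  structure(list(name = name, markers = markers), class = "marker_panel")
}

# population -> defining markers (all must be positive), per panel
population_definitions <- function(panel_name) {
  defs <- list(
    CD4_T         = "CD4",
    TREG          = c("CD4", "FOXP3"),
    CD8_T         = "CD8",
    EXHAUSTED_CD8 = c("CD8", "PD1"),
    CD3_T         = "CD3",
    B_CELL        = "CD20",
    NK_CELL       = "CD56",
    MACROPHAGE    = "CD68"
  )
  keep <- switch(panel_name,
    Panel1 = c("CD4_T", "TREG", "CD8_T", "EXHAUSTED_CD8"),
    Panel2 = c("CD3_T", "B_CELL", "NK_CELL", "MACROPHAGE"),
    both   = names(defs)
  )
  defs[keep]
}

#' All population labels known to the package
#' @return Character vector of population names.
#' @export
tme_populations <- function() {
  c("CD4_T", "CD8_T", "TREG", "EXHAUSTED_CD8",
    "CD3_T", "B_CELL", "NK_CELL", "MACROPHAGE", "TUMOUR_CELL", "OTHER")
}

#' Assign populations to a single cell from its marker calls
#'
#' Maps boolean marker positivity to the major populations. A cell can
#' belong to several populations (a Treg is also a CD4 T cell; an exhausted
#' CD8 T cell is also a CD8 T cell). PANCK takes precedence: a PANCK+ cell
#' is a tumour cell only, never an immune cell — double positives on the
#' epithelial marker are treated as segmentation artefacts. A cell matching
#' no definition is `OTHER`.
#'
#' @param marker_calls Named logical or 0/1 vector containing at least the
#'   panel's markers.
#' @param panel A [marker_panel()] or panel name.
#' @return Character vector of population labels.
#' @examples
#' assign_populations(c(PANCK = 0, CD4 = 1, CD8 = 0, FOXP3 = 1, PD1 = 0,
#'                      DAPI = 1), "Panel1")
#' @export
assign_populations <- function(marker_calls, panel = marker_panel("both")) {
  if (is.character(panel)) panel <- marker_panel(panel)
  missing <- setdiff(panel$markers, names(marker_calls))
  if (length(missing)) {
    tme_error(sprintf("marker call(s) missing from cell record: %s",
                      paste(missing, collapse = ", ")),
              class = "tme_schema_error")
  }
  calls <- as.logical(marker_calls[panel$markers])
  names(calls) <- panel$markers
  if (isTRUE(calls[["PANCK"]])) return("TUMOUR_CELL")
  defs <- population_definitions(panel$name)
  hit <- vapply(defs, function(m) all(calls[m]), logical(1))
  pops <- names(defs)[hit]
  if (!length(pops)) "OTHER" else pops
}

#' Phenotype a cell table
#'
#' Vectorised population assignment over a per-cell table. Adds one logical
#' column per population (named as in [tme_populations()]), applying the
#' same PANCK-precedence and subset-counting rules as
#' [assign_populations()].
#'
#' @param cells Data frame with one row per segmented cell and 0/1 marker
#'   columns for the panel's markers.
#' @param panel A [marker_panel()] or panel name.
#' @return `cells` with population indicator columns appended.
#' @export
phenotype_cells <- function(cells, panel = marker_panel("both")) {
  if (is.character(panel)) panel <- marker_panel(panel)
  missing <- setdiff(panel$markers, names(cells))
  if (length(missing)) {
    tme_error(sprintf("marker column(s) missing from cell table: %s",
                      paste(missing, collapse = ", ")),
              class = "tme_schema_error")
  }
  tumour <- as.logical(cells[["PANCK"]])
  defs <- population_definitions(panel$name)
  any_immune <- rep(FALSE, nrow(cells))
  for (pop in names(defs)) {
    pos <- !tumour
    for (m in defs[[pop]]) pos <- pos & as.logical(cells[[m]])
    cells[[pop]] <- pos
    any_immune <- any_immune | pos
  }
  other_pops <- setdiff(names(population_definitions("both")), names(defs))
  for (pop in other_pops) cells[[pop]] <- rep(FALSE, nrow(cells))
  cells[["TUMOUR_CELL"]] <- tumour
  cells[["OTHER"]] <- !tumour & !any_immune
  cells
}

#' Retain nucleated in-bounds cells
#'
#' Drops DAPI-negative rows (the nucleated-cell gate) and, when ROI bounds
#' are known, rows whose centroid falls outside its ROI. Counts dropped are
#' reported via `message()`.
#'
#' @param cells Per-cell table with a `DAPI` column and `x_um`/`y_um`
#'   coordinates.
#' @param geometries Optional named list of [region_geometry()] objects
#'   keyed by `roi_id`; when supplied, out-of-bounds cells are dropped.
#' @return Filtered cell table.
#' @export
filter_cells <- function(cells, geometries = NULL) {
  n0 <- nrow(cells)
  if (!"DAPI" %in% names(cells)) {
    tme_error("cell table lacks a DAPI column", class = "tme_schema_error")
  }
  cells <- cells[as.logical(cells$DAPI), , drop = FALSE]
  n_dapi <- n0 - nrow(cells)
  n_oob <- 0L
  if (!is.null(geometries) && nrow(cells)) {
    keep <- rep(TRUE, nrow(cells))
    for (rid in unique(cells$roi_id)) {
      geom <- geometries[[rid]]
      if (is.null(geom)) next
      idx <- which(cells$roi_id == rid)
      b <- geom$roi_bounds
      keep[idx] <- cells$x_um[idx] >= b[1] & cells$x_um[idx] <= b[3] &
        cells$y_um[idx] >= b[2] & cells$y_um[idx] <= b[4]
    }
    n_oob <- sum(!keep)
    cells <- cells[keep, , drop = FALSE]
  }
  if (n_dapi + n_oob > 0) {
    message(sprintf("filter_cells: dropped %d DAPI- and %d out-of-bounds of %d cells",
                    n_dapi, n_oob, n0))
  }
  rownames(cells) <- NULL
  cells
}
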