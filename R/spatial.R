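# Tumour-to-immune spatial metrics: nearest-neighbour distance and counts
# within a fixed physiologic radius.

#' Spatial-metric configuration
#'
#' @param radius Interaction radius in micrometres (default 30, a distance
#'   over which direct tumour-immune cell contact is plausible).
#' @param min_target_cells Minimum number of cells of the target population
#'   that must be present for the nearest-neighbour summary to count as
#'   computable (default 1).
#' @return An object of class `spatial_config`.
#' @export
spatial_config <- function(radius = 30, min_target_cells = 1L) {
  check_number(radius, "radius", lower = 0, strict_lower = TRUE)
  check_number(min_target_cells, "min_target_cells", lower = 1)
  structure(list(radius = radius, min_target_cells = as.integer(min_target_cells)),
            class = "spatial_config")
}

# --- exhaustive kernels (used for small inputs; the grid path must agree
# with these exactly) -----------------------------------------------------

nnd_exhaustive <- function(ref, tgt, chunk = 2048L) {
  out <- numeric(nrow(ref))
  for (s in seq(1L, nrow(ref), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(ref))
    d2 <- outer(ref[s:e, 1], tgt[, 1], "-")^2 + outer(ref[s:e, 2], tgt[, 2], "-")^2
    out[s:e] <- sqrt(.rowMins(d2))
  }
  out
}

.rowMins <- function(m) {
  if (ncol(m) == 1L) return(m[, 1])
  do.call(pmin, as.data.frame(m))
}

count_exhaustive <- function(ref, tgt, radius, chunk = 2048L) {
  out <- integer(nrow(ref))
  r2 <- radius^2
  for (s in seq(1L, nrow(ref), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(ref))
    d2 <- outer(ref[s:e, 1], tgt[, 1], "-")^2 + outer(ref[s:e, 2], tgt[, 2], "-")^2
    out[s:e] <- as.integer(rowSums(d2 <= r2))
  }
  out
}

# --- grid-accelerated kernels --------------------------------------------

# Bin points on a square grid of cell size h; returns a list of index
# vectors keyed by "ix,iy".
grid_bin <- function(xy, h, x0, y0) {
  ix <- floor((xy[, 1] - x0) / h)
  iy <- floor((xy[, 2] - y0) / h)
  split(seq_len(nrow(xy)), paste(ix, iy, sep = ","))
}

nnd_grid <- function(ref, tgt) {
  span <- max(diff(range(c(ref[, 1], tgt[, 1]))), diff(range(c(ref[, 2], tgt[, 2]))))
  h <- span / max(4, floor(sqrt(nrow(tgt))))
  if (!is.finite(h) || h <= 0) h <- 1
  x0 <- min(ref[, 1], tgt[, 1]); y0 <- min(ref[, 2], tgt[, 2])
  bins <- grid_bin(tgt, h, x0, y0)
  max_ring <- ceiling(span / h) + 1L
  out <- numeric(nrow(ref))
  for (i in seq_len(nrow(ref))) {
    cx <- floor((ref[i, 1] - x0) / h)
    cy <- floor((ref[i, 2] - y0) / h)
    best <- Inf
    for (k in 0:max_ring) {
      # cells on Chebyshev ring k around (cx, cy)
      if (k == 0L) {
        keys <- paste(cx, cy, sep = ",")
      } else {
        xs <- (cx - k):(cx + k)
        keys <- c(paste(xs, cy - k, sep = ","),
                  paste(xs, cy + k, sep = ","),
                  paste(cx - k, (cy - k + 1):(cy + k - 1), sep = ","),
                  paste(cx + k, (cy - k + 1):(cy + k - 1), sep = ","))
      }
      idx <- unlist(bins[keys], use.names = FALSE)
      if (length(idx)) {
        d <- euclid2(ref[i, 1], ref[i, 2], tgt[idx, 1], tgt[idx, 2])
        best <- min(best, d)
      }
      # any point in ring k+1 or beyond is at distance >= k*h
      if (best <= k * h) break
    }
    out[i] <- best
  }
  out
}

count_grid <- function(ref, tgt, radius) {
  h <- radius
  x0 <- min(ref[, 1], tgt[, 1]); y0 <- min(ref[, 2], tgt[, 2])
  bins <- grid_bin(tgt, h, x0, y0)
  r2 <- radius^2
  out <- integer(nrow(ref))
  for (i in seq_len(nrow(ref))) {
    cx <- floor((ref[i, 1] - x0) / h)
    cy <- floor((ref[i, 2] - y0) / h)
    keys <- paste(rep((cx - 1):(cx + 1), each = 3), (cy - 1):(cy + 1), sep = ",")
    idx <- unlist(bins[keys], use.names = FALSE)
    if (length(idx)) {
      d2 <- (ref[i, 1] - tgt[idx, 1])^2 + (ref[i, 2] - tgt[idx, 2])^2
      out[i] <- sum(d2 <= r2)
    }
  }
  out
}

as_xy <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2) tme_error("coordinates must have two columns (x, y)")
  storage.mode(p) <- "double"
  unname(p)
}

#' Nearest-neighbour distances from reference to target cells
#'
#' For each reference cell (typically a tumour cell), the minimal Euclidean
#' distance to any target cell (an immune population). Uses a grid-bucket
#' accelerated search for large inputs; results are identical to the
#' exhaustive pairwise scan.
#'
#' @param reference_xy,target_xy Two-column matrices (or data frames) of
#'   coordinates in micrometres.
#' @param method `"auto"` (default), `"grid"` or `"exhaustive"`.
#' @return Numeric vector of distances, one per reference cell; `NULL`
#'   (with a warning) when there is no target cell — the metric is not
#'   computable and no distance is fabricated. An empty reference set
#'   yields `numeric(0)` with a warning.
#' @examples
#' nearest_neighbour_distances(cbind(0, 0), cbind(3, 4))
#' @export
nearest_neighbour_distances <- function(reference_xy, target_xy,
                                        method = c("auto", "grid", "exhaustive")) {
  method <- match.arg(method)
  ref <- as_xy(reference_xy)
  if (nrow(ref) == 0L) {
    warning("empty reference set; no nearest-neighbour distances")
    return(numeric(0))
  }
  tgt <- as_xy(target_xy)
  if (nrow(tgt) == 0L) {
    warning("no target cells; nearest-neighbour distance not computable")
    return(NULL)
  }
  use_grid <- switch(method,
    grid = TRUE,
    exhaustive = FALSE,
    auto = nrow(tgt) > 128 && as.double(nrow(ref)) * nrow(tgt) > 5e5
  )
  if (use_grid) nnd_grid(ref, tgt) else nnd_exhaustive(ref, tgt)
}

#' Target-cell counts within a fixed radius of each reference cell
#'
#' Counts target cells at Euclidean distance less than or equal to the
#' configured radius (inclusive boundary) around each reference cell.
#'
#' @inheritParams nearest_neighbour_distances
#' @param config A [spatial_config()].
#' @return List with `counts` (integer per reference cell) and `mean`.
#'   An empty target set gives all-zero counts.
#' @examples
#' count_within_radius(cbind(0, 0), cbind(c(29.9, 30, 30.1), 0))
#' @export
count_within_radius <- function(reference_xy, target_xy,
                                config = spatial_config(),
                                method = c("auto", "grid", "exhaustive")) {
  method <- match.arg(method)
  ref <- as_xy(reference_xy)
  if (nrow(ref) == 0L) {
    warning("empty reference set; no counts")
    return(list(counts = integer(0), mean = NaN))
  }
  tgt <- as_xy(target_xy)
  if (nrow(tgt) == 0L) {
    return(list(counts = integer(nrow(ref)), mean = 0))
  }
  use_grid <- switch(method,
    grid = TRUE,
    exhaustive = FALSE,
    auto = nrow(tgt) > 128 && as.double(nrow(ref)) * nrow(tgt) > 5e5
  )
  counts <- if (use_grid) count_grid(ref, tgt, config$radius)
            else count_exhaustive(ref, tgt, config$radius)
  list(counts = counts, mean = mean(counts))
}

#' Per-patient spatial summary for one population
#'
#' Pools a patient's ROIs and summarises, over all tumour cells, the mean
#' nearest-neighbour distance to the population and the mean number of
#' population cells within the configured radius. Distances are computed
#' within an ROI only (different physical fields are never matched); the
#' pooled mean is taken over the per-tumour-cell values. Tumour cells in an
#' ROI with no cell of the population contribute zero counts but no
#' nearest-neighbour distance. The summary is flagged not computable when
#' the patient's ROIs contain fewer than `min_target_cells` cells of the
#' population.
#'
#' @param cells Phenotyped cell table for one patient (see
#'   [phenotype_cells()]), with `roi_id`, `x_um`, `y_um` and population
#'   indicator columns.
#' @param population Population name (see [tme_populations()]).
#' @param config A [spatial_config()].
#' @return A one-row data frame: `patient_id`, `population`, `mean_nnd_um`,
#'   `mean_count_within_radius`, `n_tumour_cells`, `n_target_cells`,
#'   `computable`.
#' @export
patient_spatial_summary <- function(cells, population, config = spatial_config()) {
  if (!population %in% names(cells)) {
    tme_error(sprintf("population column '%s' absent; phenotype the cells first",
                      population), class = "tme_schema_error")
  }
  pid <- if (nrow(cells)) as.character(cells$patient_id[1]) else NA_character_
  n_ref_total <- 0L
  n_tgt_total <- 0L
  all_nnd <- numeric(0)
  all_counts <- integer(0)
  for (rid in unique(cells$roi_id)) {
    roi <- cells[cells$roi_id == rid, , drop = FALSE]
    ref <- roi[as.logical(roi$TUMOUR_CELL), c("x_um", "y_um"), drop = FALSE]
    tgt <- roi[as.logical(roi[[population]]), c("x_um", "y_um"), drop = FALSE]
    n_ref_total <- n_ref_total + nrow(ref)
    n_tgt_total <- n_tgt_total + nrow(tgt)
    if (nrow(ref) == 0L) next
    cnt <- suppressWarnings(count_within_radius(ref, tgt, config))
    all_counts <- c(all_counts, cnt$counts)
    if (nrow(tgt) > 0L) {
      all_nnd <- c(all_nnd, nearest_neighbour_distances(ref, tgt))
    }
  }
  computable <- n_tgt_total >= config$min_target_cells && n_ref_total > 0L
  data.frame(
    patient_id = pid,
    population = population,
    mean_nnd_um = if (computable && length(all_nnd)) mean(all_nnd) else NA_real_,
    mean_count_within_radius = if (n_ref_total > 0L) mean(all_counts) else NA_real_,
    n_tumour_cells = n_ref_total,
    n_target_cells = n_tgt_total,
    computable = computable,
    stringsAsFactors = FALSE
  )
}

#' Cohort-level spatial summary table
#'
#' Applies [patient_spatial_summary()] per patient and population.
#'
#' @param cells Phenotyped cell table for the whole cohort.
#' @param populations Character vector of population names (default: Tregs
#'   and exhausted CD8 T cells, the populations of primary interest).
#' @param config A [spatial_config()].
#' @return Data frame, one row per patient and population.
#' @export
cohort_spatial_summary <- function(cells,
                                   populations = c("TREG", "EXHAUSTED_CD8"),
                                   config = spatial_config()) {
  out <- list()
  for (pid in unique(cells$patient_id)) {
    sub <- cells[cells$patient_id == pid, , drop = FALSE]
    for (pop in populations) {
      out[[length(out) + 1L]] <- patient_spatial_summary(sub, pop, config)
    }
  }
  do.call(rbind, out)
}
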