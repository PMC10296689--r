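# I/O and pipeline orchestration: column-registry CSV readers/writers,
# geometry JSON, the end-to-end analysis run and its manifest.

cells_mandatory_cols <- c("patient_id", "roi_id", "cell_id", "x_um", "y_um",
                          "PANCK", "CD4", "CD8", "FOXP3", "PD1",
                          "CD3", "CD20", "CD56", "CD68", "DAPI")
patients_mandatory_cols <- c("patient_id", "age", "sex", "smoking", "stage",
                             "ecog", "met_brain", "met_bone", "met_liver",
                             "met_adrenal", "met_pleura", "met_contralateral_lung",
                             "tki", "pdl1_tps", "pdl1_group", "best_response",
                             "pfs_months", "pfs_event", "os_months", "os_event")

validate_columns <- function(df, mandatory, optional, file) {
  missing <- setdiff(mandatory, names(df))
  if (length(missing)) {
    tme_error(sprintf("%s: missing mandatory column(s): %s", file,
                      paste(missing, collapse = ", ")),
              class = "tme_schema_error")
  }
  unknown <- setdiff(names(df), c(mandatory, optional))
  if (length(unknown)) {
    warning(sprintf("%s: unknown column(s) tolerated: %s", file,
                    paste(unknown, collapse = ", ")))
  }
  invisible(df)
}

check_event_flags <- function(df, cols, file) {
  for (col in cols) {
    bad <- which(!df[[col]] %in% c(0, 1))
    if (length(bad)) {
      tme_error(sprintf("%s: column %s must be 0/1; offending row %d (value '%s')",
                        file, col, bad[1], df[[col]][bad[1]]),
                class = "tme_schema_error")
    }
  }
  invisible(df)
}

#' Read a per-cell table
#'
#' Strict column validation: mandatory columns (identifiers, micrometre
#' coordinates, one 0/1 column per marker) are fatal when absent; unknown
#' columns are tolerated with a warning; marker flags must be 0/1.
#'
#' @param path CSV file path.
#' @return Cell data frame.
#' @export
read_cells <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_columns(df, cells_mandatory_cols,
                   optional = c("compartment", "im_label", "true_profile"),
                   file = path)
  check_event_flags(df, c("PANCK", "CD4", "CD8", "FOXP3", "PD1",
                          "CD3", "CD20", "CD56", "CD68", "DAPI"), path)
  df
}

#' Read a patient-level clinical table
#'
#' @param path CSV file path.
#' @return Patient data frame; survival event flags must be 0/1, best
#'   response in CR/PR/SD/PD.
#' @export
read_patients <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_columns(df, patients_mandatory_cols,
                   optional = c("lp_pfs", "lp_os"), file = path)
  check_event_flags(df, c("pfs_event", "os_event"), path)
  bad <- which(!df$best_response %in% c("CR", "PR", "SD", "PD"))
  if (length(bad)) {
    tme_error(sprintf("%s: best_response must be CR/PR/SD/PD; offending row %d",
                      path, bad[1]), class = "tme_schema_error")
  }
  df
}

#' Read ROI geometries from JSON
#'
#' The format is a JSON array of objects `{roi_id, roi_bounds,
#' tumour_polygons}` where each polygon is an array of `[x, y]` vertices
#' in micrometres.
#'
#' @param path JSON file path.
#' @return Named list of [region_geometry()] keyed by ROI id.
#' @export
read_geometry <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  for (item in raw) {
    polys <- lapply(item$tumour_polygons, function(p) {
      m <- do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))
      storage.mode(m) <- "double"
      m
    })
    out[[item$roi_id]] <- region_geometry(item$roi_id, polys,
                                          as.numeric(unlist(item$roi_bounds)))
  }
  out
}

#' Write geometries to JSON
#'
#' @param geometries Named list of [region_geometry()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geometries, path) {
  payload <- lapply(unname(geometries), function(g) {
    list(roi_id = g$roi_id, roi_bounds = g$roi_bounds,
         tumour_polygons = lapply(g$tumour_polygons, function(p) unname(p)))
  })
  # digits = I(17): significant digits, enough to round-trip doubles exactly
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

# write.csv with double columns rendered at 17 significant digits, so
# numeric fields survive a write/read cycle bit-for-bit
write_csv_full <- function(df, path) {
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      df[[col]] <- ifelse(is.na(df[[col]]), NA,
                          formatC(df[[col]], digits = 17, format = "g"))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
}

#' Write a synthetic cohort to disk
#'
#' Emits `cells.csv`, `geometry.json` and `patients.csv` in the package's
#' column registry; all numeric fields round-trip at full precision
#' through [read_cells()] / [read_patients()] / [read_geometry()].
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_full(cohort$cells, file.path(dir, "cells.csv"))
  write_csv_full(cohort$patients, file.path(dir, "patients.csv"))
  write_geometry(cohort$geometries, file.path(dir, "geometry.json"))
  invisible(dir)
}

#' Pipeline configuration
#'
#' @param cells_path,geometry_path,patients_path Input files (any may be
#'   `NULL`; stages without inputs are skipped with a log line).
#' @param out_dir Output directory.
#' @param spatial,region,stats Sub-configurations.
#' @param spatial_populations Populations to summarise spatially.
#' @param cutpoint_populations Populations whose all-region proportion is
#'   dichotomised by [optimal_cutpoint()] for the stratified survival
#'   report.
#' @param minprop Minimum group fraction for the cutpoint search.
#' @param ties Cox tie handling.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cells_path = NULL, geometry_path = NULL,
                            patients_path = NULL, out_dir = "tme_out",
                            spatial = spatial_config(),
                            region = region_config(),
                            stats = stats_config(),
                            spatial_populations = c("TREG", "EXHAUSTED_CD8"),
                            cutpoint_populations = c("TREG", "EXHAUSTED_CD8"),
                            minprop = 0.1, ties = "breslow", seed = 1L) {
  for (p in c(cells_path, geometry_path, patients_path)) {
    if (!is.null(p) && !file.exists(p)) {
      tme_config_error("paths", sprintf("input file does not exist: %s", p))
    }
  }
  structure(list(cells_path = cells_path, geometry_path = geometry_path,
                 patients_path = patients_path, out_dir = out_dir,
                 spatial = spatial, region = region, stats = stats,
                 spatial_populations = spatial_populations,
                 cutpoint_populations = cutpoint_populations,
                 minprop = minprop, ties = ties, seed = as.integer(seed)),
            class = "pipeline_config")
}

mw_row <- function(id, a, b, cfg) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) return(NULL)
  t <- mann_whitney_u(a, b, cfg)
  data.frame(comparison = id, method = t$method, statistic = t$statistic,
             p_value = t$p_value, n_high = length(a), n_low = length(b),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates phenotyping, region annotation, composition, spatial
#' metrics, group statistics and survival modelling over the supplied
#' inputs, writing `composition.csv`, `spatial_summary.csv`,
#' `stats_report.csv`, `survival_report.csv`, `cox_report.csv` and
#' `manifest.json` to the output directory. Stages whose inputs are
#' absent are skipped with an explicit log line in the manifest.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  warns <- character(0)
  note <- function(msg) log_lines <<- c(log_lines, msg)
  counts <- list()

  cells <- NULL; geoms <- NULL; patients <- NULL
  withCallingHandlers({
    if (!is.null(config$cells_path)) {
      cells <- read_cells(config$cells_path)
      counts$cells_in <- nrow(cells)
    } else note("no cells input: phenotyping/composition/spatial stages skipped")
    if (!is.null(config$geometry_path)) {
      geoms <- read_geometry(config$geometry_path)
      counts$rois <- length(geoms)
    }
    if (!is.null(config$patients_path)) {
      patients <- read_patients(config$patients_path)
      counts$patients <- nrow(patients)
    } else note("no patients input: cohort statistics and survival stages skipped")

    comp_df <- NULL; spat_df <- NULL
    if (!is.null(cells)) {
      cells <- filter_cells(cells, geoms)
      counts$cells_retained <- nrow(cells)
      cells <- phenotype_cells(cells, marker_panel("both"))
      if (!is.null(geoms)) {
        cells <- annotate_regions(cells, geoms, config$region)
      } else if ("compartment" %in% names(cells)) {
        cells$im_label <- "NONE"
        note("no geometry: using supplied compartment labels; invasive-margin metrics skipped")
      } else {
        note("no geometry and no compartment column: compartment-level stages skipped")
      }
      regions <- if ("compartment" %in% names(cells)) {
        if (!is.null(geoms)) c("ALL", "TUMOUR", "STROMA", "IM_T", "IM_S")
        else c("ALL", "TUMOUR", "STROMA")
      } else "ALL"
      comp_df <- cohort_composition(cells, geoms, regions = regions,
                                    config = config$region)
      utils::write.csv(comp_df, file.path(config$out_dir, "composition.csv"),
                       row.names = FALSE)
      counts$composition_rows <- nrow(comp_df)
      spat_df <- cohort_spatial_summary(cells, config$spatial_populations,
                                        config$spatial)
      utils::write.csv(spat_df, file.path(config$out_dir, "spatial_summary.csv"),
                       row.names = FALSE)
      counts$spatial_rows <- nrow(spat_df)
    }

    if (!is.null(patients)) {
      stats_rows <- list()
      hi_ids <- patients$patient_id[patients$pdl1_group == "high"]
      lo_ids <- patients$patient_id[patients$pdl1_group == "low"]
      rr_hi <- response_rates(patients$best_response[patients$pdl1_group == "high"])
      rr_lo <- response_rates(patients$best_response[patients$pdl1_group == "low"])
      resp <- patients$best_response %in% c("CR", "PR")
      ctrl <- patients$best_response %in% c("CR", "PR", "SD")
      hi <- patients$pdl1_group == "high"
      orr_tab <- rbind(c(sum(resp & !hi), sum(!resp & !hi)),
                       c(sum(resp & hi), sum(!resp & hi)))
      dcr_tab <- rbind(c(sum(ctrl & !hi), sum(!ctrl & !hi)),
                       c(sum(ctrl & hi), sum(!ctrl & hi)))
      for (nm in list(list("ORR", orr_tab, rr_lo[["orr"]], rr_hi[["orr"]]),
                      list("DCR", dcr_tab, rr_lo[["dcr"]], rr_hi[["dcr"]]))) {
        t <- tryCatch(pearson_chi2_2x2(nm[[2]]),
                      tme_degenerate_table_error = function(e) fisher_exact_2x2(nm[[2]]))
        stats_rows[[length(stats_rows) + 1L]] <- data.frame(
          comparison = sprintf("%s (low %.3f vs high %.3f)", nm[[1]], nm[[3]], nm[[4]]),
          method = t$method, statistic = t$statistic, p_value = t$p_value,
          n_high = sum(hi), n_low = sum(!hi), stringsAsFactors = FALSE)
      }
      if (!is.null(comp_df)) {
        for (rg in unique(comp_df$region)) {
          for (pop in unique(comp_df$population)) {
            sub <- comp_df[comp_df$region == rg & comp_df$population == pop, ]
            row <- mw_row(sprintf("proportion %s in %s by PD-L1 group", pop, rg),
                          sub$proportion[sub$patient_id %in% hi_ids],
                          sub$proportion[sub$patient_id %in% lo_ids],
                          config$stats)
            if (!is.null(row)) stats_rows[[length(stats_rows) + 1L]] <- row
          }
        }
      }
      if (!is.null(spat_df)) {
        for (pop in unique(spat_df$population)) {
          sub <- spat_df[spat_df$population == pop & spat_df$computable, ]
          row <- mw_row(sprintf("mean NND to %s by PD-L1 group", pop),
                        sub$mean_nnd_um[sub$patient_id %in% hi_ids],
                        sub$mean_nnd_um[sub$patient_id %in% lo_ids],
                        config$stats)
          if (!is.null(row)) stats_rows[[length(stats_rows) + 1L]] <- row
          sub2 <- spat_df[spat_df$population == pop, ]
          row2 <- mw_row(sprintf("mean count of %s within radius by PD-L1 group", pop),
                         sub2$mean_count_within_radius[sub2$patient_id %in% hi_ids],
                         sub2$mean_count_within_radius[sub2$patient_id %in% lo_ids],
                         config$stats)
          if (!is.null(row2)) stats_rows[[length(stats_rows) + 1L]] <- row2
        }
      }
      stats_df <- do.call(rbind, stats_rows)
      utils::write.csv(stats_df, file.path(config$out_dir, "stats_report.csv"),
                       row.names = FALSE)
      counts$stats_rows <- nrow(stats_df)

      surv_rows <- list()
      add_km <- function(rep, stratifier_label) {
        for (i in seq_len(nrow(rep$summary))) {
          p <- if (!is.null(rep$pairwise) && nrow(rep$pairwise) == 1L && i == 1L) {
            rep$pairwise$p_value[1]
          } else NA_real_
          surv_rows[[length(surv_rows) + 1L]] <<- cbind(
            data.frame(endpoint = rep$endpoint, stratifier = stratifier_label),
            rep$summary[i, ], data.frame(logrank_p = p))
        }
      }
      for (ep in c("pfs", "os")) {
        add_km(stratified_km_report(patients, "pdl1_group", ep), "pdl1_group")
      }
      if (!is.null(comp_df)) {
        for (pop in config$cutpoint_populations) {
          sub <- comp_df[comp_df$region == "ALL" & comp_df$population == pop, ]
          m <- match(patients$patient_id, sub$patient_id)
          vals <- sub$proportion[m]
          ok <- is.finite(vals)
          if (sum(ok) >= 4 && length(unique(vals[ok])) >= 2) {
            for (ep in c("pfs", "os")) {
              cp <- tryCatch(optimal_cutpoint(vals[ok],
                                              patients[[paste0(ep, "_months")]][ok],
                                              patients[[paste0(ep, "_event")]][ok],
                                              minprop = config$minprop),
                             tme_error = function(e) NULL)
              if (is.null(cp)) next
              note(sprintf("cutpoint for %s (%s): %.6g; post-selection log-rank p is optimistic",
                           pop, ep, cp$cutpoint))
              lab <- rep(NA_character_, nrow(patients))
              lab[ok] <- as.character(cp$groups)
              rep_ <- stratified_km_report(patients[ok, ],
                                           lab[ok], ep)
              add_km(rep_, sprintf("%s_level(cut=%.4g)", pop, cp$cutpoint))
            }
          }
        }
      }
      surv_df <- do.call(rbind, surv_rows)
      utils::write.csv(surv_df, file.path(config$out_dir, "survival_report.csv"),
                       row.names = FALSE)
      counts$survival_rows <- nrow(surv_df)

      cox_rows <- list()
      for (ep in c("pfs", "os")) {
        res <- univariate_screen_then_multivariate(patients, ep, ties = config$ties)
        cox_rows[[length(cox_rows) + 1L]] <- res$univariate
        if (!is.null(res$multivariate)) {
          cox_rows[[length(cox_rows) + 1L]] <-
            cbind(res$multivariate$table, endpoint = ep, analysis = "multivariate")
        }
        if (!is.null(res$note)) note(sprintf("%s: %s", ep, res$note))
      }
      cox_df <- do.call(rbind, cox_rows)
      utils::write.csv(cox_df, file.path(config$out_dir, "cox_report.csv"),
                       row.names = FALSE)
      counts$cox_rows <- nrow(cox_df)
    }
  }, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  }, message = function(m) {
    note(sub("\n$", "", conditionMessage(m)))
    invokeRestart("muffleMessage")
  })

  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg_for_hash, cfg_file, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mifTME")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    row_counts = counts,
    log = log_lines,
    warnings = warns
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(manifest)
}
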