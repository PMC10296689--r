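# Synthetic cohort generator: patients, ROI geometry and cells with the
# statistical structure the downstream analysis assumes.

#' Default planted population rates
#'
#' Fractions of cells per PD-L1 group and compartment drawn into each
#' population (remainder are unlabelled "other" nucleated cells). Treg and
#' exhausted-CD8 rates differ by PD-L1 group (the enrichment the cohort is
#' designed to carry: Tregs 2.55e-3 vs 6.6e-5, exhausted CD8 1.31e-3 vs
#' 1.65e-4); lineage populations are group-independent.
#'
#' @return Nested list `rates[[group]][[compartment]]` of named rate
#'   vectors.
#' @export
default_population_rates <- function() {
  base_tumour <- c(TUMOUR_CELL = 0.70, CD4_T = 0.03, CD8_T = 0.05,
                   TREG = NA, EXHAUSTED_CD8 = NA,
                   CD3_T = 0.04, B_CELL = 0.010, NK_CELL = 0.005, MACROPHAGE = 0.03)
  base_stroma <- c(TUMOUR_CELL = 0.05, CD4_T = 0.06, CD8_T = 0.08,
                   TREG = NA, EXHAUSTED_CD8 = NA,
                   CD3_T = 0.07, B_CELL = 0.030, NK_CELL = 0.010, MACROPHAGE = 0.06)
  fill <- function(v, treg, exh) {
    v["TREG"] <- treg; v["EXHAUSTED_CD8"] <- exh; v
  }
  list(
    low = list(tumour = fill(base_tumour, 6.6e-5, 1.65e-4),
               stroma = fill(base_stroma, 6.6e-5, 1.65e-4)),
    high = list(tumour = fill(base_tumour, 2.55e-3, 1.31e-3),
                stroma = fill(base_stroma, 2.55e-3, 1.31e-3))
  )
}

#' Default survival model
#'
#' Exponential proportional-hazards models for PFS (clock starts at TKI
#' initiation; baseline median 16.4 months) and OS (clock starts at
#' diagnosis; long baseline median so that the low-risk group's median is
#' typically not reached within follow-up), with planted log hazard ratios
#' for PD-L1-high (PFS HR 2.792, OS HR 3.348), bone metastasis (PFS HR
#' 2.123) and ECOG 1-2 (OS HR 6.420). Censoring is independent exponential
#' at a rate matching a median follow-up of about 37 months.
#'
#' @return List with elements `pfs`, `os` (each `baseline_rate` and named
#'   `log_hr`) and `censoring_rate`.
#' @export
default_survival_model <- function() {
  list(
    pfs = list(baseline_rate = log(2) / 16.4,
               log_hr = c(pdl1_high = log(2.792), met_bone = log(2.123),
                          ecog_1_2 = 0)),
    os = list(baseline_rate = log(2) / 70,
              log_hr = c(pdl1_high = log(3.348), met_bone = 0,
                         ecog_1_2 = log(6.420))),
    censoring_rate = log(2) / 37
  )
}

#' Default response model
#'
#' Best-response probabilities per PD-L1 group: objective response 70% vs
#' 50% and disease control 97.5% vs 83.3% for the low and high groups.
#' A tenth of responders are complete responses.
#'
#' @return List with per-group `orr`/`dcr` and `cr_fraction`.
#' @export
default_response_model <- function() {
  list(low = c(orr = 0.70, dcr = 0.975),
       high = c(orr = 0.50, dcr = 0.833),
       cr_fraction = 0.10)
}

#' Simulation configuration
#'
#' Study conditions for the synthetic cohort. Defaults mirror the
#' motivating cohort: 52 patients, 12 of them PD-L1 high (tumour
#' proportion score >= 50%), 2-3 regions of interest per patient, tumour
#' nests as disjoint discs, homogeneous Poisson cell placement per
#' compartment, group-dependent Treg/exhausted-CD8 enrichment, exponential
#' proportional-hazards survival and group-dependent response rates.
#'
#' @param n_patients Number of patients (non-negative integer).
#' @param prop_pdl1_high Probability a patient is PD-L1 high.
#' @param rois_per_patient Integer range `c(min, max)` of ROIs per patient
#'   (sampled uniformly).
#' @param roi_width,roi_height ROI extent in micrometres.
#' @param n_nests Tumour nests per ROI (discs; 0 gives an all-stroma ROI).
#' @param nest_radius_range Nest radius range in micrometres; the maximum
#'   must be below half the smaller ROI extent.
#' @param cell_density Named vector `c(tumour = , stroma = )` in cells per
#'   square millimetre.
#' @param population_rates See [default_population_rates()]; per-stratum
#'   rates must lie in \[0, 1\] and sum to at most 1.
#' @param survival_model See [default_survival_model()].
#' @param response_model See [default_response_model()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 52L,
                              prop_pdl1_high = 12 / 52,
                              rois_per_patient = c(2L, 3L),
                              roi_width = 1000, roi_height = 1000,
                              n_nests = 3L,
                              nest_radius_range = c(100, 220),
                              cell_density = c(tumour = 2000, stroma = 1500),
                              population_rates = default_population_rates(),
                              survival_model = default_survival_model(),
                              response_model = default_response_model()) {
  check_number(n_patients, "n_patients", lower = 0)
  check_fraction(prop_pdl1_high, "prop_pdl1_high")
  if (length(rois_per_patient) != 2L || any(rois_per_patient < 1) ||
      rois_per_patient[1] > rois_per_patient[2]) {
    tme_config_error("rois_per_patient", "must be an increasing integer range c(min, max), min >= 1")
  }
  check_number(roi_width, "roi_width", lower = 0, strict_lower = TRUE)
  check_number(roi_height, "roi_height", lower = 0, strict_lower = TRUE)
  check_number(n_nests, "n_nests", lower = 0)
  if (length(nest_radius_range) != 2L || any(nest_radius_range <= 0) ||
      nest_radius_range[1] > nest_radius_range[2]) {
    tme_config_error("nest_radius_range", "must be a positive increasing range")
  }
  if (n_nests > 0 && nest_radius_range[2] >= min(roi_width, roi_height) / 2) {
    tme_config_error("nest_radius_range", "maximum radius must be below half the ROI extent")
  }
  if (!all(c("tumour", "stroma") %in% names(cell_density)) ||
      any(cell_density <= 0)) {
    tme_config_error("cell_density", "must be strictly positive with names 'tumour' and 'stroma'")
  }
  for (grp in c("low", "high")) {
    for (comp in c("tumour", "stroma")) {
      r <- population_rates[[grp]][[comp]]
      if (is.null(r) || any(r < 0) || any(r > 1) || sum(r) > 1 + 1e-12) {
        tme_config_error("population_rates",
                         sprintf("stratum %s/%s must have rates in [0,1] summing to <= 1", grp, comp))
      }
    }
  }
  for (ep in c("pfs", "os")) {
    if (!is.numeric(survival_model[[ep]]$baseline_rate) ||
        survival_model[[ep]]$baseline_rate <= 0) {
      tme_config_error("survival_model", sprintf("%s baseline_rate must be > 0", ep))
    }
  }
  if (!is.numeric(survival_model$censoring_rate) || survival_model$censoring_rate < 0) {
    tme_config_error("survival_model", "censoring_rate must be >= 0 (Inf allowed)")
  }
  for (grp in c("low", "high")) {
    rm_ <- response_model[[grp]]
    if (is.null(rm_) || rm_["orr"] < 0 || rm_["orr"] > rm_["dcr"] || rm_["dcr"] > 1) {
      tme_config_error("response_model",
                       sprintf("group %s must satisfy 0 <= orr <= dcr <= 1", grp))
    }
  }
  structure(list(
    n_patients = as.integer(n_patients), prop_pdl1_high = prop_pdl1_high,
    rois_per_patient = as.integer(rois_per_patient),
    roi_width = roi_width, roi_height = roi_height,
    n_nests = as.integer(n_nests), nest_radius_range = nest_radius_range,
    cell_density = cell_density, population_rates = population_rates,
    survival_model = survival_model, response_model = response_model
  ), class = "simulation_config")
}

# profile -> positive markers (all cells additionally get DAPI = 1)
profile_markers <- list(
  TUMOUR_CELL = "PANCK", CD4_T = "CD4", CD8_T = "CD8",
  TREG = c("CD4", "FOXP3"), EXHAUSTED_CD8 = c("CD8", "PD1"),
  CD3_T = "CD3", B_CELL = "CD20", NK_CELL = "CD56", MACROPHAGE = "CD68",
  OTHER = character(0)
)

# Draw n population profiles from a stratum's rate vector.
draw_profiles <- function(n, rates) {
  probs <- c(rates, OTHER = 1 - sum(rates))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

profiles_to_marker_table <- function(profiles) {
  markers <- c("PANCK", "CD4", "CD8", "FOXP3", "PD1",
               "CD3", "CD20", "CD56", "CD68")
  out <- matrix(0L, nrow = length(profiles), ncol = length(markers),
                dimnames = list(NULL, markers))
  for (prof in unique(profiles)) {
    pos <- profile_markers[[prof]]
    if (length(pos)) out[profiles == prof, pos] <- 1L
  }
  cbind(as.data.frame(out), DAPI = rep(1L, length(profiles)))
}

sample_in_polygon <- function(poly, n) {
  if (n == 0L) return(cbind(numeric(0), numeric(0)))
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  got <- matrix(numeric(0), ncol = 2)
  while (nrow(got) < n) {
    m <- max(32L, 2L * (n - nrow(got)))
    x <- stats::runif(m, xr[1], xr[2]); y <- stats::runif(m, yr[1], yr[2])
    ok <- points_in_ring(x, y, poly)
    got <- rbind(got, cbind(x[ok], y[ok]))
  }
  got[seq_len(n), , drop = FALSE]
}

place_nests <- function(config) {
  polys <- list()
  centres <- matrix(numeric(0), ncol = 2)
  radii <- numeric(0)
  gap <- 25  # um clearance so rings never touch and the border stays simple
  for (j in seq_len(config$n_nests)) {
    placed <- FALSE
    for (attempt in 1:300) {
      r <- stats::runif(1, config$nest_radius_range[1], config$nest_radius_range[2])
      cx <- stats::runif(1, r + 1, config$roi_width - r - 1)
      cy <- stats::runif(1, r + 1, config$roi_height - r - 1)
      if (nrow(centres)) {
        d <- euclid2(cx, cy, centres[, 1], centres[, 2])
        if (any(d <= r + radii + gap)) next
      }
      centres <- rbind(centres, c(cx, cy))
      radii <- c(radii, r)
      polys[[length(polys) + 1L]] <- make_disc_polygon(cx, cy, r)
      placed <- TRUE
      break
    }
    if (!placed) break  # ROI too crowded; accept fewer nests
  }
  polys
}

#' Simulate one ROI: geometry and cells
#'
#' Places disjoint disc-shaped tumour nests inside the ROI, then scatters
#' cells by homogeneous Poisson sampling: the tumour compartment (union of
#' nests) and the stroma (the remainder) each at their configured density.
#' Each cell is assigned a population profile by a categorical draw from
#' the stratum's planted rates and receives the corresponding marker
#' calls.
#'
#' @param roi_id ROI identifier.
#' @param pdl1_group `"low"` or `"high"` (selects the rate stratum).
#' @param config A [simulation_config()].
#' @param seed Integer seed for this ROI's substream.
#' @return List with `geometry` (a [region_geometry()]) and `cells`
#'   (data frame with coordinates, marker calls and the generator's
#'   `compartment` label).
#' @export
simulate_roi <- function(roi_id, pdl1_group, config, seed) {
  stopifnot(pdl1_group %in% c("low", "high"))
  with_seed(seed, {
    polys <- place_nests(config)
    geom <- region_geometry(roi_id, polys,
                            c(0, 0, config$roi_width, config$roi_height))
    um2_to_mm2 <- 1e-6
    nest_areas <- vapply(polys, shoelace_area, numeric(1))
    tumour_area <- sum(nest_areas) * um2_to_mm2
    total_area <- config$roi_width * config$roi_height * um2_to_mm2
    stroma_area <- total_area - tumour_area

    # tumour-compartment cells
    n_t <- stats::rpois(1, config$cell_density[["tumour"]] * tumour_area)
    xy_t <- matrix(numeric(0), ncol = 2)
    if (n_t > 0) {
      nest_of <- sample.int(length(polys), n_t, replace = TRUE,
                            prob = nest_areas)
      xy_t <- do.call(rbind, lapply(seq_along(polys), function(j) {
        sample_in_polygon(polys[[j]], sum(nest_of == j))
      }))
    }
    # stroma cells: uniform in the ROI, rejected out of nests
    n_s <- stats::rpois(1, config$cell_density[["stroma"]] * stroma_area)
    xy_s <- matrix(numeric(0), ncol = 2)
    while (nrow(xy_s) < n_s) {
      m <- max(64L, 2L * (n_s - nrow(xy_s)))
      x <- stats::runif(m, 0, config$roi_width)
      y <- stats::runif(m, 0, config$roi_height)
      inside <- rep(FALSE, m)
      for (poly in polys) inside <- inside | points_in_ring(x, y, poly)
      xy_s <- rbind(xy_s, cbind(x[!inside], y[!inside]))
    }
    xy_s <- xy_s[seq_len(n_s), , drop = FALSE]

    comp <- c(rep("tumour", nrow(xy_t)), rep("stroma", nrow(xy_s)))
    xy <- rbind(xy_t, xy_s)
    rates <- config$population_rates[[pdl1_group]]
    profiles <- c(
      if (nrow(xy_t)) draw_profiles(nrow(xy_t), rates$tumour) else character(0),
      if (nrow(xy_s)) draw_profiles(nrow(xy_s), rates$stroma) else character(0)
    )
    cells <- data.frame(
      roi_id = rep(roi_id, nrow(xy)),
      cell_id = if (nrow(xy)) paste0(roi_id, "_c", seq_len(nrow(xy))) else character(0),
      x_um = xy[, 1], y_um = xy[, 2],
      stringsAsFactors = FALSE
    )
    cells <- cbind(cells, profiles_to_marker_table(profiles))
    cells$compartment <- comp
    cells$true_profile <- profiles
    list(geometry = geom, cells = cells)
  })
}

#' Simulate survival endpoints under the exponential hazards model
#'
#' Event times are exponential with rate `baseline_rate * exp(x' beta)`;
#' censoring is independent exponential at `censoring_rate` (use `Inf` to
#' censor everything at time zero, `0` for no censoring). The observed
#' time is the minimum, with the event flag set accordingly. PFS and OS
#' are drawn independently (their clocks start at treatment and diagnosis
#' respectively and the generator does not model the joint process).
#'
#' @param covariates Data frame containing the columns named by the
#'   models' `log_hr` vectors (0/1 or numeric).
#' @param survival_model See [default_survival_model()].
#' @param seed Integer seed.
#' @return Data frame with `pfs_months`, `pfs_event`, `os_months`,
#'   `os_event` and the linear predictors `lp_pfs`, `lp_os`.
#' @export
simulate_survival <- function(covariates, survival_model = default_survival_model(),
                              seed = 1L) {
  n <- nrow(covariates)
  draw <- function(model) {
    lp <- rep(0, n)
    for (v in names(model$log_hr)) {
      if (!v %in% names(covariates)) {
        tme_config_error("survival_model",
                         sprintf("log_hr names covariate '%s' absent from table", v))
      }
      lp <- lp + model$log_hr[[v]] * as.numeric(covariates[[v]])
    }
    t_event <- stats::rexp(n, model$baseline_rate * exp(lp))
    list(t = t_event, lp = lp)
  }
  with_seed(seed, {
    pfs <- draw(survival_model$pfs)
    os <- draw(survival_model$os)
    cens_rate <- survival_model$censoring_rate
    t_cens_pfs <- if (cens_rate == 0) rep(Inf, n) else stats::rexp(n, cens_rate)
    t_cens_os <- if (cens_rate == 0) rep(Inf, n) else stats::rexp(n, cens_rate)
    data.frame(
      pfs_months = pmin(pfs$t, t_cens_pfs),
      pfs_event = as.integer(pfs$t <= t_cens_pfs),
      os_months = pmin(os$t, t_cens_os),
      os_event = as.integer(os$t <= t_cens_os),
      lp_pfs = pfs$lp, lp_os = os$lp
    )
  })
}

#' Simulate the patient-level table
#'
#' Draws demographics, metastasis flags, PD-L1 group and tumour proportion
#' score, TKI, RECIST best response and survival endpoints for
#' `n_patients` patients. Each patient's covariates come from a
#' counter-derived substream of the root seed, so editing one patient's
#' stream leaves the others unchanged.
#'
#' @param config A [simulation_config()].
#' @param seed Integer root seed.
#' @return Patient data frame (see the column registry in
#'   [write_cohort()]); linear predictors of the survival model are
#'   attached as columns `lp_pfs` and `lp_os`.
#' @export
simulate_patients <- function(config = simulation_config(), seed = 1L) {
  n <- config$n_patients
  if (n == 0L) {
    return(data.frame(patient_id = character(0)))
  }
  one <- function(i) {
    with_seed(derive_seed(seed, i, salt = 1L), {
      grp <- if (stats::runif(1) < config$prop_pdl1_high) "high" else "low"
      tps <- if (grp == "high") {
        stats::runif(1, 0.50, 1.0)
      } else if (stats::runif(1) < 23 / 40) 0 else stats::runif(1, 0.01, 0.49)
      rm_ <- config$response_model[[grp]]
      p_cr <- config$response_model$cr_fraction * rm_[["orr"]]
      probs <- c(CR = p_cr, PR = rm_[["orr"]] - p_cr,
                 SD = rm_[["dcr"]] - rm_[["orr"]], PD = 1 - rm_[["dcr"]])
      data.frame(
        patient_id = sprintf("P%03d", i),
        age = max(25, min(90, round(stats::rnorm(1, 51, 12)))),
        sex = sample(c("female", "male"), 1, prob = c(0.596, 0.404)),
        smoking = sample(c("never", "former_current"), 1, prob = c(0.731, 0.269)),
        stage = sample(c("IV", "IIIB-IIIC"), 1, prob = c(0.942, 0.058)),
        ecog = sample(0:2, 1, prob = c(0.346, 0.519, 0.135)),
        met_brain = stats::rbinom(1, 1, 0.346),
        met_bone = stats::rbinom(1, 1, 0.462),
        met_liver = stats::rbinom(1, 1, 0.212),
        met_adrenal = stats::rbinom(1, 1, 0.077),
        met_pleura = stats::rbinom(1, 1, 0.250),
        met_contralateral_lung = stats::rbinom(1, 1, 0.346),
        tki = sample(c("crizotinib", "alectinib"), 1, prob = c(0.808, 0.192)),
        pdl1_tps = tps,
        pdl1_group = grp,
        best_response = sample(names(probs), 1, prob = probs),
        stringsAsFactors = FALSE
      )
    })
  }
  patients <- do.call(rbind, lapply(seq_len(n), one))
  covars <- data.frame(
    pdl1_high = as.numeric(patients$pdl1_group == "high"),
    met_bone = patients$met_bone,
    ecog_1_2 = as.numeric(patients$ecog >= 1)
  )
  surv <- simulate_survival(covars, config$survival_model,
                            seed = derive_seed(seed, 0L, salt = 2L))
  cbind(patients, surv)
}

#' Simulate a full synthetic cohort
#'
#' Generates the patient table, per-patient ROI geometries and per-cell
#' marker tables. Deterministic for a fixed `(config, seed)` pair.
#'
#' @param config A [simulation_config()].
#' @param seed Integer root seed.
#' @return An object of class `synthetic_cohort`: list with `patients`,
#'   `cells` (one pooled data frame), `geometries` (named list of
#'   [region_geometry()] keyed by ROI id) and `ground_truth` (planted
#'   rates, survival model and per-patient linear predictors).
#' @examples
#' coh <- simulate_cohort(simulation_config(n_patients = 2), seed = 7)
#' names(coh)
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1L) {
  patients <- simulate_patients(config, seed)
  cells_list <- list()
  geometries <- list()
  if (nrow(patients)) {
    for (i in seq_len(nrow(patients))) {
      pid <- patients$patient_id[i]
      n_roi <- with_seed(derive_seed(seed, i, salt = 3L), {
        sample(seq(config$rois_per_patient[1], config$rois_per_patient[2]), 1)
      })
      for (j in seq_len(n_roi)) {
        rid <- sprintf("%s_R%d", pid, j)
        roi <- simulate_roi(rid, patients$pdl1_group[i], config,
                            seed = derive_seed(seed, i, salt = 100L + j))
        roi$cells <- cbind(data.frame(patient_id = rep(pid, nrow(roi$cells)),
                                      stringsAsFactors = FALSE),
                           roi$cells)
        cells_list[[rid]] <- roi$cells
        geometries[[rid]] <- roi$geometry
      }
    }
  }
  cells <- if (length(cells_list)) do.call(rbind, cells_list) else
    data.frame(patient_id = character(0), roi_id = character(0))
  rownames(cells) <- NULL
  structure(list(
    patients = patients,
    cells = cells,
    geometries = geometries,
    ground_truth = list(
      population_rates = config$population_rates,
      survival_model = config$survival_model,
      linear_predictors = if (nrow(patients)) {
        patients[, c("patient_id", "lp_pfs", "lp_os")]
      } else NULL
    )
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d ROIs, %d cells\n",
              nrow(x$patients), length(x$geometries), nrow(x$cells)))
  invisible(x)
}
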