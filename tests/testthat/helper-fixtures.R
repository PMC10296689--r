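# Small fixtures built in code.

# a minimal phenotyped cell table with explicit populations/compartments
make_cells <- function(patient_id = "P001", roi_id = "P001_R1",
                       x, y, profile, compartment = NULL) {
  n <- length(x)
  df <- data.frame(
    patient_id = rep(patient_id, n), roi_id = rep(roi_id, n),
    cell_id = paste0("c", seq_len(n)), x_um = x, y_um = y,
    stringsAsFactors = FALSE
  )
  markers <- c("PANCK", "CD4", "CD8", "FOXP3", "PD1", "CD3", "CD20", "CD56", "CD68")
  for (m in markers) df[[m]] <- 0L
  df$DAPI <- 1L
  map <- list(TUMOUR_CELL = "PANCK", CD4_T = "CD4", CD8_T = "CD8",
              TREG = c("CD4", "FOXP3"), EXHAUSTED_CD8 = c("CD8", "PD1"),
              CD3_T = "CD3", B_CELL = "CD20", NK_CELL = "CD56",
              MACROPHAGE = "CD68", OTHER = character(0))
  for (i in seq_len(n)) {
    for (m in map[[profile[i]]]) df[[m]][i] <- 1L
  }
  if (!is.null(compartment)) df$compartment <- compartment
  phenotype_cells(df)
}

# half-plane-like geometry: tall square tumour nest occupying x in [-1000, 0]
half_plane_geometry <- function() {
  poly <- cbind(c(-1000, 0, 0, -1000), c(-1000, -1000, 1000, 1000))
  region_geometry("hp", list(poly), c(-1000, -1000, 1000, 1000))
}

random_survival_data <- function(n, rate = 0.1, censor_rate = 0.03) {
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::rexp(n, censor_rate)
  list(times = pmin(t_event, t_cens), events = as.integer(t_event <= t_cens))
}
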