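# Survival analysis: Kaplan-Meier, log-rank, Cox univariate-to-multivariate
# selection, maximally selected log-rank cutpoints.

check_surv_input <- function(times, events) {
  if (length(times) != length(events)) tme_error("times and events differ in length")
  if (any(is.na(times)) || any(times < 0)) tme_error("survival times must be non-negative")
  if (!all(events %in% c(0, 1))) tme_error("event indicators must be 0 or 1")
}

#' Kaplan-Meier fit with median survival
#'
#' Product-limit estimator; at tied times deaths are processed before
#' censorings. The median is the earliest time at which the survival curve
#' drops to 0.5 or below, `NA` (not reached) when the curve never does.
#' Median confidence limits use the complementary log-log transform of the
#' curve.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `km_fit`: list with `time`, `surv`,
#'   `n_risk`, `n_event`, `n`, `median`, `median_ci`, `not_reached`.
#' @examples
#' km_fit(1:5, rep(1, 5))$median
#' @export
km_fit <- function(times, events, conf_level = 0.95) {
  check_surv_input(times, events)
  if (!length(times)) tme_error("no observations")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  tab <- summary(fit)$table
  med <- unname(tab["median"])
  lcl_name <- grep("LCL", names(tab), value = TRUE)[1]
  ucl_name <- grep("UCL", names(tab), value = TRUE)[1]
  structure(list(
    time = fit$time, surv = fit$surv,
    n_risk = fit$n.risk, n_event = fit$n.event,
    n = length(times),
    median = med,
    median_ci = c(unname(tab[lcl_name]), unname(tab[ucl_name])),
    not_reached = is.na(med)
  ), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NR" else format(v, digits = 4)
  cat(sprintf("<km_fit> n = %d, median = %s (95%% CI %s-%s)\n",
              x$n, fmt(x$median), fmt(x$median_ci[1]), fmt(x$median_ci[2])))
  invisible(x)
}

#' Log-rank test
#'
#' Standard k-group log-rank chi-squared test with two-sided p-value.
#'
#' @inheritParams km_fit
#' @param group_labels Group membership vector (>= 2 non-empty groups).
#' @return A `tme_test`.
#' @export
logrank_test <- function(times, events, group_labels) {
  check_surv_input(times, events)
  g <- factor(group_labels)
  if (nlevels(g) < 2L) tme_error("log-rank test needs at least two groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- length(sd$n) - 1L
  tme_test(sd$chisq, stats::pchisq(sd$chisq, df, lower.tail = FALSE),
           "log-rank", n = as.vector(sd$n))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximisation with Breslow tie handling by default
#' (Efron available). Reports per-variable hazard ratio, Wald confidence
#' interval and two-sided Wald p.
#'
#' @param covariates Data frame or matrix of covariates (no constant
#'   column; n must exceed the number of covariates).
#' @param times,events As in [km_fit()].
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param conf_level Confidence level for the hazard-ratio interval.
#' @return An object of class `cox_result`: list with `table` (data frame
#'   of `variable`, `coef`, `hr`, `lcl`, `ucl`, `p`), `ties`, `converged`,
#'   `iter`, `loglik` and the underlying `survival::coxph` `fit`.
#' @export
cox_fit <- function(covariates, times, events, ties = c("breslow", "efron"),
                    conf_level = 0.95) {
  ties <- match.arg(ties)
  check_surv_input(times, events)
  x <- as.data.frame(covariates)
  x[] <- lapply(x, function(col) if (is.logical(col)) as.numeric(col) else col)
  const <- vapply(x, function(col) is.numeric(col) && stats::var(col) == 0, logical(1))
  if (any(const)) {
    tme_error(sprintf("constant covariate(s): %s",
                      paste(names(x)[const], collapse = ", ")))
  }
  if (length(times) <= ncol(x)) tme_error("need more observations than covariates")
  dat <- cbind(data.frame(.time = times, .event = events), x)
  fit <- tryCatch(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = ties, control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                        ties = ties, control = survival::coxph.control(eps = 1e-9, iter.max = 50)))
      attr(f, "tme_warning") <- conditionMessage(w)
      f
    })
  s <- summary(fit, conf.int = conf_level)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tab <- data.frame(
    variable = names(beta),
    coef = unname(beta),
    hr = exp(unname(beta)),
    lcl = exp(unname(beta) - z * se),
    ucl = exp(unname(beta) + z * se),
    p = unname(2 * stats::pnorm(-abs(beta / se))),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, ties = ties,
                 converged = is.null(attr(fit, "tme_warning")),
                 warning = attr(fit, "tme_warning"),
                 iter = fit$iter, loglik = fit$loglik, fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> ties = %s, iter = %d%s\n", x$ties, x$iter,
              if (!x$converged) " (warning raised)" else ""))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

# canonical candidate design matrix built from a patient table
cox_candidates <- function(patients) {
  data.frame(
    age_ge65 = as.numeric(patients$age >= 65),
    sex_female = as.numeric(patients$sex == "female"),
    smoking_former_current = as.numeric(patients$smoking == "former_current"),
    stage_iv = as.numeric(patients$stage == "IV"),
    ecog_1_2 = as.numeric(patients$ecog >= 1),
    met_brain = as.numeric(patients$met_brain),
    met_bone = as.numeric(patients$met_bone),
    met_liver = as.numeric(patients$met_liver),
    met_adrenal = as.numeric(patients$met_adrenal),
    met_pleura = as.numeric(patients$met_pleura),
    met_contralateral_lung = as.numeric(patients$met_contralateral_lung),
    pdl1_high = as.numeric(patients$pdl1_group == "high"),
    tki_alectinib = as.numeric(patients$tki == "alectinib")
  )
}

#' Select variables by univariate p-value
#'
#' The entry rule for the multivariate Cox model: keep every candidate
#' whose univariate two-sided p-value is below `alpha`.
#'
#' @param p_values Named numeric vector of univariate p-values.
#' @param alpha Entry threshold (default 0.05).
#' @return Character vector of selected variable names (possibly empty).
#' @export
screen_variables <- function(p_values, alpha = 0.05) {
  names(p_values)[is.finite(p_values) & p_values < alpha]
}

#' Univariate screen followed by multivariate Cox model
#'
#' Fits each candidate covariate alone against the endpoint, selects those
#' with univariate p below the entry threshold, and refits the selected
#' set jointly. With an empty selection only the univariate results are
#' returned, with a note.
#'
#' @param patients Patient table with clinical covariates and
#'   `pfs_months`/`pfs_event`/`os_months`/`os_event` columns.
#' @param endpoint `"pfs"` or `"os"`.
#' @param alpha_entry Univariate entry threshold (default 0.05).
#' @param candidates Optional data frame of candidate covariates (one
#'   column per variable); defaults to the standard clinical candidate set
#'   (age >= 65, sex, smoking, stage, ECOG 1-2, metastasis sites, PD-L1
#'   >= 50%, TKI).
#' @param ties Tie handling for the Cox fits.
#' @return List with `univariate` (data frame), `selected` (character),
#'   `multivariate` (a `cox_result` or `NULL`) and `note`.
#' @export
univariate_screen_then_multivariate <- function(patients,
                                                endpoint = c("pfs", "os"),
                                                alpha_entry = 0.05,
                                                candidates = NULL,
                                                ties = "breslow") {
  endpoint <- match.arg(endpoint)
  times <- patients[[paste0(endpoint, "_months")]]
  events <- patients[[paste0(endpoint, "_event")]]
  if (is.null(times) || is.null(events)) {
    tme_error(sprintf("patient table lacks %s time/event columns", endpoint),
              class = "tme_schema_error")
  }
  if (is.null(candidates)) candidates <- cox_candidates(patients)
  usable <- vapply(candidates, function(col) stats::var(as.numeric(col)) > 0, logical(1))
  dropped <- names(candidates)[!usable]
  if (length(dropped)) {
    warning(sprintf("constant candidate(s) dropped: %s", paste(dropped, collapse = ", ")))
  }
  candidates <- candidates[usable]
  uni <- do.call(rbind, lapply(names(candidates), function(v) {
    res <- cox_fit(candidates[v], times, events, ties = ties)
    cbind(res$table, endpoint = endpoint, analysis = "univariate")
  }))
  p <- stats::setNames(uni$p, uni$variable)
  selected <- screen_variables(p, alpha_entry)
  multi <- NULL
  note <- NULL
  if (length(selected)) {
    multi <- cox_fit(candidates[selected], times, events, ties = ties)
  } else {
    note <- "no candidate passed the univariate entry threshold; multivariate model not fitted"
  }
  list(univariate = uni, selected = selected, multivariate = multi, note = note)
}

# Standardized two-group log-rank statistic (O - E)/sqrt(V) for group1
# membership g (logical). Hypergeometric variance, deaths before
# censorings at tied times.
logrank_z_stat <- function(times, events, g) {
  o <- order(times)
  t_s <- times[o]; e_s <- events[o]; g_s <- g[o]
  ut <- unique(t_s[e_s == 1])
  O1 <- E1 <- V <- 0
  for (u in ut) {
    at <- t_s >= u
    n <- sum(at)
    n1 <- sum(at & g_s)
    d <- sum(t_s == u & e_s == 1)
    d1 <- sum(t_s == u & e_s == 1 & g_s)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) return(NA_real_)
  (O1 - E1) / sqrt(V)
}

#' Maximally selected log-rank cutpoint
#'
#' Dichotomises a continuous marker at the value that maximises the
#' absolute standardized two-group log-rank statistic over all admissible
#' splits between consecutive distinct marker values. A split at cutpoint
#' c compares `value <= c` ("low") against `value > c` ("high"); splits
#' leaving either side with fewer than `minprop` of the subjects are not
#' admissible. Ties in the statistic are broken toward the lower cutpoint.
#'
#' The post-selection log-rank p-value is optimistic (the cutpoint was
#' chosen to maximise separation); it is reported as-is, as in common
#' practice, and a warning notes the optimism.
#'
#' @param values Continuous marker, one value per subject (>= 2 distinct).
#' @param times,events As in [km_fit()].
#' @param minprop Minimum fraction of subjects on each side (default 0.1).
#' @return An object of class `cutpoint_result`: list with `cutpoint`,
#'   `statistic` (signed standardized log-rank statistic at the optimum),
#'   `abs_statistic`, `groups` (factor `high`/`low` per subject),
#'   `minprop`, `n_candidates`.
#' @export
optimal_cutpoint <- function(values, times, events, minprop = 0.1) {
  check_surv_input(times, events)
  if (length(values) != length(times)) tme_error("values and times differ in length")
  check_number(minprop, "minprop", 0, 0.5)
  sv <- sort(unique(values))
  if (length(sv) < 2L) {
    tme_error("marker is constant; no cutpoint exists",
              class = "tme_degenerate_marker_error")
  }
  cuts <- sv[-length(sv)]
  n <- length(values)
  n_low <- vapply(cuts, function(cc) sum(values <= cc), numeric(1))
  admissible <- n_low >= minprop * n & (n - n_low) >= minprop * n
  cuts <- cuts[admissible]
  if (!length(cuts)) {
    tme_error("no admissible split satisfies minprop on both sides",
              class = "tme_degenerate_marker_error")
  }
  zs <- vapply(cuts, function(cc) logrank_z_stat(times, events, values <= cc),
               numeric(1))
  az <- abs(zs)
  az[is.na(az)] <- -Inf
  best <- which.max(az)  # which.max takes the first = lowest cutpoint on ties
  groups <- factor(ifelse(values > cuts[best], "high", "low"),
                   levels = c("low", "high"))
  structure(list(cutpoint = cuts[best], statistic = zs[best],
                 abs_statistic = abs(zs[best]), groups = groups,
                 minprop = minprop, n_candidates = length(cuts)),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("<cutpoint_result> cutpoint = %g, |standardized log-rank| = %.4f (%d candidate splits, minprop %g)\n",
              x$cutpoint, x$abs_statistic, x$n_candidates, x$minprop))
  invisible(x)
}

#' Kaplan-Meier report stratified by a grouping
#'
#' Per-stratum KM medians with confidence intervals and pairwise log-rank
#' p-values, for a clinical stratifier (e.g. PD-L1 group) or a composite
#' one (e.g. PD-L1 group x immune-cell level). Strata with fewer than two
#' subjects are dropped with a warning.
#'
#' @param patients Patient table with endpoint columns.
#' @param stratifier Column name in `patients`, or a vector of group
#'   labels of the same length.
#' @param endpoint `"pfs"` or `"os"`.
#' @return List with `summary` (data frame: group, n, events, median,
#'   lcl, ucl) and `pairwise` (data frame of pairwise log-rank p-values;
#'   `NULL` when fewer than two usable strata remain).
#' @export
stratified_km_report <- function(patients, stratifier, endpoint = c("pfs", "os")) {
  endpoint <- match.arg(endpoint)
  times <- patients[[paste0(endpoint, "_months")]]
  events <- patients[[paste0(endpoint, "_event")]]
  g <- if (length(stratifier) == 1L && is.character(stratifier)) {
    as.character(patients[[stratifier]])
  } else {
    as.character(stratifier)
  }
  keep_levels <- names(which(table(g) >= 2))
  dropped <- setdiff(unique(g), keep_levels)
  if (length(dropped)) {
    warning(sprintf("stratum(a) with fewer than 2 subjects dropped: %s",
                    paste(dropped, collapse = ", ")))
  }
  keep <- g %in% keep_levels
  times <- times[keep]; events <- events[keep]; g <- g[keep]
  summ <- do.call(rbind, lapply(sort(unique(g)), function(lev) {
    km <- km_fit(times[g == lev], events[g == lev])
    data.frame(group = lev, n = km$n, events = sum(events[g == lev]),
               median = km$median, lcl = km$median_ci[1], ucl = km$median_ci[2],
               stringsAsFactors = FALSE)
  }))
  pairwise <- NULL
  levs <- sort(unique(g))
  if (length(levs) >= 2L) {
    combos <- utils::combn(levs, 2)
    pairwise <- do.call(rbind, apply(combos, 2, function(pair) {
      sel <- g %in% pair
      lt <- logrank_test(times[sel], events[sel], g[sel])
      data.frame(group1 = pair[1], group2 = pair[2],
                 chisq = lt$statistic, p_value = lt$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(endpoint = endpoint, summary = summ, pairwise = pairwise)
}
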