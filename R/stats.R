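# Cohort statistics: Mann-Whitney, Spearman with the strong-correlation
# rule, exact and chi-squared contingency tests, response rates.

#' Statistics configuration
#'
#' @param strong_r_threshold Absolute Spearman coefficient above which a
#'   correlation is called strong (default 0.60).
#' @param alpha Two-sided significance level (default 0.05).
#' @param exact_mw_max_n Largest group size for which the Mann-Whitney test
#'   uses exact null enumeration (default 20; beyond that, or with ties,
#'   the tie-corrected normal approximation is used).
#' @return An object of class `stats_config`.
#' @export
stats_config <- function(strong_r_threshold = 0.60, alpha = 0.05,
                         exact_mw_max_n = 20L) {
  check_number(strong_r_threshold, "strong_r_threshold", 0, 1, strict_lower = TRUE)
  check_number(alpha, "alpha", 0, 1, strict_lower = TRUE)
  check_number(exact_mw_max_n, "exact_mw_max_n", lower = 1)
  structure(list(strong_r_threshold = strong_r_threshold, alpha = alpha,
                 exact_mw_max_n = as.integer(exact_mw_max_n)),
            class = "stats_config")
}

tme_test <- function(statistic, p_value, method, n, extra = list()) {
  structure(c(list(statistic = unname(statistic), p_value = unname(p_value),
                   method = method, n = n), extra),
            class = "tme_test")
}

#' @export
print.tme_test <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %s, p = %.4g, n = %s\n", x$method,
              format(x$statistic, digits = 5), x$p_value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact null enumeration when both groups are small and there are no
#' ties; otherwise the normal approximation with tie correction (no
#' continuity correction, so the two branches agree closely).
#'
#' @param group_a,group_b Numeric vectors.
#' @param config A [stats_config()].
#' @return A `tme_test` with the U statistic and two-sided p-value.
#' @export
mann_whitney_u <- function(group_a, group_b, config = stats_config()) {
  if (!length(group_a) || !length(group_b)) {
    tme_error("both groups must be non-empty for the Mann-Whitney U test")
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- !ties && max(length(group_a), length(group_b)) <= config$exact_mw_max_n
  res <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = FALSE)
  )
  tme_test(res$statistic, res$p.value,
           if (exact) "Mann-Whitney U (exact)" else "Mann-Whitney U (normal approx., tie-corrected)",
           n = c(length(group_a), length(group_b)))
}

#' Spearman rank correlation with the strong-correlation rule
#'
#' Rank correlation (average ranks for ties); flags the correlation as
#' strong when the absolute coefficient exceeds the configured threshold.
#' Exact permutation p-value for n <= 9 without ties, otherwise the
#' t-distribution approximation.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param config A [stats_config()].
#' @return A `tme_test` with elements `estimate` (rho) and `strong`.
#' @export
spearman_corr <- function(x, y, config = stats_config()) {
  if (length(x) != length(y)) tme_error("x and y must have equal length")
  if (length(x) < 3L) tme_error("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; Spearman correlation undefined")
    return(tme_test(NA_real_, NA_real_, "Spearman rank correlation",
                    n = length(x), extra = list(estimate = NA_real_, strong = FALSE)))
  }
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  exact <- length(x) <= 9L && !ties
  res <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact)
  )
  rho <- unname(res$estimate)
  tme_test(res$statistic, res$p.value,
           if (exact) "Spearman rank correlation (exact)" else "Spearman rank correlation (t approx.)",
           n = length(x),
           extra = list(estimate = rho,
                        strong = is.finite(rho) && abs(rho) > config$strong_r_threshold))
}

check_2x2 <- function(m) {
  m <- as.matrix(m)
  if (any(dim(m) != c(2L, 2L))) tme_error("table must be 2x2")
  if (any(m < 0) || anyNA(m)) tme_error("table entries must be non-negative counts")
  storage.mode(m) <- "double"
  m
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional on the margins, the two-sided p-value sums the
#' hypergeometric probabilities of all tables whose point probability does
#' not exceed (within a small relative tolerance) that of the observed
#' table.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return A `tme_test` with the odds-ratio estimate as statistic.
#' @examples
#' fisher_exact_2x2(matrix(c(28, 10, 12, 2), 2))
#' @export
fisher_exact_2x2 <- function(table) {
  m <- check_2x2(table)
  res <- stats::fisher.test(m)
  tme_test(res$estimate, res$p.value, "Fisher exact (two-sided)", n = sum(m))
}

#' Pearson chi-squared test for a 2x2 table
#'
#' No continuity correction by default (the convention that reproduces
#' mainstream response-rate analyses); Yates correction available by flag.
#'
#' @param table 2x2 matrix of non-negative counts with positive total.
#' @param correction Apply the Yates continuity correction (default FALSE).
#' @return A `tme_test` with the X-squared statistic (df = 1).
#' @export
pearson_chi2_2x2 <- function(table, correction = FALSE) {
  m <- check_2x2(table)
  if (sum(m) <= 0) tme_error("table has zero total")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) {
    tme_error("a cell has zero expected count; use fisher_exact_2x2() instead",
              class = "tme_degenerate_table_error")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = correction))
  tme_test(res$statistic, res$p.value,
           if (correction) "Pearson chi-squared (Yates-corrected)" else "Pearson chi-squared",
           n = sum(m))
}

#' Exact test for an r x c contingency table
#'
#' Freeman-Halton generalisation of the Fisher exact test, for tables such
#' as a 2 x 3 performance-status breakdown.
#'
#' @param table r x c matrix of non-negative counts.
#' @return A `tme_test`.
#' @export
freeman_halton_exact <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || anyNA(m)) tme_error("table entries must be non-negative counts")
  res <- stats::fisher.test(m, workspace = 2e6)
  tme_test(NA_real_, res$p.value, "Freeman-Halton exact (r x c)", n = sum(m))
}

#' Objective response and disease control rates
#'
#' ORR is the fraction of patients achieving complete (CR) or partial (PR)
#' response; DCR additionally includes stable disease (SD).
#'
#' @param best_responses Character vector with values in
#'   `c("CR", "PR", "SD", "PD")`.
#' @return Named numeric vector `c(orr = , dcr = )` (fractions).
#' @examples
#' response_rates(c("CR", "PR", "PR", "SD", "PD"))
#' @export
response_rates <- function(best_responses) {
  bad <- setdiff(unique(best_responses), c("CR", "PR", "SD", "PD"))
  if (length(bad)) {
    tme_error(sprintf("unknown response category: %s", paste(bad, collapse = ", ")))
  }
  n <- length(best_responses)
  if (n == 0L) tme_error("no responses supplied")
  c(orr = sum(best_responses %in% c("CR", "PR")) / n,
    dcr = sum(best_responses %in% c("CR", "PR", "SD")) / n)
}

#' Baseline characteristics table by PD-L1 group
#'
#' Builds the standard baseline table comparing the PD-L1 high and low
#' groups: counts per level with Fisher exact p-values for two-level
#' characteristics and the Freeman-Halton exact test for the three-level
#' performance-status row.
#'
#' @param patients Patient table (see [simulate_patients()] for the
#'   column registry).
#' @return Data frame with columns `characteristic`, `level`, `n_low`,
#'   `n_high`, `p_value` (p on the first row of each characteristic).
#' @export
baseline_table <- function(patients) {
  hi <- patients$pdl1_group == "high"
  rows <- list()
  add <- function(characteristic, level_labels, low_counts, high_counts, p) {
    for (i in seq_along(level_labels)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        characteristic = characteristic, level = level_labels[i],
        n_low = low_counts[i], n_high = high_counts[i],
        p_value = if (i == 1L) p else NA_real_, stringsAsFactors = FALSE)
    }
  }
  two_level <- function(characteristic, flag, labels = c("yes", "no")) {
    tab <- rbind(c(sum(flag & !hi), sum(flag & hi)),
                 c(sum(!flag & !hi), sum(!flag & hi)))
    p <- fisher_exact_2x2(tab)$p_value
    add(characteristic, labels, tab[, 1], tab[, 2], p)
  }
  two_level("age", patients$age >= 65, c(">=65", "<65"))
  two_level("sex", patients$sex == "female", c("female", "male"))
  two_level("smoking", patients$smoking == "former_current", c("former/current", "never"))
  two_level("stage", patients$stage == "IV", c("IV", "IIIB-IIIC"))
  ecog_tab <- rbind(table(factor(patients$ecog[!hi], levels = 0:2)),
                    table(factor(patients$ecog[hi], levels = 0:2)))
  add("ecog", c("0", "1", "2"), ecog_tab[1, ], ecog_tab[2, ],
      freeman_halton_exact(ecog_tab)$p_value)
  for (site in c("brain", "bone", "liver", "adrenal", "pleura", "contralateral_lung")) {
    col <- paste0("met_", site)
    if (col %in% names(patients)) {
      two_level(paste0("metastasis_", site), as.logical(patients[[col]]))
    }
  }
  two_level("tki", patients$tki == "alectinib", c("alectinib", "crizotinib"))
  do.call(rbind, rows)
}
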