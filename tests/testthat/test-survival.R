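test_that("Kaplan-Meier estimator steps correctly and reports the median", {
  km <- km_fit(1:5, rep(1, 5))
  expect_equal(km$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$median, 3)   # earliest time with S <= 0.5
  cens <- km_fit(c(2, 4, 6), c(0, 0, 0))
  expect_true(cens$not_reached)
  expect_true(is.na(cens$median))
  expect_error(km_fit(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(21)
  t <- round(rexp(400, 0.2), 2)
  km <- km_fit(t, rep(1, 400))
  emp <- vapply(km$time, function(u) mean(t > u), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("log-rank test matches the hand-computed statistic and its null behaviour", {
  # group A events at 1, 2; group B events at 3, 4 -> chisq = 49/17
  lt <- logrank_test(c(1, 2, 3, 4), rep(1, 4), c("A", "A", "B", "B"))
  expect_equal(unname(lt$statistic), 49 / 17, tolerance = 1e-9)
  # two identical groups: statistic 0, p = 1
  t <- c(1, 3, 5, 7); e <- c(1, 0, 1, 1)
  lt0 <- logrank_test(c(t, t), c(e, e), rep(c("A", "B"), each = 4))
  expect_equal(unname(lt0$statistic), 0, tolerance = 1e-12)
  expect_equal(lt0$p_value, 1)
  expect_error(logrank_test(t, e, rep("A", 4)), "two groups")
})

test_that("log-rank rejects nearly always under a strong planted hazard ratio", {
  set.seed(33)
  rejections <- vapply(1:60, function(i) {
    x <- rep(c(0, 1), each = 200)
    t <- rexp(400, 0.1 * exp(log(3) * x))
    logrank_test(t, rep(1, 400), x)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.95)
})

test_that("Cox estimate matches brute-force partial-likelihood maximisation on a tiny dataset", {
  times <- c(1.3, 2.1, 3.7, 4.2, 5.9, 7.5)
  events <- c(1, 1, 0, 1, 1, 1)
  x <- c(1, 0, 1, 0, 1, 0)
  fit <- cox_fit(data.frame(x = x), times, events)
  grid <- seq(-4, 4, by = 1e-4)
  ll <- oracle_cox_loglik(grid, x, times, events)
  expect_equal(fit$table$coef, grid[which.max(ll)], tolerance = 5e-4)
  # score condition: log-likelihood at estimate >= at 0
  expect_gte(fit$loglik[2], fit$loglik[1])
})

test_that("Cox Wald interval covers the null at about the nominal rate under no effect", {
  set.seed(44)
  cover <- vapply(1:100, function(i) {
    x <- rbinom(100, 1, 0.5)
    t <- rexp(100, 0.1)
    e <- as.integer(t < rexp(100, 0.03))
    t <- pmin(t, 60)
    fit <- cox_fit(data.frame(x = x), t, e)
    fit$table$lcl <= 1 && 1 <= fit$table$ucl
  }, logical(1))
  expect_gte(mean(cover), 0.88)
})

test_that("Cox input guards and tie-handling options work", {
  expect_error(cox_fit(data.frame(x = rep(1, 10)), rexp(10), rep(1, 10)),
               "constant covariate")
  set.seed(9)
  x <- rbinom(60, 1, 0.5)
  t <- sample(1:8, 60, replace = TRUE)  # heavy ties
  e <- rbinom(60, 1, 0.8)
  b <- cox_fit(data.frame(x = x), t, e, ties = "breslow")$table$coef
  f <- cox_fit(data.frame(x = x), t, e, ties = "efron")$table$coef
  expect_false(isTRUE(all.equal(b, f, tolerance = 1e-10)))
})

test_that("univariate screen selects by p-value and gates the multivariate fit", {
  expect_identical(screen_variables(c(a = 0.04, b = 0.6, c = 0.049), 0.05),
                   c("a", "c"))
  expect_identical(screen_variables(c(a = 0.5, b = 0.6)), character(0))
  set.seed(12)
  pts <- simulate_patients(simulation_config(n_patients = 150), seed = 3)
  res <- univariate_screen_then_multivariate(pts, "pfs")
  expect_true(all(res$univariate$p[match(res$selected, res$univariate$variable)] < 0.05))
  if (length(res$selected)) {
    expect_setequal(res$multivariate$table$variable, res$selected)
  }
  # all-null covariates: no selection, multivariate skipped with a note
  null_pts <- pts
  null_cand <- data.frame(noise1 = rnorm(150), noise2 = rnorm(150))
  res0 <- univariate_screen_then_multivariate(null_pts, "os",
                                              alpha_entry = 1e-6,
                                              candidates = null_cand)
  expect_identical(res0$selected, character(0))
  expect_null(res0$multivariate)
  expect_match(res0$note, "no candidate")
})

test_that("optimal cutpoint maximises the standardized log-rank statistic", {
  # frozen via the survdiff oracle: |z| = 1.334, 1.698, 1.732 at cuts 1, 2, 3
  cp <- optimal_cutpoint(c(1, 2, 3, 4), c(10, 9, 2, 1), rep(1, 4), minprop = 0)
  expect_equal(cp$cutpoint, 3)
  expect_equal(cp$abs_statistic, sqrt(3), tolerance = 1e-9)
  expect_identical(as.character(cp$groups), c("low", "low", "low", "high"))
  expect_error(optimal_cutpoint(rep(2, 5), 1:5, rep(1, 5)),
               "constant", class = "tme_degenerate_marker_error")
  # minprop restricts admissible splits
  set.seed(17)
  v <- c(rnorm(19), 100)
  d <- random_survival_data(20)
  cp2 <- optimal_cutpoint(v, d$times, d$events, minprop = 0.25)
  expect_true(min(table(cp2$groups)) >= 0.25 * 20)
})

test_that("optimal cutpoint equals exhaustive oracle search on random instances", {
  set.seed(23)
  for (i in 1:12) {
    n <- sample(15:80, 1)
    v <- round(rnorm(n), sample(1:2, 1))
    if (length(unique(v)) < 2) next
    d <- random_survival_data(n)
    cp <- tryCatch(optimal_cutpoint(v, d$times, d$events, minprop = 0.1),
                   tme_error = function(e) NULL)
    or <- oracle_cutpoint(v, d$times, d$events, minprop = 0.1)
    if (is.null(cp) || is.null(or)) next
    expect_equal(cp$cutpoint, or$cutpoint)
    expect_equal(cp$abs_statistic, or$abs_statistic, tolerance = 1e-9)
  }
})

test_that("stratified KM report drops degenerate strata and orders medians by planted risk", {
  pts <- simulate_patients(simulation_config(n_patients = 400), seed = 5)
  rep_ <- stratified_km_report(pts, "pdl1_group", "pfs")
  expect_setequal(rep_$summary$group, c("high", "low"))
  # planted PFS hazard ratio 2.792: high group progresses earlier
  expect_lt(rep_$summary$median[rep_$summary$group == "high"],
            rep_$summary$median[rep_$summary$group == "low"])
  expect_true(rep_$pairwise$p_value < 0.05)
  # identical strata -> p = 1
  dup <- rbind(pts[1:30, ], pts[1:30, ])
  dup$grp <- rep(c("A", "B"), each = 30)
  expect_equal(stratified_km_report(dup, "grp", "pfs")$pairwise$p_value, 1)
  # single-patient stratum dropped with a warning
  lab <- c("solo", rep(c("x", "y"), length.out = nrow(pts) - 1))
  expect_warning(r2 <- stratified_km_report(pts, lab, "os"), "solo")
  expect_false("solo" %in% r2$summary$group)
})
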