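test_that("Mann-Whitney exact branch matches full enumeration", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 0.1)   # 2/20 labelings as extreme
  set.seed(5)
  for (i in 1:10) {
    a <- runif(sample(3:6, 1)); b <- runif(sample(3:6, 1))
    expect_equal(mann_whitney_u(a, b)$p_value, oracle_mw_exact(a, b),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney is symmetric under identical groups and branches agree", {
  expect_equal(mann_whitney_u(c(1, 2), c(1, 2))$p_value, 1, tolerance = 1e-9)
  set.seed(6)
  for (i in 1:10) {
    a <- rnorm(15); b <- rnorm(15, 0.4)
    p_exact <- mann_whitney_u(a, b, stats_config(exact_mw_max_n = 20))$p_value
    p_approx <- mann_whitney_u(a, b, stats_config(exact_mw_max_n = 5))$p_value
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("Spearman correlation handles monotone, tied and constant input", {
  r1 <- spearman_corr(1:3, c(2, 4, 6))
  expect_equal(r1$estimate, 1)
  expect_true(r1$strong)
  r2 <- spearman_corr(1:3, c(6, 4, 2))
  expect_equal(r2$estimate, -1)
  expect_true(r2$strong)
  # average ranks with a tie: hand-computed rho
  r3 <- spearman_corr(1:4, c(1, 1, 3, 4))
  expect_equal(r3$estimate, 4.5 / sqrt(5 * 4.5), tolerance = 1e-12)
  expect_equal(r3$estimate, 0.9487, tolerance = 1e-4)
  expect_warning(r4 <- spearman_corr(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r4$estimate))
  expect_false(r4$strong)
  # self-correlation of any non-constant vector is 1
  set.seed(8)
  x <- rnorm(12)
  expect_equal(spearman_corr(x, x)$estimate, 1)
})

test_that("Fisher exact equals hypergeometric enumeration and is label-swap symmetric", {
  set.seed(13)
  for (i in 1:30) {
    m <- matrix(rpois(4, sample(2:12, 1)), 2)
    if (sum(m) > 60 || sum(m) == 0) next
    p_pkg <- fisher_exact_2x2(m)$p_value
    expect_equal(p_pkg, oracle_fisher_2x2(m), tolerance = 1e-10)
    expect_equal(fisher_exact_2x2(m[2:1, ])$p_value, p_pkg, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(m[, 2:1])$p_value, p_pkg, tolerance = 1e-12)
  }
  # zero margin: only one attainable table
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 5, 7), 2))$p_value, 1)
})

test_that("chi-squared test without correction behaves on degenerate and symmetric tables", {
  prop <- pearson_chi2_2x2(rbind(c(20, 20), c(10, 10)))
  expect_equal(unname(prop$statistic), 0)
  expect_equal(prop$p_value, 1)
  m <- rbind(c(28, 12), c(6, 6))
  expect_equal(pearson_chi2_2x2(m[2:1, ])$p_value, pearson_chi2_2x2(m)$p_value)
  expect_error(pearson_chi2_2x2(rbind(c(0, 0), c(3, 4))),
               "zero expected", class = "tme_degenerate_table_error")
  # Yates flag changes the statistic
  expect_lt(pearson_chi2_2x2(m, correction = TRUE)$statistic,
            pearson_chi2_2x2(m)$statistic)
})

test_that("response rates count CR/PR and CR/PR/SD fractions", {
  rr <- response_rates(c("CR", "PR", "PR", "SD", "PD"))
  expect_equal(unname(rr), c(0.6, 0.8))
  expect_equal(unname(response_rates(rep("PD", 4))), c(0, 0))
  expect_error(response_rates(c("CR", "XX")), "unknown response")
})

test_that("baseline table reports counts per group with valid p-values", {
  pts <- simulate_patients(simulation_config(n_patients = 40), seed = 2)
  tab <- baseline_table(pts)
  expect_true(all(c("characteristic", "level", "n_low", "n_high", "p_value") %in% names(tab)))
  p <- tab$p_value[!is.na(tab$p_value)]
  expect_true(all(p >= 0 & p <= 1))
  # counts add up to the group sizes within each characteristic
  for (ch in unique(tab$characteristic)) {
    sub <- tab[tab$characteristic == ch, ]
    expect_equal(sum(sub$n_low), sum(pts$pdl1_group == "low"))
    expect_equal(sum(sub$n_high), sum(pts$pdl1_group == "high"))
  }
})
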