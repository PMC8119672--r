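test_that("degenerate variances reproduce the overall mean exactly", {
  spec <- cohort_sim_spec(between_group_sd = c(0, 0),
                          within_logvar_mean = c(-60, -60),
                          within_logvar_sd = c(1e-12, 1e-12),
                          corr_dispersion = 0, seed = 1)
  tbl <- simulate_cohort(spec)
  expect_equal(tbl$y_elm_rpe, rep(10, nrow(tbl)), tolerance = 1e-6)
  expect_equal(tbl$y_hb, rep(9, nrow(tbl)), tolerance = 1e-6)
})

test_that("group-mean moments match the configured hierarchy", {
  # many small groups: sample moments of the group means against (mu, Sigma_mu)
  spec <- cohort_sim_spec(n_mice_per_group = rep(2, 2000),
                          between_group_sd = c(3, 2.4),
                          between_group_corr = 0.975, seed = 7)
  tbl <- simulate_cohort(spec)
  tr <- attr(tbl, "truth")
  mu_g <- t(vapply(tr$groups, function(g) g$mu, numeric(2)))
  n <- nrow(mu_g)
  se_mean <- spec$between_group_sd / sqrt(n)
  expect_lt(abs(mean(mu_g[, 1]) - 10), 3 * se_mean[1])
  expect_lt(abs(mean(mu_g[, 2]) - 9), 3 * se_mean[2])
  expect_lt(abs(sd(mu_g[, 1]) - 3), 3 * 3 / sqrt(2 * n))
  expect_lt(abs(cor(mu_g[, 1], mu_g[, 2]) - 0.975), 0.02)
})

test_that("invalid covariance or correlation settings are rejected", {
  expect_error(cohort_sim_spec(between_group_corr = 1.2), "\\[-1, 1\\]")
  expect_error(cohort_sim_spec(overall_within_corr = 0.5,
                               corr_dispersion = 0.2), "beta variance")
  expect_error(drug_sim_spec(intercept_corr = 2), "positive semi-definite")
})

test_that("drug multipliers scale treated means by the law of large numbers", {
  spec <- drug_sim_spec(n_per_group = c(ACZ = 10, DNP10 = 2000),
                        intercept_sd = c(0.5, 0.5), resid_sd = c(0.5, 0.5),
                        seed = 11)
  tbl <- simulate_drug_cohort(spec)
  d10 <- tbl[tbl$drug_group == "DNP10", ]
  m_t <- mean(d10$y_hb[d10$treated == 1])
  m_c <- mean(d10$y_hb[d10$treated == 0])
  expect_lt(abs(m_t / m_c - 0.04), 0.01)
})

test_that("cohort simulation is reproducible under a fixed seed", {
  s <- cohort_sim_spec(seed = 123)
  expect_identical(simulate_cohort(s), simulate_cohort(s))
  d <- drug_sim_spec(seed = 123)
  expect_identical(simulate_drug_cohort(d), simulate_drug_cohort(d))
})
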