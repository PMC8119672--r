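# unit-level model checks at reduced sampler settings; full recovery studies
# live in test-acceptance.R

test_that("group-hierarchical posterior concentrates on degenerate data", {
  tbl <- tibble::tibble(group = rep(c("a", "b", "c"), each = 4),
                        y_hb = rep(5, 12) + rep(c(-0.01, 0.01), 6))
  f <- fit_group_hierarchical(tbl, "y_hb", settings = quick_settings(), seed = 2)
  td <- tidy(f)
  expect_equal(unname(td$estimate[td$term == "mu0"]), 5, tolerance = 0.2)
  expect_true(all(abs(td$estimate[grepl("^theta_", td$term)] - 5) < 0.2))
})

test_that("a single-mouse group shrinks toward the overall mean", {
  set.seed(1)
  tbl <- tibble::tibble(
    group = c(rep("big1", 8), rep("big2", 8), "solo"),
    y_hb = c(rnorm(8, 5, 0.3), rnorm(8, 5.4, 0.3), 12))
  f <- fit_group_hierarchical(tbl, "y_hb", settings = quick_settings(), seed = 3)
  solo <- tidy(f)$estimate[tidy(f)$term == "theta_solo"]
  expect_lt(solo, 12)    # pulled off its own datum
  expect_gt(solo, 5.2)   # but not collapsed onto the grand mean
})

test_that("joint model input contracts are enforced", {
  tbl <- simulate_cohort(cohort_sim_spec(seed = 1))
  expect_error(fit_joint_bivariate(tbl[tbl$group %in% c("g1", "g2"), ]),
               "at least 3 groups")
  one <- tbl[tbl$group != "g1" | tbl$mouse_id == "g1_m01", ]
  expect_error(fit_joint_bivariate(one), "at least 2 mice")
})

test_that("joint model recovers strong between-group correlation", {
  tbl <- simulate_cohort(cohort_sim_spec(seed = 2))
  f <- fit_joint_bivariate(tbl, settings = quick_settings(4, 1500), seed = 4)
  r <- post_draws(f, "r_mu")
  expect_gt(mean(r), 0.6)
  ci <- credibility_interval(f, term = "r_mu")
  expect_true(ci$excludes_zero)
  # slope draws are consistent with their definition
  expect_equal(post_draws(f, "slope_hb_on_elm"),
               r * post_draws(f, "sd_mu_hb") / post_draws(f, "sd_mu_elm_rpe"))
})

test_that("unpaired drug-cohort rows are rejected with the mouse ids", {
  tbl <- simulate_drug_cohort(drug_sim_spec(seed = 1))
  broken <- tbl[-2, ]
  expect_error(fit_drug_mixed(broken, settings = quick_settings()),
               "unpaired.*ACZ_01")
})

test_that("normalized drug response arithmetic follows its definition", {
  # fitted control mean 10, treated mean 4 for DNP5 -> (4 - 10) / 10 = -0.6
  post <- fake_drug_post(c(beta_hb_intercept = 6, beta_hb_DNP5 = 4,
                           beta_hb_treat = -2, beta_hb_treat_DNP5 = -4))
  r <- normalized_drug_response(post, "DNP5", "hb")
  expect_equal(unique(r$draws), -0.6)
  # drug mean equal to control -> all draws 0
  post0 <- fake_drug_post(c(beta_hb_intercept = 10, beta_hb_treat = 0))
  expect_equal(unique(normalized_drug_response(post0, "ACZ", "hb")$draws), 0)
  # complete elimination -> -1
  post1 <- fake_drug_post(c(beta_hb_intercept = 10, beta_hb_treat = -10))
  expect_equal(unique(normalized_drug_response(post1, "ACZ", "hb")$draws), -1)
})

test_that("a control mean straddling zero aborts the normalized response", {
  draws <- matrix(c(rnorm(150, 3, 0.1), rnorm(50, -3, 0.1),
                    rep(-1, 200)), ncol = 2,
                  dimnames = list(NULL, c("beta_hb_intercept", "beta_hb_treat")))
  post <- fake_drug_post(c(beta_hb_intercept = 0, beta_hb_treat = 0))
  post$draws <- draws
  expect_error(normalized_drug_response(post, "ACZ", "hb"), "ill-defined")
})

test_that("drug-response contrasts are per-draw differences", {
  post <- fake_drug_post(c(beta_hb_intercept = 10, beta_hb_treat = -6,
                           beta_hb_DNP5 = 0, beta_hb_treat_DNP5 = -3))
  ct <- drug_response_contrast(post, list(drug_group = "DNP5", trait = "hb"),
                               list(drug_group = "ACZ", trait = "hb"))
  expect_equal(ct$estimate, -0.3, tolerance = 1e-12) # -0.9 - (-0.6)
})

test_that("F-actin model recovers a programmed group deficit", {
  pr <- simulate_factin_profiles(n_per_group = 6, seed = 5)
  pk <- factin_peak_table(pr)
  f <- fit_factin_model(pk, settings = quick_settings(2, 1200), seed = 6)
  ct <- factin_contrast(f, "DNP", "C57", side = "apical")
  expect_lt(ct$estimate, 0)
  expect_true(ct$excludes_zero)
  expect_equal(ct$estimate, -16, tolerance = 6)
})

test_that("a group missing one side loses its interaction with a warning", {
  pk <- factin_peak_table(simulate_factin_profiles(n_per_group = 3, seed = 2))
  pk <- pk[!(pk$group == "DNP" & pk$side == "basal"), ]
  expect_warning(f <- fit_factin_model(pk, settings = quick_settings(1, 400),
                                       seed = 1),
                 "missing one side")
  expect_false("group_DNP:side_basal" %in% f$data_info$design_cols)
})

test_that("equal treated and control ERG generative processes center the drug effect on 0", {
  spec <- erg_sim_spec(noise_sd = 5, c_treated_factor = 1, seed = 21)
  tab <- intensity_response_table(simulate_erg_cohort(spec, n_per_arm = 4))
  f <- fit_erg_model(tab, "c", settings = quick_settings(2, 1200), seed = 3)
  expect_false(f$drug_interval$excludes_zero)
  # the drug main effect rides a flat ridge with the between-arm random
  # intercepts at this size; the interval, not the point draw, is the claim
  expect_lt(abs(mean(post_draws(f$posterior, "drug"))), 25)
})
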