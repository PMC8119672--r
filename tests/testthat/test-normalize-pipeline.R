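test_that("group-SD normalization matches hand arithmetic and is scale-free", {
  tbl <- tibble::tibble(group = "g1", y_hb = c(4, 6), y_elm_rpe = c(8, 12))
  out <- normalize_by_group_sd(tbl)
  expect_equal(out$normalized[out$trait == "y_hb"], 5 / sqrt(2),
               tolerance = 1e-12)
  scaled <- dplyr::mutate(tbl, y_hb = 3 * y_hb, y_elm_rpe = 3 * y_elm_rpe)
  expect_equal(normalize_by_group_sd(scaled)$normalized, out$normalized)
  zero <- tibble::tibble(group = "g", y_hb = c(2, 2), y_elm_rpe = c(1, 2))
  expect_error(normalize_by_group_sd(zero), "zero within-group SD")
  expect_error(normalize_by_group_sd(tbl[1, ]), "at least 2 mice")
})

test_that("light-dark differencing pairs subjects and drops orphans", {
  per_eye <- tibble::tibble(
    subject_id = c("m1", "m1", "m2", "m2", "m3"),
    group = "g1",
    state = c("light", "dark", "light", "dark", "light"),
    hb_magnitude = c(9, 2, 8, 3, 7),
    elm_rpe_um = c(60, 50, 58, 51, 57))
  expect_message(d <- light_dark_difference_table(per_eye), "m3")
  expect_equal(nrow(d), 2)
  expect_equal(d$y_elm_rpe[d$mouse_id == "m1"], 10)
  expect_equal(d$y_hb[d$mouse_id == "m1"], 7)
})

test_that("B-scan TIFF round trip preserves metadata and quantized pixels", {
  p <- phantom_params(noise_sd = 2, seed = 6)
  b <- generate_bscan(p, "light", subject_id = "mx", group = "gx")
  prefix <- file.path(withr::local_tempdir(), "scan1")
  write_bscan(b, prefix)
  b2 <- read_bscan(prefix)
  expect_equal(b2$pixels, round(b$pixels)) # 8-bit quantization only
  expect_equal(b2$axial_um_per_px, b$axial_um_per_px)
  expect_equal(b2$state, "light")
  expect_equal(b2$subject_id, "mx")
  expect_equal(b2$truth$hb_magnitude, b$truth$hb_magnitude, tolerance = 1e-9)
})

test_that("CSV round trip is lossless for measurement tables", {
  tbl <- simulate_cohort(cohort_sim_spec(seed = 3))
  attr(tbl, "truth") <- NULL # in-memory provenance, not a CSV field
  path <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(tbl, path)
  back <- read_table_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl), tolerance = 1e-12)
})

test_that("pipeline config validates its schema before any compute", {
  expect_error(pipeline_config(), "out_dir is required")
  expect_error(pipeline_config(out_dir = tempdir(),
                               groups = tibble::tibble(name = "g")),
               "must have columns")
})

test_that("the demo pipeline completes and writes its tables and manifest", {
  dir <- withr::local_tempdir()
  cfg <- pipeline_config(
    out_dir = dir, seed = 3,
    groups = tibble::tibble(name = c("g1", "g2"), n_mice = 3,
                            hb_drop_mean = c(7, 10), hb_drop_sd = 0.8,
                            elm_rpe_mean = 58, elm_rpe_sd = 0.5),
    sampler = quick_settings(2, 600),
    write_figures = FALSE)
  res <- run_pipeline(cfg)
  expect_true(all(file.exists(file.path(dir,
    c("per_eye.csv", "cohort_differences.csv", "normalized_responses.csv",
      "posterior_summary.csv", "report.md", "manifest.json")))))
  expect_equal(nrow(res$per_eye), 12) # 6 mice x 2 states
  expect_equal(nrow(res$cohort), 6)
})
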