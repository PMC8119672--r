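gauss_profile <- function(height = 40, center = 15, depth = seq(0, 60, 0.5)) {
  tibble::tibble(mouse_id = "m", group = "g", depth_um = depth,
                 intensity = height * exp(-(depth - center)^2 / (2 * 9)))
}

test_that("peak at the HB region follows closed forms", {
  flat <- gauss_profile(0)
  expect_equal(factin_peak_at_hb(flat, c(5, 25)), 0)
  bump <- gauss_profile(40, center = 15)
  expect_equal(factin_peak_at_hb(bump, c(5, 25)), 40)
  # bump outside the window contributes only its far tail
  expect_lt(factin_peak_at_hb(bump, c(40, 55)), 1e-6)
  expect_error(factin_peak_at_hb(bump, c(50, 70)), "outside profile support")
})

test_that("background-subtracted peak scales linearly with intensity", {
  bump <- gauss_profile(40)
  bump$intensity <- bump$intensity + 7 # session offset
  p1 <- factin_peak_at_hb(bump, c(5, 25), subtract_background = TRUE)
  bump3 <- bump; bump3$intensity <- 3 * bump$intensity
  p3 <- factin_peak_at_hb(bump3, c(5, 25), subtract_background = TRUE)
  expect_equal(p3, 3 * p1, tolerance = 1e-8)
})

test_that("the peak table recovers simulated apical/basal structure", {
  pr <- simulate_factin_profiles(n_per_group = 4, noise_sd = 0, mouse_sd = 0,
                                 seed = 3)
  pk <- factin_peak_table(pr)
  expect_equal(nrow(pk), 4 * 4 * 2)
  apical <- pk[pk$side == "apical", ]
  means <- tapply(apical$peak, apical$group, mean)
  expect_equal(unname(means["C57"] - means["DNP"]), 16, tolerance = 0.5)
  # deterministic under the seed
  expect_identical(pr, simulate_factin_profiles(n_per_group = 4, noise_sd = 0,
                                                mouse_sd = 0, seed = 3))
})
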