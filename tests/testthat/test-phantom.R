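test_that("layer specification invariants are enforced", {
  expect_silent(retina_layers())
  bad <- retina_layers()
  bad$center_um[3] <- bad$center_um[2] # not strictly increasing
  expect_error(phantom_params(layers = bad), "strictly increasing")
  bad2 <- retina_layers(); bad2$peak[1] <- 300
  expect_error(phantom_params(layers = bad2), "\\[0, 255\\]")
  expect_error(phantom_params(hb_depth_drop = -1), "hb_depth_drop")
  expect_error(phantom_params(noise_sd = -0.1), "noise_sd")
})

test_that("a trough wider than the PRT-RPE gap is rejected", {
  expect_error(phantom_params(hb_width_um = 20), "narrower than the PRT-RPE")
})

test_that("B-scan generation is bit-reproducible under a fixed seed", {
  p <- phantom_params(noise_sd = 3, seed = 17)
  b1 <- generate_bscan(p, "light")
  b2 <- generate_bscan(p, "light")
  expect_identical(b1$pixels, b2$pixels)
  set1 <- generate_radial_set(p, "dark")
  set2 <- generate_radial_set(p, "dark")
  expect_identical(lapply(set1, `[[`, "pixels"), lapply(set2, `[[`, "pixels"))
})

test_that("a zero-depth trough yields zero downstream HB magnitude", {
  p <- phantom_params(hb_depth_drop = 0, noise_sd = 0)
  b <- generate_bscan(p, "light")
  expect_equal(b$truth$hb_magnitude, 0, tolerance = 1e-6)
  m <- quantify_eye(b)
  expect_lt(m$hb_magnitude, 0.05)
})

test_that("noiseless trough depth is recovered from the chord geometry", {
  p <- phantom_params(hb_depth_drop = 10, noise_sd = 0)
  b <- generate_bscan(p, "light")
  # truth computed on a dense grid; nominal depth minus the small chord-tail
  # correction
  expect_equal(b$truth$hb_magnitude, 10, tolerance = 0.25)
  m <- quantify_eye(b)
  expect_equal(m$hb_magnitude, b$truth$hb_magnitude, tolerance = 0.25)
})

test_that("dark state scales the trough and outer-retina span", {
  p <- phantom_params(hb_depth_drop = 10, noise_sd = 0)
  tl <- generate_bscan(p, "light")$truth
  td <- generate_bscan(p, "dark")$truth
  expect_equal(td$nominal_drop, 2, tolerance = 1e-9) # x 0.2
  expect_equal(td$elm_rpe_um / tl$elm_rpe_um, 0.9, tolerance = 0.02)
})

test_that("radial scans share truth, differ only in noise and axial shift", {
  p <- phantom_params(noise_sd = 0, seed = 3)
  scans <- generate_radial_set(p, "light", shifts = c(0, 0, 0, 0))
  expect_identical(scans[[1]]$pixels, scans[[4]]$pixels)
  shifted <- generate_radial_set(p, "light", shifts = c(0, 1, 2, 3))
  avg <- align_at_elm(lapply(shifted, function(b)
    align_at_elm(bin_profiles(extract_roi_profiles(b), 10))))
  ref <- align_at_elm(bin_profiles(extract_roi_profiles(scans[[1]]), 10))
  # aligned-and-averaged shifted set reproduces the unshifted profile around
  # the ELM anchor
  win <- -20:40
  expect_equal(avg$intensity[avg$elm_index + win],
               ref$intensity[ref$elm_index + win], tolerance = 1e-8)
})
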