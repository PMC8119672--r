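test_that("ROI selection converts the lateral band to the correct columns", {
  # ONH at column 500 of 1000, 1.4 um/px: 350/1.4 = 250 px, 630/1.4 = 450 px
  p <- phantom_params(noise_sd = 0)
  b <- generate_bscan(p, "light")
  ps <- extract_roi_profiles(b)
  dist <- abs(seq_len(1000) - 500)
  expect_equal(ncol(ps$intensity), sum(dist >= 250 & dist <= 450))
  # ONH near the edge: only one band, with a warning
  b$onh_center_px <- 10
  expect_warning(one <- extract_roi_profiles(b), "one side")
  expect_true(ncol(one$intensity) < ncol(ps$intensity))
  # ROI entirely outside a narrow image
  b2 <- b
  b2$pixels <- b$pixels[, 1:100]
  b2$onh_center_px <- 50
  expect_error(extract_roi_profiles(b2), "ROI outside image")
})

test_that("lateral binning averages complete bins and drops the remainder", {
  ax <- 1.6
  mk <- function(cols) octhb:::new_profile_set(cols, ax)
  ident <- matrix(rep(1:50, 10), ncol = 10)
  out <- bin_profiles(mk(ident), 10)
  expect_equal(ncol(out$intensity), 1)
  expect_equal(out$intensity[, 1], as.numeric(1:50))
  consts <- matrix(rep(1:10, each = 4), nrow = 4, byrow = FALSE)
  expect_equal(bin_profiles(mk(consts), 10)$intensity[, 1], rep(5.5, 4))
  m23 <- matrix(rnorm(23 * 8), nrow = 8)
  expect_equal(ncol(bin_profiles(mk(m23), 10)$intensity), 2)
  expect_warning(bin_profiles(mk(m23[, 1:3, drop = FALSE]), 10), "fewer columns")
})

test_that("ELM alignment is an identity for one profile and undoes shifts", {
  p <- phantom_params(noise_sd = 0)
  base <- align_at_elm(bin_profiles(extract_roi_profiles(
    generate_bscan(p, "light")), 10))
  single <- align_at_elm(list(base))
  expect_equal(single$intensity, base$intensity)
  # two copies, one shifted by +2 samples
  shifted <- octhb:::new_trp(c(base$intensity[1], base$intensity[1],
                               head(base$intensity, -2)),
                             base$axial_um_per_px)
  avg <- align_at_elm(list(base, shifted))
  win <- -30:40
  expect_equal(avg$intensity[avg$elm_index + win],
               base$intensity[base$elm_index + win], tolerance = 1e-10)
})

test_that("landmark detection matches generator geometry and fails loudly", {
  p <- phantom_params(noise_sd = 0)
  prof <- align_at_elm(bin_profiles(extract_roi_profiles(
    generate_bscan(p, "light")), 10))
  lm <- find_layer_landmarks(prof)
  ax <- prof$axial_um_per_px
  expect_lt(abs((lm$isep_peak - lm$elm_peak) * ax - 14), 1.7)
  expect_lt(abs((lm$prt_peak - lm$elm_peak) * ax - 36), 1.7)
  expect_true(lm$elm_peak < lm$isep_peak && lm$isep_peak < lm$prt_peak &&
                lm$prt_peak < lm$rpe_peak && lm$rpe_peak < lm$rpe_basal)
  mono <- octhb:::new_trp(seq(0, 200, length.out = 150), 1.6)
  expect_error(find_layer_landmarks(mono), "landmark")
})

test_that("equal-height peak candidates resolve to the most vitreal index", {
  x <- c(0, 0, 5, 0, 5, 0, 0)
  expect_identical(octhb:::tallest_peak(x, 1, 7), 3L)
})

test_that("baseline chord is exact linear interpolation between the peaks", {
  prof <- octhb:::new_trp(c(200, rep(0, 9), 100, 0), 1.6)
  lm <- structure(list(prt_peak = 1L, rpe_peak = 11L), class = "layer_landmarks")
  bl <- construct_baseline(prof, lm)
  expect_equal(bl$baseline[6], 150) # midpoint of the line
  expect_equal(bl$baseline, seq(200, 100, by = -10))
  lm_bad <- structure(list(prt_peak = 11L, rpe_peak = 1L), class = "layer_landmarks")
  expect_error(construct_baseline(prof, lm_bad), "vitreal")
})

test_that("HB magnitude is the peak deviation, floored at zero", {
  flat <- profile_with_dip(rep(0, 1))
  expect_equal(hb_magnitude(flat$profile, flat$baseline)$magnitude, 0)
  # V-shaped dip of depth 7
  v <- profile_with_dip(c(3.5, 7, 3.5))
  expect_equal(hb_magnitude(v$profile, v$baseline)$magnitude, 7)
  above <- profile_with_dip(-c(1, 2, 1)) # profile above baseline
  expect_equal(hb_magnitude(above$profile, above$baseline)$magnitude, 0)
})

test_that("HB width follows similar-triangles and refuses a zero magnitude", {
  # symmetric triangular dip: depth 8, rising over 5 px each side ->
  # half-max crossings 2.5 px either side of the apex: 5 px = 8 um at 1.6
  tri <- profile_with_dip(c(1.6, 3.2, 4.8, 6.4, 8, 6.4, 4.8, 3.2, 1.6))
  w <- hb_width(tri$profile, tri$baseline)
  expect_equal(as.numeric(w), 5 * 1.6)
  expect_false(attr(w, "truncated"))
  flat <- profile_with_dip(rep(0, 3))
  expect_error(hb_width(flat$profile, flat$baseline), "magnitude is 0")
  # deviation still above half-maximum at the interval edge: truncated, flagged
  prof <- octhb:::new_trp(c(200, 192, 193, 194, 195), 1.6)
  bl <- tibble::tibble(index = 1:5, baseline = 200)
  expect_warning(wt <- hb_width(prof, bl), "truncated")
  expect_true(attr(wt, "truncated"))
})

test_that("ELM-RPE thickness is the calibrated peak-to-basal distance", {
  lm <- structure(list(elm_peak = 100L, rpe_basal = 135), class = "layer_landmarks")
  expect_equal(elm_rpe_thickness(lm, 1.6), 56)
})

test_that("intensity offsets and axial shifts do not change HB readouts", {
  p <- phantom_params(hb_depth_drop = 9, noise_sd = 0)
  b <- generate_bscan(p, "light")
  m0 <- quantify_eye(b)
  b_off <- b; b_off$pixels <- pmin(b$pixels + 20, 255)
  m_off <- quantify_eye(b_off)
  expect_equal(m_off$hb_magnitude, m0$hb_magnitude, tolerance = 1e-6)
  expect_equal(m_off$hb_width_um, m0$hb_width_um, tolerance = 1e-6)
  b_sh <- b; b_sh$pixels <- octhb:::shift_rows(b$pixels, 4L)
  m_sh <- quantify_eye(b_sh)
  expect_equal(m_sh$hb_magnitude, m0$hb_magnitude, tolerance = 1e-6)
  expect_equal(m_sh$elm_rpe_um, m0$elm_rpe_um, tolerance = 1e-6)
})

test_that("measured magnitude is monotone in the programmed trough depth", {
  drops <- seq(2, 12, by = 2)
  mags <- vapply(drops, function(d) {
    quantify_eye(generate_bscan(
      phantom_params(hb_depth_drop = d, noise_sd = 0), "light"))$hb_magnitude
  }, numeric(1))
  expect_true(all(diff(mags) > 0))
})

test_that("RPE flattening undoes a linear tilt and is identity when flat", {
  p <- phantom_params(noise_sd = 0)
  b <- generate_bscan(p, "light")
  expect_equal(flatten_to_rpe(b)$pixels, b$pixels)
  tilted <- b
  shifts <- round(seq(0, 12, length.out = ncol(b$pixels)))
  for (j in seq_len(ncol(b$pixels)))
    tilted$pixels[, j] <- octhb:::shift_rows(b$pixels[, j, drop = FALSE], shifts[j])
  flat <- flatten_to_rpe(tilted)
  rpe_rows <- apply(flat$pixels, 2, which.max)
  expect_equal(var(rpe_rows), 0)
  # flattened tilted phantom reproduces the straight phantom's HB magnitude
  m_ref <- quantify_eye(b)
  m_flat <- quantify_eye(flat)
  expect_equal(m_flat$hb_magnitude, m_ref$hb_magnitude, tolerance = 0.05)
  # human mode: no ONH reference, flatten then measure over the full width
  human <- flatten_to_rpe(tilted)
  human$onh_center_px <- NA
  expect_message(m_h <- quantify_eye(human), "full lateral extent")
  expect_equal(m_h$hb_magnitude, m_ref$hb_magnitude, tolerance = 0.05)
})

test_that("repeated quantification of the same input is identical", {
  p <- phantom_params(noise_sd = 2, seed = 5)
  scans <- generate_radial_set(p, "light")
  expect_identical(quantify_eye(scans), quantify_eye(scans))
})
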