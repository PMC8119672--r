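make_trace <- function(voltage, t = seq(0, 9, by = 0.01), onset = 1) {
  tibble::tibble(time_s = t, voltage_uv = voltage, stim_onset_s = onset)
}

test_that("a flat trace yields zero amplitudes", {
  amp <- measure_erg_amplitudes(make_trace(rep(0, 901)))
  expect_equal(c(amp$a_wave, amp$b_wave, amp$c_wave), c(0, 0, 0))
})

test_that("noiseless synthetic traces return the programmed amplitudes exactly", {
  spec <- erg_sim_spec(noise_sd = 0)
  traces <- simulate_erg(spec, treated = FALSE, mouse_id = "m1")
  for (I in spec$intensities) {
    x <- log10(I)
    amp <- measure_erg_amplitudes(traces[traces$intensity_cd_m2 == I, ])
    expect_equal(amp$a_wave, max(octhb:::polyval(spec$a_coef, x), 0))
    expect_equal(amp$b_wave, max(octhb:::polyval(spec$b_coef, x), 0))
    expect_equal(amp$c_wave, max(octhb:::polyval(spec$c_coef, x), 0))
  }
  # treated scales only the c-wave by the configured factor
  tr <- simulate_erg(spec, treated = TRUE, mouse_id = "m1")
  a1 <- measure_erg_amplitudes(tr[tr$intensity_cd_m2 == 100, ])
  a0 <- measure_erg_amplitudes(traces[traces$intensity_cd_m2 == 100, ])
  expect_equal(a1$c_wave / a0$c_wave, 1.10, tolerance = 1e-9)
  expect_equal(a1$a_wave, a0$a_wave)
})

test_that("a pure positive dome gives a = 0 and c = its height", {
  t <- seq(0, 9, by = 0.01)
  v <- 120 * octhb:::rc_bump(t - 1, 2, 6) # peaks at 4 s post-onset
  amp <- measure_erg_amplitudes(make_trace(v, t))
  expect_equal(amp$a_wave, 0)
  expect_equal(amp$c_wave, 120)
  expect_equal(amp$c_peak_time_s, 4)
})

test_that("amplitudes are invariant to a constant voltage offset", {
  spec <- erg_sim_spec(noise_sd = 0)
  tr <- simulate_erg(spec, FALSE, "m1")
  one <- tr[tr$intensity_cd_m2 == 10, ]
  off <- one; off$voltage_uv <- off$voltage_uv + 250
  expect_equal(measure_erg_amplitudes(off)[, 1:3],
               measure_erg_amplitudes(one)[, 1:3])
})

test_that("amplitudes survive sampling-rate doubling of a noiseless trace", {
  s1 <- erg_sim_spec(noise_sd = 0, sampling_rate_hz = 100)
  s2 <- erg_sim_spec(noise_sd = 0, sampling_rate_hz = 200)
  a1 <- measure_erg_amplitudes(simulate_erg(s1, FALSE, "m")[1:901, ])
  a2 <- measure_erg_amplitudes(simulate_erg(s2, FALSE, "m")[1:1801, ])
  expect_equal(a1$a_wave, a2$a_wave, tolerance = 0.05)
  expect_equal(a1$c_wave, a2$c_wave, tolerance = 0.05)
})

test_that("a missing pre-stimulus window is an error", {
  t <- seq(1, 9, by = 0.01) # starts at onset
  expect_error(measure_erg_amplitudes(make_trace(rep(0, length(t)), t)),
               "pre-stimulus")
  expect_error(measure_erg_amplitudes(
    make_trace(rep(0, 201), seq(0, 2, 0.01)),
    erg_windows(c_window_s = c(2, 6))), "outside the trace")
})

test_that("the intensity-response table has one row per mouse x intensity", {
  spec <- erg_sim_spec(noise_sd = 5, seed = 8)
  traces <- simulate_erg_cohort(spec, n_per_arm = 3)
  tab <- intensity_response_table(traces)
  expect_equal(nrow(tab), 2 * 3 * length(spec$intensities))
  expect_setequal(unique(tab$log10_intensity), seq(-2, 3))
  # duplicated traces are averaged with a warning
  dup <- dplyr::bind_rows(traces[traces$mouse_id == "ctl01" &
                                   traces$intensity_cd_m2 == 1, ],
                          traces)
  expect_warning(tab2 <- intensity_response_table(dup), "duplicate")
  expect_equal(nrow(tab2), nrow(tab))
})
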