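#' ERG simulation specification
#'
#' Parameters of the synthetic step-response electroretinogram. Each trace is
#' a baseline plus three components with disjoint temporal support: a fast
#' corneal-negative a-wave trough, a positive b-wave peak, and a slow c-wave
#' dome peaking a few seconds after light onset. Component amplitudes vary
#' with stimulus intensity through polynomial functions of log10 intensity
#' (`*_coef`, intercept first). Because the components do not overlap in
#' time, the programmed amplitudes are recovered exactly from noiseless
#' traces by [measure_erg_amplitudes()].
#'
#' @param intensities Stimulus intensities in cd/m^2 (positive; default six
#'   steps spanning 0.01 to 1000, the standard step-stimulus range).
#' @param stim_onset_s Light onset time within the trace, s.
#' @param stim_duration_s Step duration, s (10 by default).
#' @param pre_s,post_s Recorded time before onset and after onset, s.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param a_coef,b_coef,c_coef Polynomial coefficients (intercept first) of
#'   the a-, b- and c-wave amplitudes in uV as functions of log10 intensity.
#' @param c_treated_factor Multiplier applied to the c-wave amplitude of
#'   treated animals (default 1.10, a ~10 percent increase).
#' @param noise_sd Additive Gaussian noise SD, uV.
#' @param seed Integer seed.
#' @return A list of class `erg_sim_spec`.
#' @export
erg_sim_spec <- function(intensities = 10^seq(-2, 3),
                         stim_onset_s = 1, stim_duration_s = 10,
                         pre_s = 1, post_s = 8, sampling_rate_hz = 100,
                         a_coef = c(150, 40, -5),
                         b_coef = c(220, 50, -6),
                         c_coef = c(90, 25, -4),
                         c_treated_factor = 1.10,
                         noise_sd = 10, seed = 1) {
  if (any(intensities <= 0)) abort("stimulus intensities must be positive")
  if (stim_duration_s <= 0) abort("stim_duration_s must be positive")
  if (pre_s < 0.2) abort("at least 0.2 s of pre-stimulus recording is required")
  structure(list(intensities = intensities, stim_onset_s = stim_onset_s,
                 stim_duration_s = stim_duration_s, pre_s = pre_s,
                 post_s = post_s, sampling_rate_hz = sampling_rate_hz,
                 a_coef = a_coef, b_coef = b_coef, c_coef = c_coef,
                 c_treated_factor = c_treated_factor, noise_sd = noise_sd,
                 seed = seed),
            class = "erg_sim_spec")
}

polyval <- function(coef, x) {
  out <- 0
  for (k in seq_along(coef)) out <- out + coef[k] * x^(k - 1)
  out
}

# raised-cosine bump of unit peak on [t0, t1], zero outside
rc_bump <- function(t, t0, t1) {
  out <- numeric(length(t))
  inside <- t >= t0 & t <= t1
  out[inside] <- 0.5 * (1 - cos(2 * pi * (t[inside] - t0) / (t1 - t0)))
  out
}

#' Simulate step-response ERG traces for one mouse
#'
#' One trace per stimulus intensity. Amplitudes follow the spec's polynomial
#' intensity-response functions; the treated flag scales the c-wave by
#' `c_treated_factor`. Component supports (seconds post-onset): a-wave
#' trough 0.02-0.14 (trough at 0.08 s), b-wave 0.2-0.9 (peak at 0.55 s),
#' c-wave 2-6 (peak at 4 s) — disjoint, so trough-to-peak conventions
#' recover the programmed values exactly in the absence of noise.
#'
#' @param spec An [erg_sim_spec()].
#' @param treated Logical treatment flag.
#' @param mouse_id Label carried on the rows.
#' @return Long tibble: `mouse_id`, `treated`, `intensity_cd_m2`,
#'   `stim_onset_s`, `stim_duration_s`, `time_s`, `voltage_uv`.
#' @export
simulate_erg <- function(spec, treated = FALSE, mouse_id = "m1") {
  stopifnot(inherits(spec, "erg_sim_spec"))
  dt <- 1 / spec$sampling_rate_hz
  t_abs <- seq(0, spec$pre_s + spec$post_s, by = dt)
  on <- spec$stim_onset_s
  set.seed(derive_seed(spec$seed, "erg", mouse_id, treated))
  purrr::map_dfr(spec$intensities, function(I) {
    x <- log10(I)
    a <- max(polyval(spec$a_coef, x), 0)
    b <- max(polyval(spec$b_coef, x), 0)
    cc <- max(polyval(spec$c_coef, x), 0) * if (treated) spec$c_treated_factor else 1
    tp <- t_abs - on
    v <- -a * rc_bump(tp, 0.02, 0.14) +
      (b - a) * rc_bump(tp, 0.2, 0.9) +
      cc * rc_bump(tp, 2, 6)
    if (spec$noise_sd > 0) v <- v + rnorm(length(v), sd = spec$noise_sd)
    tibble::tibble(mouse_id = mouse_id, treated = treated,
                   intensity_cd_m2 = I, stim_onset_s = on,
                   stim_duration_s = spec$stim_duration_s,
                   time_s = t_abs, voltage_uv = v)
  })
}

#' Simulate a two-arm ERG cohort
#'
#' @param spec An [erg_sim_spec()].
#' @param n_per_arm Mice per arm (control and treated).
#' @return Long tibble of traces for all mice in both arms.
#' @export
simulate_erg_cohort <- function(spec, n_per_arm = 5) {
  purrr::map_dfr(c(FALSE, TRUE), function(tr) {
    purrr::map_dfr(seq_len(n_per_arm), function(i) {
      simulate_erg(spec, treated = tr,
                   mouse_id = sprintf("%s%02d", if (tr) "dnp" else "ctl", i))
    })
  })
}

#' ERG measurement windows
#'
#' Analysis windows in seconds relative to light onset. The a-window default
#' (0-0.3 s) brackets the fast phototransduction trough; the c-window
#' default (2-6 s) brackets the slow RPE/Mueller dome that typically peaks
#' around 3-5 s after onset.
#'
#' @param pre_s Pre-stimulus baseline window length, s.
#' @param a_window_s a-wave search window, s post-onset.
#' @param b_end_s End of the b-wave search window (starts at the a-trough).
#' @param c_window_s c-wave search window, s post-onset.
#' @return List of class `erg_windows`.
#' @export
erg_windows <- function(pre_s = 0.2, a_window_s = c(0, 0.3),
                        b_end_s = 1, c_window_s = c(2, 6)) {
  structure(list(pre_s = pre_s, a_window_s = a_window_s,
                 b_end_s = b_end_s, c_window_s = c_window_s),
            class = "erg_windows")
}

#' Measure a-, b- and c-wave amplitudes of one ERG trace
#'
#' Baseline is the mean voltage over the pre-stimulus window. The a-wave is
#' baseline to the negative trough in the a-window; the b-wave is trough to
#' positive peak (a-trough to the maximum before `b_end_s`); the c-wave is
#' baseline to the maximum in the c-window. Negative results are floored at
#' zero and flagged.
#'
#' @param trace Tibble for a single trace: `time_s`, `voltage_uv`,
#'   `stim_onset_s` (constant column).
#' @param windows An [erg_windows()].
#' @return One-row tibble: `a_wave`, `b_wave`, `c_wave` (uV),
#'   `a_trough_time_s`, `b_peak_time_s`, `c_peak_time_s`, `floored`.
#' @export
measure_erg_amplitudes <- function(trace, windows = erg_windows()) {
  stopifnot(all(c("time_s", "voltage_uv", "stim_onset_s") %in% names(trace)))
  on <- trace$stim_onset_s[1]
  t <- trace$time_s; v <- trace$voltage_uv
  pre <- t < on & t >= on - windows$pre_s
  if (!any(t < on) || sum(pre) < 2)
    abort("trace lacks a pre-stimulus baseline window")
  win <- function(w) {
    sel <- t >= on + w[1] & t <= on + w[2]
    if (!any(sel)) abort(sprintf("window [%g, %g] s post-onset lies outside the trace", w[1], w[2]))
    sel
  }
  baseline <- mean(v[pre])
  a_sel <- win(windows$a_window_s)
  ia <- which(a_sel)[which.min(v[a_sel])]
  a <- baseline - v[ia]
  b_sel <- t >= t[ia] & t <= on + windows$b_end_s
  ib <- which(b_sel)[which.max(v[b_sel])]
  b <- v[ib] - v[ia]
  c_sel <- win(windows$c_window_s)
  ic <- which(c_sel)[which.max(v[c_sel])]
  cw <- v[ic] - baseline
  floored <- any(c(a, b, cw) < 0)
  tibble::tibble(a_wave = max(a, 0), b_wave = max(b, 0), c_wave = max(cw, 0),
                 a_trough_time_s = t[ia] - on, b_peak_time_s = t[ib] - on,
                 c_peak_time_s = t[ic] - on, floored = floored)
}

#' Build the intensity-response table from a set of traces
#'
#' Measures every (mouse, treated, intensity) trace and returns the long
#' table feeding [fit_erg_model()], with intensities on the log10 scale.
#' Duplicate trace keys are averaged with a warning.
#'
#' @param traces Long tibble of traces (as from [simulate_erg_cohort()]).
#' @param windows An [erg_windows()].
#' @return Tibble: `mouse_id`, `treated`, `intensity_cd_m2`,
#'   `log10_intensity`, `a_wave`, `b_wave`, `c_wave`.
#' @export
intensity_response_table <- function(traces, windows = erg_windows()) {
  keys <- dplyr::distinct(traces, .data$mouse_id, .data$treated, .data$intensity_cd_m2)
  out <- purrr::map_dfr(seq_len(nrow(keys)), function(i) {
    tr <- dplyr::semi_join(traces, keys[i, ], by = c("mouse_id", "treated", "intensity_cd_m2"))
    n_tr <- length(unique(tr$time_s))
    if (nrow(tr) > n_tr) {
      warn(sprintf("duplicate traces for (%s, %s, %g); averaging",
                   keys$mouse_id[i], keys$treated[i], keys$intensity_cd_m2[i]))
      tr <- dplyr::summarise(dplyr::group_by(tr, .data$time_s),
                             voltage_uv = mean(.data$voltage_uv),
                             stim_onset_s = .data$stim_onset_s[1], .groups = "drop")
    }
    amp <- measure_erg_amplitudes(tr, windows)
    dplyr::bind_cols(keys[i, ], amp[, c("a_wave", "b_wave", "c_wave")])
  })
  dplyr::mutate(out, log10_intensity = log10(.data$intensity_cd_m2),
                .after = "intensity_cd_m2")
}
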