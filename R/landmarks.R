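#' Locate outer-retina layer landmarks on an averaged profile
#'
#' Finds the axial indices of the ELM, IS/ep, PRT and RPE intensity maxima
#' and the basal RPE boundary on a transretinal profile. The ELM is the
#' profile's `elm_index` anchor when present (set by [align_at_elm()]),
#' otherwise the tallest local maximum in the configured search window. Each
#' subsequent layer peak is the tallest local maximum inside its window
#' sclerad of the ELM; equal-height candidates resolve to the most vitreal
#' index. The basal RPE boundary is the first index sclerad of the RPE peak
#' where intensity falls below half of the RPE peak height above the distal
#' background floor (median of the `floor_n` most scleral samples).
#'
#' @param profile A `trp` profile.
#' @param config A [quantify_config()].
#' @return A `layer_landmarks` list: `elm_peak`, `isep_peak`, `prt_peak`,
#'   `rpe_peak`, `rpe_basal` (axial indices) and `intensities` at the peaks.
#' @export
find_layer_landmarks <- function(profile, config = quantify_config()) {
  stopifnot(inherits(profile, "trp"))
  x <- profile$intensity
  ax <- profile$axial_um_per_px
  elm <- profile$elm_index
  if (is.na(elm)) elm <- detect_elm(x, ax, config)
  if (is.na(elm)) abort("landmark detection failed: no ELM peak found")
  px_window <- function(w) elm + round(w / ax)
  pick <- function(w, layer) {
    win <- px_window(w)
    i <- tallest_peak(x, win[1], win[2])
    if (is.na(i))
      abort(sprintf("landmark detection failed: no local maximum for %s in [%d, %d] px",
                    layer, win[1], win[2]))
    i
  }
  isep <- pick(config$isep_window_um, "IS/ep")
  prt <- pick(config$prt_window_um, "PRT")
  rpe <- pick(config$rpe_window_um, "RPE")
  if (!(elm < isep && isep < prt && prt < rpe))
    abort("landmark ordering violated: expected ELM < IS/ep < PRT < RPE")
  floor_v <- median(tail(x, config$floor_n))
  thr <- floor_v + (x[rpe] - floor_v) / 2
  past <- which(x < thr & seq_along(x) > rpe)
  if (!length(past))
    abort("landmark detection failed: no basal RPE half-height crossing before the profile end")
  # sub-pixel crossing between the straddling samples
  j <- past[1]
  basal <- j - 1 + (x[j - 1] - thr) / (x[j - 1] - x[j])
  structure(list(elm_peak = elm, isep_peak = isep, prt_peak = prt,
                 rpe_peak = rpe, rpe_basal = basal,
                 intensities = c(ELM = x[elm], IS_ep = x[isep],
                                 PRT = x[prt], RPE = x[rpe])),
            class = "layer_landmarks")
}

#' Construct the PRT-RPE baseline chord
#'
#' The HB baseline is the straight line connecting the maximum intensity of
#' the PRT layer with that of the RPE layer, evaluated at every axial index
#' between the two peaks (both endpoints included).
#'
#' @param profile A `trp` profile.
#' @param landmarks A `layer_landmarks` object for the same profile.
#' @return Tibble with `index` and `baseline` (grayscale units).
#' @export
construct_baseline <- function(profile, landmarks) {
  p <- landmarks$prt_peak; r <- landmarks$rpe_peak
  if (p >= r) abort("PRT peak must be vitreal of the RPE peak")
  idx <- p:r
  x <- profile$intensity
  tibble::tibble(index = idx,
                 baseline = x[p] + (x[r] - x[p]) * (idx - p) / (r - p))
}

#' HB magnitude: peak deviation below the baseline
#'
#' The hyporeflective band magnitude is the maximum of (baseline - intensity)
#' over the interior of the baseline interval, floored at zero. A profile at
#' or above its baseline everywhere has magnitude 0.
#'
#' @param profile A `trp` profile.
#' @param baseline Tibble from [construct_baseline()].
#' @return List with `magnitude` (grayscale units) and `peak_index` (axial
#'   index of the peak deviation; `NA` when the magnitude is 0).
#' @export
hb_magnitude <- function(profile, baseline) {
  if (nrow(baseline) < 3) abort("baseline interval must span at least 3 indices")
  interior <- 2:(nrow(baseline) - 1)
  d <- baseline$baseline[interior] - profile$intensity[baseline$index[interior]]
  i <- which.max(d)
  m <- d[i]
  if (m <= 0) return(list(magnitude = 0, peak_index = NA_integer_))
  # 3-point parabolic refinement: the axial grid (1.6 um default) undersamples
  # a trough only a few um wide, so the raw sample maximum is biased low by a
  # grid-phase-dependent amount
  if (i > 1 && i < length(d)) {
    denom <- d[i - 1] - 2 * d[i] + d[i + 1]
    if (denom < 0) {
      off <- 0.5 * (d[i - 1] - d[i + 1]) / denom
      if (abs(off) < 1) m <- d[i] - 0.25 * (d[i - 1] - d[i + 1]) * off
    }
  }
  list(magnitude = m, peak_index = baseline$index[interior][i])
}

#' HB width: distance between the half-maximum points
#'
#' On the deviation curve d(i) = baseline - intensity the two crossings of
#' d = magnitude / 2 flanking the peak deviation are located by linear
#' interpolation between adjacent samples; the width is their distance in
#' micrometers. If a crossing is not found inside the baseline interval the
#' width is truncated at the interval edge and flagged (attribute
#' `truncated`, plus a warning).
#'
#' @inheritParams hb_magnitude
#' @return Width in um, with attribute `truncated` (logical).
#' @export
hb_width <- function(profile, baseline) {
  mg <- hb_magnitude(profile, baseline)
  if (mg$magnitude <= 0) abort("HB width is undefined when the magnitude is 0")
  d <- baseline$baseline - profile$intensity[baseline$index]
  ip <- which(baseline$index == mg$peak_index)
  half <- mg$magnitude / 2
  z <- (baseline$index - 1) * profile$axial_um_per_px
  truncated <- FALSE
  side <- function(dir) {
    i <- ip
    while (i + dir >= 1 && i + dir <= length(d) && d[i + dir] > half) i <- i + dir
    j <- i + dir
    if (j < 1 || j > length(d)) {
      truncated <<- TRUE
      return(z[i])
    }
    z[i] + (z[j] - z[i]) * (d[i] - half) / (d[i] - d[j])
  }
  w <- side(1L) - side(-1L)
  if (truncated)
    warn("HB half-maximum crossing fell outside the baseline interval; width truncated")
  structure(w, truncated = truncated)
}

#' ELM-RPE thickness
#'
#' Outer retina length from the ELM peak to the basal side of the RPE band.
#'
#' @param landmarks A `layer_landmarks` object.
#' @param axial_um_per_px Axial calibration, um per pixel.
#' @return Thickness in um.
#' @export
elm_rpe_thickness <- function(landmarks, axial_um_per_px) {
  (landmarks$rpe_basal - landmarks$elm_peak) * axial_um_per_px
}

#' Flatten a B-scan to its RPE band
#'
#' For acquisitions without a usable ONH reference (human scans), each
#' column is translated axially so the per-column RPE peak rows coincide at
#' their median row; vacated rows are filled with the column's edge value.
#' The RPE peak is taken as the column's global intensity maximum; a column
#' whose maximum sits on the image border is counted undetectable, and the
#' operation fails if more than 20 percent of columns are undetectable.
#'
#' @param bscan A `bscan` object.
#' @return The flattened `bscan` (attribute `flattened = TRUE`).
#' @export
flatten_to_rpe <- function(bscan) {
  stopifnot(inherits(bscan, "bscan"))
  px <- bscan$pixels
  n <- nrow(px)
  rpe_rows <- apply(px, 2, which.max)
  bad <- rpe_rows <= 1 | rpe_rows >= n
  if (mean(bad) > 0.2)
    abort(sprintf("RPE peak undetectable in %.0f%% of columns (limit 20%%)", 100 * mean(bad)))
  target <- round(median(rpe_rows[!bad]))
  for (j in which(!bad)) {
    s <- target - rpe_rows[j]
    if (s > 0) px[, j] <- px[c(rep(1L, s), seq_len(n - s)), j]
    else if (s < 0) px[, j] <- px[c(seq(1 - s, n), rep(n, -s)), j]
  }
  bscan$pixels <- px
  attr(bscan, "flattened") <- TRUE
  bscan
}
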