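#' Quantification configuration
#'
#' Collects the tunable windows of the OCT quantification pipeline. Lengths
#' are micrometers. The ELM is located as the tallest local maximum within a
#' window vitreal of the RPE anchor (the most scleral sample reaching
#' `rpe_global_frac` of the profile maximum); the IS/ep, PRT and RPE peaks
#' are then successive local maxima within windows sclerad of the ELM.
#' Defaults fit the mouse outer retina; human or non-standard geometries
#' override them.
#'
#' @param roi_um Lateral analysis band, distance from the ONH center (um).
#' @param bin Lateral binning factor in pixels (columns averaged per bin).
#' @param elm_search_rel_rpe_um Window vitreal of the global maximum searched
#'   for the ELM peak.
#' @param isep_window_um,prt_window_um,rpe_window_um Per-layer search windows
#'   sclerad of the detected ELM peak.
#' @param floor_n Number of most-scleral samples whose median defines the
#'   distal background floor for the basal-RPE half-height boundary.
#' @param rpe_global_frac Fraction of the profile maximum a local maximum
#'   must reach to qualify as the RPE anchor (the most scleral such peak).
#' @return A list of class `quantify_config`.
#' @export
quantify_config <- function(roi_um = c(350, 630), bin = 10,
                            elm_search_rel_rpe_um = c(46, 85),
                            isep_window_um = c(4, 24),
                            prt_window_um = c(24, 45),
                            rpe_window_um = c(40, 75),
                            floor_n = 20,
                            rpe_global_frac = 0.9) {
  stopifnot(length(roi_um) == 2, roi_um[1] >= 0, roi_um[2] > roi_um[1],
            bin >= 1)
  structure(list(roi_um = roi_um, bin = as.integer(bin),
                 elm_search_rel_rpe_um = elm_search_rel_rpe_um,
                 isep_window_um = isep_window_um,
                 prt_window_um = prt_window_um,
                 rpe_window_um = rpe_window_um,
                 floor_n = as.integer(floor_n),
                 rpe_global_frac = rpe_global_frac),
            class = "quantify_config")
}

new_profile_set <- function(mat, axial_um_per_px) {
  structure(list(intensity = mat, axial_um_per_px = axial_um_per_px),
            class = "profile_set")
}

new_trp <- function(intensity, axial_um_per_px, elm_index = NA_integer_) {
  structure(list(intensity = as.numeric(intensity),
                 axial_um_per_px = axial_um_per_px,
                 elm_index = as.integer(elm_index)),
            class = "trp")
}

#' @export
print.trp <- function(x, ...) {
  cat(sprintf("<transretinal profile> %d samples @ %.2f um/px, ELM index %s\n",
              length(x$intensity), x$axial_um_per_px, x$elm_index))
  invisible(x)
}

#' Convert a transretinal profile to a tibble
#'
#' @param x A `trp` profile.
#' @param ... Unused.
#' @return Tibble with `index`, `depth_um`, `intensity`.
#' @export
as_tibble.trp <- function(x, ...) {
  tibble::tibble(index = seq_along(x$intensity),
                 depth_um = (seq_along(x$intensity) - 1) * x$axial_um_per_px,
                 intensity = x$intensity)
}

#' Extract analysis-ROI A-scan profiles from a B-scan
#'
#' Selects the A-scan columns whose lateral distance from the ONH center lies
#' within `config$roi_um` (default 350-630 um) on both the nasal and temporal
#' sides, the band analyzed in small-animal light-dark protocols. If one side
#' falls outside the image only the other band is returned, with a warning.
#'
#' @param bscan A `bscan` object with a known `onh_center_px`.
#' @param config A [quantify_config()].
#' @return A `profile_set` (axial x columns intensity matrix + calibration).
#' @export
extract_roi_profiles <- function(bscan, config = quantify_config()) {
  stopifnot(inherits(bscan, "bscan"))
  if (is.na(bscan$onh_center_px)) {
    # human-mode scans carry no ONH reference: the image is assumed to be
    # cropped to the analysis region already, so every column is used
    inform("no ONH position on this scan; using the full lateral extent")
    return(new_profile_set(bscan$pixels, bscan$axial_um_per_px))
  }
  nlat <- ncol(bscan$pixels)
  # inclusive band edges, robust to floating-point division
  lo <- config$roi_um[1] / bscan$lateral_um_per_px - 1e-9
  hi <- config$roi_um[2] / bscan$lateral_um_per_px + 1e-9
  dist <- abs(seq_len(nlat) - bscan$onh_center_px)
  left <- which(dist >= lo & dist <= hi & seq_len(nlat) < bscan$onh_center_px)
  right <- which(dist >= lo & dist <= hi & seq_len(nlat) > bscan$onh_center_px)
  need <- ceiling(hi) - floor(lo)
  if (!length(left) && !length(right))
    abort(sprintf(paste("ROI outside image: need columns %.0f-%.0f px from the ONH",
                        "center (%.0f) on at least one side of a %d-column image"),
                  lo, hi, bscan$onh_center_px, nlat))
  if (!length(left) || !length(right))
    warn("ROI available on one side of the ONH only; using the single band")
  cols <- c(left, right)
  new_profile_set(bscan$pixels[, cols, drop = FALSE], bscan$axial_um_per_px)
}

#' Bin neighbouring A-scan profiles
#'
#' Averages consecutive groups of `bin` lateral columns pointwise (the
#' "binned every 10 pixels" step); a trailing partial bin is dropped.
#'
#' @param profiles A `profile_set`.
#' @param bin Bin size in columns.
#' @return A `profile_set` with `floor(ncol / bin)` columns.
#' @export
bin_profiles <- function(profiles, bin = 10) {
  stopifnot(inherits(profiles, "profile_set"), bin >= 1)
  m <- profiles$intensity
  nb <- floor(ncol(m) / bin)
  if (nb == 0) {
    warn(sprintf("fewer columns (%d) than the bin size (%d); returning a single average",
                 ncol(m), bin))
    return(new_profile_set(matrix(rowMeans(m), ncol = 1), profiles$axial_um_per_px))
  }
  out <- vapply(seq_len(nb), function(k)
    rowMeans(m[, ((k - 1) * bin + 1):(k * bin), drop = FALSE]),
    numeric(nrow(m)))
  new_profile_set(matrix(out, nrow = nrow(m)), profiles$axial_um_per_px)
}

# RPE anchor: the most scleral sample reaching at least `rpe_global_frac`
# of the profile maximum. Not required to be a strict local maximum, so it
# stays robust when the PRT and RPE bands have comparable brightness and the
# intervening samples form a plateau; the anchor only centers the ELM search
# window, so a few pixels of slack are immaterial.
detect_rpe_anchor <- function(intensity, config) {
  bright <- which(intensity >= config$rpe_global_frac * max(intensity))
  if (!length(bright)) return(NA_integer_)
  max(bright)
}

# ELM peak index of one intensity profile: tallest local maximum within the
# configured window vitreal of the RPE anchor
detect_elm <- function(intensity, axial_um_per_px, config) {
  rpe <- detect_rpe_anchor(intensity, config)
  if (is.na(rpe)) return(NA_integer_)
  w <- config$elm_search_rel_rpe_um / axial_um_per_px
  tallest_peak(intensity, rpe - w[2], rpe - w[1])
}

#' Align profiles at their ELM peaks and average
#'
#' Shifts each profile by an integer number of samples so that all ELM peaks
#' coincide at a common anchor (the median ELM index), then averages the
#' profiles pointwise over their shared support. Profiles in which no ELM
#' peak is detectable are excluded with a message; if none remain the
#' operation fails.
#'
#' @param profiles A `profile_set` or a list of `trp` profiles.
#' @param config A [quantify_config()].
#' @return A `trp` averaged profile with `elm_index` set to the anchor.
#' @export
align_at_elm <- function(profiles, config = quantify_config()) {
  if (inherits(profiles, "profile_set")) {
    ax <- profiles$axial_um_per_px
    cols <- lapply(seq_len(ncol(profiles$intensity)),
                   function(j) profiles$intensity[, j])
  } else {
    stopifnot(length(profiles) >= 1)
    ax <- profiles[[1]]$axial_um_per_px
    cols <- lapply(profiles, `[[`, "intensity")
  }
  elms <- vapply(cols, detect_elm, integer(1), axial_um_per_px = ax, config = config)
  keep <- !is.na(elms)
  if (any(!keep))
    inform(sprintf("excluding %d profile(s) without a detectable ELM peak", sum(!keep)))
  if (!any(keep)) abort("no profile has a detectable ELM peak; cannot align")
  cols <- cols[keep]; elms <- elms[keep]
  anchor <- as.integer(round(median(elms)))
  shifts <- anchor - elms           # positive: shift profile sclerad
  # shared support in anchor coordinates
  lo <- max(1 + shifts)
  hi <- min(vapply(cols, length, integer(1)) + shifts)
  avg <- rowMeans(vapply(seq_along(cols), function(k)
    cols[[k]][(lo - shifts[k]):(hi - shifts[k])], numeric(hi - lo + 1)))
  new_trp(avg, ax, elm_index = anchor - lo + 1L)
}
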