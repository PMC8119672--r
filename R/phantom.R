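#' Default retinal layer reflectivity specification
#'
#' Builds the ordered table of Gaussian reflectivity layers used by the
#' phantom generator, from the nerve fiber layer (NFL) down to the retinal
#' pigment epithelium (RPE). Depths are in micrometers from the inner (vitreal)
#' retinal surface; peak intensities are grayscale units on the 8-bit scale of
#' log-intensity OCT exports. The RPE center is placed so that the distance
#' from the ELM peak to the half-height scleral flank of the RPE band (the
#' operational "basal RPE" boundary) equals `elm_rpe_um`.
#'
#' @param elm_rpe_um Target ELM-to-basal-RPE thickness in um (ground truth).
#' @param elm_depth_um Depth of the external limiting membrane peak, um.
#' @param prt_offset_um,isep_offset_um Offsets of the photoreceptor-tip (PRT)
#'   and inner-segment/ellipsoid peaks sclerad of the ELM, um.
#' @return A tibble with columns `layer`, `center_um`, `peak`, `sd_um`.
#' @export
#' @examples
#' retina_layers()
retina_layers <- function(elm_rpe_um = 56, elm_depth_um = 170,
                          prt_offset_um = 36, isep_offset_um = 14) {
  rpe_sd <- 3
  rpe_center <- elm_depth_um + elm_rpe_um - rpe_sd * sqrt(2 * log(2))
  out <- tibble::tibble(
    layer     = c("NFL", "IPL", "INL", "OPL", "ONL", "ELM", "IS_ep", "PRT", "RPE"),
    center_um = c(10, 45, 75, 95, 125, elm_depth_um,
                  elm_depth_um + isep_offset_um,
                  elm_depth_um + prt_offset_um, rpe_center),
    peak      = c(160, 120, 70, 100, 40, 150, 170, 210, 210),
    sd_um     = c(4, 8, 7, 5, 10, 2.5, 3, 2.5, rpe_sd)
  )
  validate_layers(out)
  out
}

validate_layers <- function(layers) {
  stopifnot(is.data.frame(layers),
            all(c("layer", "center_um", "peak", "sd_um") %in% names(layers)))
  if (any(diff(layers$center_um) <= 0))
    abort("layer center depths must be strictly increasing from NFL to RPE")
  if (any(layers$peak < 0 | layers$peak > 255))
    abort("layer peak intensities must lie in [0, 255]")
  if (any(layers$sd_um <= 0)) abort("layer axial SDs must be positive")
  invisible(layers)
}

#' Parameters of the synthetic B-scan phantom
#'
#' Collects the geometry, intensity and noise parameters of the layered
#' retinal phantom. The hyporeflective band (HB) is a Gaussian-shaped trough
#' subtracted from the straight chord joining the PRT and RPE reflectivity
#' peaks; its nominal depth `hb_depth_drop` and full width at half maximum
#' `hb_width_um` are therefore (near) closed-form ground truth for the
#' downstream measurements. In the dark-adapted state the trough depth is
#' multiplied by `dark_drop_factor` and the outer-retina span (all offsets
#' sclerad of the ELM) by `dark_span_factor`.
#'
#' Default calibration mirrors a small-animal OCT system with a theoretical
#' axial resolution in tissue of 1.6 um and a 1.4 mm scan sampled by 1000
#' A-scans (1.4 um laterally). Light-state HB depths of interest span roughly
#' 5.6 to 12.7 grayscale units on 8-bit log-intensity images.
#'
#' @param layers Layer table from [retina_layers()].
#' @param hb_depth_drop Trough depth below the PRT-RPE chord, grayscale units.
#' @param hb_width_um Trough full width at half maximum, um.
#' @param dark_drop_factor,dark_span_factor Dark-state multipliers for trough
#'   depth and ELM-to-RPE span.
#' @param noise_sd Additive Gaussian pixel noise SD, grayscale units.
#' @param axial_um_per_px,lateral_um_per_px Spatial calibration, um per pixel.
#' @param n_ascans Number of A-scan columns per B-scan.
#' @param onh_center_px Lateral pixel index (1-based) of the optic nerve head.
#' @param background Background reflectivity floor, grayscale units.
#' @param depth_margin_um Extra scleral depth kept beyond the RPE center, um.
#' @param max_align_shift_px Largest random axial shift applied to individual
#'   radial scans (exercises ELM alignment).
#' @param seed Integer seed; all phantom randomness derives from it.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(layers = retina_layers(),
                           hb_depth_drop = 9.2,
                           hb_width_um = 7,
                           dark_drop_factor = 0.2,
                           dark_span_factor = 0.9,
                           noise_sd = 0,
                           axial_um_per_px = 1.6,
                           lateral_um_per_px = 1.4,
                           n_ascans = 1000,
                           onh_center_px = 500,
                           background = 15,
                           depth_margin_um = 40,
                           max_align_shift_px = 3,
                           seed = 1) {
  validate_layers(layers)
  if (hb_depth_drop < 0) abort("hb_depth_drop must be >= 0")
  if (hb_width_um <= 0) abort("hb_width_um must be positive")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (axial_um_per_px <= 0 || lateral_um_per_px <= 0)
    abort("spatial calibrations must be positive")
  p <- list(layers = layers, hb_depth_drop = hb_depth_drop,
            hb_width_um = hb_width_um, dark_drop_factor = dark_drop_factor,
            dark_span_factor = dark_span_factor, noise_sd = noise_sd,
            axial_um_per_px = axial_um_per_px,
            lateral_um_per_px = lateral_um_per_px, n_ascans = n_ascans,
            onh_center_px = onh_center_px, background = background,
            depth_margin_um = depth_margin_um,
            max_align_shift_px = max_align_shift_px, seed = seed)
  class(p) <- "phantom_params"
  # geometry check happens per state (the dark state narrows the gap)
  for (st in c("light", "dark")) phantom_geometry(p, st)
  p
}

# state-adjusted geometry: layer centers, trough center/sigma/depth.
# errors if the trough would not fit between the PRT and RPE peaks.
phantom_geometry <- function(params, state) {
  ly <- params$layers
  elm <- ly$center_um[ly$layer == "ELM"]
  if (state == "dark") {
    outer <- ly$center_um > elm
    ly$center_um[outer] <- elm + (ly$center_um[outer] - elm) * params$dark_span_factor
    drop <- params$hb_depth_drop * params$dark_drop_factor
  } else {
    drop <- params$hb_depth_drop
  }
  prt <- ly$center_um[ly$layer == "PRT"]
  rpe <- ly$center_um[ly$layer == "RPE"]
  gap <- rpe - prt
  if (params$hb_width_um >= gap)
    abort(sprintf(paste("HB trough FWHM (%.1f um) must be narrower than the",
                        "PRT-RPE peak gap (%.1f um)"), params$hb_width_um, gap))
  list(layers = ly, drop = drop,
       trough_center = (prt + rpe) / 2,
       trough_sd = params$hb_width_um / (2 * sqrt(2 * log(2))))
}

# continuous noiseless transretinal profile at depths z (um):
# layer Gaussian mixture, bridged to its PRT-RPE chord between the two peak
# locations, minus the full HB trough Gaussian, clipped to [0, 255]
phantom_profile_fun <- function(params, state) {
  geo <- phantom_geometry(params, state)
  ly <- geo$layers
  mixture <- function(z) {
    out <- rep(params$background, length(z))
    for (i in seq_len(nrow(ly)))
      out <- out + ly$peak[i] * exp(-(z - ly$center_um[i])^2 / (2 * ly$sd_um[i]^2))
    out
  }
  # locate the PRT and RPE peaks of the mixture on a fine grid
  locate <- function(center) {
    zz <- seq(center - 6, center + 6, by = 0.02)
    zz[which.max(mixture(zz))]
  }
  z1 <- locate(ly$center_um[ly$layer == "PRT"])
  z2 <- locate(ly$center_um[ly$layer == "RPE"])
  y1 <- mixture(z1); y2 <- mixture(z2)
  function(z) {
    v <- mixture(z)
    inside <- z >= z1 & z <= z2
    v[inside] <- y1 + (y2 - y1) * (z[inside] - z1) / (z2 - z1)
    v <- v - geo$drop * exp(-(z - geo$trough_center)^2 / (2 * geo$trough_sd^2))
    pmin(pmax(v, 0), 255)
  }
}

# ground truth measured from the noiseless continuous profile on a grid
# >= 8x finer than the pixel grid, with the same operational definitions
# as the measurement path (chord between detected peaks, half-max crossings,
# half-height basal RPE boundary above the distal background floor)
phantom_truth <- function(params, state) {
  geo <- phantom_geometry(params, state)
  ly <- geo$layers
  f <- phantom_profile_fun(params, state)
  res <- params$axial_um_per_px / 8
  zmax <- max(ly$center_um) + params$depth_margin_um
  z <- seq(0, zmax, by = res)
  v <- f(z)
  near <- function(center, half = 6) {
    sel <- which(abs(z - center) <= half)
    sel[which.max(v[sel])]
  }
  i_elm <- near(ly$center_um[ly$layer == "ELM"])
  i_prt <- near(ly$center_um[ly$layer == "PRT"])
  i_rpe <- near(ly$center_um[ly$layer == "RPE"])
  # HB: deviation below the chord between the PRT and RPE peaks
  idx <- i_prt:i_rpe
  chord <- v[i_prt] + (v[i_rpe] - v[i_prt]) * (z[idx] - z[i_prt]) / (z[i_rpe] - z[i_prt])
  d <- chord - v[idx]
  mag <- max(d, 0)
  width <- if (mag > 0) {
    ip <- which.max(d)
    half <- mag / 2
    left <- cross_up(z[idx], d, ip, half, -1L)
    right <- cross_up(z[idx], d, ip, half, 1L)
    right - left
  } else NA_real_
  # basal RPE: half-height crossing on the scleral flank above the floor
  floor_v <- median(tail(v, 20))
  thr <- floor_v + (v[i_rpe] - floor_v) / 2
  below <- which(v < thr & seq_along(v) > i_rpe)
  i_basal <- below[1]
  list(hb_magnitude = mag, hb_width_um = width,
       elm_rpe_um = z[i_basal] - z[i_elm],
       nominal_drop = geo$drop, state = state,
       peak_intensities = c(ELM = v[i_elm], PRT = v[i_prt], RPE = v[i_rpe]))
}

# linearly interpolated depth where the deviation curve d crosses `half`
# moving in `dir` from the peak index ip; falls back to the interval edge
cross_up <- function(z, d, ip, half, dir) {
  i <- ip
  while (i + dir >= 1 && i + dir <= length(d) && d[i + dir] > half) i <- i + dir
  j <- i + dir
  if (j < 1 || j > length(d)) return(z[i])
  z[i] + (z[j] - z[i]) * (d[i] - half) / (d[i] - d[j])
}

#' Generate a synthetic OCT B-scan
#'
#' Renders the layered phantom as an axial-by-lateral grayscale image. Every
#' A-scan column carries the same noiseless transretinal profile (the phantom
#' has no lateral structure beyond the ONH bookkeeping position); independent
#' Gaussian noise of SD `noise_sd` is then added per pixel and intensities are
#' clipped to `[0, 255]`. The dense-grid ground truth of the three outer
#' retina indices is recorded in the `truth` field.
#'
#' @param params A [phantom_params()] object.
#' @param state `"light"` or `"dark"` adaptation state.
#' @param subject_id,group,drug,dose Metadata labels carried on the scan.
#' @param seed Optional override of the seed derived from `params$seed`.
#' @return A `bscan` object: list with `pixels` (matrix, rows = axial),
#'   calibration fields, metadata and `truth`.
#' @export
#' @examples
#' b <- generate_bscan(phantom_params(noise_sd = 0), "light")
#' dim(b$pixels)
#' b$truth$hb_magnitude
generate_bscan <- function(params, state = c("light", "dark"),
                           subject_id = "phantom", group = "sim",
                           drug = "none", dose = 0, seed = NULL) {
  state <- match.arg(state)
  stopifnot(inherits(params, "phantom_params"))
  seed <- seed %||% derive_seed(params$seed, "bscan", state, subject_id)
  f <- phantom_profile_fun(params, state)
  zmax <- max(params$layers$center_um) + params$depth_margin_um
  nrows <- ceiling(zmax / params$axial_um_per_px) + 1
  z <- (seq_len(nrows) - 1) * params$axial_um_per_px
  col <- f(z)
  px <- matrix(col, nrow = nrows, ncol = params$n_ascans)
  if (params$noise_sd > 0) {
    set.seed(seed)
    px <- px + matrix(rnorm(length(px), sd = params$noise_sd), nrow = nrows)
    px <- pmin(pmax(px, 0), 255)
  }
  new_bscan(px, params$axial_um_per_px, params$lateral_um_per_px,
            onh_center_px = params$onh_center_px, state = state,
            subject_id = subject_id, group = group, drug = drug, dose = dose,
            truth = phantom_truth(params, state))
}

new_bscan <- function(pixels, axial_um_per_px, lateral_um_per_px,
                      onh_center_px = NA, state = NA_character_,
                      subject_id = NA_character_, group = NA_character_,
                      drug = NA_character_, dose = NA_real_, truth = NULL) {
  if (any(pixels < 0 | pixels > 255)) abort("bscan pixels must lie in [0, 255]")
  if (axial_um_per_px <= 0 || lateral_um_per_px <= 0)
    abort("bscan calibrations must be positive")
  structure(list(pixels = pixels, axial_um_per_px = axial_um_per_px,
                 lateral_um_per_px = lateral_um_per_px,
                 onh_center_px = onh_center_px, state = state,
                 subject_id = subject_id, group = group, drug = drug,
                 dose = dose, truth = truth),
            class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan> %d x %d px (%.2f um axial, %.2f um lateral), state=%s, subject=%s\n",
              nrow(x$pixels), ncol(x$pixels), x$axial_um_per_px,
              x$lateral_um_per_px, x$state, x$subject_id))
  invisible(x)
}

#' Generate a set of radial B-scans of one eye
#'
#' Emulates the four radial scans (45-degree steps) acquired per eye: all
#' scans share the same phantom ground truth but receive independent pixel
#' noise and an independent small global axial shift (default at most
#' `params$max_align_shift_px` pixels), which exercises the ELM alignment
#' step of the quantification pipeline.
#'
#' @inheritParams generate_bscan
#' @param n_scans Number of radial scans (the instrument default is 4).
#' @param shifts Optional integer vector of per-scan axial shifts in pixels;
#'   drawn uniformly from `0:max_align_shift_px` when `NULL`.
#' @return List of `bscan` objects.
#' @export
generate_radial_set <- function(params, state = c("light", "dark"),
                                n_scans = 4, shifts = NULL,
                                subject_id = "phantom", group = "sim",
                                drug = "none", dose = 0) {
  state <- match.arg(state)
  if (is.null(shifts)) {
    set.seed(derive_seed(params$seed, "shifts", state, subject_id))
    shifts <- sample(0:params$max_align_shift_px, n_scans, replace = TRUE)
  }
  stopifnot(length(shifts) == n_scans)
  lapply(seq_len(n_scans), function(k) {
    b <- generate_bscan(params, state, subject_id = subject_id, group = group,
                        drug = drug, dose = dose,
                        seed = derive_seed(params$seed, "scan", state, subject_id, k))
    b$pixels <- shift_rows(b$pixels, shifts[k])
    b
  })
}

# shift image rows sclerad by s pixels (s >= 0), replicating the top edge
shift_rows <- function(px, s) {
  s <- as.integer(s)
  if (s == 0) return(px)
  n <- nrow(px)
  out <- px[c(rep(1L, s), seq_len(n - s)), , drop = FALSE]
  out
}
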