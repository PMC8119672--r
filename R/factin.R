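#' Simulate F-actin depth-intensity profiles
#'
#' Generates per-mouse phalloidin fluorescence depth profiles across the
#' outer retina with two Gaussian peaks: an apical peak at the HB region and
#' a basal peak. Peak heights follow a group + side + group-by-side
#' interaction structure with mouse-level random intercepts, the generative
#' model assumed by [fit_factin_model()].
#'
#' @param group_means Named numeric vector of apical peak means per group
#'   (fluorescence units). Defaults to the four study groups with the
#'   uncoupler-treated group 16 units below control.
#' @param side_effect Basal-minus-apical offset common to all groups.
#' @param interaction Named numeric vector (same names as `group_means`) of
#'   group-specific additions to the basal side; defaults to 0.
#' @param n_per_group Mice per group.
#' @param mouse_sd SD of the mouse random intercept.
#' @param noise_sd SD of the per-peak residual noise.
#' @param depth_max_um,depth_step_um Depth grid of the profiles, um.
#' @param seed Integer seed.
#' @return Long tibble: `mouse_id`, `group`, `depth_um`, `intensity`, with
#'   the per-mouse true peak heights attached as attribute `"truth"`.
#' @export
simulate_factin_profiles <- function(group_means = c(C57_saline = 60, C57 = 60,
                                                     S129 = 52, DNP = 44),
                                     side_effect = -8,
                                     interaction = NULL,
                                     n_per_group = 6,
                                     mouse_sd = 4, noise_sd = 3,
                                     depth_max_um = 60, depth_step_um = 0.5,
                                     seed = 1) {
  groups <- names(group_means)
  if (is.null(groups)) abort("group_means must be a named vector")
  interaction <- interaction %||% setNames(rep(0, length(groups)), groups)
  depth <- seq(0, depth_max_um, by = depth_step_um)
  apical_c <- 0.25 * depth_max_um; basal_c <- 0.75 * depth_max_um
  set.seed(derive_seed(seed, "factin"))
  truth <- list()
  out <- purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(seq_len(n_per_group), function(i) {
      id <- sprintf("%s_%02d", g, i)
      u <- rnorm(1, 0, mouse_sd)
      h_ap <- max(group_means[[g]] + u + rnorm(1, 0, noise_sd), 0)
      h_ba <- max(group_means[[g]] + side_effect + interaction[[g]] + u +
                    rnorm(1, 0, noise_sd), 0)
      truth[[id]] <<- c(apical = h_ap, basal = h_ba)
      tibble::tibble(mouse_id = id, group = g, depth_um = depth,
                     intensity = h_ap * exp(-(depth - apical_c)^2 / (2 * 9)) +
                       h_ba * exp(-(depth - basal_c)^2 / (2 * 9)))
    })
  })
  attr(out, "truth") <- truth
  out
}

#' Peak F-actin fluorescence at the HB region
#'
#' Maximum intensity within a depth window, optionally minus a local
#' background (median intensity in the flanking region outside the window),
#' floored at zero. Background subtraction is off by default: reported peak
#' fluorescence is conventionally the raw maximum, but session-dependent
#' offsets can be removed when profiles are not co-calibrated.
#'
#' @param profile Tibble with `depth_um` and `intensity` for one profile.
#' @param hb_window Depth window in um (length-2).
#' @param subtract_background Subtract the flanking median?
#' @param flank_um Width of the background flank on each side of the window.
#' @return Peak fluorescence (units of the profile).
#' @export
factin_peak_at_hb <- function(profile, hb_window,
                              subtract_background = FALSE, flank_um = 10) {
  stopifnot(all(c("depth_um", "intensity") %in% names(profile)),
            length(hb_window) == 2)
  d <- profile$depth_um
  if (hb_window[1] < min(d) || hb_window[2] > max(d))
    abort(sprintf("HB window [%g, %g] um outside profile support [%g, %g] um",
                  hb_window[1], hb_window[2], min(d), max(d)))
  inside <- d >= hb_window[1] & d <= hb_window[2]
  pk <- max(profile$intensity[inside])
  if (subtract_background) {
    flank <- !inside & d >= hb_window[1] - flank_um & d <= hb_window[2] + flank_um
    if (any(flank)) pk <- pk - median(profile$intensity[flank])
  }
  max(pk, 0)
}

#' Per-mouse, per-side F-actin peak table
#'
#' Applies [factin_peak_at_hb()] to the apical (HB region) and basal windows
#' of every mouse profile; the result feeds [fit_factin_model()].
#'
#' @param profiles Long tibble from [simulate_factin_profiles()] or read
#'   from CSV with the same columns.
#' @param apical_window,basal_window Depth windows, um.
#' @inheritParams factin_peak_at_hb
#' @return Tibble: `mouse_id`, `group`, `side`, `peak`.
#' @export
factin_peak_table <- function(profiles, apical_window = c(5, 25),
                              basal_window = c(35, 55),
                              subtract_background = FALSE) {
  keys <- dplyr::distinct(profiles, .data$mouse_id, .data$group)
  purrr::map_dfr(seq_len(nrow(keys)), function(i) {
    pr <- dplyr::semi_join(profiles, keys[i, ], by = c("mouse_id", "group"))
    tibble::tibble(
      mouse_id = keys$mouse_id[i], group = keys$group[i],
      side = c("apical", "basal"),
      peak = c(factin_peak_at_hb(pr, apical_window, subtract_background),
               factin_peak_at_hb(pr, basal_window, subtract_background)))
  })
}
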