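#' Normalize per-group light-dark responses by the group SD
#'
#' For each group and trait, the group mean light-dark difference divided by
#' the within-group sample standard deviation (denominator n - 1) of the
#' differences — the scale-free per-group response used to compare traits
#' on a common axis.
#'
#' @param data Tibble with a `group` column and one column per trait.
#' @param traits Character vector of trait column names.
#' @return Tibble: `group`, `trait`, `n`, `mean`, `sd`, `normalized`.
#' @export
#' @examples
#' tbl <- tibble::tibble(group = "g1", y_hb = c(4, 6))
#' normalize_by_group_sd(tbl, "y_hb") # mean 5 / sd sqrt(2) = 3.536
normalize_by_group_sd <- function(data, traits = c("y_hb", "y_elm_rpe")) {
  stopifnot("group" %in% names(data), all(traits %in% names(data)))
  out <- tidyr::pivot_longer(data[, c("group", traits)], -"group",
                             names_to = "trait", values_to = "value") |>
    dplyr::group_by(.data$group, .data$trait) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = sd(.data$value), .groups = "drop")
  if (any(out$n < 2)) abort("every group needs at least 2 mice")
  if (any(out$sd == 0)) abort("zero within-group SD; normalization undefined")
  dplyr::mutate(out, normalized = .data$mean / .data$sd)
}

#' Per-mouse light-dark difference table
#'
#' Pairs the light and dark measurements of each subject (within session,
#' when a `session` column is present) and returns the light-minus-dark
#' differences of HB magnitude and ELM-RPE thickness, the response variables
#' of the hierarchical models. Unpaired records are listed and excluded.
#'
#' @param per_eye Tibble of per-eye measurements as produced by
#'   [quantify_eye()] rows (columns `subject_id`, `state`, `hb_magnitude`,
#'   `elm_rpe_um`, optionally `group`, `session`).
#' @return Tibble: `mouse_id`, `group`, `y_hb`, `y_elm_rpe` (one row per
#'   subject-session).
#' @export
light_dark_difference_table <- function(per_eye) {
  need <- c("subject_id", "state", "hb_magnitude", "elm_rpe_um")
  stopifnot(all(need %in% names(per_eye)))
  keys <- intersect(c("subject_id", "group", "session"), names(per_eye))
  wide <- tidyr::pivot_wider(
    per_eye[, c(keys, "state", "hb_magnitude", "elm_rpe_um")],
    names_from = "state", values_from = c("hb_magnitude", "elm_rpe_um"))
  complete <- stats::complete.cases(
    wide[, c("hb_magnitude_light", "hb_magnitude_dark",
             "elm_rpe_um_light", "elm_rpe_um_dark")])
  if (any(!complete))
    inform(paste("excluding unpaired subject(s):",
                 paste(wide$subject_id[!complete], collapse = ", ")))
  wide <- wide[complete, ]
  tibble::tibble(
    mouse_id = wide$subject_id,
    group = if ("group" %in% keys) wide$group else NA_character_,
    y_hb = wide$hb_magnitude_light - wide$hb_magnitude_dark,
    y_elm_rpe = wide$elm_rpe_um_light - wide$elm_rpe_um_dark)
}
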