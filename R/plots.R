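#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_vline
#'   geom_hline geom_errorbar geom_segment labs theme_minimal facet_wrap
#'   autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a transretinal intensity profile
#'
#' Depth-intensity curve with optional layer landmark markers and the
#' PRT-RPE baseline chord.
#'
#' @param object A `trp` profile.
#' @param landmarks Optional `layer_landmarks` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trp <- function(object, landmarks = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$depth_um, y = .data$intensity)) +
    geom_line() +
    labs(x = "depth (µm)", y = "intensity (grayscale)") +
    theme_minimal()
  if (!is.null(landmarks)) {
    ax <- object$axial_um_per_px
    lm_df <- tibble::tibble(
      layer = c("ELM", "IS/ep", "PRT", "RPE"),
      depth_um = (c(landmarks$elm_peak, landmarks$isep_peak,
                    landmarks$prt_peak, landmarks$rpe_peak) - 1) * ax,
      intensity = unname(landmarks$intensities))
    ch <- tibble::tibble(
      x = (c(landmarks$prt_peak, landmarks$rpe_peak) - 1) * ax,
      y = unname(landmarks$intensities[c("PRT", "RPE")]))
    p <- p +
      geom_point(data = lm_df, colour = "red3") +
      ggplot2::geom_text(data = lm_df, aes(label = .data$layer),
                         vjust = -0.8, size = 3) +
      geom_segment(data = ch[1, ], aes(x = .data$x, y = .data$y,
                                       xend = ch$x[2], yend = ch$y[2]),
                   linetype = 2, colour = "grey40")
  }
  p
}

#' Bar panel of normalized group responses
#'
#' One bar per group and trait on the common mean/SD scale.
#'
#' @param normalized Tibble from [normalize_by_group_sd()].
#' @return A ggplot.
#' @export
plot_group_responses <- function(normalized) {
  ggplot(normalized, aes(x = .data$group, y = .data$normalized)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = 0) +
    facet_wrap(~ .data$trait) +
    labs(x = NULL, y = "light–dark response (mean / SD)") +
    theme_minimal()
}

#' Between-group correlation scatter with the model-implied line
#'
#' Group mean light-dark differences (HB magnitude vs ELM-RPE thickness)
#' with the regression line implied by the posterior between-group
#' correlation of [fit_joint_bivariate()].
#'
#' @param post Posterior from [fit_joint_bivariate()].
#' @param cohort The cohort table the model was fitted to.
#' @return A ggplot.
#' @export
plot_correlation <- function(post, cohort) {
  stopifnot(inherits(post, "octhb_post"), post$model == "joint_bivariate")
  gm <- dplyr::summarise(dplyr::group_by(cohort, .data$group),
                         elm = mean(.data$y_elm_rpe), hb = mean(.data$y_hb),
                         se_elm = sd(.data$y_elm_rpe) / sqrt(dplyr::n()),
                         se_hb = sd(.data$y_hb) / sqrt(dplyr::n()),
                         .groups = "drop")
  slope <- mean(post$draws[, "slope_hb_on_elm"])
  mu_e <- mean(post$draws[, "mu_elm_rpe"]); mu_h <- mean(post$draws[, "mu_hb"])
  r_ci <- credibility_interval(post, term = "r_mu")
  ggplot(gm, aes(x = .data$elm, y = .data$hb)) +
    ggplot2::geom_abline(slope = slope, intercept = mu_h - slope * mu_e,
                         colour = "red3") +
    geom_errorbar(aes(ymin = .data$hb - .data$se_hb,
                      ymax = .data$hb + .data$se_hb), width = 0) +
    ggplot2::geom_errorbarh(aes(xmin = .data$elm - .data$se_elm,
                                xmax = .data$elm + .data$se_elm), height = 0) +
    geom_point(size = 2) +
    labs(x = "light–dark Δ ELM-RPE thickness (µm)",
         y = "light–dark Δ HB magnitude (grayscale)",
         subtitle = sprintf("between-group r = %.3f [%.3f, %.3f]",
                            mean(post$draws[, "r_mu"]), r_ci$lower, r_ci$upper)) +
    theme_minimal()
}

#' Posterior interval plot
#'
#' Point estimates with 95 percent credibility intervals for a selection of
#' parameters; intervals excluding zero are highlighted.
#'
#' @param object An `octhb_post` posterior.
#' @param terms Optional character vector of parameter names to show
#'   (defaults to all non-group-level parameters).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.octhb_post <- function(object, terms = NULL, ...) {
  td <- tidy(object)
  if (is.null(terms))
    terms <- td$term[!grepl("^(mu_g|s2|r_w|zr|u)\\[", td$term)]
  td <- td[td$term %in% terms, ]
  td$excludes_zero <- td$conf.low > 0 | td$conf.high < 0
  ggplot(td, aes(x = .data$estimate, y = .data$term,
                 colour = .data$excludes_zero)) +
    geom_vline(xintercept = 0, linetype = 2) +
    geom_errorbar(aes(xmin = .data$conf.low, xmax = .data$conf.high),
                  width = 0.2) +
    geom_point() +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey40",
                                            "TRUE" = "red3"),
                                 guide = "none") +
    labs(x = "posterior estimate (95% CI)", y = NULL) +
    theme_minimal()
}

#' Plot ERG traces by stimulus intensity
#'
#' @param traces Long tibble of traces (e.g. from [simulate_erg()]).
#' @return A ggplot faceted by intensity.
#' @export
plot_erg_traces <- function(traces) {
  ggplot(traces, aes(x = .data$time_s - .data$stim_onset_s,
                     y = .data$voltage_uv,
                     colour = factor(.data$treated))) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~ .data$intensity_cd_m2, scales = "free_y",
               labeller = ggplot2::label_both) +
    geom_vline(xintercept = 0, linetype = 3) +
    labs(x = "time from light onset (s)", y = "voltage (µV)",
         colour = "treated") +
    theme_minimal()
}
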