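#' Specification of the hierarchical bivariate cohort simulation
#'
#' Defines the generative model assumed by the joint analysis of per-mouse
#' light-dark differences in ELM-RPE thickness (um) and HB magnitude
#' (grayscale units): group mean vectors drawn from MVN(mu, Sigma_mu) with
#' between-group correlation `between_group_corr`; per-group within-group
#' covariances built from lognormal variances and a beta-distributed
#' correlation centered on `overall_within_corr` with dispersion
#' `corr_dispersion`; per-mouse bivariate differences drawn MVN around their
#' group mean. Default group sizes are the eight study groups (4, 4, 5, 6,
#' 10, 8, 6, 5 mice).
#'
#' @param n_mice_per_group Integer vector of group sizes.
#' @param overall_mean Length-2 mean vector `c(elm_rpe, hb)`.
#' @param between_group_sd Length-2 SDs of the group means.
#' @param between_group_corr Correlation of the two traits across group
#'   means (`r_mu`).
#' @param within_logvar_mean,within_logvar_sd Length-2 location and scale of
#'   the lognormal distribution of within-group variances, per trait.
#' @param overall_within_corr Mean within-group correlation (`r`).
#' @param corr_dispersion Variance of the beta distribution of per-group
#'   within correlations on the (r+1)/2 scale; must respect the beta
#'   variance bound.
#' @param seed Integer seed.
#' @return A list of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_mice_per_group = c(4, 4, 5, 6, 10, 8, 6, 5),
                            overall_mean = c(elm_rpe = 10, hb = 9),
                            between_group_sd = c(3, 2.4),
                            between_group_corr = 0.975,
                            within_logvar_mean = log(c(2, 1.5)^2),
                            within_logvar_sd = c(0.3, 0.3),
                            overall_within_corr = 0.5,
                            corr_dispersion = 0.01,
                            seed = 1) {
  if (abs(between_group_corr) > 1 || abs(overall_within_corr) > 1)
    abort("correlations must lie in [-1, 1]")
  check_psd(cov2(between_group_sd, between_group_corr), "between-group covariance")
  m <- (overall_within_corr + 1) / 2
  if (corr_dispersion > 0) beta_shapes(m, corr_dispersion) # admissibility check
  structure(list(n_mice_per_group = n_mice_per_group,
                 overall_mean = overall_mean,
                 between_group_sd = between_group_sd,
                 between_group_corr = between_group_corr,
                 within_logvar_mean = within_logvar_mean,
                 within_logvar_sd = within_logvar_sd,
                 overall_within_corr = overall_within_corr,
                 corr_dispersion = corr_dispersion, seed = seed),
            class = "cohort_sim_spec")
}

#' Simulate a hierarchical bivariate cohort of light-dark differences
#'
#' Draws from the generative model in [cohort_sim_spec()]. The true group
#' mean vectors, within-group SDs and correlations are attached as attribute
#' `"truth"` for recovery scoring.
#'
#' @param spec A [cohort_sim_spec()].
#' @return Tibble: `mouse_id`, `group`, `y_elm_rpe`, `y_hb`.
#' @export
#' @examples
#' simulate_cohort(cohort_sim_spec(seed = 42))
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(derive_seed(spec$seed, "cohort"))
  J <- length(spec$n_mice_per_group)
  Sig_mu <- cov2(spec$between_group_sd, spec$between_group_corr)
  mu_g <- rmvn(J, spec$overall_mean, Sig_mu)
  m <- (spec$overall_within_corr + 1) / 2
  out <- vector("list", J)
  truth_g <- vector("list", J)
  for (j in seq_len(J)) {
    s2 <- exp(rnorm(2, spec$within_logvar_mean, spec$within_logvar_sd))
    r_j <- if (spec$corr_dispersion > 0) {
      sh <- beta_shapes(m, spec$corr_dispersion)
      2 * stats::rbeta(1, sh[1], sh[2]) - 1
    } else spec$overall_within_corr
    Sig_j <- cov2(sqrt(s2), r_j)
    n <- spec$n_mice_per_group[j]
    y <- rmvn(n, mu_g[j, ], Sig_j)
    out[[j]] <- tibble::tibble(
      mouse_id = sprintf("g%d_m%02d", j, seq_len(n)),
      group = sprintf("g%d", j),
      y_elm_rpe = y[, 1], y_hb = y[, 2])
    truth_g[[j]] <- list(mu = mu_g[j, ], sd = sqrt(s2), corr = r_j)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "truth") <- list(overall_mean = spec$overall_mean,
                             between_group_sd = spec$between_group_sd,
                             r_mu = spec$between_group_corr,
                             groups = truth_g)
  res
}

#' Specification of the paired drug-treatment cohort
#'
#' Generative model for the bivariate drug-effect mixed model: every mouse
#' contributes a pre-treatment (control) and a post-treatment session; the
#' two traits share a mouse random intercept with covariance `Sigma_b` and
#' residual covariance `Sigma_e`. Treated-session means are the control
#' means multiplied by the per-drug-group, per-trait
#' `drug_effect_multipliers` (a multiplier of 0.04 corresponds to ~96
#' percent suppression of the light-dark response). Default group sizes are
#' the study's drug arms (ACZ 10, DNP 5 mg/kg 6, DNP 10 mg/kg 5).
#'
#' @param n_per_group Named integer vector of mice per drug group.
#' @param control_mean Length-2 control-session mean `c(elm_rpe, hb)`.
#' @param drug_effect_multipliers Named list (per drug group) of length-2
#'   multipliers `c(elm_rpe, hb)` applied to the treated-session mean.
#' @param intercept_sd,intercept_corr Mouse random-intercept SDs and
#'   correlation (`Sigma_b`).
#' @param resid_sd,resid_corr Residual SDs and correlation (`Sigma_e`).
#' @param seed Integer seed.
#' @return A list of class `drug_sim_spec`.
#' @export
drug_sim_spec <- function(n_per_group = c(ACZ = 10, DNP5 = 6, DNP10 = 5),
                          control_mean = c(elm_rpe = 10, hb = 9),
                          drug_effect_multipliers = list(
                            ACZ = c(0.60, 0.95),
                            DNP5 = c(0.42, 0.42),
                            DNP10 = c(0.04, 0.04)),
                          intercept_sd = c(1.0, 0.9),
                          intercept_corr = 0.3,
                          resid_sd = c(1.2, 1.1),
                          resid_corr = 0.3,
                          seed = 1) {
  if (is.null(names(n_per_group)) ||
      !all(names(n_per_group) %in% names(drug_effect_multipliers)))
    abort("every drug group needs an entry in drug_effect_multipliers")
  check_psd(cov2(intercept_sd, intercept_corr), "random-intercept covariance")
  check_psd(cov2(resid_sd, resid_corr), "residual covariance")
  structure(list(n_per_group = n_per_group, control_mean = control_mean,
                 drug_effect_multipliers = drug_effect_multipliers,
                 intercept_sd = intercept_sd, intercept_corr = intercept_corr,
                 resid_sd = resid_sd, resid_corr = resid_corr, seed = seed),
            class = "drug_sim_spec")
}

#' Simulate the paired drug-treatment cohort
#'
#' @param spec A [drug_sim_spec()].
#' @return Tibble with one row per mouse-session: `mouse_id`, `drug_group`,
#'   `treated` (0 control / 1 treated), `y_elm_rpe`, `y_hb`; true session
#'   means attached as attribute `"truth"`.
#' @export
simulate_drug_cohort <- function(spec) {
  stopifnot(inherits(spec, "drug_sim_spec"))
  set.seed(derive_seed(spec$seed, "drug_cohort"))
  Sig_b <- cov2(spec$intercept_sd, spec$intercept_corr)
  Sig_e <- cov2(spec$resid_sd, spec$resid_corr)
  truth <- list()
  out <- purrr::map_dfr(names(spec$n_per_group), function(g) {
    mult <- spec$drug_effect_multipliers[[g]]
    truth[[g]] <<- list(control = spec$control_mean,
                        treated = spec$control_mean * mult)
    purrr::map_dfr(seq_len(spec$n_per_group[[g]]), function(i) {
      u <- drop(rmvn(1, c(0, 0), Sig_b))
      y0 <- spec$control_mean + u + drop(rmvn(1, c(0, 0), Sig_e))
      y1 <- spec$control_mean * mult + u + drop(rmvn(1, c(0, 0), Sig_e))
      tibble::tibble(mouse_id = sprintf("%s_%02d", g, i), drug_group = g,
                     treated = c(0L, 1L),
                     y_elm_rpe = c(y0[1], y1[1]), y_hb = c(y0[2], y1[2]))
    })
  })
  attr(out, "truth") <- truth
  out
}
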