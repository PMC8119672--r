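# All models run in JAGS. "Diffuse" priors are concretized adaptively from
# the response scale (normal with SD 100 x MAD for location parameters,
# half-Cauchy with scale 5 x MAD for SDs), so the models are unit-free;
# every scale is overridable through the `priors` argument. Correlations are
# mapped from (0,1)-supported priors through r = 0.9999 * (2 z - 1), the
# slight shrinkage keeping 2x2 covariance factorizations nonsingular when
# the posterior piles up near |r| = 1.

prior_scales <- function(y, priors = NULL) {
  s <- mad(y)
  if (!is.finite(s) || s == 0) s <- max(sd(y), 1e-3)
  list(location = priors$location %||% (100 * s),
       scale = priors$scale %||% (5 * s))
}

jags_group_hier <- "
model {
  for (n in 1:N) { y[n] ~ dnorm(theta[g[n]], 1 / pow(sigma_w, 2)) }
  for (j in 1:J) { theta[j] ~ dnorm(mu0, 1 / pow(sigma_b, 2)) }
  mu0 ~ dnorm(0, 1 / pow(pr_loc, 2))
  sigma_w ~ dt(0, 1 / pow(pr_sc, 2), 1) T(0,)
  sigma_b ~ dt(0, 1 / pow(pr_sc, 2), 1) T(0,)
}
"

#' Hierarchical model of per-group light-dark responses
#'
#' One-trait hierarchical normal model: an overall mean with a diffuse
#' normal prior, group means drawn around it with a between-group SD, and
#' half-Cauchy priors on the within- and between-group SDs. This is the
#' model behind per-group response summaries and their credibility
#' intervals.
#'
#' @param data Tibble with a `group` column and the trait column.
#' @param trait Name of the response column (e.g. `"y_hb"`).
#' @param priors Optional list with `location` and `scale` prior SDs.
#' @param settings A [sampler_settings()].
#' @param seed Integer seed.
#' @return An `octhb_post` posterior with terms `mu0`, `theta_<group>`,
#'   `sigma_w`, `sigma_b`.
#' @export
fit_group_hierarchical <- function(data, trait = "y_hb", priors = NULL,
                                   settings = sampler_settings(), seed = 1) {
  stopifnot(is.data.frame(data), "group" %in% names(data), trait %in% names(data))
  groups <- unique(data$group)
  if (length(groups) < 2) abort("at least 2 groups are required")
  y <- data[[trait]]
  ps <- prior_scales(y, priors)
  dat <- list(y = y, g = match(data$group, groups), N = length(y),
              J = length(groups), pr_loc = ps$location, pr_sc = ps$scale)
  mc <- jags_fit(jags_group_hier, dat, c("mu0", "theta", "sigma_w", "sigma_b"),
                 settings, seed)
  post <- new_posterior(mc, "group_hierarchical", settings,
                        list(trait = trait, groups = groups))
  colnames(post$draws) <- sub("^theta\\[(\\d+)\\]$", "theta_\\1", colnames(post$draws))
  for (j in seq_along(groups)) {
    colnames(post$draws)[colnames(post$draws) == paste0("theta_", j)] <-
      paste0("theta_", groups[j])
    post$diagnostics$term[post$diagnostics$term == sprintf("theta[%d]", j)] <-
      paste0("theta_", groups[j])
  }
  post
}

jags_joint_bivariate <- "
model {
  # per-mouse bivariate likelihood, factorized as Y1 then Y2 | Y1
  for (n in 1:N) {
    Y[n, 1] ~ dnorm(mu_g[g[n], 1], 1 / s2[g[n], 1])
    Y[n, 2] ~ dnorm(mu_g[g[n], 2] + r_w[g[n]] * sqrt(s2[g[n], 2] / s2[g[n], 1])
                    * (Y[n, 1] - mu_g[g[n], 1]),
                    1 / (s2[g[n], 2] * (1 - pow(r_w[g[n]], 2))))
  }
  # hierarchical group means with between-group correlation r_mu
  for (j in 1:J) {
    mu_g[j, 1] ~ dnorm(mu[1], 1 / pow(sd_mu[1], 2))
    mu_g[j, 2] ~ dnorm(mu[2] + r_mu * (sd_mu[2] / sd_mu[1]) * (mu_g[j, 1] - mu[1]),
                       1 / (pow(sd_mu[2], 2) * (1 - pow(r_mu, 2))))
    # within-group covariance hierarchy
    s2[j, 1] ~ dlnorm(mu_s[1], 1 / sig2_s[1])
    s2[j, 2] ~ dlnorm(mu_s[2], 1 / sig2_s[2])
    zr[j] ~ dbeta(a_r, b_r)
    r_w[j] <- 0.9999 * (2 * zr[j] - 1)
  }
  for (k in 1:2) {
    mu[k] ~ dnorm(0, 1 / pow(pr_loc[k], 2))
    sd_mu[k] ~ dt(0, 1 / pow(pr_sc[k], 2), 1) T(0,)
    mu_s[k] ~ dt(0, 1 / pow(pr_ls[k], 2), 1)
    sig2_s[k] ~ dt(0, 1 / pow(pr_lss[k], 2), 1) T(0,)
  }
  z_mu ~ dbeta(0.5, 0.5)
  r_mu <- 0.9999 * (2 * z_mu - 1)
  # within-group correlations: beta around the overall correlation r
  z ~ dbeta(0.5, 0.5)
  r <- 0.9999 * (2 * z - 1)
  m_r <- (r + 1) / 2
  sig2_r ~ dunif(0, m_r * (1 - m_r))
  phi_r <- m_r * (1 - m_r) / sig2_r - 1
  a_r <- max(m_r * phi_r, 0.01)
  b_r <- max((1 - m_r) * phi_r, 0.01)
}
"

#' Joint bivariate hierarchical model of two light-dark responses
#'
#' Jointly models per-mouse light-dark differences in ELM-RPE thickness and
#' HB magnitude as bivariate normal within groups, with a hierarchical
#' bivariate normal prior on the group mean vectors. The headline estimand
#' is the between-group correlation `r_mu` of the two traits' group means
#' (reported with its percentile credibility interval and the equivalent
#' regression slope of HB magnitude on ELM-RPE thickness). Priors: beta(0.5,
#' 0.5) on (r+1)/2 for both correlation levels, lognormal within-group
#' variances with Cauchy hyperpriors, half-Cauchy between-group SDs, and a
#' uniform(0, bound) prior on the dispersion of within-group correlations.
#'
#' @param data Tibble with columns `group`, `y_elm_rpe`, `y_hb` (one row per
#'   mouse, untreated condition).
#' @param priors Optional list overriding prior scales: `location`, `scale`
#'   (length-2, per trait), `logvar_location`, `logvar_scale`.
#' @param settings A [sampler_settings()].
#' @param seed Integer seed.
#' @param rhat_limit Convergence gate on `r_mu` and the overall means.
#' @param on_nonconvergence `"warn"` (default) or `"error"`.
#' @return An `octhb_post` with terms `mu_elm_rpe`, `mu_hb`,
#'   `sd_mu_elm_rpe`, `sd_mu_hb`, `r_mu`, `r`, `sig2_r`, `slope_hb_on_elm`,
#'   plus per-group means, variances and correlations.
#' @export
fit_joint_bivariate <- function(data, priors = NULL,
                                settings = sampler_settings(), seed = 1,
                                rhat_limit = 1.05,
                                on_nonconvergence = c("warn", "error")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  stopifnot(all(c("group", "y_elm_rpe", "y_hb") %in% names(data)))
  groups <- unique(data$group)
  sizes <- table(factor(data$group, levels = groups))
  if (length(groups) < 3) abort("at least 3 groups are required")
  if (any(sizes < 2)) abort("every group needs at least 2 mice")
  Y <- cbind(data$y_elm_rpe, data$y_hb)
  ps1 <- prior_scales(Y[, 1], priors); ps2 <- prior_scales(Y[, 2], priors)
  dat <- list(Y = Y, g = match(data$group, groups), N = nrow(Y),
              J = length(groups),
              pr_loc = c(ps1$location, ps2$location),
              pr_sc = c(ps1$scale, ps2$scale),
              pr_ls = priors$logvar_location %||% c(10, 10),
              pr_lss = priors$logvar_scale %||% c(5, 5))
  mc <- jags_fit(jags_joint_bivariate, dat,
                 c("mu", "sd_mu", "r_mu", "r", "sig2_r", "mu_g", "s2", "r_w"),
                 settings, seed)
  post <- new_posterior(mc, "joint_bivariate", settings,
                        list(groups = groups, traits = c("y_elm_rpe", "y_hb")))
  ren <- c("mu[1]" = "mu_elm_rpe", "mu[2]" = "mu_hb",
           "sd_mu[1]" = "sd_mu_elm_rpe", "sd_mu[2]" = "sd_mu_hb")
  idx <- match(names(ren), colnames(post$draws))
  colnames(post$draws)[idx] <- ren
  post$diagnostics$term[match(names(ren), post$diagnostics$term)] <- ren
  # between-group correlation expressed as a regression slope (HB on ELM-RPE)
  slope <- post$draws[, "r_mu"] * post$draws[, "sd_mu_hb"] / post$draws[, "sd_mu_elm_rpe"]
  post$draws <- cbind(post$draws, slope_hb_on_elm = slope)
  post$diagnostics <- dplyr::bind_rows(
    post$diagnostics,
    tibble::tibble(term = "slope_hb_on_elm", rhat = NA_real_, ess = NA_real_))
  check_convergence(post, c("r_mu", "mu_elm_rpe", "mu_hb"),
                    rhat_limit, on_nonconvergence)
  post
}

jags_drug_mixed <- "
model {
  for (n in 1:N) {
    muH[n] <- inprod(X[n, ], betaH) + uH[m[n]]
    y1[n] ~ dnorm(muH[n], 1 / s2e[1])
    muE[n] <- inprod(X[n, ], betaE) + uE[m[n]]
             + re * sqrt(s2e[2] / s2e[1]) * (y1[n] - muH[n])
    y2[n] ~ dnorm(muE[n], 1 / (s2e[2] * (1 - pow(re, 2))))
  }
  for (i in 1:M) {
    uH[i] ~ dnorm(0, 1 / s2b[1])
    uE[i] ~ dnorm(rb * sqrt(s2b[2] / s2b[1]) * uH[i], 1 / (s2b[2] * (1 - pow(rb, 2))))
  }
  for (p in 1:P) {
    betaH[p] ~ dnorm(0, 1 / pow(pr_loc[1], 2))
    betaE[p] ~ dnorm(0, 1 / pow(pr_loc[2], 2))
  }
  for (k in 1:2) {
    sde[k] ~ dt(0, 1 / pow(pr_sc[k], 2), 1) T(0,)
    s2e[k] <- pow(sde[k], 2)
    sdb[k] ~ dt(0, 1 / pow(pr_sc[k], 2), 1) T(0,)
    s2b[k] <- pow(sdb[k], 2)
  }
  re ~ dunif(-0.999, 0.999)
  rb ~ dunif(-0.999, 0.999)
}
"

#' Bivariate linear mixed model of drug effects
#'
#' Jointly models the light-dark change in HB magnitude and ELM-RPE
#' thickness across paired control/treated sessions. Fixed effects per
#' trait: intercept, treatment session, drug-group main effects, and
#' treatment-by-drug-group interactions (reference level: control session
#' of the first drug group, ACZ when present). Mouse random intercepts are
#' bivariate with covariance Sigma_b; residuals are bivariate with
#' covariance Sigma_e. Coefficients have diffuse normal priors.
#'
#' @param data Tibble with `mouse_id`, `drug_group`, `treated` (0/1),
#'   `y_hb`, `y_elm_rpe`; every mouse needs one control and one treated row.
#' @inheritParams fit_joint_bivariate
#' @return An `octhb_post` with terms `beta_hb_<term>`,
#'   `beta_elm_rpe_<term>`, `sd_resid_*`, `sd_mouse_*`, `r_resid`,
#'   `r_mouse`.
#' @export
fit_drug_mixed <- function(data, priors = NULL, settings = sampler_settings(),
                           seed = 1, rhat_limit = 1.05,
                           on_nonconvergence = c("warn", "error")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  need <- c("mouse_id", "drug_group", "treated", "y_hb", "y_elm_rpe")
  stopifnot(all(need %in% names(data)))
  paired <- tidyr::pivot_wider(dplyr::count(data, .data$mouse_id, .data$treated),
                               names_from = "treated", values_from = "n")
  ok <- !is.na(paired[["0"]]) & !is.na(paired[["1"]]) &
    paired[["0"]] == 1 & paired[["1"]] == 1
  if (!all(ok))
    abort(paste("unpaired or duplicated mouse sessions:",
                paste(paired$mouse_id[!ok], collapse = ", ")))
  grp_levels <- unique(data$drug_group)
  if ("ACZ" %in% grp_levels) grp_levels <- c("ACZ", setdiff(grp_levels, "ACZ"))
  gf <- factor(data$drug_group, levels = grp_levels)
  X <- model.matrix(~ treated * gf, data = data.frame(treated = data$treated, gf = gf))
  terms <- c("intercept", "treat", grp_levels[-1],
             paste0("treat_", grp_levels[-1]))
  colnames(X) <- terms
  mice <- unique(data$mouse_id)
  ps1 <- prior_scales(data$y_hb, priors); ps2 <- prior_scales(data$y_elm_rpe, priors)
  dat <- list(y1 = data$y_hb, y2 = data$y_elm_rpe, X = X,
              m = match(data$mouse_id, mice), N = nrow(data),
              M = length(mice), P = ncol(X),
              pr_loc = c(ps1$location, ps2$location),
              pr_sc = c(ps1$scale, ps2$scale))
  mc <- jags_fit(jags_drug_mixed, dat,
                 c("betaH", "betaE", "sde", "sdb", "re", "rb"), settings, seed)
  post <- new_posterior(mc, "drug_mixed", settings,
                        list(terms = terms, groups = grp_levels,
                             reference = grp_levels[1]))
  ren <- c(setNames(paste0("beta_hb_", terms), sprintf("betaH[%d]", seq_along(terms))),
           setNames(paste0("beta_elm_rpe_", terms), sprintf("betaE[%d]", seq_along(terms))),
           "sde[1]" = "sd_resid_hb", "sde[2]" = "sd_resid_elm_rpe",
           "sdb[1]" = "sd_mouse_hb", "sdb[2]" = "sd_mouse_elm_rpe",
           "re" = "r_resid", "rb" = "r_mouse")
  idx <- match(names(ren), colnames(post$draws))
  colnames(post$draws)[idx[!is.na(idx)]] <- ren[!is.na(idx)]
  post$diagnostics$term[match(names(ren), post$diagnostics$term)] <- ren
  check_convergence(post, grep("^beta_", colnames(post$draws), value = TRUE),
                    rhat_limit, on_nonconvergence)
  post
}

#' Normalized drug response
#'
#' The scale-free drug effect `(Y_drug - Y_control) / Y_control`, computed
#' per posterior draw from the model-implied mean light-dark differences of
#' [fit_drug_mixed()]: `Y_control` is the fitted control-session mean of the
#' drug group and `Y_drug` its fitted treated-session mean. A value of -1 is
#' complete elimination of the light-dark response. Draws whose `Y_control`
#' has the opposite sign to the posterior median of `Y_control` are flagged;
#' if they exceed 1 percent of draws the functional is ill-defined and the
#' computation aborts.
#'
#' @param post Posterior from [fit_drug_mixed()].
#' @param drug_group Drug group label (e.g. `"DNP10"`).
#' @param trait `"hb"` or `"elm_rpe"`.
#' @param level Credibility level.
#' @return List of class `drug_response`: `draws`, `interval`
#'   (one-row tibble), `n_flagged`, `drug_group`, `trait`.
#' @export
normalized_drug_response <- function(post, drug_group, trait = c("hb", "elm_rpe"),
                                     level = 0.95) {
  trait <- match.arg(trait)
  stopifnot(inherits(post, "octhb_post"), post$model == "drug_mixed")
  ref <- post$data_info$reference
  b <- function(term) {
    nm <- paste0("beta_", trait, "_", term)
    if (nm %in% colnames(post$draws)) post$draws[, nm] else 0
  }
  y_ctl <- b("intercept") + if (drug_group != ref) b(drug_group) else 0
  y_drug <- y_ctl + b("treat") + if (drug_group != ref) b(paste0("treat_", drug_group)) else 0
  flagged <- sign(y_ctl) != sign(median(y_ctl))
  if (mean(flagged) > 0.01)
    abort(sprintf(paste("normalized response ill-defined: %.1f%% of draws have",
                        "a control mean crossing 0"), 100 * mean(flagged)))
  draws <- (y_drug - y_ctl) / y_ctl
  structure(list(draws = draws,
                 interval = dplyr::mutate(credibility_interval(draws, level),
                                          estimate = mean(draws), .before = 1),
                 n_flagged = sum(flagged),
                 drug_group = drug_group, trait = trait),
            class = "drug_response")
}

#' @export
print.drug_response <- function(x, ...) {
  cat(sprintf("normalized %s response, %s: %.3f [%.3f, %.3f]%s\n",
              x$drug_group, x$trait, x$interval$estimate, x$interval$lower,
              x$interval$upper,
              if (x$interval$excludes_zero) " *" else ""))
  invisible(x)
}

#' Contrast of two normalized drug responses
#'
#' Per-draw difference of [normalized_drug_response()] functionals, used to
#' compare doses or traits on a common scale.
#'
#' @param post Posterior from [fit_drug_mixed()].
#' @param a,b Lists `list(drug_group =, trait =)` defining the two
#'   responses; the contrast is a - b.
#' @param level Credibility level.
#' @return One-row tibble with `estimate`, `lower`, `upper`,
#'   `excludes_zero`.
#' @export
drug_response_contrast <- function(post, a, b, level = 0.95) {
  da <- normalized_drug_response(post, a$drug_group, a$trait, level)$draws
  db <- normalized_drug_response(post, b$drug_group, b$trait, level)$draws
  d <- da - db
  dplyr::mutate(credibility_interval(d, level), estimate = mean(d), .before = 1)
}

jags_hier_lm <- "
model {
  for (n in 1:N) {
    mu[n] <- inprod(X[n, ], beta) + u[g[n]]
    y[n] ~ dnorm(mu[n], 1 / s2e)
  }
  for (i in 1:M) { u[i] ~ dnorm(0, 1 / s2u) }
  for (p in 1:P) { beta[p] ~ dnorm(0, 1 / pow(pr_loc, 2)) }
  sde ~ dt(0, 1 / pow(pr_sc, 2), 1) T(0,)
  s2e <- pow(sde, 2)
  sdu ~ dt(0, 1 / pow(pr_sc, 2), 1) T(0,)
  s2u <- pow(sdu, 2)
}
"

# shared fitter for fixed effects + one random intercept; returns the
# posterior with beta renamed to the design column names and a pointwise
# log-likelihood matrix attached for information criteria
fit_hier_lm <- function(y, X, group_idx, model_name, settings, seed,
                        priors = NULL, data_info = list()) {
  ps <- prior_scales(y, priors)
  dat <- list(y = y, X = X, g = group_idx, N = length(y), M = max(group_idx),
              P = ncol(X), pr_loc = ps$location, pr_sc = ps$scale)
  mc <- jags_fit(jags_hier_lm, dat, c("beta", "u", "sde", "sdu"), settings, seed)
  post <- new_posterior(mc, model_name, settings, data_info)
  terms <- colnames(X)
  ren <- setNames(terms, sprintf("beta[%d]", seq_along(terms)))
  idx <- match(names(ren), colnames(post$draws))
  colnames(post$draws)[idx] <- ren
  post$diagnostics$term[match(names(ren), post$diagnostics$term)] <- ren
  B <- post$draws[, terms, drop = FALSE]
  U <- post$draws[, sprintf("u[%d]", seq_len(max(group_idx))), drop = FALSE]
  mu <- B %*% t(X) + U[, group_idx, drop = FALSE]
  ll <- matrix(stats::dnorm(rep(y, each = nrow(mu)), mu, post$draws[, "sde"],
                            log = TRUE), nrow = nrow(mu))
  attr(post, "loglik") <- ll
  post
}

#' Hierarchical model of F-actin peak fluorescence
#'
#' Fixed effects of group, side (apical vs basal, apical as reference) and
#' their interaction, with a random intercept for mouse nested within
#' group; diffuse normal priors on coefficients and half-Cauchy priors on
#' SDs. Groups observed on only one side lose their interaction column with
#' a warning.
#'
#' @param peaks Tibble from [factin_peak_table()]: `mouse_id`, `group`,
#'   `side`, `peak`.
#' @param priors,settings,seed As in [fit_group_hierarchical()].
#' @return An `octhb_post`; use [factin_contrast()] for group differences.
#' @export
fit_factin_model <- function(peaks, priors = NULL,
                             settings = sampler_settings(), seed = 1) {
  stopifnot(all(c("mouse_id", "group", "side", "peak") %in% names(peaks)))
  groups <- unique(peaks$group)
  if (length(groups) < 2 || any(table(peaks$group[!duplicated(peaks$mouse_id)]) < 2))
    abort("at least 2 groups with at least 2 mice each are required")
  gf <- factor(peaks$group, levels = groups)
  sf <- factor(peaks$side, levels = c("apical", "basal"))
  X <- model.matrix(~ gf * sf)
  colnames(X) <- c("intercept", paste0("group_", groups[-1]), "side_basal",
                   paste0("group_", groups[-1], ":side_basal"))
  tab <- table(gf, sf)
  incomplete <- rownames(tab)[apply(tab == 0, 1, any)]
  if (length(incomplete)) {
    warn(sprintf("group(s) missing one side: %s; dropping their interaction terms",
                 paste(incomplete, collapse = ", ")))
    drop_cols <- paste0("group_", incomplete, ":side_basal")
    X <- X[, setdiff(colnames(X), drop_cols), drop = FALSE]
  }
  mice <- unique(peaks$mouse_id)
  fit_hier_lm(peaks$peak, X, match(peaks$mouse_id, mice), "factin", settings,
              seed, priors,
              data_info = list(groups = groups, design_cols = colnames(X)))
}

#' Group difference in fitted F-actin peak fluorescence
#'
#' Per-draw difference of the model-implied cell means of two groups at a
#' given side (population level, random intercept at zero).
#'
#' @param post Posterior from [fit_factin_model()].
#' @param group_a,group_b Group labels; the contrast is a - b.
#' @param side `"apical"` or `"basal"`.
#' @param level Credibility level.
#' @return One-row tibble with `estimate`, `lower`, `upper`,
#'   `excludes_zero`.
#' @export
factin_contrast <- function(post, group_a, group_b, side = "apical",
                            level = 0.95) {
  stopifnot(inherits(post, "octhb_post"), post$model == "factin")
  cols <- post$data_info$design_cols
  cell <- function(g) {
    v <- setNames(numeric(length(cols)), cols)
    v["intercept"] <- 1
    gcol <- paste0("group_", g)
    if (gcol %in% cols) v[gcol] <- 1
    if (side == "basal") {
      v["side_basal"] <- 1
      icol <- paste0(gcol, ":side_basal")
      if (icol %in% cols) v[icol] <- 1
    }
    drop(post$draws[, cols, drop = FALSE] %*% v)
  }
  d <- cell(group_a) - cell(group_b)
  dplyr::mutate(credibility_interval(d, level), estimate = mean(d), .before = 1)
}

#' Polynomial ERG intensity-response model with information-criterion
#' selection
#'
#' Candidate models regress one wave's amplitude on polynomials of degree 1
#' to `max_degree` in centered log10 intensity, each with a drug main
#' effect, drug-by-intensity-term interactions, and a mouse random
#' intercept. WAIC and PSIS-LOO are computed for every candidate; a higher
#' degree is adopted only when it improves the selection criterion by at
#' least `margin` (default 4), otherwise the simpler model is preferred.
#' When more than 10 percent of Pareto-k diagnostics exceed 0.7 the
#' selection falls back to WAIC with a warning.
#'
#' @param data Long table from [intensity_response_table()].
#' @param wave `"a"`, `"b"` or `"c"`.
#' @param max_degree Highest polynomial degree considered.
#' @param margin Criterion-difference threshold favouring the simpler model.
#' @param criterion `"waic"` (default) or `"loo"`.
#' @param priors,settings,seed As in [fit_group_hierarchical()].
#' @return List of class `erg_fit`: `wave`, `selected_degree`, `selection`
#'   (per-degree criteria tibble), `posterior` (selected model), and the
#'   drug-coefficient credibility interval `drug_interval`.
#' @export
fit_erg_model <- function(data, wave = c("a", "b", "c"), max_degree = 3,
                          margin = 4, criterion = c("waic", "loo"),
                          priors = NULL, settings = sampler_settings(),
                          seed = 1) {
  wave <- match.arg(wave); criterion <- match.arg(criterion)
  ycol <- paste0(wave, "_wave")
  stopifnot(all(c(ycol, "log10_intensity", "treated", "mouse_id") %in% names(data)))
  if (length(unique(data$log10_intensity)) < 4)
    abort("at least 4 distinct stimulus intensities are required")
  y <- data[[ycol]]
  xc <- data$log10_intensity - mean(data$log10_intensity)
  drug <- as.numeric(data$treated)
  mice <- unique(data$mouse_id)
  gi <- match(data$mouse_id, mice)
  fits <- vector("list", max_degree)
  sel <- purrr::map_dfr(seq_len(max_degree), function(d) {
    # orthogonal polynomial basis: same span as raw powers, far better
    # conditioned for Gibbs sampling of the coefficients
    P <- stats::poly(xc, degree = d, raw = FALSE)
    X <- cbind(1, drug, P, P * drug)
    colnames(X) <- c("intercept", "drug", paste0("logI_", seq_len(d)),
                     paste0("drug:logI_", seq_len(d)))
    f <- fit_hier_lm(y, X, gi, paste0("erg_", wave, "_deg", d),
                     settings, seed = derive_seed(seed, "erg", wave, d),
                     priors = priors, data_info = list(degree = d))
    fits[[d]] <<- f
    ll <- attr(f, "loglik")
    w <- waic(ll); l <- psis_loo(ll)
    tibble::tibble(degree = d, waic = w$waic, p_waic = w$p_waic,
                   looic = l$estimates$looic,
                   frac_high_k = mean(l$pareto_k > 0.7))
  })
  use_loo <- criterion == "loo"
  if (use_loo && any(sel$frac_high_k > 0.1)) {
    warn("more than 10% of Pareto-k diagnostics exceed 0.7; selecting by WAIC")
    use_loo <- FALSE
  }
  crit <- if (use_loo) sel$looic else sel$waic
  chosen <- 1L
  for (d in seq_len(max_degree)[-1]) {
    if (crit[d] < crit[chosen] - margin) chosen <- d
  }
  post <- fits[[chosen]]
  structure(list(wave = wave, selected_degree = chosen, selection = sel,
                 criterion = if (use_loo) "loo" else "waic",
                 posterior = post,
                 drug_interval = credibility_interval(post, term = "drug")),
            class = "erg_fit")
}

#' @export
print.erg_fit <- function(x, ...) {
  cat(sprintf("<erg_fit> %s-wave: degree %d selected by %s\n", x$wave,
              x$selected_degree, x$criterion))
  print(x$selection)
  invisible(x)
}
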