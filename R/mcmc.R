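#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' MCMC sampler settings
#'
#' Defaults follow the analysis convention of four chains of 30,000
#' iterations thinned by 5, with the first half of each chain discarded as
#' warmup. Any sampler meeting the convergence contract (split R-hat below
#' the configured limit, adequate effective sample size) is acceptable;
#' reduced settings are appropriate for simulation studies.
#'
#' @param chains Number of chains.
#' @param iterations Total iterations per chain (warmup included).
#' @param thin Thinning interval applied after warmup.
#' @param warmup_frac Fraction of iterations discarded as warmup.
#' @param adapt JAGS adaptation steps.
#' @return List of class `sampler_settings`.
#' @export
sampler_settings <- function(chains = 4, iterations = 30000, thin = 5,
                             warmup_frac = 0.5, adapt = 500) {
  stopifnot(chains >= 1, iterations >= 20, thin >= 1,
            warmup_frac > 0, warmup_frac < 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations), thin = as.integer(thin),
                 warmup_frac = warmup_frac, adapt = as.integer(adapt)),
            class = "sampler_settings")
}

# run a JAGS model and return a coda::mcmc.list; every chain's RNG is seeded
# from `seed` so results are reproducible
jags_fit <- function(model_string, data, monitors, settings, seed,
                     inits = NULL) {
  warmup <- floor(settings$iterations * settings$warmup_frac)
  keep <- settings$iterations - warmup
  init_list <- lapply(seq_len(settings$chains), function(i) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = derive_seed(seed, "chain", i))
    if (!is.null(inits)) ini <- c(ini, inits(i))
    ini
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = init_list, n.chains = settings$chains,
                          n.adapt = settings$adapt, quiet = TRUE)
  stats::update(jm, warmup, progress.bar = "none")
  rjags::coda.samples(jm, monitors, n.iter = keep, thin = settings$thin,
                      progress.bar = "none")
}

# wrap an mcmc.list as the package's posterior container
new_posterior <- function(mcmc, model, settings, data_info = list()) {
  mat <- as.matrix(mcmc)
  per_chain <- lapply(mcmc, as.matrix)
  diag_tbl <- tibble::tibble(
    term = colnames(mat),
    rhat = vapply(colnames(mat), function(p)
      split_rhat(vapply(per_chain, function(ch) ch[, p], numeric(nrow(per_chain[[1]])))),
      numeric(1)),
    ess = tryCatch(as.numeric(coda::effectiveSize(mcmc)[colnames(mat)]),
                   error = function(e) rep(NA_real_, ncol(mat))))
  structure(list(draws = mat, n_chains = length(mcmc),
                 n_iter = nrow(per_chain[[1]]), model = model,
                 settings = settings, diagnostics = diag_tbl,
                 data_info = data_info),
            class = "octhb_post")
}

#' @export
print.octhb_post <- function(x, ...) {
  cat(sprintf("<octhb posterior: %s> %d chains x %d retained draws, %d parameters\n",
              x$model, x$n_chains, x$n_iter, ncol(x$draws)))
  cat(sprintf("  max split-Rhat %.3f, min ESS %.0f\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE)))
  invisible(x)
}

#' Extract draws of one parameter
#'
#' @param post An `octhb_post` posterior.
#' @param term Parameter name as in `tidy(post)$term`.
#' @return Numeric vector of pooled posterior draws.
#' @export
post_draws <- function(post, term) {
  stopifnot(inherits(post, "octhb_post"))
  if (!term %in% colnames(post$draws))
    abort(sprintf("no parameter '%s'; available: %s", term,
                  paste(head(colnames(post$draws), 20), collapse = ", ")))
  as.numeric(post$draws[, term])
}

#' Posterior draws as a tibble
#'
#' @param x An `octhb_post` posterior.
#' @param ... Unused.
#' @return Tibble with `.chain`, `.iteration` and one column per parameter.
#' @export
as_tibble.octhb_post <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(.chain = rep(seq_len(x$n_chains), each = x$n_iter),
                   .iteration = rep(seq_len(x$n_iter), x$n_chains)),
    tibble::as_tibble(x$draws))
}

#' Tidy posterior summaries
#'
#' One row per parameter: posterior mean, SD, percentile credibility
#' interval, split R-hat and effective sample size.
#'
#' @param x An `octhb_post` posterior.
#' @param conf.level Credibility level.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `rhat`, `ess`.
#' @export
tidy.octhb_post <- function(x, conf.level = 0.95, ...) {
  a <- (1 - conf.level) / 2
  tibble::tibble(
    term = colnames(x$draws),
    estimate = colMeans(x$draws),
    std.error = apply(x$draws, 2, sd),
    conf.low = apply(x$draws, 2, quantile, probs = a),
    conf.high = apply(x$draws, 2, quantile, probs = 1 - a)) |>
    dplyr::left_join(x$diagnostics, by = "term")
}

#' One-row posterior fit summary
#'
#' @param x An `octhb_post` posterior.
#' @param ... Unused.
#' @return Tibble: model, chains, retained draws, max R-hat, min ESS.
#' @export
glance.octhb_post <- function(x, ...) {
  tibble::tibble(model = x$model, chains = x$n_chains,
                 draws = x$n_chains * x$n_iter,
                 max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
                 min_ess = min(x$diagnostics$ess, na.rm = TRUE))
}

#' Percentile credibility interval
#'
#' Empirical central interval from the observed percentiles of posterior
#' draws (linear interpolation of order statistics). `excludes_zero` is the
#' conventional significance flag: the interval lies entirely on one side
#' of zero.
#'
#' @param draws Numeric vector of at least 100 posterior draws, or an
#'   `octhb_post` together with `term`.
#' @param level Credibility level (default 0.95).
#' @param term Parameter name when `draws` is a posterior object.
#' @return One-row tibble: `lower`, `upper`, `level`, `excludes_zero`.
#' @export
#' @examples
#' credibility_interval(rnorm(1000))
credibility_interval <- function(draws, level = 0.95, term = NULL) {
  if (inherits(draws, "octhb_post")) draws <- post_draws(draws, term)
  if (length(draws) < 100)
    abort("at least 100 draws are required for a percentile interval")
  a <- (1 - level) / 2
  q <- unname(quantile(draws, c(a, 1 - a), type = 7))
  tibble::tibble(lower = q[1], upper = q[2], level = level,
                 excludes_zero = q[1] > 0 || q[2] < 0)
}

# convergence gate shared by the fitting functions
check_convergence <- function(post, params, rhat_limit, action) {
  d <- post$diagnostics[post$diagnostics$term %in% params, ]
  bad <- d$term[!is.na(d$rhat) & d$rhat > rhat_limit]
  if (length(bad)) {
    msg <- sprintf("split R-hat above %.2f for: %s (max %.3f); increase iterations",
                   rhat_limit, paste(bad, collapse = ", "),
                   max(d$rhat, na.rm = TRUE))
    if (action == "error") abort(msg) else warn(msg)
  }
  invisible(post)
}
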