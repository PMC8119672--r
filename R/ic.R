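# Information criteria for posterior predictive comparison: WAIC and
# Pareto-smoothed importance-sampling leave-one-out (PSIS-LOO), computed from
# a pointwise log-likelihood matrix (draws x observations).

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Widely applicable information criterion
#'
#' @param loglik Matrix of pointwise log-likelihood values, posterior draws
#'   in rows, observations in columns.
#' @return One-row tibble: `waic`, `elpd`, `p_waic`.
#' @export
waic <- function(loglik) {
  S <- nrow(loglik)
  lppd <- sum(apply(loglik, 2, function(l) logsumexp(l) - log(S)))
  p <- sum(apply(loglik, 2, var))
  tibble::tibble(waic = -2 * (lppd - p), elpd = lppd - p, p_waic = p)
}

# generalized Pareto fit to exceedances (Zhang & Stephens 2009 profile
# posterior mean). Returns the shape in the convention where a heavy tail
# gives positive k (the Pareto-k diagnostic) and the matching scale.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30 + floor(sqrt(n))
  prior_b <- 3
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  if (xstar <= 0) xstar <- mean(x[x > 0])
  if (!is.finite(xstar) || x[n] <= 0) return(list(k = -Inf, sigma = NA_real_))
  theta <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (prior_b * xstar)
  kz <- vapply(theta, function(th) -mean(log1p(-th * x)), numeric(1))
  l_j <- n * (log(theta / kz) + kz - 1)
  l_j[!is.finite(l_j)] <- -Inf
  w <- exp(l_j - logsumexp(l_j))
  th_hat <- sum(w * theta)
  k <- mean(log1p(-th_hat * x))
  list(k = k, sigma = -k / th_hat)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

#' PSIS-LOO: leave-one-out cross-validation by Pareto-smoothed importance
#' sampling
#'
#' For each observation the importance ratios (inverse pointwise
#' likelihoods) have their upper tail replaced by expected order statistics
#' of a generalized Pareto fit; the fitted shape parameter `k` is the
#' reliability diagnostic (values above 0.7 flag an unreliable estimate).
#'
#' @inheritParams waic
#' @return List with a one-row tibble `estimates` (`looic`, `elpd_loo`) and
#'   the per-observation `pareto_k` vector.
#' @export
psis_loo <- function(loglik) {
  S <- nrow(loglik); N <- ncol(loglik)
  elpd_i <- numeric(N); k_i <- numeric(N)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  for (i in seq_len(N)) {
    lw <- -loglik[, i]
    lw <- lw - max(lw)
    ord <- order(lw)
    tail_ids <- ord[(S - M + 1):S]
    cut <- exp(lw[ord[S - M]])
    exceed <- exp(lw[tail_ids]) - cut
    if (length(unique(exceed)) < 5) {
      k_i[i] <- -Inf
    } else {
      fit <- gpd_fit(exceed)
      k_i[i] <- fit$k
      if (is.finite(fit$k) && is.finite(fit$sigma)) {
        p <- (seq_len(M) - 0.5) / M
        smoothed <- log(cut + gpd_quantile(p, fit$k, fit$sigma))
        lw[tail_ids[order(lw[tail_ids])]] <- pmin(smoothed, 0)
      }
    }
    lw <- lw - logsumexp(lw)
    elpd_i[i] <- logsumexp(lw + loglik[, i])
  }
  elpd <- sum(elpd_i)
  list(estimates = tibble::tibble(looic = -2 * elpd, elpd_loo = elpd),
       pareto_k = k_i)
}
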