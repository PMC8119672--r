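#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats rnorm quantile median var sd mad setNames model.matrix
#'   runif rbinom complete.cases
#' @importFrom tibble tibble as_tibble
#' @importFrom utils head tail
NULL

MOD31 <- 2147483647 # 2^31 - 1

#' Derive a reproducible child seed from a master seed and a label
#'
#' All randomness in the package flows from one user-supplied integer seed.
#' Stages derive their own seeds by hashing the master seed together with a
#' stage label, so adding or reordering stages never perturbs the random
#' streams of other stages.
#'
#' @param seed Master integer seed.
#' @param ... Character or numeric labels identifying the consumer.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "phantom", 3)
derive_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                         character(1)), collapse = "/")
  h <- as.numeric(seed) %% MOD31
  for (ch in utf8ToInt(labels)) {
    # 69069: classic multiplicative congruential multiplier; products stay < 2^53
    h <- (h * 69069 + ch) %% MOD31
  }
  as.integer(h %% (MOD31 - 2) + 1)
}

# build a 2x2 covariance matrix from sds and a correlation
cov2 <- function(sds, r) {
  m <- diag(sds^2)
  m[1, 2] <- m[2, 1] <- r * sds[1] * sds[2]
  m
}

# draw n rows from MVN(mu, Sigma); tolerates PSD (rank-deficient) Sigma
rmvn <- function(n, mu, sigma) {
  p <- length(mu)
  e <- eigen(sigma, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  L <- e$vectors %*% diag(sqrt(ev), p)
  z <- matrix(rnorm(n * p), n, p)
  sweep(z %*% t(L), 2, mu, "+")
}

check_psd <- function(m, what = "covariance matrix") {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    abort(paste(what, "must be symmetric"))
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    abort(paste(what, "must be positive semi-definite"))
  invisible(m)
}

# beta(mean, variance) -> shape parameters, with admissibility check
beta_shapes <- function(mean, variance) {
  if (mean <= 0 || mean >= 1) abort("beta mean must be in (0, 1)")
  bound <- mean * (1 - mean)
  if (variance <= 0 || variance >= bound)
    abort(sprintf("beta variance must be in (0, %.4g) for mean %.3g", bound, mean))
  phi <- bound / variance - 1
  c(shape1 = mean * phi, shape2 = (1 - mean) * phi)
}

# split-Rhat (Gelman et al.): x is an iterations x chains matrix
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- floor(nrow(x) / 2)
  if (n < 2) return(NA_real_)
  xs <- cbind(x[seq_len(n), , drop = FALSE],
              x[seq(nrow(x) - n + 1, nrow(x)), , drop = FALSE])
  W <- mean(apply(xs, 2, var))
  if (W == 0) return(1)
  B <- n * var(colMeans(xs))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# local maxima of a numeric vector; plateaus yield their most vitreal index.
# The tolerance admits near-flat plateaus (e.g. a chord segment ending at a
# peak of nominally equal height): 1e-3 grayscale is far below meaningful
# 8-bit image structure but far above floating-point slack.
local_maxima <- function(x, tol = 1e-3) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  which(x[i] > x[i - 1] - tol & x[i] >= x[i + 1] - tol) + 1L
}

# tallest local maximum (of the full profile) within index window [lo, hi];
# heights are compared after quantization to 1e-5 grayscale so that
# floating-point plateaus count as ties, and ties resolve to the most
# vitreal (smallest) index
tallest_peak <- function(x, lo, hi) {
  lo <- max(1L, as.integer(ceiling(lo))); hi <- min(length(x), as.integer(floor(hi)))
  if (hi < lo) return(NA_integer_)
  pk <- local_maxima(x)
  pk <- pk[pk >= lo & pk <= hi]
  if (!length(pk)) return(NA_integer_)
  pk[order(-round(x[pk] * 1e5), pk)][1]
}
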