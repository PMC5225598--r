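# Empirical significance calibration of Q-scores.
#
# Q-scores of random (unrelated) pocket pairs form the null distribution; it
# is modeled with a generalized extreme value (GEV) law with shape k,
# location mu and scale sigma, whose survival function
#   P(s > x) = 1 - exp(-[1 + k (x - mu) / sigma]^(-1/k))
# turns an observed Q into a P-value. Fitting is maximum likelihood
# initialized from L-moment estimates.

#' EVD (generalized extreme value) parameters
#'
#' @param k shape; `k = 0` is the Gumbel limit.
#' @param mu location.
#' @param sigma scale, > 0.
#' @export
evd_params <- function(k, mu, sigma) {
  stopifnot(is.finite(k), is.finite(mu), is.finite(sigma), sigma > 0)
  structure(list(k = unname(k), mu = unname(mu), sigma = unname(sigma)),
            class = "EVDParams")
}

# GEV distribution functions in the shape convention above (k is the usual
# GEV shape xi). Support: 1 + k (x - mu) / sigma > 0.
.pgev <- function(x, k, mu, sigma) {
  z <- (x - mu) / sigma
  if (abs(k) < 1e-10) return(exp(-exp(-z)))
  arg <- 1 + k * z
  out <- numeric(length(x))
  ok <- arg > 0
  out[ok] <- exp(-arg[ok]^(-1 / k))
  # outside the support: CDF is 0 below (k > 0) and 1 above (k < 0)
  out[!ok] <- if (k > 0) 0 else 1
  out
}

.qgev <- function(p, k, mu, sigma) {
  if (abs(k) < 1e-10) return(mu - sigma * log(-log(p)))
  mu + sigma * ((-log(p))^(-k) - 1) / k
}

#' Random GEV deviates
#'
#' Inverse-CDF sampler for the calibration null; used by tests and the
#' acceptance checks for parameter recovery on self-generated data.
#'
#' @param n number of draws.
#' @param params an [evd_params()] object.
#' @export
rgev <- function(n, params) .qgev(runif(n), params$k, params$mu, params$sigma)

# Sample L-moment GEV estimates (Hosking): moment estimators used to
# initialize the likelihood optimization and as a fallback.
.lmom_gev <- function(x) {
  x <- sort(x)
  n <- length(x)
  i <- seq_len(n)
  b0 <- mean(x)
  b1 <- sum((i - 1) / (n - 1) * x) / n
  b2 <- sum((i - 1) * (i - 2) / ((n - 1) * (n - 2)) * x) / n
  l1 <- b0; l2 <- 2 * b1 - b0; l3 <- 6 * b2 - 6 * b1 + b0
  t3 <- l3 / l2
  cc <- 2 / (3 + t3) - log(2) / log(3)
  kh <- 7.8590 * cc + 2.9554 * cc^2           # Hosking's k = -shape
  g <- gamma(1 + kh)
  sigma <- l2 * kh / ((1 - 2^(-kh)) * g)
  mu <- l1 - sigma * (1 - g) / kh
  c(k = -kh, mu = mu, sigma = sigma)
}

.gev_nll <- function(theta, x) {
  mu <- theta[1]; sigma <- exp(theta[2]); k <- theta[3]
  z <- (x - mu) / sigma
  if (abs(k) < 1e-10) {
    return(length(x) * log(sigma) + sum(z) + sum(exp(-z)))
  }
  arg <- 1 + k * z
  if (any(arg <= 0)) return(1e10)
  length(x) * log(sigma) + (1 + 1 / k) * sum(log(arg)) + sum(arg^(-1 / k))
}

#' Fit a generalized extreme value distribution to Q-score samples
#'
#' Maximum-likelihood GEV fit initialized by L-moment estimates; records the
#' Kolmogorov--Smirnov statistic of the fit as a goodness measure.
#'
#' @param q_samples at least 100 finite values with nonzero variance.
#' @return A `CalibrationModel`: `params` ([evd_params()]), `n_samples`,
#'   `fit_method` (`"mle"`, or `"lmoments"` if the optimizer failed to
#'   improve on the initial estimates), `ks` statistic.
#' @export
fit_evd <- function(q_samples) {
  x <- q_samples[is.finite(q_samples)]
  if (length(x) < 100) stop("need at least 100 finite samples to fit")
  if (sd(x) < 1e-12) stop("degenerate (constant) samples: cannot fit an EVD")
  init <- .lmom_gev(x)
  if (!all(is.finite(init)) || init["sigma"] <= 0)
    init <- c(k = 0.0, mu = mean(x) - 0.45 * sd(x), sigma = 0.78 * sd(x))
  theta0 <- c(init["mu"], log(init["sigma"]), init["k"])
  fit <- tryCatch(
    optim(theta0, .gev_nll, x = x, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(fit) && is.finite(fit$value) &&
      fit$value <= .gev_nll(theta0, x)) {
    params <- evd_params(k = fit$par[3], mu = fit$par[1],
                         sigma = exp(fit$par[2]))
    method <- "mle"
  } else {
    params <- evd_params(k = init["k"], mu = init["mu"],
                         sigma = init["sigma"])
    method <- "lmoments"
  }
  xs <- sort(x)
  Fhat <- .pgev(xs, params$k, params$mu, params$sigma)
  n <- length(xs)
  ks <- max(abs(Fhat - seq_len(n) / n), abs(Fhat - (seq_len(n) - 1) / n))
  structure(list(params = params, n_samples = n, fit_method = method,
                 ks = ks), class = "CalibrationModel")
}

#' @export
print.CalibrationModel <- function(x, ...) {
  cat(sprintf(
    "CalibrationModel (%s, n = %d): k = %.4f, mu = %.5f, sigma = %.5f, KS = %.4f\n",
    x$fit_method, x$n_samples, x$params$k, x$params$mu, x$params$sigma, x$ks))
  invisible(x)
}

#' P-value of a Q-score under the calibrated null
#'
#' Survival probability `P(s > q)` of the fitted GEV. Outside the support
#' the value is clamped: below the lower endpoint (k > 0) it is 1, above the
#' upper endpoint (k < 0) it is 0. For `|k| < 1e-10` the Gumbel limit
#' `1 - exp(-exp(-(q - mu)/sigma))` is used.
#'
#' @param q Q-score (vectorized).
#' @param params an [evd_params()] object or a `CalibrationModel`.
#' @export
p_value <- function(q, params) {
  if (inherits(params, "CalibrationModel")) params <- params$params
  if (any(!is.finite(q))) stop("non-finite q")
  1 - .pgev(q, params$k, params$mu, params$sigma)
}

#' Sample random background pocket pairs
#'
#' Draws `n_pairs` uniformly random pairs of distinct pockets (with
#' replacement across pairs), reproducibly from `seed`.
#'
#' @param background list of `PocketStructure`, length >= 2.
#' @param n_pairs number of pairs.
#' @param seed RNG seed.
#' @return Two-column integer matrix of pocket indices.
#' @export
sample_background_pairs <- function(background, n_pairs, seed) {
  n <- length(background)
  if (n < 2) stop("background must contain at least 2 pockets")
  set.seed(seed)
  i <- sample.int(n, n_pairs, replace = TRUE)
  j <- sample.int(n - 1L, n_pairs, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)  # uniform over distinct partners
  cbind(a = i, b = j)
}

#' Calibrate the Q-score null from background pockets
#'
#' Aligns `n_pairs` random background pocket pairs and fits the GEV null to
#' their Q-scores.
#'
#' @param background list of `PocketStructure` (a non-redundant background
#'   set; real use cuts these from any non-redundant protein set, tests use
#'   the synthetic generator).
#' @param n_pairs number of random pairs (default 20000).
#' @param seed RNG seed for pair sampling.
#' @param params an [alignment_params()] object.
#' @param progress log every this many pairs (0 = silent).
#' @return A `CalibrationModel`; the raw Q-scores are attached as
#'   `attr(, "q_samples")`.
#' @export
calibrate_background <- function(background, n_pairs = 20000, seed = 1,
                                 params = alignment_params(), progress = 0) {
  pairs <- sample_background_pairs(background, n_pairs, seed)
  q <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- background[[pairs[k, 1]]]
    b <- background[[pairs[k, 2]]]
    raw <- .align_xyz(a$xyz, b$xyz, params)
    q[k] <- raw$q
    if (progress > 0 && k %% progress == 0)
      message(sprintf("[calibrate] %d / %d pairs", k, nrow(pairs)))
  }
  model <- fit_evd(q)
  attr(model, "q_samples") <- q
  model
}

#' Write / read a calibration model as JSON
#'
#' @param model a `CalibrationModel`.
#' @param path JSON file.
#' @export
write_calibration <- function(model, path) {
  jsonlite::write_json(
    list(k = model$params$k, mu = model$params$mu, sigma = model$params$sigma,
         n_samples = model$n_samples, fit_method = model$fit_method,
         ks = model$ks),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(params = evd_params(j$k, j$mu, j$sigma),
                 n_samples = j$n_samples, fit_method = j$fit_method,
                 ks = j$ks), class = "CalibrationModel")
}
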