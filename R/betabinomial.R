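# Beta-binomial null model for network crosstalk: counts x_i in 0..n are
# Binomial(n, p) with p ~ Beta(alpha, beta), capturing the over-dispersion
# of crosstalk across degree-matched random sets.

.betabinom_loglik <- function(x, n, alpha, beta) {
  sum(lchoose(n, x) + lbeta(x + alpha, n - x + beta) - lbeta(alpha, beta))
}

#' Fit a beta-binomial distribution by maximum likelihood
#'
#' Maximizes the beta-binomial log-likelihood over `(alpha, beta) > 0`,
#' initialized at the method-of-moments estimate. When the sample shows no
#' over-dispersion relative to a binomial (sample variance at or below the
#' binomial variance at the sample-mean proportion) the likelihood has no
#' interior maximum in the concentration; the fit then falls back to a large
#' concentration `alpha + beta = 1e6` at the sample-mean proportion
#' (effectively binomial) with a warning.
#'
#' @param samples nonnegative integer counts, each at most `n_trials`.
#' @param n_trials the number of trials (maximum possible count).
#' @return an object of class `betabinom_fit`: list with `alpha`, `beta`,
#'   `n_trials`, `log_likelihood`, `mean`, `sd`, and logical `fallback`.
#' @export
fit_betabinomial <- function(samples, n_trials) {
  stopifnot(length(samples) >= 2, n_trials >= 1)
  samples <- as.numeric(samples)
  if (any(samples < 0) || any(samples > n_trials)) {
    stop("all samples must lie in [0, n_trials]")
  }
  n <- n_trials
  m <- mean(samples)
  v <- var(samples)
  p_hat <- min(max(m / n, 1e-9), 1 - 1e-9)
  binom_var <- n * p_hat * (1 - p_hat)

  fallback_fit <- function(reason) {
    warning(sprintf("beta-binomial fit degenerate (%s); %s", reason,
                    "falling back to alpha + beta = 1e6 at the sample-mean proportion"))
    gamma <- 1e6
    a <- p_hat * gamma
    b <- (1 - p_hat) * gamma
    .new_betabinom_fit(a, b, n, .betabinom_loglik(samples, n, a, b),
                       fallback = TRUE)
  }

  if (v == 0) return(fallback_fit("all samples identical"))
  if (v <= binom_var) return(fallback_fit("no over-dispersion"))

  # Method of moments: (gamma + n)/(gamma + 1) = v / (n p (1-p)).
  r <- v / binom_var
  gamma0 <- if (r < n) (n - r) / (r - 1) else 1
  gamma0 <- max(gamma0, 1e-3)
  par0 <- log(c(p_hat * gamma0, (1 - p_hat) * gamma0))
  ll0 <- .betabinom_loglik(samples, n, exp(par0[1]), exp(par0[2]))

  negll <- function(par) {
    -.betabinom_loglik(samples, n, exp(par[1]), exp(par[2]))
  }
  opt <- stats::optim(par0, negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  a <- exp(opt$par[1]); b <- exp(opt$par[2])
  ll <- -opt$value
  if (ll < ll0) { # optimizer contract: never worse than the start
    a <- exp(par0[1]); b <- exp(par0[2]); ll <- ll0
  }
  .new_betabinom_fit(a, b, n, ll, fallback = FALSE)
}

.new_betabinom_fit <- function(alpha, beta, n_trials, log_likelihood,
                               fallback) {
  g <- alpha + beta
  mu <- n_trials * alpha / g
  va <- n_trials * alpha * beta * (g + n_trials) / (g^2 * (g + 1))
  structure(
    list(alpha = alpha, beta = beta, n_trials = as.integer(n_trials),
         log_likelihood = log_likelihood, mean = mu, sd = sqrt(va),
         fallback = fallback),
    class = "betabinom_fit"
  )
}

#' @export
print.betabinom_fit <- function(x, ...) {
  cat(sprintf(
    "beta-binomial fit: alpha = %.4g, beta = %.4g, n = %d (mean %.3g, sd %.3g)%s\n",
    x$alpha, x$beta, x$n_trials, x$mean, x$sd,
    if (x$fallback) " [binomial fallback]" else ""))
  invisible(x)
}
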