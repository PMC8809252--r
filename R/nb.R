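#' Negative-binomial parameter pair
#'
#' Container for the mean/dispersion parameterization used throughout the
#' package: a negative binomial with mean `mu` and dispersion `theta` has
#' variance `mu + mu^2 / theta`, so `theta -> Inf` recovers the Poisson.
#' Larger `theta` means less overdispersion.
#'
#' @param mu Non-negative mean (vector or matrix).
#' @param theta Positive dispersion, recyclable against `mu`.
#' @return An object of class `nb_params`.
#' @examples
#' nb_params(mu = 2, theta = 1.5)
#' @export
nb_params <- function(mu, theta) {
  if (any(mu < 0)) stop("nb_params: mu must be non-negative")
  if (any(theta <= 0)) stop("nb_params: theta must be strictly positive")
  structure(list(mu = mu, theta = theta), class = "nb_params")
}

#' @export
print.nb_params <- function(x, ...) {
  cat("<nb_params> mu:", format(head(x$mu, 3)),
      if (length(x$mu) > 3) "..." else "",
      " theta:", format(head(x$theta, 3)), "\n")
  invisible(x)
}

# mu floor keeps log-pmf finite at mu = 0 (k = 0 then has probability ~ 1,
# k > 0 a very large negative but finite log-probability)
.MU_FLOOR <- 1e-8

#' Negative-binomial log-probability mass
#'
#' Log-pmf of counts under the mean/dispersion negative binomial
#' (variance `mu + mu^2/theta`). The mean is floored at `1e-8` so the
#' degenerate `mu = 0` case stays finite.
#'
#' @param k Non-negative integer counts.
#' @param params An [nb_params] object (recycled against `k`).
#' @return Log-probabilities, same shape as `k`.
#' @examples
#' nb_logpmf(0:5, nb_params(mu = 2, theta = 1.5))
#' @export
nb_logpmf <- function(k, params) {
  stopifnot(inherits(params, "nb_params"))
  if (any(k < 0) || any(k != floor(k))) {
    stop("nb_logpmf: k must be non-negative integers")
  }
  mu <- pmax(params$mu, .MU_FLOOR)
  stats::dnbinom(k, size = params$theta, mu = mu, log = TRUE)
}

#' Foreground/background negative-binomial mixture log-pmf
#'
#' Two-component NB mixture with a shared dispersion, the observation model
#' for multiplexed antibody counts: a foreground component tied to the
#' signal of interest and a background component for ambient capture.
#'
#' @param k Non-negative integer counts.
#' @param fg,bg [nb_params] for the foreground and background components;
#'   their dispersions must match.
#' @param w_fg Foreground mixing weight in `[0, 1]`.
#' @return Log-probabilities computed stably via log-sum-exp.
#' @export
mixture_nb_logpmf <- function(k, fg, bg, w_fg) {
  stopifnot(inherits(fg, "nb_params"), inherits(bg, "nb_params"))
  if (any(abs(fg$theta - bg$theta) > 1e-12)) {
    stop("mixture_nb_logpmf: foreground and background must share dispersion theta")
  }
  if (any(w_fg < 0 | w_fg > 1)) stop("mixture_nb_logpmf: w_fg must lie in [0, 1]")
  lf <- nb_logpmf(k, fg)
  lb <- nb_logpmf(k, bg)
  logaddexp(log(w_fg) + lf, log1p(-w_fg) + lb)
}

# elementwise stable log(exp(a) + exp(b)); -Inf handled
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  m[is.infinite(m) & m < 0] <- 0 # both -Inf -> result -Inf via log(0+0) guard below
  r <- m + log(exp(a - m) + exp(b - m))
  r[a == -Inf & b == -Inf] <- -Inf
  r
}

# stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Analytic gradients of the NB log-pmf
#'
#' Partial derivatives of `log NB(k; mu, theta)` with respect to the mean
#' and the dispersion, used by model gradient callables.
#'
#' @param k Counts; `mu`, `theta` as in [nb_logpmf()] (recycled).
#' @return Elementwise gradient, same shape as the broadcast inputs.
#' @export
nb_grad_mu <- function(k, mu, theta) {
  mu <- pmax(mu, .MU_FLOOR)
  k / mu - (k + theta) / (mu + theta)
}

#' @rdname nb_grad_mu
#' @export
nb_grad_theta <- function(k, mu, theta) {
  mu <- pmax(mu, .MU_FLOOR)
  digamma(k + theta) - digamma(theta) + log(theta) + 1 -
    log(theta + mu) - (k + theta) / (theta + mu)
}
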