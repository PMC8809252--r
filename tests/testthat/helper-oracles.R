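# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the NB oracle is the explicit Gamma-function
# formula, gradients are checked by central finite differences, and the
# grid-search deconvolution oracle enumerates the simplex.

# log NB(k; mu, theta) from the Gamma-function formula
nb_oracle <- function(k, mu, theta) {
  lgamma(k + theta) - lgamma(theta) - lfactorial(k) +
    theta * log(theta / (theta + mu)) + k * log(mu / (theta + mu))
}

# central finite-difference gradient of f at x (vector), elementwise
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}

# all compositions of the K-simplex on a grid with the given step
simplex_grid <- function(K, step = 0.02) {
  n <- round(1 / step)
  if (K == 3) {
    out <- list()
    idx <- 1
    for (i in 0:n) for (j in 0:(n - i)) {
      out[[idx]] <- c(i, j, n - i - j) / n
      idx <- idx + 1
    }
    do.call(rbind, out)
  } else {
    stop("simplex_grid: only K = 3 supported")
  }
}

# Bernoulli presence simulator for the abundance-curve tests: baseline
# presence probability 0.5, condition B multiplies the odds by `effect`
# inside the pericentral band (z > 0.6, logistic edge)
simulate_presence <- function(n_per_condition, effect, seed,
                              baseline = 0.5) {
  set.seed(seed)
  n <- 2 * n_per_condition
  z <- stats::runif(n)
  cond <- rep(c("A", "B"), each = n_per_condition)
  odds <- rep(baseline / (1 - baseline), n)
  boost <- 1 + (effect - 1) * stats::plogis((z - 0.6) / 0.08)
  odds[cond == "B"] <- odds[cond == "B"] * boost[cond == "B"]
  p <- odds / (1 + odds)
  list(presence = stats::runif(n) < p, z = z, condition = cond)
}

# small deconvolution fixture shared by several tests (memoized)
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, make) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- make()
  .fixture_env[[name]]
}
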