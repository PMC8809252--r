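#' Amortization network
#'
#' A small fully-connected encoder mapping per-spot features to variational
#' parameters, with the fixed architecture Linear(100) - BatchNorm - ReLU -
#' Linear(100) - ReLU - Linear(d_out). Forward and backward passes are
#' implemented explicitly; BatchNorm uses batch statistics in training mode
#' and stored running statistics in evaluation mode, so transfer of a trained
#' encoder to new data is deterministic.
#'
#' @param d_in Input feature dimension.
#' @param d_out Output dimension (2 for a location/log-scale pair).
#' @param hidden Hidden layer widths (default `c(100, 100)`).
#' @param seed Seed for weight initialization.
#' @param init_out_bias Initial bias of the output layer (length `d_out`).
#' @param input_dropout Fraction of input features randomly dropped (inverted
#'   dropout) per training step; regularizes the encoder toward functions of
#'   many features so it transfers to unseen spots. Inactive at evaluation.
#' @return An object of class `mlp`.
#' @export
mlp <- function(d_in, d_out = 2, hidden = c(100, 100), seed = 1,
                init_out_bias = c(0, -1), input_dropout = 0.2) {
  set.seed(seed)
  h1 <- hidden[1]; h2 <- hidden[2]
  he <- function(fan_in) sqrt(2 / fan_in)
  par <- list(
    W1 = matrix(stats::rnorm(d_in * h1, 0, he(d_in)), d_in, h1),
    b1 = numeric(h1),
    gamma = rep(1, h1), beta = numeric(h1),
    W2 = matrix(stats::rnorm(h1 * h2, 0, he(h1)), h1, h2),
    b2 = numeric(h2),
    W3 = matrix(stats::rnorm(h2 * d_out, 0, 0.01), h2, d_out),
    b3 = rep_len(init_out_bias, d_out)
  )
  structure(list(par = par, running_mean = numeric(h1), running_var = rep(1, h1),
                 momentum = 0.1, bn_eps = 1e-5, d_in = d_in, d_out = d_out,
                 input_dropout = input_dropout, feature_names = NULL),
            class = "mlp")
}

#' @export
print.mlp <- function(x, ...) {
  cat("<mlp>", x$d_in, "->", ncol(x$par$W1), "-> bn/relu ->",
      ncol(x$par$W2), "-> relu ->", x$d_out, "\n")
  invisible(x)
}

# Forward pass. training=TRUE uses batch statistics (and updates running
# statistics in the returned net); training=FALSE uses running statistics.
mlp_forward <- function(net, X, training = FALSE) {
  p <- net$par
  if (training && net$input_dropout > 0) {
    keep <- matrix(stats::runif(length(X)) >= net$input_dropout,
                   nrow(X), ncol(X))
    X <- X * keep / (1 - net$input_dropout)
  }
  a1 <- sweep(X %*% p$W1, 2, p$b1, "+")
  if (training) {
    mu <- colMeans(a1)
    va <- colMeans(sweep(a1, 2, mu)^2)
  } else {
    mu <- net$running_mean
    va <- net$running_var
  }
  inv_sd <- 1 / sqrt(va + net$bn_eps)
  hhat <- sweep(sweep(a1, 2, mu), 2, inv_sd, "*")
  bn <- sweep(sweep(hhat, 2, p$gamma, "*"), 2, p$beta, "+")
  r1 <- pmax(bn, 0)
  a2 <- sweep(r1 %*% p$W2, 2, p$b2, "+")
  r2 <- pmax(a2, 0)
  out <- sweep(r2 %*% p$W3, 2, p$b3, "+")
  cache <- list(X = X, a1 = a1, hhat = hhat, inv_sd = inv_sd, bn = bn,
                r1 = r1, a2 = a2, r2 = r2, training = training)
  if (training) {
    m <- net$momentum
    net$running_mean <- (1 - m) * net$running_mean + m * mu
    nr <- nrow(X)
    unb <- if (nr > 1) nr / (nr - 1) else 1
    net$running_var <- (1 - m) * net$running_var + m * va * unb
  }
  list(out = out, cache = cache, net = net)
}

# Backward pass for the ASCENT direction: g_out is d(objective)/d(out).
# Returns gradients for every parameter in net$par.
mlp_backward <- function(net, cache, g_out) {
  p <- net$par
  gW3 <- t(cache$r2) %*% g_out
  gb3 <- colSums(g_out)
  g_r2 <- g_out %*% t(p$W3)
  g_a2 <- g_r2 * (cache$a2 > 0)
  gW2 <- t(cache$r1) %*% g_a2
  gb2 <- colSums(g_a2)
  g_r1 <- g_a2 %*% t(p$W2)
  g_bn <- g_r1 * (cache$bn > 0)
  ggamma <- colSums(g_bn * cache$hhat)
  gbeta <- colSums(g_bn)
  g_hhat <- sweep(g_bn, 2, p$gamma, "*")
  if (cache$training) {
    n <- nrow(g_hhat)
    s1 <- colSums(g_hhat)
    s2 <- colSums(g_hhat * cache$hhat)
    g_a1 <- sweep(
      g_hhat - matrix(s1 / n, n, length(s1), byrow = TRUE) -
        cache$hhat * matrix(s2 / n, n, length(s2), byrow = TRUE),
      2, cache$inv_sd, "*")
  } else {
    g_a1 <- sweep(g_hhat, 2, cache$inv_sd, "*")
  }
  gW1 <- t(cache$X) %*% g_a1
  gb1 <- colSums(g_a1)
  list(W1 = gW1, b1 = gb1, gamma = ggamma, beta = gbeta,
       W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

mlp_adam_init <- function(net) {
  lapply(net$par, function(p) list(m = p * 0, v = p * 0))
}

mlp_adam_step <- function(net, grads, state, lr, t, weight_decay = 0) {
  for (nm in names(net$par)) {
    g <- grads[[nm]]
    if (weight_decay > 0 && nm %in% c("W1", "W2", "W3")) {
      g <- g - weight_decay * net$par[[nm]] # ascent: decay pulls toward 0
    }
    up <- .adam_step(net$par[[nm]], g, state[[nm]], lr, t)
    net$par[[nm]] <- up$param
    state[[nm]] <- up$state
  }
  list(net = net, state = state)
}
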