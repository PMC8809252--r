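# conjugate-Normal toy shared by several blocks
conjugate_toy <- function() {
  set.seed(99)
  y <- rnorm(200, 10, 1)
  prior_sd <- 10
  post_var <- 1 / (length(y) + 1 / prior_sd^2)
  list(
    y = y,
    post_mean = post_var * sum(y),
    post_sd = sqrt(post_var),
    model = vi_model(
      latents = list(vi_latent("theta", 1, "identity", init_loc = 0,
                               init_log_scale = 0)),
      log_joint = function(lat, d) {
        sum(dnorm(d$y, lat$theta, 1, log = TRUE)) +
          dnorm(lat$theta, 0, 10, log = TRUE)
      },
      grad_log_joint = function(lat, d) {
        list(theta = sum(d$y - lat$theta) - lat$theta / 100)
      },
      data = list(y = y))
  )
}

test_that("BBVI recovers the conjugate-Normal posterior over three seeds", {
  toy <- conjugate_toy()
  for (s in 1:3) {
    fit <- fit_bbvi(toy$model, fit_config(n_steps = 3000, seed = s))
    mean_hat <- fit$latents$theta$loc
    sd_hat <- exp(fit$latents$theta$log_scale)
    expect_lt(abs(mean_hat - toy$post_mean) / abs(toy$post_mean), 0.02)
    expect_lt(abs(sd_hat - toy$post_sd) / toy$post_sd, 0.10)
  }
})

test_that("BBVI recovers an NB rate from simulated counts", {
  set.seed(5)
  k <- rnbinom(1000, size = 2, mu = 5)
  model <- vi_model(
    latents = list(vi_latent("mu", 1, "positive", init_loc = 0),
                   vi_latent("theta", 1, "positive", init_loc = 0)),
    log_joint = function(lat, d) {
      sum(nb_logpmf(d$k, nb_params(lat$mu, lat$theta))) +
        dnorm(log(lat$mu), 0, 5, log = TRUE) +
        dnorm(log(lat$theta), 0, 5, log = TRUE)
    },
    grad_log_joint = function(lat, d) {
      list(mu = sum(nb_grad_mu(d$k, lat$mu, lat$theta)) -
             log(lat$mu) / (25 * lat$mu),
           theta = sum(nb_grad_theta(d$k, lat$mu, lat$theta)) -
             log(lat$theta) / (25 * lat$theta))
    },
    data = list(k = k))
  fit <- fit_bbvi(model, fit_config(n_steps = 2000, seed = 1))
  mu_hat <- posterior_mean(fit)$mu
  expect_lt(abs(mu_hat - 5) / 5, 0.10)
})

test_that("a zero-step fit returns the initialization unchanged", {
  toy <- conjugate_toy()
  fit <- fit_bbvi(toy$model, fit_config(n_steps = 0, seed = 1))
  expect_identical(unname(fit$latents$theta$loc), 0)
  expect_identical(unname(fit$latents$theta$log_scale), 0)
})

test_that("fits are bit-exact reproducible under identical seeds", {
  toy <- conjugate_toy()
  f1 <- fit_bbvi(toy$model, fit_config(n_steps = 300, seed = 7))
  f2 <- fit_bbvi(toy$model, fit_config(n_steps = 300, seed = 7))
  expect_identical(f1$latents$theta$loc, f2$latents$theta$loc)
  expect_identical(f1$elbo_trace, f2$elbo_trace)
})

test_that("a non-finite log-joint aborts with a diagnostic", {
  bad <- vi_model(
    latents = list(vi_latent("x", 1, "identity")),
    log_joint = function(lat, d) NaN,
    grad_log_joint = function(lat, d) list(x = 0),
    data = list())
  expect_error(fit_bbvi(bad, fit_config(n_steps = 5, seed = 1)),
               "non-finite log-joint")
  bad2 <- vi_model(
    latents = list(vi_latent("rate", 1, "positive")),
    log_joint = function(lat, d) 0,
    grad_log_joint = function(lat, d) list(rate = NaN),
    data = list())
  expect_error(fit_bbvi(bad2, fit_config(n_steps = 5, seed = 1)),
               "latent 'rate'")
})

test_that("sample_posterior respects domains, seeds and n", {
  model <- vi_model(
    latents = list(vi_latent("p", c(4, 3), "simplex"),
                   vi_latent("f", 5, "unit_interval"),
                   vi_latent("x", 2, "identity", init_loc = 0,
                             init_log_scale = -20)),
    log_joint = function(lat, d) 0,
    grad_log_joint = function(lat, d)
      list(p = lat$p * 0, f = lat$f * 0, x = lat$x * 0),
    data = list())
  post <- fit_bbvi(model, fit_config(n_steps = 0, seed = 1))
  dr <- sample_posterior(post, 7, seed = 11)
  expect_equal(dim(dr$p), c(7, 4, 3))
  expect_lt(max(abs(apply(dr$p, c(1, 2), sum) - 1)), 1e-8)
  expect_true(all(dr$f >= 0 & dr$f <= 1))
  expect_lt(max(abs(dr$x)), 1e-6) # collapsed posterior draws ~ location
  dr2 <- sample_posterior(post, 7, seed = 11)
  expect_identical(dr, dr2)
  expect_error(sample_posterior(post, 0), "n must be >= 1")
})

test_that("the amortizer backward pass matches finite differences", {
  set.seed(42)
  net <- mlp(d_in = 7, d_out = 2, hidden = c(5, 4), seed = 3,
             input_dropout = 0)
  X <- matrix(rnorm(6 * 7), 6, 7)
  Tg <- matrix(rnorm(6 * 2), 6, 2)
  fw <- spotzone:::mlp_forward(net, X, training = TRUE)
  gr <- spotzone:::mlp_backward(net, fw$cache, Tg)
  worst <- 0
  for (pn in names(net$par)) {
    idx <- sample(length(net$par[[pn]]), min(4, length(net$par[[pn]])))
    for (i in idx) {
      f <- function(v) {
        np <- net; np$par[[pn]][i] <- v
        sum(Tg * spotzone:::mlp_forward(np, X, training = TRUE)$out)
      }
      num <- (f(net$par[[pn]][i] + 1e-6) - f(net$par[[pn]][i] - 1e-6)) / 2e-6
      worst <- max(worst, abs(gr[[pn]][i] - num))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("the ELBO trend is non-decreasing on a well-posed problem", {
  toy <- conjugate_toy()
  fit <- fit_bbvi(toy$model, fit_config(n_steps = 1500, seed = 2))
  tr <- fit$elbo_trace
  w <- 150
  means <- sapply(seq(1, length(tr) - w, by = w),
                  function(i) mean(tr[i:(i + w - 1)]))
  expect_true(all(diff(means) > -1)) # smoothed trend never drops materially
})
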