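#' Configuration for variational fits
#'
#' @param lr_variational Adam learning rate for directly-parameterized
#'   variational parameters (default 0.01).
#' @param lr_amortized Adam learning rate for amortization-network weights
#'   (default 0.001).
#' @param n_steps Maximum number of optimization steps (default 2000).
#' @param n_mc_samples_elbo Monte-Carlo samples per ELBO gradient estimate
#'   (default 1, the standard single-sample reparameterized estimator).
#' @param seed Integer seed; recorded in every fit result.
#' @param method `"vi"` for full variational inference, `"map"` for a
#'   deterministic maximum-a-posteriori fit in unconstrained space (scales are
#'   not optimized and no entropy term enters the objective).
#' @param early_stop_tol Relative change in windowed mean objective below
#'   which optimization stops early (default 1e-5).
#' @param early_stop_window Window length (steps) for early stopping.
#' @param amortizer_weight_decay L2 weight decay applied to amortizer
#'   linear-layer weights during training (default 1e-3), regularizing the
#'   encoder so it transfers to unseen data.
#' @param tail_average_frac Fraction of final steps over which
#'   directly-parameterized locations/scales are averaged to damp
#'   stochastic-gradient jitter (default 0.2; amortized parameters are never
#'   averaged).
#' @return A `fit_config` list.
#' @export
fit_config <- function(lr_variational = 0.01, lr_amortized = 0.001,
                       n_steps = 2000, n_mc_samples_elbo = 1, seed = 1,
                       method = c("vi", "map"),
                       early_stop_tol = 1e-5, early_stop_window = 100,
                       amortizer_weight_decay = 1e-3,
                       tail_average_frac = 0.2) {
  method <- match.arg(method)
  stopifnot(lr_variational > 0, lr_amortized > 0, n_steps >= 0,
            n_mc_samples_elbo >= 1)
  structure(list(lr_variational = lr_variational, lr_amortized = lr_amortized,
                 n_steps = as.integer(n_steps),
                 n_mc_samples_elbo = as.integer(n_mc_samples_elbo),
                 seed = as.integer(seed), method = method,
                 early_stop_tol = early_stop_tol,
                 early_stop_window = as.integer(early_stop_window),
                 amortizer_weight_decay = amortizer_weight_decay,
                 tail_average_frac = tail_average_frac),
            class = "fit_config")
}

#' Declare a latent variable for a variational model
#'
#' @param name Latent name; must match a name consumed by the model's
#'   log-joint and gradient callables.
#' @param dim Integer shape: a scalar `n` for a vector latent or `c(n, K)`
#'   for a matrix latent (rows are softmaxed for simplex latents).
#' @param transform Transform name, see [domain_transform()].
#' @param init_loc,init_log_scale Initial unconstrained location / log
#'   standard deviation (recycled to `dim`).
#' @param amortizer Optional [mlp] network producing `(loc, log_scale)` per
#'   row of `amortizer_input`; only valid for vector latents.
#' @param amortizer_input Numeric matrix with `dim` rows fed to the network.
#' @param freeze_steps Hold this latent at its initialization for the first
#'   `freeze_steps` optimization steps (warm-up staging for latents that
#'   would otherwise absorb early misfit of the others).
#' @return A `vi_latent` declaration.
#' @export
vi_latent <- function(name, dim, transform = "identity",
                      init_loc = 0, init_log_scale = -2,
                      amortizer = NULL, amortizer_input = NULL,
                      freeze_steps = 0) {
  dim <- as.integer(dim)
  stopifnot(length(dim) %in% 1:2, all(dim >= 1))
  if (!is.null(amortizer)) {
    stopifnot(length(dim) == 1, is.matrix(amortizer_input),
              nrow(amortizer_input) == dim)
  }
  structure(list(name = name, dim = dim,
                 transform = domain_transform(transform),
                 init_loc = init_loc, init_log_scale = init_log_scale,
                 amortizer = amortizer, amortizer_input = amortizer_input,
                 freeze_steps = as.numeric(freeze_steps)),
            class = "vi_latent")
}

#' Assemble a variational model
#'
#' A model couples latent declarations with a log-joint density over
#' constrained latent values and its analytic gradient.
#'
#' @param latents List of [vi_latent()] declarations.
#' @param log_joint `function(lat, data)` returning the scalar log joint
#'   density (priors + likelihood) at the named list of constrained latents.
#' @param grad_log_joint `function(lat, data)` returning a named list of
#'   gradients of the log joint wrt each constrained latent, same shapes.
#' @param data Arbitrary data payload passed through to the callables.
#' @return A `vi_model`.
#' @export
vi_model <- function(latents, log_joint, grad_log_joint, data = list()) {
  nm <- vapply(latents, function(l) l$name, "")
  stopifnot(!anyDuplicated(nm))
  names(latents) <- nm
  structure(list(latents = latents, log_joint = log_joint,
                 grad_log_joint = grad_log_joint, data = data),
            class = "vi_model")
}

.shape_array <- function(x, dim) {
  if (length(dim) == 2) matrix(x, dim[1], dim[2]) else rep_len(x, dim)
}

.adam_new <- function(param) list(m = param * 0, v = param * 0)

.adam_step <- function(param, grad, state, lr, t,
                       beta1 = 0.9, beta2 = 0.99, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(param = param + lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Fit a variational model by black-box variational inference
#'
#' Optimizes the ELBO of a diagonal-Normal variational posterior in
#' unconstrained space (reparameterization-trick gradients, Adam) with
#' split learning rates for direct variational parameters and amortization
#' networks. Latents with an amortizer get their variational parameters from
#' the network; its weights are trained jointly at `lr_amortized`.
#'
#' @param model A [vi_model()].
#' @param config A [fit_config()].
#' @return A `variational_posterior` holding per-latent unconstrained
#'   location/log-scale, transforms, trained amortizers, the ELBO trace and
#'   the seed.
#' @export
fit_bbvi <- function(model, config = fit_config()) {
  stopifnot(inherits(model, "vi_model"), inherits(config, "fit_config"))
  set.seed(config$seed)
  map_mode <- config$method == "map"

  lats <- model$latents
  P <- list()       # direct parameters per latent: loc, log_scale
  A <- list()       # adam states
  nets <- list()    # amortizer nets by latent name
  for (l in lats) {
    if (is.null(l$amortizer)) {
      loc <- .shape_array(l$init_loc, l$dim)
      lsc <- .shape_array(l$init_log_scale, l$dim)
      P[[l$name]] <- list(loc = loc, log_scale = lsc)
      A[[l$name]] <- list(loc = .adam_new(loc), log_scale = .adam_new(lsc))
    } else {
      nets[[l$name]] <- l$amortizer
      A[[l$name]] <- mlp_adam_init(l$amortizer)
    }
  }

  elbo_trace <- numeric(0)
  tail_from <- max(1L, ceiling(config$n_steps * (1 - config$tail_average_frac)))
  tail_sum <- list()
  tail_n <- 0L

  step <- 0L
  while (step < config$n_steps) {
    step <- step + 1L
    S <- if (map_mode) 1L else config$n_mc_samples_elbo
    g_loc_acc <- list(); g_lsc_acc <- list(); g_net_acc <- list()
    caches <- list()
    elbo_s <- 0

    for (s in seq_len(S)) {
      lat_u <- list(); lat_x <- list(); epss <- list()
      # forward: amortizers first (training mode batch statistics)
      for (l in lats) {
        nm <- l$name
        if (is.null(l$amortizer)) {
          loc <- P[[nm]]$loc; lsc <- P[[nm]]$log_scale
        } else {
          fw <- mlp_forward(nets[[nm]], l$amortizer_input, training = TRUE)
          caches[[nm]] <- fw$cache
          nets[[nm]] <- fw$net # running batch-norm statistics advance
          loc <- fw$out[, 1]; lsc <- fw$out[, 2]
        }
        if (map_mode) {
          eps <- loc * 0
        } else {
          eps <- .shape_array(stats::rnorm(prod(l$dim)), l$dim)
        }
        u <- loc + exp(lsc) * eps
        x <- l$transform$forward(u)
        lat_u[[nm]] <- u; lat_x[[nm]] <- x; epss[[nm]] <- eps
        if (!is.null(l$amortizer)) P[[nm]] <- list(loc = loc, log_scale = lsc)
      }

      lp <- model$log_joint(lat_x, model$data)
      if (!is.finite(lp)) {
        stop("fit_bbvi: non-finite log-joint at step ", step,
             "; latents: ", paste(names(lat_x), collapse = ", "))
      }
      obj <- lp
      for (l in lats) {
        obj <- obj + l$transform$log_jac(lat_u[[l$name]], lat_x[[l$name]])
        if (!map_mode) {
          obj <- obj + sum(P[[l$name]]$log_scale) +
            prod(l$dim) * 0.5 * log(2 * pi * exp(1))
        }
      }
      elbo_s <- elbo_s + obj / S

      gx <- model$grad_log_joint(lat_x, model$data)
      for (l in lats) {
        nm <- l$name
        g_u <- l$transform$backprop(gx[[nm]], lat_u[[nm]], lat_x[[nm]])
        if (any(!is.finite(g_u))) {
          stop("fit_bbvi: non-finite gradient for latent '", nm,
               "' at step ", step)
        }
        # "sticking the landing" path-derivative estimator: the entropy
        # gradient is taken through the sample path (score term dropped),
        # which is unbiased and zero-variance at a Gaussian optimum
        scl <- exp(P[[nm]]$log_scale)
        g_loc <- if (map_mode) g_u else g_u + epss[[nm]] / scl
        g_lsc <- if (map_mode) NULL else g_u * epss[[nm]] * scl + epss[[nm]]^2
        if (is.null(l$amortizer)) {
          g_loc_acc[[nm]] <- if (is.null(g_loc_acc[[nm]])) g_loc / S else g_loc_acc[[nm]] + g_loc / S
          if (!map_mode) {
            g_lsc_acc[[nm]] <- if (is.null(g_lsc_acc[[nm]])) g_lsc / S else g_lsc_acc[[nm]] + g_lsc / S
          }
        } else {
          g_out <- cbind(g_loc, if (map_mode) g_loc * 0 else g_lsc)
          gn <- mlp_backward(nets[[nm]], caches[[nm]], g_out)
          g_net_acc[[nm]] <- if (is.null(g_net_acc[[nm]])) {
            lapply(gn, function(g) g / S)
          } else {
            mapply(function(a, b) a + b / S, g_net_acc[[nm]], gn, SIMPLIFY = FALSE)
          }
        }
      }
    }

    elbo_trace[step] <- elbo_s

    for (l in lats) {
      nm <- l$name
      if (step <= l$freeze_steps) next
      if (is.null(l$amortizer)) {
        up <- .adam_step(P[[nm]]$loc, g_loc_acc[[nm]], A[[nm]]$loc,
                         config$lr_variational, step)
        P[[nm]]$loc <- up$param; A[[nm]]$loc <- up$state
        if (!map_mode) {
          up <- .adam_step(P[[nm]]$log_scale, g_lsc_acc[[nm]], A[[nm]]$log_scale,
                           config$lr_variational, step)
          P[[nm]]$log_scale <- up$param; A[[nm]]$log_scale <- up$state
        }
      } else {
        res <- mlp_adam_step(nets[[nm]], g_net_acc[[nm]], A[[nm]],
                             config$lr_amortized, step,
                             weight_decay = config$amortizer_weight_decay)
        nets[[nm]] <- res$net; A[[nm]] <- res$state
      }
    }

    if (step >= tail_from) {
      tail_n <- tail_n + 1L
      for (nm in names(P)) {
        if (!is.null(lats[[nm]]$amortizer)) next
        if (is.null(tail_sum[[nm]])) {
          tail_sum[[nm]] <- list(loc = P[[nm]]$loc, log_scale = P[[nm]]$log_scale)
        } else {
          tail_sum[[nm]]$loc <- tail_sum[[nm]]$loc + P[[nm]]$loc
          tail_sum[[nm]]$log_scale <- tail_sum[[nm]]$log_scale + P[[nm]]$log_scale
        }
      }
    }

    w <- config$early_stop_window
    if (step >= 2 * w && step %% w == 0) {
      recent <- mean(elbo_trace[(step - w + 1):step])
      prev <- mean(elbo_trace[(step - 2 * w + 1):(step - w)])
      if (abs(recent - prev) / (abs(prev) + 1) < config$early_stop_tol) break
    }
  }

  if (tail_n > 1L) {
    for (nm in names(tail_sum)) {
      P[[nm]]$loc <- tail_sum[[nm]]$loc / tail_n
      if (!map_mode) P[[nm]]$log_scale <- tail_sum[[nm]]$log_scale / tail_n
    }
  }

  # freeze amortized latents: evaluation-mode forward with running statistics
  for (l in lats) {
    nm <- l$name
    if (!is.null(l$amortizer)) {
      fw <- mlp_forward(nets[[nm]], l$amortizer_input, training = FALSE)
      P[[nm]] <- list(loc = fw$out[, 1], log_scale = fw$out[, 2])
    }
  }

  post <- list()
  for (l in lats) {
    post[[l$name]] <- list(loc = P[[l$name]]$loc,
                           log_scale = P[[l$name]]$log_scale,
                           transform = l$transform, dim = l$dim)
  }
  structure(list(latents = post, amortizers = nets,
                 elbo_trace = elbo_trace, config = config,
                 seed = config$seed, steps_run = step),
            class = "variational_posterior")
}

#' @export
print.variational_posterior <- function(x, ...) {
  cat("<variational_posterior>", length(x$latents), "latents;",
      x$steps_run, "steps; final ELBO",
      if (length(x$elbo_trace)) format(utils::tail(x$elbo_trace, 1)) else "NA", "\n")
  for (nm in names(x$latents)) {
    l <- x$latents[[nm]]
    cat("  ", nm, " [", paste(l$dim, collapse = "x"), "] ",
        l$transform$name, "\n", sep = "")
  }
  invisible(x)
}

#' Posterior means on the constrained scale
#'
#' Monte-Carlo estimate of `E[T(u)]` per latent (the transform of the mean is
#' used when `n_mc = 0`, i.e. a plug-in point estimate).
#'
#' @param posterior A fitted `variational_posterior`.
#' @param n_mc Number of draws (0 = plug-in transform of the location).
#' @param seed Seed for the draws.
#' @return Named list of posterior mean arrays.
#' @export
posterior_mean <- function(posterior, n_mc = 0, seed = 1) {
  if (n_mc == 0) {
    lapply(posterior$latents, function(l) l$transform$forward(l$loc))
  } else {
    draws <- sample_posterior(posterior, n_mc, seed)
    lapply(draws, function(d) {
      if (length(dim(d)) == 3) apply(d, c(2, 3), mean)
      else if (is.matrix(d)) colMeans(d)
      else mean(d)
    })
  }
}

#' Draw samples from a fitted variational posterior
#'
#' @param posterior A `variational_posterior`.
#' @param n Number of draws (>= 1).
#' @param seed Seed; draws are reproducible per seed.
#' @return Named list; vector latents give an `n x dim` matrix, matrix latents
#'   an `n x d1 x d2` array. All draws respect the latent's domain.
#' @export
sample_posterior <- function(posterior, n, seed = 1) {
  stopifnot(inherits(posterior, "variational_posterior"))
  if (n < 1) stop("sample_posterior: n must be >= 1")
  set.seed(seed)
  out <- list()
  for (nm in names(posterior$latents)) {
    l <- posterior$latents[[nm]]
    d <- l$dim
    if (length(d) == 2) {
      draws <- array(NA_real_, c(n, d[1], d[2]))
      for (i in seq_len(n)) {
        u <- l$loc + exp(l$log_scale) * matrix(stats::rnorm(prod(d)), d[1], d[2])
        draws[i, , ] <- l$transform$forward(u)
      }
    } else {
      draws <- matrix(NA_real_, n, d)
      for (i in seq_len(n)) {
        u <- l$loc + exp(l$log_scale) * stats::rnorm(d)
        draws[i, ] <- l$transform$forward(u)
      }
    }
    out[[nm]] <- draws
  }
  out
}
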