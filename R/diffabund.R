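#' Fit a presence-vs-zonation abundance curve
#'
#' Models binary cell-type presence per spot as Bernoulli with
#' `logit p = basis(z) . coefficients`, the coefficients carrying a Gaussian
#' random-walk prior with unit step scale. Fitted as a deterministic
#' maximum-a-posteriori optimization through the inference engine.
#'
#' @param presence Logical (or 0/1) vector, one per spot.
#' @param z Zonation coordinates in `[0, 1]`, aligned with `presence`.
#' @param basis A [spline_basis()].
#' @param config A [fit_config()]; default 600 MAP steps at lr 0.05.
#' @param condition Optional two-level factor; when given, a second
#'   coefficient set models the condition-specific curve (used by
#'   [lrt_interaction()]).
#' @param init_coef Optional initial coefficient matrix (knots x sets).
#' @return An `abundance_curve_fit` with coefficients (one column per
#'   condition, or a single column), the Bernoulli data log-likelihood at
#'   the MAP, the log-prior, and a `curve(z, cond)` evaluator.
#' @export
fit_abundance_curve <- function(presence, z, basis = spline_basis(),
                                config = fit_config(n_steps = 600,
                                                    lr_variational = 0.05,
                                                    method = "map"),
                                condition = NULL, init_coef = NULL) {
  presence <- as.logical(presence)
  stopifnot(length(presence) == length(z), all(z >= 0 & z <= 1))
  if (length(presence) < 20) stop("fit_abundance_curve: need >= 20 spots")
  if (all(presence) || !any(presence)) {
    warning("fit_abundance_curve: presence is constant; curve is degenerate")
  }
  K <- basis$n_knots
  B <- gaussian_basis(z, basis)
  y <- as.numeric(presence)

  if (is.null(condition)) {
    cond_idx <- rep(1L, length(y)); n_cond <- 1L
  } else {
    condition <- as.factor(condition)
    stopifnot(nlevels(condition) <= 2)
    cond_idx <- as.integer(condition); n_cond <- nlevels(condition)
  }
  p0 <- min(max(mean(y), 1e-3), 1 - 1e-3)
  init <- if (is.null(init_coef)) {
    matrix(stats::qlogis(p0), K, n_cond)
  } else {
    matrix(init_coef, K, n_cond)
  }

  data <- list(B = B, y = y, cond_idx = cond_idx, n_cond = n_cond, K = K)
  rw <- function(co) {
    sum(stats::dnorm(co[-1, ] - co[-nrow(co), ], 0, 1, log = TRUE)) +
      sum(stats::dnorm(co[1, ], 0, 10, log = TRUE))
  }
  eta_of <- function(co, d) {
    e <- d$B %*% co          # spots x n_cond
    e[cbind(seq_along(d$y), d$cond_idx)]
  }
  log_joint <- function(lat, d) {
    eta <- eta_of(lat$coef, d)
    sum(d$y * eta - log1p(exp(eta))) + rw(lat$coef)
  }
  grad_log_joint <- function(lat, d) {
    eta <- eta_of(lat$coef, d)
    r <- d$y - stats::plogis(eta)    # spots
    g <- matrix(0, d$K, d$n_cond)
    for (cc in seq_len(d$n_cond)) {
      sel <- d$cond_idx == cc
      g[, cc] <- crossprod(d$B[sel, , drop = FALSE], r[sel])
    }
    st <- lat$coef[-1, , drop = FALSE] - lat$coef[-d$K, , drop = FALSE]
    g[-1, ] <- g[-1, , drop = FALSE] - st
    g[-d$K, ] <- g[-d$K, , drop = FALSE] + st
    g[1, ] <- g[1, ] - lat$coef[1, ] / 100
    list(coef = g)
  }
  model <- vi_model(
    list(vi_latent("coef", c(K, n_cond), "identity", init_loc = init,
                   init_log_scale = -2)),
    log_joint, grad_log_joint, data)
  post <- fit_bbvi(model, config)
  coef <- post$latents$coef$loc
  eta <- eta_of(coef, data)
  ll <- sum(y * eta - log1p(exp(eta)))
  structure(list(coefficients = coef, basis = basis,
                 loglik = ll, logprior = rw(coef),
                 n_cond = n_cond,
                 conditions = if (n_cond > 1) levels(condition) else NULL,
                 curve = function(zg, cond = 1) {
                   stats::plogis(gaussian_basis(zg, basis) %*% coef[, cond])
                 },
                 seed = config$seed),
            class = "abundance_curve_fit")
}

#' @export
print.abundance_curve_fit <- function(x, ...) {
  cat("<abundance_curve_fit>", nrow(x$coefficients), "knots x",
      x$n_cond, "condition set(s); loglik", round(x$loglik, 2), "\n")
  invisible(x)
}

#' Likelihood-ratio test for a zonation-by-condition interaction
#'
#' Fits a shared-coefficient curve and a condition-specific-coefficient
#' curve to the same presence/zonation data and reports
#' `log-LR = LL_separate - LL_shared` (Bernoulli data log-likelihoods at the
#' respective penalized MAP estimates). The separate fit is initialized from
#' the shared solution, so the separate likelihood can only improve; should
#' numerical optimization leave it below the shared one, the shared solution
#' duplicated into both conditions is returned (log-LR 0).
#'
#' @param presence,z As in [fit_abundance_curve()].
#' @param condition Two-level factor/vector, >= 20 spots per level.
#' @param basis A [spline_basis()].
#' @param config A [fit_config()] for both MAP fits.
#' @param threshold Decision threshold on the log-LR (default 10).
#' @return An `abundance_curve_fit` extended with `shared`, `loglik_shared`,
#'   `log_lr` and `significant`.
#' @export
lrt_interaction <- function(presence, z, condition, basis = spline_basis(),
                            config = fit_config(n_steps = 600,
                                                lr_variational = 0.05,
                                                method = "map"),
                            threshold = 10) {
  condition <- as.factor(condition)
  if (nlevels(condition) < 2) stop("lrt_interaction: need two conditions")
  if (min(table(condition)) < 20) {
    stop("lrt_interaction: each condition needs >= 20 spots")
  }
  shared <- fit_abundance_curve(presence, z, basis, config)
  sep <- fit_abundance_curve(presence, z, basis, config, condition = condition,
                             init_coef = shared$coefficients[, c(1, 1)])
  if (sep$loglik < shared$loglik) {
    sep$coefficients <- shared$coefficients[, c(1, 1)]
    sep$loglik <- shared$loglik
    co <- sep$coefficients; bas <- basis
    sep$curve <- function(zg, cond = 1) {
      stats::plogis(gaussian_basis(zg, bas) %*% co[, cond])
    }
  }
  sep$shared <- shared
  sep$loglik_shared <- shared$loglik
  sep$log_lr <- sep$loglik - shared$loglik
  sep$threshold <- threshold
  sep$significant <- sep$log_lr > threshold
  sep
}

#' Differential abundance along zonation for all cell types
#'
#' Joins deconvolution presence calls with the zonation posterior and fits a
#' presence-vs-z curve per cell type; with a two-level condition, performs
#' the condition-interaction likelihood-ratio test.
#'
#' @param deconv A fitted `deconvolution_result` (with presence calls).
#' @param zonation A fitted `zonation_result` on the same spots.
#' @param conditions Optional per-spot condition labels (two levels).
#' @param celltypes Cell types to report (default: all in `deconv`).
#' @param z_grid Grid on `[0, 1]` at which fitted curves are evaluated.
#' @param config Passed to the curve fits.
#' @return Data frame, one row per cell type: fraction present, log-LR and
#'   decision (when conditions given), and fitted probabilities over
#'   `z_grid` as a nested matrix in attribute `"curves"`.
#' @export
zonation_abundance_report <- function(deconv, zonation, conditions = NULL,
                                      celltypes = NULL,
                                      z_grid = seq(0.05, 0.95, by = 0.1),
                                      config = fit_config(n_steps = 600,
                                                          lr_variational = 0.05,
                                                          method = "map")) {
  stopifnot(inherits(deconv, "deconvolution_result"),
            inherits(zonation, "zonation_result"))
  if (is.null(deconv$presence)) stop("zonation_abundance_report: presence calls missing")
  spots <- rownames(deconv$nu)
  if (!identical(spots, names(zonation$z_mu))) {
    stop("zonation_abundance_report: spot index mismatch between deconvolution and zonation")
  }
  if (is.null(celltypes)) celltypes <- deconv$type_names
  z <- zonation$z_mu
  rows <- list(); curves <- list()
  for (ct in celltypes) {
    pres <- deconv$presence[, ct]
    if (is.null(conditions)) {
      fit <- suppressWarnings(fit_abundance_curve(pres, z, config = config))
      rows[[ct]] <- data.frame(celltype = ct, frac_present = mean(pres),
                               log_lr = NA_real_, significant = NA)
      curves[[ct]] <- as.numeric(fit$curve(z_grid))
    } else {
      fit <- lrt_interaction(pres, z, conditions, config = config)
      rows[[ct]] <- data.frame(celltype = ct, frac_present = mean(pres),
                               log_lr = fit$log_lr,
                               significant = fit$significant)
      curves[[ct]] <- cbind(A = as.numeric(fit$curve(z_grid, 1)),
                            B = as.numeric(fit$curve(z_grid, 2)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  attr(out, "z_grid") <- z_grid
  out
}
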