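#' Gaussian spline basis on the zonation axis
#'
#' @param n_knots Number of knots (default 10), placed at the fixed uniform
#'   positions `(k - 0.5) / n_knots` on `[0, 1]`.
#' @param sigma Gaussian basis width (default 0.05).
#' @return A `spline_basis`.
#' @export
spline_basis <- function(n_knots = 10, sigma = 0.05) {
  stopifnot(n_knots >= 2, sigma > 0)
  knots <- (seq_len(n_knots) - 0.5) / n_knots
  structure(list(n_knots = as.integer(n_knots), knots = knots, sigma = sigma),
            class = "spline_basis")
}

#' Evaluate the Gaussian basis design matrix
#'
#' Entry `(i, k)` is `exp(-(z_i - knot_k)^2 / (2 sigma^2))`.
#'
#' @param z Values in `[0, 1]`.
#' @param basis A [spline_basis()].
#' @return `length(z) x n_knots` design matrix.
#' @export
gaussian_basis <- function(z, basis = spline_basis()) {
  stopifnot(inherits(basis, "spline_basis"))
  if (any(z < 0 | z > 1)) stop("gaussian_basis: z must lie in [0, 1]")
  exp(-outer(z, basis$knots, "-")^2 / (2 * basis$sigma^2))
}

# d/dz of the design matrix rows
.gaussian_basis_dz <- function(z, basis) {
  B <- gaussian_basis(z, basis)
  B * (-outer(z, basis$knots, "-") / basis$sigma^2)
}

#' Per-gene random-walk step scale for the zonation spline prior
#'
#' Twice the standard deviation of the `log1p`-transformed expression values
#' over the whole dataset, per gene.
#'
#' @param counts Spot x gene non-negative matrix.
#' @return Named per-gene vector.
#' @export
compute_sigma_gene <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  2 * apply(log1p(counts), 2, stats::sd)
}

# per-spot amortizer features: library-normalized log1p counts
.zonation_features <- function(counts, scale = 1e4) {
  lib <- rowSums(counts)
  lib[lib == 0] <- 1
  log1p(counts / lib * scale)
}

#' Fit the latent zonation model
#'
#' Each spot gets a latent coordinate `z ~ Uniform(0, 1)`; per-gene
#' log-expression is a Gaussian-basis spline of `z` whose coefficients carry
#' a Gaussian random-walk prior with per-gene step scale from
#' [compute_sigma_gene()]. The `z` variational parameters are amortized by
#' an encoder (Linear(100)-BatchNorm-ReLU-Linear(100)-ReLU-Linear(2)) over
#' library-normalized `log1p` counts, trained at the amortized learning
#' rate, so the trained encoder can transfer zonation to new data.
#'
#' @param spots A [spot_dataset()] or a spot x feature count matrix (the
#'   feature space may equally be an antibody panel).
#' @param basis A [spline_basis()].
#' @param config A [fit_config()]; default 2000 steps.
#' @param sigma_floor Lower bound on the random-walk step scale (default
#'   1e-4; a zero scale collapses the prior to a constant spline).
#' @param input_dropout Input-feature dropout of the amortizer during
#'   training (default 0.3).
#' @return A `zonation_result` with per-spot `z_mu`/`z_sigma`, gene x knot
#'   `coefficients`, `sigma_gene`, the trained `amortizer` and the basis.
#' @export
fit_zonation <- function(spots, basis = spline_basis(),
                         config = fit_config(n_steps = 2000),
                         sigma_floor = 1e-4, input_dropout = 0.2) {
  counts <- if (inherits(spots, "spot_dataset")) spots$counts else as.matrix(spots)
  S <- nrow(counts); G <- ncol(counts)
  if (G < 2 || S < 10) stop("fit_zonation: need >= 2 genes and >= 10 spots")
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("f%04d", seq_len(G))
  lib <- rowSums(counts)
  lib[lib == 0] <- 1
  K <- basis$n_knots

  sigma_gene <- pmax(compute_sigma_gene(counts), sigma_floor)
  X <- .zonation_features(counts)
  set.seed(config$seed)
  net <- mlp(d_in = G, d_out = 2, seed = config$seed, init_out_bias = c(0, -1),
             input_dropout = input_dropout)
  net$feature_names <- colnames(counts)

  init_coef <- matrix(log(pmax(colMeans(counts / lib), 1e-8)), G, K)

  latents <- list(
    vi_latent("z", S, "unit_interval", amortizer = net, amortizer_input = X),
    vi_latent("coef", c(G, K), "identity", init_loc = init_coef,
              init_log_scale = -2),
    vi_latent("theta", G, "positive", init_loc = log(5), init_log_scale = -2)
  )
  data <- list(counts = counts, lib = lib, basis = basis,
               sigma_gene = sigma_gene, S = S, G = G, K = K)

  rw_logprior <- function(coef, d) {
    steps <- coef[, -1, drop = FALSE] - coef[, -d$K, drop = FALSE]
    sum(stats::dnorm(steps, 0, d$sigma_gene, log = TRUE)) +
      sum(stats::dnorm(coef[, 1], 0, 10, log = TRUE))
  }

  log_joint <- function(lat, d) {
    B <- gaussian_basis(lat$z, d$basis)
    logrho <- B %*% t(lat$coef)
    mu <- exp(logrho) * d$lib
    th <- rep(lat$theta, each = d$S)
    ll <- sum(stats::dnbinom(d$counts, size = th, mu = pmax(mu, .MU_FLOOR),
                             log = TRUE))
    ll + rw_logprior(lat$coef, d) +
      sum(stats::dnorm(log(lat$theta), 0, 5, log = TRUE))
  }

  grad_log_joint <- function(lat, d) {
    B <- gaussian_basis(lat$z, d$basis)
    logrho <- B %*% t(lat$coef)
    mu <- pmax(exp(logrho) * d$lib, .MU_FLOOR)
    th <- rep(lat$theta, each = d$S)
    dmu <- nb_grad_mu(d$counts, mu, th)
    dlogrho <- dmu * mu
    g_coef <- t(dlogrho) %*% B
    stepsg <- (lat$coef[, -1, drop = FALSE] - lat$coef[, -d$K, drop = FALSE]) /
      d$sigma_gene^2
    g_coef[, -1] <- g_coef[, -1, drop = FALSE] - stepsg
    g_coef[, -d$K] <- g_coef[, -d$K, drop = FALSE] + stepsg
    g_coef[, 1] <- g_coef[, 1] - lat$coef[, 1] / 100
    dB <- .gaussian_basis_dz(lat$z, d$basis)
    g_z <- rowSums(dlogrho * (dB %*% t(lat$coef)))
    g_theta <- colSums(matrix(nb_grad_theta(d$counts, mu, th), d$S, d$G)) -
      log(lat$theta) / (25 * lat$theta)
    list(z = g_z, coef = g_coef, theta = g_theta)
  }

  model <- vi_model(latents, log_joint, grad_log_joint, data)
  post <- fit_bbvi(model, config)

  z_mu <- stats::plogis(post$latents$z$loc)
  z_sigma <- exp(post$latents$z$log_scale)
  coef <- post$latents$coef$loc
  dimnames(coef) <- list(colnames(counts), NULL)
  structure(list(z_mu = stats::setNames(z_mu, rownames(counts)),
                 z_sigma = stats::setNames(z_sigma, rownames(counts)),
                 z_loc = post$latents$z$loc,
                 coefficients = coef,
                 sigma_gene = sigma_gene,
                 amortizer = post$amortizers$z,
                 basis = basis, posterior = post,
                 features = colnames(counts), seed = config$seed),
            class = "zonation_result")
}

#' @export
print.zonation_result <- function(x, ...) {
  cat("<zonation_result>", length(x$z_mu), "spots;",
      nrow(x$coefficients), "genes x", ncol(x$coefficients), "knots\n")
  invisible(x)
}

#' Transfer a trained zonation encoder to new data
#'
#' Applies the amortizer in inference mode (stored batch-normalization
#' statistics, no parameter updates) to new counts. Features are aligned by
#' name to the training panel; missing features are zero-filled with a
#' warning and an overlap below 50% is an error.
#'
#' @param result A fitted `zonation_result`.
#' @param new_data A [spot_dataset()] or counts matrix with named columns
#'   (genes or proteins).
#' @return Data frame with `z_mu` and `z_sigma` per row of `new_data`.
#' @export
transfer_zonation <- function(result, new_data) {
  stopifnot(inherits(result, "zonation_result"))
  counts <- if (inherits(new_data, "spot_dataset")) new_data$counts else
    as.matrix(new_data)
  feats <- result$features
  overlap <- intersect(feats, colnames(counts))
  if (length(overlap) < 0.5 * length(feats)) {
    stop("transfer_zonation: only ", length(overlap), "/", length(feats),
         " training features present (< 50%)")
  }
  if (length(overlap) < length(feats)) {
    warning("transfer_zonation: ", length(feats) - length(overlap),
            " missing features zero-filled")
  }
  X_all <- .zonation_features(counts)
  X <- matrix(0, nrow(counts), length(feats),
              dimnames = list(rownames(counts), feats))
  X[, overlap] <- X_all[, overlap]
  out <- mlp_forward(result$amortizer, X, training = FALSE)$out
  data.frame(barcode = rownames(counts) %||% sprintf("spot%04d", seq_len(nrow(counts))),
             z_mu = stats::plogis(out[, 1]),
             z_sigma = exp(out[, 2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Orient a zonation axis by anchor genes
#'
#' Zonation is identifiable only up to reflection; this fixes the
#' orientation so portal anchor genes decrease along `z` (portal at
#' `z = 0`, central at `z = 1`). `z` is reflected iff the portal anchors'
#' expression correlates positively with `z` (equivalently central anchors
#' negatively, when only those are given).
#'
#' @param z Per-spot zonation values in `[0, 1]`.
#' @param anchor_genes_portal,anchor_genes_central Gene sets (at least one
#'   nonempty and present in `counts`).
#' @param counts Spot x gene counts aligned with `z`.
#' @return Possibly reflected `z` (attribute `reflected` records the
#'   decision).
#' @export
orient_zonation <- function(z, anchor_genes_portal = character(),
                            anchor_genes_central = character(), counts) {
  counts <- as.matrix(counts)
  pg <- intersect(anchor_genes_portal, colnames(counts))
  cg <- intersect(anchor_genes_central, colnames(counts))
  if (!length(pg) && !length(cg)) {
    stop("orient_zonation: no anchor genes present in counts")
  }
  expr <- function(gs) rowMeans(log1p(counts[, gs, drop = FALSE]))
  score <- 0
  if (length(pg)) score <- score + suppressWarnings(stats::cor(z, expr(pg)))
  if (length(cg)) score <- score - suppressWarnings(stats::cor(z, expr(cg)))
  if (is.na(score) || score == 0) {
    warning("orient_zonation: anchor expression uninformative; keeping orientation")
    reflected <- FALSE
  } else {
    reflected <- score > 0
  }
  out <- if (reflected) 1 - z else z
  attr(out, "reflected") <- reflected
  out
}
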