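#' Deconvolution model specification
#'
#' Species-level constants of the spot deconvolution model: the hemoglobin
#' genes that act as free parameters of the red-blood-cell pseudo-type, the
#' hepatocyte complement-factor genes modelled as free parameters (their
#' spatial expression is known to deviate from the dissociation-based
#' reference), and the Monte-Carlo presence-test settings.
#'
#' @param species `"mouse"` or `"human"`.
#' @param hemoglobin,complement Gene symbol vectors (species defaults).
#' @param hepatocyte_celltype Name of the hepatocyte type in the reference.
#' @param n_mc_presence Monte-Carlo draws for the presence test.
#' @param presence_threshold Log-likelihood-ratio call threshold (default 10).
#' @param ambient_prior_frac,ambient_prior_sd Empirical ambient-background
#'   prior: `log bg_g ~ N(log(ambient_prior_frac * mean_g), ambient_prior_sd)`
#'   where `mean_g` is the gene's mean observed count. The defaults
#'   (0.02, 0.5) suit typical Visium libraries where ambient contamination is
#'   a few percent; raise them for ambient-heavy preparations.
#' @return A `deconv_model_spec`.
#' @export
deconv_model_spec <- function(species = c("mouse", "human"),
                              hemoglobin = NULL, complement = NULL,
                              hepatocyte_celltype = "Hepatocyte",
                              n_mc_presence = 100, presence_threshold = 10,
                              ambient_prior_frac = 0.02, ambient_prior_sd = 0.5) {
  species <- match.arg(species)
  if (is.null(hemoglobin)) hemoglobin <- hemoglobin_genes(species)
  if (is.null(complement)) complement <- complement_genes(species)
  stopifnot(length(hemoglobin) >= 1, length(complement) >= 1,
            presence_threshold > 0)
  structure(list(species = species, hemoglobin = hemoglobin,
                 complement = complement,
                 hepatocyte_celltype = hepatocyte_celltype,
                 n_mc_presence = as.integer(n_mc_presence),
                 presence_threshold = presence_threshold,
                 ambient_prior_frac = ambient_prior_frac,
                 ambient_prior_sd = ambient_prior_sd),
            class = "deconv_model_spec")
}

#' Build the spot deconvolution model
#'
#' Encodes `mu[s, g] = (sum_t nu[s, t] rho[t, g] e^{b_g}) * lib_s * fg_s +
#' bg_g` with a negative-binomial observation model and per-gene free
#' dispersion. `nu` lives on the simplex over reference cell types plus a
#' red-blood-cell pseudo-type whose profile is zero except for free
#' hemoglobin parameters; hepatocyte complement-factor entries are also free.
#' The capture bias `b_g` has a Normal(0, 1) prior; the background mean is
#' constrained positive through the exponential transform.
#'
#' @param reference A [reference_profile()] (uncorrected rho is used).
#' @param spots A [spot_dataset()].
#' @param spec A [deconv_model_spec()].
#' @param estimate_nuisances Estimate the per-gene capture bias, ambient
#'   background, per-spot foreground and per-gene dispersion alongside the
#'   proportions (the default). With `FALSE` these stay fixed at neutral
#'   values (bias 0, background ~0, foreground ~1, dispersion at its
#'   initialization), leaving a plain linear-mixture model — useful for
#'   validating the proportion estimator itself.
#' @return A `vi_model` (with deconvolution metadata attached) ready for
#'   [fit_deconvolution()].
#' @export
build_deconv_model <- function(reference, spots, spec = deconv_model_spec(),
                               estimate_nuisances = TRUE) {
  stopifnot(inherits(reference, "reference_profile"),
            inherits(spots, "spot_dataset"),
            inherits(spec, "deconv_model_spec"))
  genes <- intersect(reference$genes, spots$genes)
  if (length(genes) < 50) {
    stop("build_deconv_model: reference and spots share only ",
         length(genes), " genes (>= 50 required)")
  }
  counts <- spots$counts[, genes, drop = FALSE]
  lib <- spots$lib
  rho_ref <- reference$rho[, genes, drop = FALSE]
  celltypes <- reference$celltypes
  n_types <- length(celltypes)
  S <- nrow(counts); G <- length(genes)

  hb <- intersect(spec$hemoglobin, genes)
  rbc_enabled <- length(hb) > 0
  if (!rbc_enabled) {
    warning("build_deconv_model: no hemoglobin genes found for species '",
            spec$species, "'; RBC pseudo-type disabled")
  }
  hep <- spec$hepatocyte_celltype
  comp <- if (hep %in% celltypes) intersect(spec$complement, genes) else character()

  rho_base <- rho_ref
  type_names <- celltypes
  if (rbc_enabled) {
    rho_base <- rbind(rho_base, RBC = 0)
    type_names <- c(celltypes, "RBC")
  }
  if (length(comp)) rho_base[hep, comp] <- 0 # free parameters take over
  n_comp_types <- nrow(rho_base)
  hb_idx <- match(hb, genes)
  comp_idx <- match(comp, genes)
  hep_idx <- match(hep, type_names)
  rbc_idx <- if (rbc_enabled) n_comp_types else NA_integer_

  # initialize proportions by multiplicative KL updates against the
  # (bias-free) reference so optimization starts inside the right basin
  nu0 <- matrix(1 / n_comp_types, S, n_comp_types)
  rho_init <- rho_base
  if (rbc_enabled) {
    rho_init[rbc_idx, hb_idx] <- colMeans(counts[, hb, drop = FALSE] / lib)
    rho_init[rbc_idx, ] <- rho_init[rbc_idx, ] /
      max(sum(rho_init[rbc_idx, ]), 1e-6)
  }
  if (length(comp)) rho_init[hep_idx, comp_idx] <- rho_ref[hep, comp]
  yn <- counts / lib
  for (it in 1:40) {
    yh <- nu0 %*% rho_init
    nu0 <- nu0 * ((yn / pmax(yh, 1e-12)) %*% t(rho_init))
    nu0 <- pmax(nu0, 1e-6)
    nu0 <- nu0 / rowSums(nu0)
  }

  latents <- list(
    vi_latent("nu", c(S, n_comp_types), "simplex", init_loc = log(nu0),
              init_log_scale = -2),
    vi_latent("bias", G, "identity", init_loc = 0, init_log_scale = -2,
              freeze_steps = if (estimate_nuisances) 200 else Inf),
    vi_latent("background", G, "positive",
              init_loc = if (estimate_nuisances) {
                log(pmax(colMeans(counts) * spec$ambient_prior_frac, 1e-6))
              } else log(1e-6),
              init_log_scale = -2,
              freeze_steps = if (estimate_nuisances) 200 else Inf),
    vi_latent("foreground", S, "unit_interval",
              init_loc = if (estimate_nuisances) 2 else 7,
              init_log_scale = -2,
              freeze_steps = if (estimate_nuisances) 200 else Inf),
    vi_latent("theta", G, "positive", init_loc = log(30),
              init_log_scale = -2,
              freeze_steps = if (estimate_nuisances) 0 else Inf)
  )
  if (rbc_enabled) {
    latents <- c(latents, list(
      vi_latent("rbc_rho", length(hb), "positive",
                init_loc = log(pmax(colMeans(counts[, hb, drop = FALSE] / lib),
                                    1e-6)),
                init_log_scale = -2)))
  }
  if (length(comp)) {
    latents <- c(latents, list(
      vi_latent("comp_rho", length(comp), "positive",
                init_loc = log(pmax(colMeans(counts[, comp, drop = FALSE] / lib),
                                    1e-6)),
                init_log_scale = -2)))
  }

  # empirical-Bayes ambient prior: background is a small fraction of each
  # gene's mean observed counts (ambient contamination in Visium is minor
  # relative to in-tissue expression); keeps the additive background from
  # absorbing expression that belongs to the cell-type mixture
  bg_prior_mu <- log(pmax(colMeans(counts) * spec$ambient_prior_frac, 1e-6))
  bg_prior_sd <- spec$ambient_prior_sd

  data <- list(counts = counts, lib = lib, rho_base = rho_base,
               hb_idx = hb_idx, comp_idx = comp_idx, hep_idx = hep_idx,
               rbc_idx = rbc_idx, rbc_enabled = rbc_enabled,
               n_comp = length(comp), S = S, G = G,
               bg_prior_mu = bg_prior_mu, bg_prior_sd = bg_prior_sd)

  effective_rho <- function(lat, d) {
    rho <- d$rho_base
    if (d$rbc_enabled) rho[d$rbc_idx, d$hb_idx] <- lat$rbc_rho
    if (d$n_comp) rho[d$hep_idx, d$comp_idx] <- lat$comp_rho
    rho
  }

  log_joint <- function(lat, d) {
    rho <- effective_rho(lat, d)
    rho_b <- sweep(rho, 2, exp(lat$bias), "*")
    mix <- lat$nu %*% rho_b
    mu <- mix * (d$lib * lat$foreground) +
      matrix(lat$background, d$S, d$G, byrow = TRUE)
    th <- rep(lat$theta, each = d$S)
    ll <- sum(stats::dnbinom(d$counts, size = th, mu = pmax(mu, .MU_FLOOR),
                             log = TRUE))
    lp <- sum(stats::dnorm(lat$bias, 0, 1, log = TRUE)) +
      sum(stats::dnorm(log(lat$background), d$bg_prior_mu, d$bg_prior_sd, log = TRUE)) +
      sum(stats::dnorm(log(lat$theta), 0, 5, log = TRUE))
    if (d$rbc_enabled) lp <- lp + sum(stats::dnorm(log(lat$rbc_rho), 0, 5, log = TRUE))
    if (d$n_comp) lp <- lp + sum(stats::dnorm(log(lat$comp_rho), 0, 5, log = TRUE))
    ll + lp
  }

  grad_log_joint <- function(lat, d) {
    rho <- effective_rho(lat, d)
    eb <- exp(lat$bias)
    rho_b <- sweep(rho, 2, eb, "*")
    mix <- lat$nu %*% rho_b
    sf <- d$lib * lat$foreground
    mu <- mix * sf + matrix(lat$background, d$S, d$G, byrow = TRUE)
    mu <- pmax(mu, .MU_FLOOR)
    th <- rep(lat$theta, each = d$S)
    dmu <- nb_grad_mu(d$counts, mu, th)

    g_nu <- (dmu * sf) %*% t(rho_b)
    g_bias <- colSums(dmu * (mix * sf)) - lat$bias
    g_bg <- colSums(dmu) -
      (log(lat$background) - d$bg_prior_mu) / (d$bg_prior_sd^2 * lat$background)
    g_fg <- rowSums(dmu * mix) * d$lib
    g_theta <- colSums(matrix(nb_grad_theta(d$counts, mu, th), d$S, d$G)) -
      log(lat$theta) / (25 * lat$theta)
    out <- list(nu = g_nu, bias = g_bias, background = g_bg,
                foreground = g_fg, theta = g_theta)
    if (d$rbc_enabled) {
      # dmu/drbc_rho_h = nu[, rbc] * e^{b_h} * lib * fg
      dh <- dmu[, d$hb_idx, drop = FALSE] * sf
      out$rbc_rho <- colSums(dh * lat$nu[, d$rbc_idx]) * eb[d$hb_idx] -
        log(lat$rbc_rho) / (25 * lat$rbc_rho)
    }
    if (d$n_comp) {
      dc <- dmu[, d$comp_idx, drop = FALSE] * sf
      out$comp_rho <- colSums(dc * lat$nu[, d$hep_idx]) * eb[d$comp_idx] -
        log(lat$comp_rho) / (25 * lat$comp_rho)
    }
    out
  }

  model <- vi_model(latents, log_joint, grad_log_joint, data)
  model$deconv <- list(genes = genes, type_names = type_names,
                       celltypes = celltypes, spec = spec,
                       barcodes = rownames(counts), coords = spots$coords)
  model
}

#' Fit the deconvolution model
#'
#' Runs [fit_bbvi()] and assembles a `deconvolution_result` with posterior
#' cell-type proportions, per-gene capture bias and background, per-spot
#' foreground, and Monte-Carlo presence calls at the spec's log-LR
#' threshold.
#'
#' @param model Model from [build_deconv_model()].
#' @param config A [fit_config()].
#' @param run_presence Compute presence log-LRs for all spots and cell types
#'   (default TRUE).
#' @return A `deconvolution_result`.
#' @export
fit_deconvolution <- function(model, config = fit_config(n_steps = 1500),
                              run_presence = TRUE) {
  stopifnot(!is.null(model$deconv))
  post <- fit_bbvi(model, config)
  est <- posterior_mean(post)
  type_names <- model$deconv$type_names
  nu <- est$nu
  dimnames(nu) <- list(model$deconv$barcodes, type_names)
  res <- structure(list(
    nu = nu,
    capture_bias = stats::setNames(est$bias, model$deconv$genes),
    background_mu = stats::setNames(est$background, model$deconv$genes),
    foreground = stats::setNames(est$foreground, model$deconv$barcodes),
    theta = stats::setNames(est$theta, model$deconv$genes),
    posterior = post, model = model,
    type_names = type_names, genes = model$deconv$genes,
    threshold = model$deconv$spec$presence_threshold,
    seed = config$seed,
    presence = NULL, presence_logLR = NULL), class = "deconvolution_result")
  if (run_presence) {
    lr <- presence_test(res, model, celltype = NULL,
                        n_mc = model$deconv$spec$n_mc_presence,
                        seed = config$seed + 1)
    res$presence_logLR <- lr
    res$presence <- lr > res$threshold
  }
  res
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat("<deconvolution_result>", nrow(x$nu), "spots x", ncol(x$nu),
      "cell types (threshold", x$threshold, ")\n")
  print(round(utils::head(x$nu, 3), 3))
  invisible(x)
}

# spot-wise NB log-likelihood matrix (spots) for one joint posterior draw,
# with the option of zeroing one cell type and renormalizing the rest
.deconv_spot_loglik <- function(draw, d, zero_type = NULL) {
  nu <- draw$nu
  if (!is.null(zero_type)) {
    nu[, zero_type] <- 0
    rs <- rowSums(nu)
    rs[rs == 0] <- 1
    nu <- nu / rs
  }
  rho <- d$rho_base
  if (d$rbc_enabled) rho[d$rbc_idx, d$hb_idx] <- draw$rbc_rho
  if (d$n_comp) rho[d$hep_idx, d$comp_idx] <- draw$comp_rho
  rho_b <- sweep(rho, 2, exp(draw$bias), "*")
  mu <- (nu %*% rho_b) * (d$lib * draw$foreground) +
    matrix(draw$background, d$S, d$G, byrow = TRUE)
  th <- rep(draw$theta, each = d$S)
  rowSums(stats::dnbinom(d$counts, size = th, mu = pmax(mu, .MU_FLOOR),
                         log = TRUE))
}

#' Monte-Carlo likelihood-ratio presence test
#'
#' Estimates, per spot, `log [ mean_m P(x | draw_m) / mean_m P(x | draw_m,
#' nu_celltype = 0) ]` over joint posterior draws, where zeroing a cell type
#' renormalizes the remaining proportions onto the simplex. A cell type is
#' called present when the log-LR exceeds the spec threshold (default 10).
#'
#' @param result A fitted `deconvolution_result`.
#' @param model The model it was fitted on (defaults to the stored one).
#' @param celltype Cell type name, or NULL for all cell types.
#' @param spot Spot index/name, or NULL for all spots.
#' @param n_mc Number of Monte-Carlo posterior draws (>= 1).
#' @param seed Seed for the draws.
#' @return A spot x celltype matrix of log-LRs (dropped to a vector/scalar
#'   when a single cell type/spot is requested).
#' @export
presence_test <- function(result, model = result$model, celltype = NULL,
                          spot = NULL, n_mc = 100, seed = 1) {
  stopifnot(inherits(result, "deconvolution_result"), n_mc >= 1)
  d <- model$data
  types <- if (is.null(celltype)) result$type_names else celltype
  miss <- setdiff(types, result$type_names)
  if (length(miss)) stop("presence_test: unknown cell type(s): ",
                         paste(miss, collapse = ", "))
  draws <- sample_posterior(result$posterior, n_mc, seed)
  ll_full <- matrix(NA_real_, n_mc, d$S)
  ll_zero <- array(NA_real_, c(n_mc, d$S, length(types)))
  for (m in seq_len(n_mc)) {
    draw <- lapply(draws, function(a) {
      if (length(dim(a)) == 3) a[m, , ] else if (is.matrix(a)) a[m, ] else a[m]
    })
    ll_full[m, ] <- .deconv_spot_loglik(draw, d)
    for (j in seq_along(types)) {
      ti <- match(types[j], result$type_names)
      ll_zero[m, , j] <- .deconv_spot_loglik(draw, d, zero_type = ti)
    }
  }
  lme <- function(v) logsumexp(v) - log(length(v))
  lr <- matrix(NA_real_, d$S, length(types),
               dimnames = list(model$deconv$barcodes, types))
  for (j in seq_along(types)) {
    lr[, j] <- apply(ll_full, 2, lme) - apply(ll_zero[, , j, drop = FALSE], 2, lme)
  }
  if (!is.null(spot)) lr <- lr[spot, , drop = length(types) > 1]
  if (length(types) == 1 && is.matrix(lr)) lr <- lr[, 1]
  lr
}

#' Tidy per-spot abundance table
#'
#' @param result A fitted `deconvolution_result` (with presence computed).
#' @return Data frame with barcode, coordinates, per-type expected
#'   proportions `nu_*` and presence calls `present_*`.
#' @export
abundance_table <- function(result) {
  stopifnot(inherits(result, "deconvolution_result"))
  df <- data.frame(barcode = rownames(result$nu))
  co <- result$model$deconv$coords
  if (!is.null(co)) {
    df <- cbind(df, co[match(df$barcode, co$barcode),
                       setdiff(names(co), "barcode"), drop = FALSE])
  }
  nu <- result$nu
  colnames(nu) <- paste0("nu_", colnames(nu))
  df <- cbind(df, as.data.frame(nu))
  if (!is.null(result$presence)) {
    pr <- result$presence
    colnames(pr) <- paste0("present_", colnames(pr))
    df <- cbind(df, as.data.frame(pr))
  }
  rownames(df) <- NULL
  df
}
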