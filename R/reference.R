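#' Estimate a cell-type expression reference from annotated counts
#'
#' Fits the linear negative-binomial model
#' `counts[c, g] ~ NB(lib_c * rho[type(c), g] * factor_g^[nucleus], theta[type(c), g])`
#' by variational inference: `rho` and `theta` are latent per (cell type,
#' gene), and nuclei get a gene-specific multiplicative correction factor
#' for the systematic differences between single-cell and single-nucleus
#' capture. The returned `rho` is the uncorrected (whole-cell) profile —
#' the one spatial deconvolution should use — with the factor reported
#' separately.
#'
#' Priors: broad Normal(0, 5^2) on log-rho and log-theta in unconstrained
#' space; log-Normal(0, 1) on the nucleus factor. Locations are initialized
#' at pooled method-of-moments estimates so the optimization starts near the
#' MLE.
#'
#' @param counts Cell x gene non-negative integer matrix.
#' @param celltype_labels Character/factor, one per cell.
#' @param assay_labels `"cell"` or `"nucleus"`, one per cell.
#' @param config A [fit_config()]; the default runs 500 steps.
#' @return A [reference_profile()] with the fitted posterior attached.
#' @export
estimate_reference <- function(counts, celltype_labels, assay_labels,
                               config = fit_config(n_steps = 500)) {
  counts <- as.matrix(counts)
  n_cells <- nrow(counts)
  stopifnot(length(celltype_labels) == n_cells,
            length(assay_labels) == n_cells)
  if (!all(assay_labels %in% c("cell", "nucleus"))) {
    stop("estimate_reference: unknown assay label(s): ",
         paste(setdiff(assay_labels, c("cell", "nucleus")), collapse = ", "))
  }
  celltypes <- sort(unique(as.character(celltype_labels)))
  tab <- table(celltype_labels)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    stop("estimate_reference: cell type(s) with < 2 cells: ",
         paste(small, collapse = ", "))
  }
  genes <- colnames(counts)
  n_genes <- ncol(counts)
  n_types <- length(celltypes)
  ti <- match(as.character(celltype_labels), celltypes)
  nuc <- assay_labels == "nucleus"
  any_nuc <- any(nuc)
  lib <- rowSums(counts)

  # method-of-moments init: pooled expression fraction per type
  init_rho <- matrix(NA_real_, n_types, n_genes,
                     dimnames = list(celltypes, genes))
  for (t in seq_len(n_types)) {
    sel <- ti == t & !nuc
    if (!any(sel)) sel <- ti == t
    init_rho[t, ] <- colSums(counts[sel, , drop = FALSE]) / sum(lib[sel])
  }
  init_rho <- pmax(init_rho, 1e-8)

  latents <- list(
    vi_latent("rho", c(n_types, n_genes), "positive",
              init_loc = log(init_rho), init_log_scale = -2),
    vi_latent("theta", c(n_types, n_genes), "positive",
              init_loc = log(3), init_log_scale = -2)
  )
  if (any_nuc) {
    latents <- c(latents, list(
      vi_latent("factor", n_genes, "positive", init_loc = 0,
                init_log_scale = -1)))
  }

  data <- list(counts = counts, lib = lib, ti = ti, nuc = nuc,
               any_nuc = any_nuc, n_types = n_types)

  log_joint <- function(lat, d) {
    mu <- lat$rho[d$ti, , drop = FALSE] * d$lib
    if (d$any_nuc) {
      mu[d$nuc, ] <- sweep(mu[d$nuc, , drop = FALSE], 2, lat$factor, "*")
    }
    th <- lat$theta[d$ti, , drop = FALSE]
    ll <- sum(stats::dnbinom(d$counts, size = th, mu = pmax(mu, .MU_FLOOR),
                             log = TRUE))
    lp <- sum(stats::dnorm(log(lat$rho), 0, 5, log = TRUE)) +
      sum(stats::dnorm(log(lat$theta), 0, 5, log = TRUE))
    if (d$any_nuc) lp <- lp + sum(stats::dnorm(log(lat$factor), 0, 1, log = TRUE))
    ll + lp
  }

  grad_log_joint <- function(lat, d) {
    mu <- lat$rho[d$ti, , drop = FALSE] * d$lib
    if (d$any_nuc) {
      mu[d$nuc, ] <- sweep(mu[d$nuc, , drop = FALSE], 2, lat$factor, "*")
    }
    th <- lat$theta[d$ti, , drop = FALSE]
    dmu <- nb_grad_mu(d$counts, mu, th)
    # chain: mu = lib * rho_type * factor^nuc
    dmu_rho_scale <- dmu * d$lib
    if (d$any_nuc) {
      dmu_rho_scale[d$nuc, ] <- sweep(dmu_rho_scale[d$nuc, , drop = FALSE],
                                      2, lat$factor, "*")
    }
    g_rho <- rowsum(dmu_rho_scale, d$ti) # rows ordered by type index 1..T
    g_rho <- g_rho - log(lat$rho) / (25 * lat$rho)
    g_theta <- rowsum(nb_grad_theta(d$counts, mu, th), d$ti)
    g_theta <- g_theta - (log(lat$theta) / 25) / lat$theta
    out <- list(rho = g_rho, theta = g_theta)
    if (d$any_nuc) {
      g_fac <- colSums((dmu * mu)[d$nuc, , drop = FALSE]) / lat$factor
      out$factor <- g_fac - log(lat$factor) / lat$factor
    }
    out
  }

  model <- vi_model(latents, log_joint, grad_log_joint, data)
  post <- fit_bbvi(model, config)

  est <- posterior_mean(post)
  rho <- est$rho; dimnames(rho) <- list(celltypes, genes)
  theta <- est$theta; dimnames(theta) <- list(celltypes, genes)
  nf <- if (any_nuc) est$factor else rep(1, n_genes)
  names(nf) <- genes
  reference_profile(rho, theta, nf, posterior = post)
}
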