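#' Synthetic data generators with full ground truth
#'
#' Every generator in this file is a pure function of its arguments and a
#' seed, and returns the generated data together with a `sim_truth` list
#' recording every stochastic quantity used (profiles, zonation coordinates,
#' Dirichlet compositions, capture biases, backgrounds, curve parameters), so
#' downstream recovery tests always have ground truth.
#'
#' @name synthetic
NULL

.mouse_hb <- c("Hbb-bt", "Hbb-bs", "Hba-a1", "Hba-a2")
.human_hb <- c("HBB", "HBA1", "HBA2")
.mouse_comp <- c("C3", "C2", "C4b")
.human_comp <- c("C3", "C2", "C4B")

#' Default hemoglobin / complement gene symbols per species
#' @param species `"mouse"` or `"human"`.
#' @return Character vector of gene symbols.
#' @export
hemoglobin_genes <- function(species = c("mouse", "human")) {
  switch(match.arg(species), mouse = .mouse_hb, human = .human_hb)
}

#' @rdname hemoglobin_genes
#' @export
complement_genes <- function(species = c("mouse", "human")) {
  switch(match.arg(species), mouse = .mouse_comp, human = .human_comp)
}

.liver_celltypes <- c("Hepatocyte", "KC", "LSEC", "Stellate", "Cholangiocyte",
                      "Tcell", "Bcell", "Neutrophil")

.gene_names <- function(n_genes, species) {
  special <- c(hemoglobin_genes(species), complement_genes(species))
  stopifnot(n_genes > length(special) + 10)
  base <- sprintf(if (species == "mouse") "Gene%04d" else "GENE%04d",
                  seq_len(n_genes - length(special)))
  c(special, base)
}

.rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s == 0) { g[which.max(alpha)] <- 1; s <- 1 }
  g / s
}

#' Simulate an annotated single-cell / single-nucleus reference
#'
#' Cell-type mean profiles are log-normal with planted marker blocks (one
#' block per type, boosted 8-fold); profiles are normalized to sum to one so
#' they are expressed per unit library. Nucleus cells' means are multiplied
#' by gene-specific correction factors (a planted subset of genes deviates
#' from 1), and counts are negative binomial with per-(type, gene)
#' dispersions.
#'
#' @param n_celltypes,n_genes,n_cells Sizes (all >= 1).
#' @param frac_nuclei Fraction of cells that are nuclei in `[0, 1]`.
#' @param seed Integer seed; output is bit-exact reproducible.
#' @param species `"mouse"` or `"human"` (controls gene symbols).
#' @param marker_boost Fold-change of planted marker blocks (default 8).
#' @param marker_frac Fraction of genes belonging to marker blocks (default
#'   0.3, emulating the marker-rich gene panels used for deconvolution).
#' @param lib_meanlog,lib_sdlog Log-normal library-size parameters
#'   (defaults 8.5 / 0.3, typical single-cell depths).
#' @return List with `counts` (cell x gene integer matrix), `celltype`,
#'   `assay` (`"cell"`/`"nucleus"`), `genes`, `celltypes`, and `truth`
#'   (`sim_truth`: `rho`, `theta`, `nucleus_factor`, `lib`, `markers`).
#' @export
make_reference <- function(n_celltypes = 5, n_genes = 200, n_cells = 2000,
                           frac_nuclei = 0.3, seed = 1, species = "mouse",
                           marker_boost = 8, marker_frac = 0.3,
                           lib_meanlog = 8.5, lib_sdlog = 0.3) {
  stopifnot(n_celltypes >= 1, n_genes >= 1, n_cells >= 1,
            frac_nuclei >= 0, frac_nuclei <= 1)
  set.seed(seed)
  genes <- .gene_names(n_genes, species)
  celltypes <- if (n_celltypes <= length(.liver_celltypes)) {
    .liver_celltypes[seq_len(n_celltypes)]
  } else {
    sprintf("CT%02d", seq_len(n_celltypes))
  }

  base <- stats::rnorm(n_genes, 0, 1)
  logmu <- matrix(rep(base, each = n_celltypes), n_celltypes, n_genes,
                  dimnames = list(celltypes, genes))
  # per-type deviations around the shared baseline: real cell types differ
  # strongly over most genes, not only at a few markers
  logmu <- logmu + matrix(stats::rnorm(n_celltypes * n_genes, 0, 1.0),
                          n_celltypes, n_genes)
  # planted marker blocks: contiguous slices after the special symbols
  n_special <- length(hemoglobin_genes(species)) + length(complement_genes(species))
  block <- max(3L, floor((n_genes - n_special) * marker_frac / n_celltypes))
  markers <- list()
  for (t in seq_len(n_celltypes)) {
    idx <- n_special + ((t - 1) * block + 1):(t * block)
    idx <- idx[idx <= n_genes]
    logmu[t, idx] <- logmu[t, idx] + log(marker_boost)
    markers[[celltypes[t]]] <- genes[idx]
  }
  rho <- exp(logmu)
  rho <- rho / rowSums(rho)

  theta <- matrix(exp(stats::rnorm(n_celltypes * n_genes, log(3), 0.4)),
                  n_celltypes, n_genes, dimnames = dimnames(rho))

  nucleus_factor <- rep(1, n_genes)
  names(nucleus_factor) <- genes
  n_fac <- floor(n_genes * 0.3)
  fac_idx <- sample(n_genes, n_fac)
  nucleus_factor[fac_idx] <- exp(sample(c(-1, 1), n_fac, replace = TRUE) *
                                   stats::runif(n_fac, 0.4, 1.0))

  celltype <- sample(celltypes, n_cells, replace = TRUE)
  assay <- ifelse(stats::runif(n_cells) < frac_nuclei, "nucleus", "cell")
  lib <- stats::rlnorm(n_cells, lib_meanlog, lib_sdlog)

  ti <- match(celltype, celltypes)
  mu <- rho[ti, , drop = FALSE] * lib
  nuc <- assay == "nucleus"
  if (any(nuc)) {
    mu[nuc, ] <- sweep(mu[nuc, , drop = FALSE], 2, nucleus_factor, "*")
  }
  th <- theta[ti, , drop = FALSE]
  counts <- matrix(stats::rnbinom(length(mu), size = th, mu = mu),
                   n_cells, n_genes,
                   dimnames = list(sprintf("cell%05d", seq_len(n_cells)), genes))

  truth <- structure(list(rho = rho, theta = theta,
                          nucleus_factor = nucleus_factor, lib = lib,
                          markers = markers, species = species),
                     class = "sim_truth")
  list(counts = counts, celltype = celltype, assay = assay,
       genes = genes, celltypes = celltypes, truth = truth)
}

# logistic abundance-vs-z weight curves, one per cell type
.zonation_weight <- function(z, curve) {
  if (is.null(curve)) return(rep(1, length(z)))
  curve$floor + (1 - curve$floor) * stats::plogis((z - curve$mid) / curve$steep *
                                                    curve$direction)
}

#' Simulate a spatial spot dataset from reference truth
#'
#' Per spot, a zonation coordinate `z* ~ Uniform(0,1)` and cell-type
#' proportions `nu* ~ Dirichlet` whose concentrations are modulated by
#' stored logistic curves of `z*` for the zonated cell types. Zonated genes
#' get a stored multiplicative log-scale modulation of `z*`. Counts follow
#' `NB((nu* . rho) * exp(b*) * m(z*) * lib * fg + bg)` with per-gene
#' dispersion; red-blood-cell contamination adds hemoglobin counts at
#' `rbc_rate` of the library.
#'
#' @param truth Reference truth from [make_reference()] (or a compatible
#'   list with `rho`, `species`).
#' @param n_spots Number of spots.
#' @param zonated_celltypes Character vector of cell types with
#'   zonation-modulated abundance.
#' @param zonated_genes Character vector (or count) of genes with
#'   zonation-modulated expression.
#' @param absent_celltypes Cell types given exactly zero abundance in every
#'   spot (their Dirichlet concentration is zeroed), for presence-test
#'   calibration.
#' @param gene_modulation Optional data frame (gene, amplitude, midpoint,
#'   steepness) fixing the per-gene zonation programs. Replicate datasets of
#'   the same tissue must share this (pass the first replicate's
#'   `truth$gene_modulation`); when NULL a new program is drawn for
#'   `zonated_genes`.
#' @param rbc_rate Mean fraction of the library contributed by red-blood-cell
#'   hemoglobin contamination (0 disables).
#' @param seed Seed.
#' @param bias_sd SD of the per-gene capture bias `b* ~ N(0, bias_sd)`.
#' @param planted_bias Optional named vector overriding `b*` for given genes.
#' @param ambient_scale Scale of the per-gene additive ambient background
#'   (mean counts per spot; 0 disables).
#' @param fg_shape1,fg_shape2 Beta parameters of the per-spot foreground
#'   (defaults 18, 2: mean 0.9).
#' @param lib_meanlog,lib_sdlog Spot library-size log-normal parameters
#'   (defaults 9 / 0.3, Visium-scale depths).
#' @param base_conc Total Dirichlet concentration (default 10).
#' @param condition,sample_id Labels stored on the dataset.
#' @return List with `dataset` (a `spot_dataset`) and `truth` (`sim_truth`
#'   with `z`, `nu`, `bias`, `background`, `foreground`, `lib`,
#'   `theta_gene`, `zonation_curves`, `gene_modulation`, `rbc_frac`).
#' @export
make_spots <- function(truth, n_spots = 500, zonated_celltypes = NULL,
                       zonated_genes = NULL, absent_celltypes = NULL,
                       rbc_rate = 0, seed = 1, gene_modulation = NULL,
                       bias_sd = 0.2, planted_bias = NULL, ambient_scale = 0.2,
                       fg_shape1 = 18, fg_shape2 = 2,
                       lib_meanlog = 9, lib_sdlog = 0.3, base_conc = 10,
                       condition = "A", sample_id = "S1") {
  set.seed(seed)
  rho <- truth$rho
  celltypes <- rownames(rho)
  genes <- colnames(rho)
  n_types <- nrow(rho)
  n_genes <- ncol(rho)
  species <- if (!is.null(truth$species)) truth$species else "mouse"
  stopifnot(all(zonated_celltypes %in% celltypes))
  if (is.numeric(zonated_genes) && length(zonated_genes) == 1) {
    zonated_genes <- setdiff(genes, c(hemoglobin_genes(species),
                                      complement_genes(species)))[seq_len(zonated_genes)]
  }
  stopifnot(all(zonated_genes %in% genes))

  z <- stats::runif(n_spots)

  curves <- vector("list", n_types)
  names(curves) <- celltypes
  zc <- which(celltypes %in% zonated_celltypes)
  for (i in seq_along(zc)) {
    curves[[zc[i]]] <- list(mid = 0.3 + 0.4 * ((i - 1) %% 3) / 2,
                            steep = 0.12,
                            direction = if (i %% 2 == 0) -1 else 1,
                            floor = 0.05)
  }
  stopifnot(all(absent_celltypes %in% celltypes))
  alpha <- matrix(0, n_spots, n_types)
  for (t in seq_len(n_types)) {
    w <- .zonation_weight(z, curves[[t]])
    alpha[, t] <- base_conc * w / n_types
  }
  alpha[, celltypes %in% absent_celltypes] <- 0
  nu <- matrix(apply(alpha, 1, .rdirichlet_one), n_types, n_spots)
  nu <- t(nu)
  colnames(nu) <- celltypes

  # per-gene zonation modulation of expression (log-scale logistic);
  # replicates of the same tissue share the program via `gene_modulation`
  mod_par <- gene_modulation
  if (is.null(mod_par) && length(zonated_genes)) {
    gi <- match(zonated_genes, genes)
    amp <- sample(c(-1, 1), length(gi), replace = TRUE) *
      stats::runif(length(gi), 1.0, 2.0)
    mid <- stats::runif(length(gi), 0.25, 0.75)
    mod_par <- data.frame(gene = zonated_genes, amplitude = amp,
                          midpoint = mid, steepness = 0.1)
  }
  M <- matrix(1, n_spots, n_genes)
  if (!is.null(mod_par)) {
    stopifnot(all(mod_par$gene %in% genes))
    gi <- match(mod_par$gene, genes)
    for (j in seq_along(gi)) {
      M[, gi[j]] <- exp(mod_par$amplitude[j] *
                          (stats::plogis((z - mod_par$midpoint[j]) /
                                           mod_par$steepness[j]) - 0.5))
    }
  }

  bias <- stats::rnorm(n_genes, 0, bias_sd)
  names(bias) <- genes
  if (!is.null(planted_bias)) {
    stopifnot(all(names(planted_bias) %in% genes))
    bias[names(planted_bias)] <- planted_bias
  }
  background <- if (ambient_scale > 0) ambient_scale * stats::rexp(n_genes) else
    rep(0, n_genes)
  names(background) <- genes
  foreground <- stats::rbeta(n_spots, fg_shape1, fg_shape2)
  lib <- stats::rlnorm(n_spots, lib_meanlog, lib_sdlog)
  theta_gene <- exp(stats::rnorm(n_genes, log(30), 0.3))
  names(theta_gene) <- genes

  mix <- (nu %*% rho) * M
  mu <- sweep(mix, 2, exp(bias), "*") * (lib * foreground) +
    matrix(background, n_spots, n_genes, byrow = TRUE)

  rbc_frac <- rep(0, n_spots)
  hb <- intersect(hemoglobin_genes(species), genes)
  if (rbc_rate > 0 && length(hb)) {
    rbc_frac <- stats::runif(n_spots, 0, 2 * rbc_rate)
    hb_profile <- .rdirichlet_one(rep(2, length(hb)))
    mu[, hb] <- mu[, hb] + (rbc_frac * lib) %o% hb_profile
  }

  counts <- matrix(stats::rnbinom(length(mu), size = rep(theta_gene, each = n_spots),
                                  mu = mu),
                   n_spots, n_genes,
                   dimnames = list(sprintf("spot%04d", seq_len(n_spots)), genes))

  side <- ceiling(sqrt(n_spots))
  coords <- data.frame(barcode = rownames(counts),
                       array_row = (seq_len(n_spots) - 1) %/% side,
                       array_col = (seq_len(n_spots) - 1) %% side)

  dataset <- spot_dataset(counts, coords = coords,
                          sample_id = sample_id, condition = condition)
  truth_out <- structure(list(z = z, nu = nu, bias = bias,
                              background = background, foreground = foreground,
                              lib = lib, theta_gene = theta_gene,
                              zonation_curves = curves, gene_modulation = mod_par,
                              rbc_frac = rbc_frac, rho = rho, species = species),
                         class = "sim_truth")
  list(dataset = dataset, truth = truth_out)
}

#' Attach a simulated multiplexed antibody panel to a spot dataset
#'
#' Each protein targets one cell type: its foreground rate tracks the true
#' abundance of that type, with zonated cell types targeted first so the
#' panel carries the zonation signal. Counts are drawn from the
#' foreground/background negative-binomial mixture with a shared dispersion.
#'
#' @param spots Result of [make_spots()] (list with `dataset` and `truth`).
#' @param n_proteins Panel size (0 leaves the protein slot absent).
#' @param seed Seed.
#' @param w_fg Foreground mixing weight (scalar or per protein).
#' @param theta Shared mixture dispersion.
#' @param bg_scale Background rate relative to the foreground base rate.
#' @return `spots` with `dataset$protein_counts` filled and
#'   `truth$protein` recording the panel parameters.
#' @export
make_protein_panel <- function(spots, n_proteins = 24, seed = 1,
                               w_fg = 0.8, theta = 10, bg_scale = 0.1) {
  stopifnot(is.list(spots), !is.null(spots$dataset), !is.null(spots$truth))
  if (n_proteins == 0) return(spots)
  set.seed(seed)
  nu <- spots$truth$nu
  lib <- spots$truth$lib
  n_spots <- nrow(nu)
  celltypes <- colnames(nu)
  zonated <- names(Filter(Negate(is.null), spots$truth$zonation_curves))
  order_types <- c(zonated, setdiff(celltypes, zonated))
  target <- rep_len(order_types, n_proteins)
  w_fg <- rep_len(w_fg, n_proteins)

  plib <- lib / 20
  scale_p <- 0.05 * exp(stats::rnorm(n_proteins, 0, 0.3))
  rho_bg <- bg_scale * scale_p * 0.5
  prot_names <- sprintf("ADT%02d_%s", seq_len(n_proteins), target)

  counts <- matrix(0L, n_spots, n_proteins,
                   dimnames = list(rownames(spots$dataset$counts), prot_names))
  for (p in seq_len(n_proteins)) {
    mu_fg <- scale_p[p] * (0.05 + nu[, target[p]]) * plib
    mu_bg <- rho_bg[p] * plib
    is_fg <- stats::runif(n_spots) < w_fg[p]
    mu <- ifelse(is_fg, mu_fg, mu_bg)
    counts[, p] <- stats::rnbinom(n_spots, size = theta, mu = mu)
  }
  spots$dataset$protein_counts <- counts
  spots$truth$protein <- list(target_type = target, scale = scale_p,
                              rho_bg = rho_bg, w_fg = w_fg, theta = theta,
                              plib = plib)
  spots
}

#' Simulate a matched two-condition spot dataset pair
#'
#' Both conditions share reference profiles, zonation structure and noise
#' parameters; condition B multiplies the abundance-vs-z concentration of
#' `interaction_celltypes` by a pericentral logistic factor of strength
#' `effect` (odds multiplier; `effect = 1` or an empty interaction set gives
#' an exact null).
#'
#' @param truth Reference truth from [make_reference()].
#' @param n_spots_per_condition Spots per condition.
#' @param interaction_celltypes Cell types whose curve differs in condition B.
#' @param effect Pericentral abundance multiplier in condition B (default 2).
#' @param seed Seed.
#' @param ... Passed to [make_spots()] (both conditions get the same values).
#' @return List with `A`, `B` (each a [make_spots()] result) and
#'   `interaction` recording the planted effect.
#' @export
make_two_condition <- function(truth, n_spots_per_condition = 500,
                               interaction_celltypes = character(), effect = 2,
                               seed = 1, ...) {
  A <- make_spots(truth, n_spots = n_spots_per_condition, seed = seed,
                  condition = "A", sample_id = "SA", ...)
  B <- make_spots(truth, n_spots = n_spots_per_condition, seed = seed + 1,
                  condition = "B", sample_id = "SB",
                  gene_modulation = A$truth$gene_modulation, ...)
  if (length(interaction_celltypes) && effect != 1) {
    stopifnot(all(interaction_celltypes %in% colnames(B$truth$nu)))
    set.seed(seed + 2)
    z <- B$truth$z
    boost <- 1 + (effect - 1) * stats::plogis((z - 0.7) / 0.08)
    nu <- B$truth$nu
    for (ct in interaction_celltypes) nu[, ct] <- nu[, ct] * boost
    nu <- nu / rowSums(nu)
    B$truth$nu <- nu
    # re-draw condition-B counts from the boosted composition
    mu <- (nu %*% B$truth$rho)
    if (!is.null(B$truth$gene_modulation)) {
      gm <- B$truth$gene_modulation
      gi <- match(gm$gene, colnames(mu))
      for (j in seq_along(gi)) {
        mu[, gi[j]] <- mu[, gi[j]] *
          exp(gm$amplitude[j] * (stats::plogis((z - gm$midpoint[j]) / gm$steepness[j]) - 0.5))
      }
    }
    mu <- sweep(mu, 2, exp(B$truth$bias), "*") *
      (B$truth$lib * B$truth$foreground) +
      matrix(B$truth$background, nrow(mu), ncol(mu), byrow = TRUE)
    counts <- matrix(stats::rnbinom(length(mu),
                                    size = rep(B$truth$theta_gene, each = nrow(mu)),
                                    mu = mu),
                     nrow(mu), ncol(mu), dimnames = dimnames(B$dataset$counts))
    B$dataset$counts <- counts
    B$dataset$lib <- rowSums(counts)
  }
  list(A = A, B = B,
       interaction = list(celltypes = interaction_celltypes, effect = effect,
                          band_mid = 0.7, band_steep = 0.08))
}

#' Simulate a two-species marker-discovery problem
#'
#' Two annotated cell-by-gene count matrices ("human" and "mouse") with a
#' designated KC cluster in each. `n_shared_markers` KC markers are
#' orthologous between species; `n_private_markers` per species are planted
#' under species-unique symbols absent from the ortholog table (mimicking
#' genes with no cross-species ortholog). Every other cluster gets its own
#' marker block so differential-expression scoring has realistic structure.
#'
#' @param n_genes Genes per species.
#' @param n_shared_markers Conserved KC markers.
#' @param n_private_markers Species-private KC markers (each species).
#' @param ortholog_noise Fraction of non-marker ortholog rows dropped.
#' @param seed Seed.
#' @param n_cells_per_cluster Cells per cluster per species.
#' @return List with per-species `human`/`mouse` (each: `counts`, `norm`
#'   (library-normalized), `labels`, `genes`, `hvg`), `orthologs`
#'   (data.frame mouse, human) and `truth` (planted conserved/private sets,
#'   in human symbols for the conserved set).
#' @export
make_species_pair <- function(n_genes = 300, n_shared_markers = 10,
                              n_private_markers = 5, ortholog_noise = 0,
                              seed = 1, n_cells_per_cluster = 60) {
  set.seed(seed)
  clusters <- c("KC", "Monocyte", "Hepatocyte", "EC")
  n_clusters <- length(clusters)

  idx_shared <- seq_len(n_shared_markers)
  idx_private <- n_shared_markers + seq_len(n_private_markers)
  idx_other_markers <- max(idx_shared, idx_private) +
    seq_len(4 * (n_clusters - 1))          # 4 markers per non-KC cluster
  stopifnot(n_genes > max(idx_other_markers) + 20)

  gene_tab <- data.frame(
    human = sprintf("GENE%04d", seq_len(n_genes)),
    mouse = sprintf("Gene%04d", seq_len(n_genes)))
  # private KC markers: species-unique symbols, no ortholog relationship
  gene_tab$human[idx_private] <- sprintf("HSPRIV%02d", seq_along(idx_private))
  gene_tab$mouse[idx_private] <- sprintf("Mmpriv%02d", seq_along(idx_private))

  sim_species <- function(col) {
    genes <- gene_tab[[col]]
    base <- stats::rnorm(n_genes, 0, 0.8)
    logmu <- matrix(rep(base, each = n_clusters), n_clusters, n_genes,
                    dimnames = list(clusters, genes))
    logmu[1, c(idx_shared, idx_private)] <-
      logmu[1, c(idx_shared, idx_private)] + log(12)
    for (k in 2:n_clusters) {
      mi <- idx_other_markers[(k - 2) * 4 + 1:4]
      logmu[k, mi] <- logmu[k, mi] + log(12)
    }
    rho <- exp(logmu); rho <- rho / rowSums(rho)
    labels <- rep(clusters, each = n_cells_per_cluster)
    lib <- stats::rlnorm(length(labels), 8, 0.25)
    mu <- rho[match(labels, clusters), ] * lib
    counts <- matrix(stats::rnbinom(length(mu), size = 4, mu = mu),
                     length(labels), n_genes,
                     dimnames = list(sprintf("%s_cell%04d", col, seq_along(labels)),
                                     genes))
    norm <- counts / rowSums(counts) * stats::median(rowSums(counts))
    v <- apply(log1p(norm), 2, stats::var)
    hvg <- genes[order(v, decreasing = TRUE)][seq_len(min(80, n_genes))]
    list(counts = counts, norm = norm, labels = labels, genes = genes, hvg = hvg)
  }

  human <- sim_species("human")
  mouse <- sim_species("mouse")

  orth <- gene_tab[-idx_private, ]
  if (ortholog_noise > 0) {
    marker_rows <- seq_len(max(idx_shared))
    droppable <- setdiff(seq_len(nrow(orth)), marker_rows)
    drop <- sample(droppable, floor(ortholog_noise * length(droppable)))
    if (length(drop)) orth <- orth[-drop, ]
  }

  truth <- structure(list(
    conserved = gene_tab$human[idx_shared],
    conserved_mouse = gene_tab$mouse[idx_shared],
    private_human = gene_tab$human[idx_private],
    private_mouse = gene_tab$mouse[idx_private],
    target_cluster = "KC"), class = "sim_truth")
  list(human = human, mouse = mouse,
       orthologs = orth[, c("mouse", "human")], truth = truth)
}
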