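#' Read a 10x-style sparse count matrix directory
#'
#' Expects `matrix.mtx`, `features.tsv` (or `genes.tsv`) and `barcodes.tsv`,
#' plain or gzipped. The matrix is stored gene-major on disk (genes x
#' barcodes, the 10x convention) and returned barcode-major (spots/cells x
#' genes).
#'
#' @param dir Directory containing the triplet files.
#' @return Integer matrix (barcodes x genes) with dimnames.
#' @export
read_10x_counts <- function(dir) {
  find <- function(stems) {
    for (st in stems) for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(st, ext))
      if (file.exists(p)) return(p)
    }
    stop("read_10x_counts: none of ", paste(stems, collapse = "/"),
         " found in ", dir)
  }
  mp <- find("matrix.mtx")
  fp <- find(c("features.tsv", "genes.tsv"))
  bp <- find("barcodes.tsv")
  m <- Matrix::readMM(mp)
  read_tsv0 <- function(p) {
    tryCatch(utils::read.table(p, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE),
             error = function(e) data.frame(V1 = character(0)))
  }
  feats <- read_tsv0(fp)
  bars <- read_tsv0(bp)[, 1]
  if (nrow(m) != nrow(feats) || ncol(m) != length(bars)) {
    stop("read_10x_counts: matrix dimensions (", nrow(m), " x ", ncol(m),
         ") do not match sidecar files (", nrow(feats), " features, ",
         length(bars), " barcodes)")
  }
  xs <- if (methods::.hasSlot(m, "x")) m@x else rep(1, Matrix::nnzero(m))
  if (any(xs != floor(xs)) || any(xs < 0)) {
    stop("read_10x_counts: non-integer or negative entries")
  }
  if (nrow(m) == 0 || ncol(m) == 0) {
    warning("read_10x_counts: empty matrix")
  }
  out <- t(as.matrix(m))
  dimnames(out) <- list(bars, if (ncol(feats) >= 2) feats[, 2] else feats[, 1])
  storage.mode(out) <- "integer"
  out
}

#' Write a count matrix as a 10x-style sparse triplet directory
#'
#' @param counts Barcode x gene integer matrix.
#' @param dir Output directory (created if needed).
#' @param gzip Write gzipped files (default FALSE).
#' @return `dir`, invisibly.
#' @export
write_10x_counts <- function(counts, dir, gzip = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(t(as.matrix(counts)), sparse = TRUE)
  ext <- if (gzip) ".gz" else ""
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(m, mtx)
  if (gzip) {
    con_in <- file(mtx, "rb"); raw <- readBin(con_in, "raw", file.size(mtx))
    close(con_in); unlink(mtx)
    con <- gzfile(paste0(mtx, ".gz"), "wb"); writeBin(raw, con); close(con)
  }
  wr <- function(x, name) {
    con <- if (gzip) gzfile(file.path(dir, paste0(name, ext)), "w") else
      file(file.path(dir, name), "w")
    utils::write.table(x, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
  }
  genes <- colnames(counts)
  wr(data.frame(id = genes, symbol = genes,
                type = rep("Gene Expression", length(genes))),
     "features.tsv")
  wr(data.frame(bc = rownames(counts)), "barcodes.tsv")
  invisible(dir)
}

#' Read a Visium tissue-positions table and join it to counts
#'
#' @param csv Path to a tissue-positions CSV with columns barcode,
#'   in_tissue, array_row, array_col, pxl_row_in_fullres, pxl_col_in_fullres
#'   (header optional, the 10x layouts).
#' @param barcodes Optional barcodes to join against; spots missing a
#'   position are dropped with a message.
#' @return Data frame of positions (in-tissue spots only when the flag is
#'   present).
#' @export
read_spot_positions <- function(csv, barcodes = NULL) {
  first <- readLines(csv, n = 1)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  df <- utils::read.csv(csv, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    names(df)[seq_len(min(6, ncol(df)))] <-
      c("barcode", "in_tissue", "array_row", "array_col",
        "pxl_row_in_fullres", "pxl_col_in_fullres")[seq_len(min(6, ncol(df)))]
  }
  if (anyDuplicated(df$barcode)) stop("read_spot_positions: duplicated barcodes")
  if (!is.null(barcodes)) {
    keep <- barcodes %in% df$barcode
    if (!any(keep)) stop("read_spot_positions: no overlapping barcodes")
    if (!all(keep)) {
      message("read_spot_positions: dropping ", sum(!keep),
              " spot(s) without positions")
    }
    df <- df[match(barcodes[keep], df$barcode), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write a spot dataset to disk (counts triplet + positions CSV)
#'
#' @param dataset A [spot_dataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_spot_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "spot_dataset"))
  write_10x_counts(dataset$counts, file.path(dir, "counts"))
  if (!is.null(dataset$coords)) {
    utils::write.csv(dataset$coords, file.path(dir, "tissue_positions.csv"),
                     row.names = FALSE)
  }
  if (!is.null(dataset$protein_counts)) {
    write_10x_counts(dataset$protein_counts, file.path(dir, "protein_counts"))
  }
  invisible(dir)
}

#' Pipeline run configuration
#'
#' Collects every tunable of the analysis stages with the package defaults
#' (presence threshold 10, 10 spline knots with sigma 0.05, learning rates
#' 0.01/0.001, specificity constants 0.50/0.30/0.70 and score floor 10).
#' Serializable to YAML; every [run_pipeline()] output directory contains
#' the resolved configuration used.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param species `"mouse"` or `"human"`.
#' @param stages Stages to run, a subset of `c("simulate", "reference",
#'   "deconvolve", "zonate", "diffabund", "signature")`.
#' @param sim Simulation sizes (list; see defaults).
#' @param fit Fit settings shared by the model stages.
#' @param deconv,zonation,signature Stage-specific settings.
#' @return A `run_config`.
#' @export
run_config <- function(out_dir = "spotzone_run", seed = 1, species = "mouse",
                       stages = c("simulate", "reference", "deconvolve",
                                  "zonate", "diffabund"),
                       sim = list(), fit = list(), deconv = list(),
                       zonation = list(), signature = list()) {
  sim <- utils::modifyList(list(n_celltypes = 5, n_genes = 150,
                                n_cells = 1500, frac_nuclei = 0.3,
                                n_spots = 400,
                                zonated_celltypes = c("KC", "LSEC"),
                                zonated_genes = 60, rbc_rate = 0.03), sim)
  fit <- utils::modifyList(list(lr_variational = 0.01, lr_amortized = 0.001,
                                n_steps_reference = 400,
                                n_steps_deconv = 1200,
                                n_steps_zonation = 1500), fit)
  deconv <- utils::modifyList(list(presence_threshold = 10,
                                   n_mc_presence = 100,
                                   ambient_prior_frac = 0.02,
                                   ambient_prior_sd = 0.5), deconv)
  zonation <- utils::modifyList(list(n_knots = 10, sigma = 0.05), zonation)
  signature <- utils::modifyList(list(min_score = 10,
                                      specificity_threshold = 2,
                                      value_threshold = 0.50,
                                      frac_threshold = 0.30,
                                      exempt_frac = 0.70, seed_k = 10),
                                 signature)
  structure(list(out_dir = out_dir, seed = as.integer(seed), species = species,
                 stages = stages, sim = sim, fit = fit, deconv = deconv,
                 zonation = zonation, signature = signature),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> seed", x$seed, "->", x$out_dir, "\n  stages:",
      paste(x$stages, collapse = ", "), "\n")
  invisible(x)
}

#' Load / save a run configuration as YAML
#' @param path YAML file path.
#' @return A `run_config` ([read_run_config()]) or `path` ([write_run_config()]).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Executes the requested stages on a fully synthetic dataset with known
#' ground truth: simulate, reference estimation, deconvolution (with
#' presence calls), zonation (with amortized transfer), differential
#' abundance, and optionally the conserved-signature funnel. Each stage
#' writes CSV/JSON artifacts into its own subdirectory; the resolved
#' configuration and a stage log are written alongside.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(config$out_dir, "resolved_config.yaml"))
  logf <- file.path(config$out_dir, "run_log.txt")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                               "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  logline("spotzone pipeline; seed ", config$seed)
  res <- list(config = config)
  need <- function(stage, dep) {
    if (is.null(res[[dep]])) {
      stop("run_pipeline: stage '", stage, "' requires output of '", dep, "'")
    }
  }

  if ("simulate" %in% config$stages) {
    s <- config$sim
    res$reference_data <- make_reference(s$n_celltypes, s$n_genes, s$n_cells,
                                         s$frac_nuclei, seed = config$seed,
                                         species = config$species)
    res$spots <- make_spots(res$reference_data$truth, n_spots = s$n_spots,
                            zonated_celltypes = s$zonated_celltypes,
                            zonated_genes = s$zonated_genes,
                            rbc_rate = s$rbc_rate, seed = config$seed + 1)
    d <- file.path(config$out_dir, "simulate")
    write_spot_dataset(res$spots$dataset, d)
    utils::write.csv(data.frame(barcode = rownames(res$spots$dataset$counts),
                                z_true = res$spots$truth$z,
                                res$spots$truth$nu, check.names = FALSE),
                     file.path(d, "truth.csv"), row.names = FALSE)
    logline("simulate: ", nrow(res$spots$dataset$counts), " spots")
  }

  if ("reference" %in% config$stages) {
    need("reference", "reference_data")
    rd <- res$reference_data
    res$reference <- estimate_reference(
      rd$counts, rd$celltype, rd$assay,
      fit_config(n_steps = config$fit$n_steps_reference,
                 lr_variational = config$fit$lr_variational,
                 seed = config$seed + 2))
    d <- file.path(config$out_dir, "reference")
    dir.create(d, showWarnings = FALSE)
    utils::write.csv(res$reference$rho, file.path(d, "rho.csv"))
    utils::write.csv(res$reference$theta, file.path(d, "theta.csv"))
    utils::write.csv(data.frame(gene = res$reference$genes,
                                nucleus_factor = res$reference$nucleus_factor),
                     file.path(d, "nucleus_factor.csv"), row.names = FALSE)
    logline("reference: ", length(res$reference$celltypes), " cell types")
  }

  if ("deconvolve" %in% config$stages) {
    need("deconvolve", "reference"); need("deconvolve", "spots")
    spec <- deconv_model_spec(config$species,
                              presence_threshold = config$deconv$presence_threshold,
                              n_mc_presence = config$deconv$n_mc_presence,
                              ambient_prior_frac = config$deconv$ambient_prior_frac,
                              ambient_prior_sd = config$deconv$ambient_prior_sd)
    model <- build_deconv_model(res$reference, res$spots$dataset, spec)
    res$deconv <- fit_deconvolution(
      model, fit_config(n_steps = config$fit$n_steps_deconv,
                        lr_variational = config$fit$lr_variational,
                        seed = config$seed + 3))
    d <- file.path(config$out_dir, "deconvolve")
    dir.create(d, showWarnings = FALSE)
    utils::write.csv(abundance_table(res$deconv),
                     file.path(d, "abundance.csv"), row.names = FALSE)
    utils::write.csv(res$deconv$presence_logLR,
                     file.path(d, "presence_logLR.csv"))
    logline("deconvolve: mean foreground ",
            round(mean(res$deconv$foreground), 3))
  }

  if ("zonate" %in% config$stages) {
    need("zonate", "spots")
    res$zonation <- fit_zonation(
      res$spots$dataset,
      spline_basis(config$zonation$n_knots, config$zonation$sigma),
      fit_config(n_steps = config$fit$n_steps_zonation,
                 lr_variational = config$fit$lr_variational,
                 lr_amortized = config$fit$lr_amortized,
                 seed = config$seed + 4))
    d <- file.path(config$out_dir, "zonate")
    dir.create(d, showWarnings = FALSE)
    utils::write.csv(data.frame(barcode = names(res$zonation$z_mu),
                                z_mu = res$zonation$z_mu,
                                z_sigma = res$zonation$z_sigma),
                     file.path(d, "zonation.csv"), row.names = FALSE)
    utils::write.csv(res$zonation$coefficients,
                     file.path(d, "spline_coefficients.csv"))
    logline("zonate: |Spearman vs truth| ",
            round(abs(stats::cor(res$zonation$z_mu, res$spots$truth$z,
                                 method = "spearman")), 3))
  }

  if ("diffabund" %in% config$stages) {
    need("diffabund", "deconv"); need("diffabund", "zonation")
    res$diffabund <- zonation_abundance_report(res$deconv, res$zonation)
    d <- file.path(config$out_dir, "diffabund")
    dir.create(d, showWarnings = FALSE)
    utils::write.csv(res$diffabund, file.path(d, "abundance_curves.csv"),
                     row.names = FALSE)
    logline("diffabund: ", nrow(res$diffabund), " cell types")
  }

  if ("signature" %in% config$stages) {
    pair <- make_species_pair(seed = config$seed + 5)
    res$signature <- conserved_signature_pipeline(
      pair, min_score = config$signature$min_score,
      specificity_threshold = config$signature$specificity_threshold,
      seed_k = config$signature$seed_k)
    d <- file.path(config$out_dir, "signature")
    dir.create(d, showWarnings = FALSE)
    writeLines(res$signature$signature, file.path(d, "signature.txt"))
    jsonlite::write_json(
      lapply(res$signature$trace$stages, function(st)
        list(name = st$name, n = st$n, genes = st$genes)),
      file.path(d, "trace.json"), auto_unbox = TRUE)
    logline("signature: ", length(res$signature$signature), " genes")
  }

  logline("done")
  invisible(res)
}
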