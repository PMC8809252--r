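#' Spot dataset container
#'
#' Holds a spot x gene integer count matrix with per-spot metadata, the
#' package's working representation of a Visium-style capture array
#' (optionally with a spot x protein matrix from the same spots).
#'
#' @param counts Spot x gene non-negative integer matrix with dimnames.
#' @param coords Data frame with `barcode`, `array_row`, `array_col` (and
#'   optionally pixel columns), one row per spot.
#' @param protein_counts Optional spot x protein integer matrix.
#' @param sample_id,condition Per-dataset or per-spot labels (recycled).
#' @return A `spot_dataset` with `lib` set to the empirical library size
#'   (row sums of `counts`).
#' @export
spot_dataset <- function(counts, coords = NULL, protein_counts = NULL,
                         sample_id = "S1", condition = NA_character_) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("spot_dataset: counts must be non-negative integers")
  }
  n <- nrow(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("spot%04d", seq_len(n))
  if (!is.null(coords)) {
    stopifnot(is.data.frame(coords), nrow(coords) == n)
  }
  if (!is.null(protein_counts)) {
    stopifnot(nrow(protein_counts) == n)
  }
  structure(list(counts = counts, protein_counts = protein_counts,
                 lib = rowSums(counts), coords = coords,
                 sample_id = rep_len(sample_id, n),
                 condition = rep_len(condition, n),
                 genes = colnames(counts),
                 barcodes = rownames(counts)),
            class = "spot_dataset")
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat("<spot_dataset>", nrow(x$counts), "spots x", ncol(x$counts), "genes;",
      if (!is.null(x$protein_counts)) paste(ncol(x$protein_counts), "proteins;") else "",
      "median library", stats::median(x$lib), "\n")
  invisible(x)
}

#' @export
dim.spot_dataset <- function(x) dim(x$counts)

#' Reference expression profile
#'
#' Per-cell-type mean expression `rho` (per unit library) and dispersion
#' `theta`, with a per-gene nucleus correction factor kept separately —
#' deconvolution of whole-cell spatial data uses the uncorrected `rho`.
#'
#' @param rho,theta Cell-type x gene matrices (theta > 0).
#' @param nucleus_factor Per-gene positive correction factor.
#' @param posterior Optional fitted `variational_posterior` kept for
#'   diagnostics.
#' @return A `reference_profile`.
#' @export
reference_profile <- function(rho, theta, nucleus_factor = NULL,
                              posterior = NULL) {
  stopifnot(is.matrix(rho), is.matrix(theta), all(dim(rho) == dim(theta)),
            all(is.finite(rho)), all(rho >= 0), all(theta > 0))
  if (is.null(nucleus_factor)) nucleus_factor <- rep(1, ncol(rho))
  stopifnot(length(nucleus_factor) == ncol(rho), all(nucleus_factor > 0))
  if (is.null(names(nucleus_factor))) names(nucleus_factor) <- colnames(rho)
  structure(list(rho = rho, theta = theta, nucleus_factor = nucleus_factor,
                 celltypes = rownames(rho), genes = colnames(rho),
                 posterior = posterior),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat("<reference_profile>", nrow(x$rho), "cell types x", ncol(x$rho),
      "genes\n")
  invisible(x)
}

#' Subset a reference profile to a gene set
#'
#' @param profile A [reference_profile()].
#' @param genes Genes to keep (order preserved as given).
#' @return The column-subset profile.
#' @export
subset_reference <- function(profile, genes) {
  stopifnot(inherits(profile, "reference_profile"))
  missing <- setdiff(genes, profile$genes)
  if (length(missing)) {
    stop("subset_reference: genes absent from profile: ",
         paste(missing, collapse = ", "))
  }
  reference_profile(profile$rho[, genes, drop = FALSE],
                    profile$theta[, genes, drop = FALSE],
                    profile$nucleus_factor[genes])
}
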