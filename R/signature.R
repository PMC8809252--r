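#' Differential-expression scoring per cluster
#'
#' For every cluster and gene computes the in-cluster mean of normalized
#' expression (`raw_normalized_mean1`), the out-of-cluster mean
#' (`raw_normalized_mean2`), the mean per-cell log2 fold change versus the
#' out-of-cluster mean (`lfc_mean`), and the marker score
#' `raw_normalized_mean1 / raw_normalized_mean2 * lfc_mean` (the
#' out-of-cluster mean floored at 1e-9 in the ratio).
#'
#' @param norm_expr Cell x gene matrix of normalized expression values.
#' @param labels Cluster label per cell (>= 2 clusters, >= 2 cells each).
#' @param lfc_eps Pseudocount inside the per-cell log2 ratio (default 1e-4).
#' @return Data frame of `DERecord`s: gene, cluster, raw_normalized_mean1,
#'   raw_normalized_mean2, lfc_mean, score.
#' @export
de_score <- function(norm_expr, labels, lfc_eps = 1e-4) {
  norm_expr <- as.matrix(norm_expr)
  labels <- as.character(labels)
  stopifnot(nrow(norm_expr) == length(labels))
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("de_score: need >= 2 clusters")
  small <- names(which(table(labels) < 2))
  if (length(small)) stop("de_score: cluster(s) with < 2 cells: ",
                          paste(small, collapse = ", "))
  genes <- colnames(norm_expr)
  out <- vector("list", length(clusters))
  for (i in seq_along(clusters)) {
    cl <- clusters[i]
    inm <- labels == cl
    mean1 <- colMeans(norm_expr[inm, , drop = FALSE])
    mean2 <- colMeans(norm_expr[!inm, , drop = FALSE])
    lfc <- colMeans(log2(sweep(norm_expr[inm, , drop = FALSE], 2, mean2 + lfc_eps,
                               "/") + lfc_eps))
    score <- mean1 / pmax(mean2, 1e-9) * lfc
    out[[i]] <- data.frame(gene = genes, cluster = cl,
                           raw_normalized_mean1 = mean1,
                           raw_normalized_mean2 = mean2,
                           lfc_mean = lfc, score = score,
                           row.names = NULL)
  }
  do.call(rbind, out)
}

#' Keep each gene only for its highest-scoring cluster
#'
#' @param records DE records from [de_score()].
#' @return Subset with one row per gene (ties broken lexicographically by
#'   cluster name, with a warning).
#' @export
assign_unique <- function(records) {
  stopifnot(all(c("gene", "cluster", "score") %in% names(records)))
  # order: score descending, cluster ascending => first row per gene wins
  ord <- records[order(records$gene, -records$score, records$cluster), ]
  first <- !duplicated(ord$gene)
  keep <- ord[first, ]
  dup_top <- ord[!first, ]
  ties <- merge(keep[, c("gene", "score")], dup_top[, c("gene", "score")],
                by = c("gene", "score"))
  if (nrow(ties)) {
    warning("assign_unique: score ties for gene(s) ",
            paste(unique(ties$gene), collapse = ", "),
            "; kept the lexicographically first cluster")
  }
  rownames(keep) <- NULL
  keep
}

#' Remove candidates scoring below a floor
#'
#' Genes with `score < min_score` are dropped; the boundary value is kept.
#'
#' @param records Scored DE records.
#' @param min_score Score floor (default 10).
#' @return Surviving records (may be empty, with a warning).
#' @export
score_floor <- function(records, min_score = 10) {
  out <- records[records$score >= min_score, , drop = FALSE]
  if (!nrow(out)) warning("score_floor: no records survive the floor")
  rownames(out) <- NULL
  out
}

#' Quantile-scale expression to the unit interval
#'
#' Per gene, values are divided by the given upper quantile (values at or
#' above it map to 1), the scaling used for marker-specificity screening.
#'
#' @param norm_expr Cell x gene normalized matrix.
#' @param q Upper quantile (default 0.99).
#' @return Matrix with entries in `[0, 1]`.
#' @export
scale_quantile <- function(norm_expr, q = 0.99) {
  norm_expr <- as.matrix(norm_expr)
  hi <- apply(norm_expr, 2, stats::quantile, probs = q, names = FALSE)
  hi[hi <= 0] <- 1
  pmin(sweep(norm_expr, 2, hi, "/"), 1)
}

#' Marker-specificity filter
#'
#' Removes a candidate gene when its scaled expression exceeds
#' `value_threshold` in more than `frac_threshold` of the cells of any
#' cluster other than the target (strict inequalities on both counts).
#' Clusters in `exempt_clusters` (e.g. a broader lineage containing the
#' target) are allowed up to `exempt_frac` instead.
#'
#' @param candidates Character vector of candidate genes.
#' @param scaled_expr Cell x gene matrix in `[0, 1]` (see [scale_quantile()]).
#' @param labels Cluster label per cell.
#' @param target_cluster The cluster whose markers are being selected.
#' @param frac_threshold,value_threshold Defaults 0.30 / 0.50.
#' @param exempt_clusters,exempt_frac Defaults none / 0.70.
#' @return Surviving genes, order preserved.
#' @export
specificity_filter <- function(candidates, scaled_expr, labels, target_cluster,
                               frac_threshold = 0.30, value_threshold = 0.50,
                               exempt_clusters = character(),
                               exempt_frac = 0.70) {
  scaled_expr <- as.matrix(scaled_expr)
  labels <- as.character(labels)
  if (!target_cluster %in% labels) {
    stop("specificity_filter: target cluster '", target_cluster, "' absent")
  }
  candidates <- candidates[candidates %in% colnames(scaled_expr)]
  others <- setdiff(unique(labels), target_cluster)
  keep <- rep(TRUE, length(candidates))
  for (cl in others) {
    rows <- labels == cl
    frac_hi <- colMeans(scaled_expr[rows, candidates, drop = FALSE] >
                          value_threshold)
    lim <- if (cl %in% exempt_clusters) exempt_frac else frac_threshold
    keep <- keep & (frac_hi <= lim)
  }
  candidates[keep]
}

#' Map gene identifiers across species through an ortholog table
#'
#' @param genes Character vector of source-species symbols.
#' @param ortholog_table Two-column data frame; columns named for the two
#'   species (or generic source/target order).
#' @param from,to Column names to map from/to (defaults: first and second
#'   column).
#' @return List with `mapped` (deduplicated, order preserving) and
#'   `unmapped` (source symbols without a table entry).
#' @export
map_orthologs <- function(genes, ortholog_table, from = NULL, to = NULL) {
  if (!is.data.frame(ortholog_table) || ncol(ortholog_table) < 2) {
    stop("map_orthologs: ortholog_table must be a two-column data frame")
  }
  if (is.null(from)) from <- names(ortholog_table)[1]
  if (is.null(to)) to <- names(ortholog_table)[2]
  stopifnot(all(c(from, to) %in% names(ortholog_table)))
  idx <- match(genes, ortholog_table[[from]])
  mapped <- ortholog_table[[to]][idx]
  list(mapped = unique(mapped[!is.na(mapped)]),
       unmapped = genes[is.na(idx)])
}

#' Intersect candidates with a highly-variable-gene list
#'
#' @param genes Candidate genes (order preserved).
#' @param hvg_list Highly variable genes of the other species' dataset.
#' @return The intersection, in `genes` order.
#' @export
hvg_intersect <- function(genes, hvg_list) {
  genes[genes %in% hvg_list]
}

#' Per-cell signature enrichment score
#'
#' Fraction of each cell's counts falling in the signature genes.
#'
#' @param counts Cell x gene count matrix.
#' @param signature Signature gene set (missing genes tolerated with a
#'   warning).
#' @return Per-cell score in `[0, 1]` (cells with zero total get 0, with a
#'   warning).
#' @export
signature_score <- function(counts, signature) {
  counts <- as.matrix(counts)
  present <- intersect(signature, colnames(counts))
  if (length(present) < length(signature)) {
    warning("signature_score: ", length(signature) - length(present),
            " signature gene(s) absent from counts")
  }
  tot <- rowSums(counts)
  sig <- if (length(present)) rowSums(counts[, present, drop = FALSE]) else
    rep(0, nrow(counts))
  zero <- tot == 0
  if (any(zero)) {
    warning("signature_score: ", sum(zero), " cell(s) with zero total counts")
    tot[zero] <- 1
    sig[zero] <- 0
  }
  out <- sig / tot
  names(out) <- rownames(counts)
  out
}

# target-vs-best-other specificity of a signature score
.signature_specificity <- function(counts, signature, labels, target_cluster) {
  sc <- suppressWarnings(signature_score(counts, signature))
  m_t <- mean(sc[labels == target_cluster])
  others <- setdiff(unique(labels), target_cluster)
  m_o <- max(vapply(others, function(cl) mean(sc[labels == cl]), 0))
  if (m_o <= 0) Inf else m_t / m_o
}

#' Signature selection trace
#'
#' Records the gene list surviving each stage of the funnel, for audit and
#' the subset ("funnel monotonicity") invariant.
#'
#' @param name Stage name.
#' @param genes Surviving genes.
#' @param params Stage parameter list.
#' @return A `signature_trace` (start a trace with `signature_trace()`, add
#'   stages with [trace_stage()]).
#' @export
signature_trace <- function() {
  structure(list(stages = list()), class = "signature_trace")
}

#' @rdname signature_trace
#' @param trace A `signature_trace`.
#' @export
trace_stage <- function(trace, name, genes, params = list()) {
  trace$stages[[length(trace$stages) + 1]] <-
    list(name = name, genes = genes, n = length(genes), params = params)
  trace
}

#' @export
print.signature_trace <- function(x, ...) {
  for (st in x$stages) cat(sprintf("  %-28s %4d genes\n", st$name, st$n))
  invisible(x)
}

#' Greedy construction of a cross-species conserved signature
#'
#' Starting from the top-`seed_k` species-B markers (by score), species-A
#' candidates are added in rank order as long as the signature's enrichment
#' stays specific to the target cluster in BOTH species: the specificity
#' metric (mean per-cell signature score in the target cluster divided by
#' the highest mean in any other cluster) must stay above
#' `specificity_threshold`.
#'
#' All genes are expected in a shared namespace (species-B candidates
#' already ortholog-mapped to species-A symbols); `map_b` translates shared
#' symbols back to species-B gene names for scoring on the species-B matrix.
#'
#' @param cand_a,cand_b Ranked candidate data frames (columns `gene`,
#'   `score`; shared namespace; highest score first or will be re-ranked).
#' @param counts_a,counts_b Cell x gene count matrices per species.
#' @param labels_a,labels_b Cluster labels per cell.
#' @param target_cluster Target cluster name (same in both species).
#' @param map_b Named character vector: shared symbol -> species-B column
#'   name (identity when omitted).
#' @param specificity_threshold Minimum target-vs-best-other enrichment
#'   ratio (default 2).
#' @param seed_k Size of the species-B seed set (default 10).
#' @param force_include Genes appended to the seed set unconditionally.
#' @return List with `signature` (shared-namespace genes) and `trace`.
#' @export
greedy_conserved_signature <- function(cand_a, cand_b, counts_a, labels_a,
                                       counts_b, labels_b, target_cluster,
                                       map_b = NULL,
                                       specificity_threshold = 2,
                                       seed_k = 10, force_include = character()) {
  if (!nrow(cand_a) || !nrow(cand_b)) {
    stop("greedy_conserved_signature: empty candidate list")
  }
  cand_a <- cand_a[order(-cand_a$score), ]
  cand_b <- cand_b[order(-cand_b$score), ]
  to_b <- function(g) {
    if (is.null(map_b)) g else unname(map_b[g])
  }
  seed <- unique(c(utils::head(cand_b$gene, seed_k), force_include))
  trace <- signature_trace()
  trace <- trace_stage(trace, "seed (top species-B markers)", seed,
                       list(seed_k = seed_k))
  sig <- seed
  spec_ok <- function(sig) {
    sa <- .signature_specificity(counts_a, sig, labels_a, target_cluster)
    sb <- .signature_specificity(counts_b, to_b(sig), labels_b, target_cluster)
    sa > specificity_threshold && sb > specificity_threshold
  }
  for (g in cand_a$gene) {
    if (g %in% sig) next
    cand_sig <- c(sig, g)
    if (spec_ok(cand_sig)) sig <- cand_sig
  }
  trace <- trace_stage(trace, "greedy augmentation", sig,
                       list(specificity_threshold = specificity_threshold))
  list(signature = sig, trace = trace)
}

#' Full two-species conserved-marker funnel
#'
#' Runs the complete selection procedure on a species pair: per-species DE
#' scoring, unique cluster assignment, score floor, specificity filtering,
#' cross-species ortholog mapping, HVG intersection, and greedy signature
#' construction. Stage-by-stage gene lists are recorded in the returned
#' trace.
#'
#' @param pair A list shaped like the output of [make_species_pair()]:
#'   per-species `counts`/`norm`, `labels`, `hvg`; plus `orthologs`
#'   (data frame with columns `mouse`, `human`).
#' @param target_cluster Target cluster (default `"KC"`).
#' @param min_score Score floor applied to both species (default 10).
#' @param specificity_threshold Greedy enrichment threshold (default 2).
#' @param seed_k Seed set size (default 10).
#' @return List with `signature` (human-namespace symbols), `trace`
#'   (`signature_trace` covering every stage), and the per-species candidate
#'   tables.
#' @export
conserved_signature_pipeline <- function(pair, target_cluster = "KC",
                                         min_score = 10,
                                         specificity_threshold = 2,
                                         seed_k = 10) {
  trace <- signature_trace()
  species_candidates <- function(sp, label) {
    rec <- de_score(sp$norm, sp$labels)
    rec <- assign_unique(rec)
    rec <- rec[rec$cluster == target_cluster, , drop = FALSE]
    t1 <- trace_stage(signature_trace(), paste0(label, ": markers"), rec$gene)
    rec <- score_floor(rec, min_score)
    t1 <- trace_stage(t1, paste0(label, ": score >= ", min_score), rec$gene)
    sc <- scale_quantile(sp$norm)
    surv <- specificity_filter(rec$gene, sc, sp$labels, target_cluster)
    rec <- rec[rec$gene %in% surv, , drop = FALSE]
    t1 <- trace_stage(t1, paste0(label, ": specificity filter"), rec$gene)
    list(rec = rec, trace = t1)
  }
  hum <- species_candidates(pair$human, "human")
  mus <- species_candidates(pair$mouse, "mouse")
  trace$stages <- c(hum$trace$stages, mus$trace$stages)

  # human candidates -> mouse namespace: keep those that are mouse HVGs
  h2m <- map_orthologs(hum$rec$gene, pair$orthologs, from = "human", to = "mouse")
  trace <- trace_stage(trace, "human markers with mouse ortholog", h2m$mapped)
  h_in_m <- hvg_intersect(h2m$mapped, pair$mouse$hvg)
  trace <- trace_stage(trace, "human markers HVG in mouse", h_in_m)

  # mouse candidates -> human namespace: keep those that are human HVGs
  m2h <- map_orthologs(mus$rec$gene, pair$orthologs, from = "mouse", to = "human")
  trace <- trace_stage(trace, "mouse markers with human ortholog", m2h$mapped)
  m_in_h <- hvg_intersect(m2h$mapped, pair$human$hvg)
  trace <- trace_stage(trace, "mouse markers HVG in human", m_in_h)

  # shared namespace: human symbols; map back to mouse for scoring
  m2h_map <- stats::setNames(pair$orthologs$human, pair$orthologs$mouse)
  h2m_map <- stats::setNames(pair$orthologs$mouse, pair$orthologs$human)

  cand_a <- hum$rec[!is.na(h2m_map[hum$rec$gene]) &
                      h2m_map[hum$rec$gene] %in% h_in_m, , drop = FALSE]
  cand_b <- mus$rec[!is.na(m2h_map[mus$rec$gene]) &
                      m2h_map[mus$rec$gene] %in% m_in_h, , drop = FALSE]
  cand_b$gene <- unname(m2h_map[cand_b$gene]) # to shared (human) namespace

  gr <- greedy_conserved_signature(cand_a, cand_b,
                                   pair$human$counts, pair$human$labels,
                                   pair$mouse$counts, pair$mouse$labels,
                                   target_cluster, map_b = h2m_map,
                                   specificity_threshold = specificity_threshold,
                                   seed_k = seed_k)
  trace$stages <- c(trace$stages, gr$trace$stages)
  list(signature = sort(gr$signature), trace = trace,
       candidates_human = cand_a, candidates_mouse = cand_b)
}
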