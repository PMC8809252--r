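test_that("de_score matches a hand-computed spreadsheet oracle", {
  ne <- matrix(c(10, 0,
                 8, 1,
                 0, 5,
                 1, 6), 4, 2, byrow = TRUE,
               dimnames = list(paste0("c", 1:4), c("g1", "g2")))
  labels <- c("A", "A", "B", "B")
  rec <- de_score(ne, labels, lfc_eps = 1e-4)
  # independent computation, cluster A / gene g1:
  # mean1 = (10+8)/2 = 9; mean2 = (0+1)/2 = 0.5
  # lfc = mean(log2(10/(0.5+1e-4) + 1e-4), log2(8/(0.5+1e-4) + 1e-4))
  lfc_a_g1 <- mean(log2(c(10, 8) / 0.5001 + 1e-4))
  a_g1 <- rec[rec$cluster == "A" & rec$gene == "g1", ]
  expect_equal(a_g1$raw_normalized_mean1, 9)
  expect_equal(a_g1$raw_normalized_mean2, 0.5)
  expect_equal(a_g1$lfc_mean, lfc_a_g1, tolerance = 1e-12)
  expect_equal(a_g1$score, 9 / 0.5 * lfc_a_g1, tolerance = 1e-12)
  # gene exclusive to B scores top for B; scores are symmetric in structure
  b_g2 <- rec[rec$cluster == "B" & rec$gene == "g2", ]
  expect_gt(b_g2$score, 0)
  expect_gt(a_g1$score, rec[rec$cluster == "B" & rec$gene == "g1", "score"])
})

test_that("uniform genes score near zero and exclusive genes at the top", {
  set.seed(1)
  ne <- cbind(uniform = rep(5, 40),
              excl = c(rep(20, 10), rep(0.01, 30)))
  labels <- rep(c("KC", "B", "C", "D"), each = 10)
  rec <- de_score(ne, labels)
  expect_lt(abs(rec[rec$gene == "uniform" & rec$cluster == "KC", "score"]),
            0.01)
  kc_excl <- rec[rec$gene == "excl" & rec$cluster == "KC", "score"]
  expect_gt(kc_excl, 10)
  expect_error(de_score(ne, rep("onlyone", 40)), ">= 2 clusters")
})

test_that("assign_unique keeps the top-scoring cluster with documented ties", {
  rec <- data.frame(gene = c("g1", "g1", "g2", "g3", "g3"),
                    cluster = c("A", "B", "A", "B", "A"),
                    score = c(5, 9, 4, 7, 7))
  expect_warning(u <- assign_unique(rec), "g3")
  expect_identical(u$cluster[u$gene == "g1"], "B")
  expect_identical(u$cluster[u$gene == "g2"], "A")
  expect_identical(u$cluster[u$gene == "g3"], "A") # lexicographic winner
  expect_equal(nrow(u), 3)
})

test_that("score_floor applies the boundary exactly", {
  rec <- data.frame(gene = c("a", "b", "c"), cluster = "KC",
                    score = c(9.99, 10, 10.01))
  out <- score_floor(rec, 10)
  expect_identical(out$gene, c("b", "c"))
  expect_warning(score_floor(rec[1, , drop = FALSE], 10), "no records")
})

test_that("specificity filter enforces strict boundary semantics", {
  # 10 cells per cluster; scaled expression crafted per case
  labels <- rep(c("KC", "B", "mac"), each = 10)
  mk <- function(frac_b, frac_mac) {
    cbind(g = c(rep(1, 10),
                rep(c(0.9, 0.1), times = c(round(10 * frac_b),
                                           10 - round(10 * frac_b))),
                rep(c(0.9, 0.1), times = c(round(10 * frac_mac),
                                           10 - round(10 * frac_mac)))))
  }
  # 40% of B above 0.5: removed
  expect_identical(specificity_filter("g", mk(0.4, 0), labels, "KC"),
                   character(0))
  # exactly 30%: kept (strict inequality)
  expect_identical(specificity_filter("g", mk(0.3, 0), labels, "KC"), "g")
  # exempt cluster at 60%: kept; at 80%: removed
  expect_identical(specificity_filter("g", mk(0, 0.6), labels, "KC",
                                      exempt_clusters = "mac"), "g")
  expect_identical(specificity_filter("g", mk(0, 0.8), labels, "KC",
                                      exempt_clusters = "mac"),
                   character(0))
  expect_error(specificity_filter("g", mk(0, 0), labels, "LAM"), "absent")
})

test_that("quantile scaling maps expression into the unit interval", {
  set.seed(2)
  m <- matrix(rexp(200, 0.1), 20, 10)
  s <- scale_quantile(m, 0.99)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(max(s), 1)
})

test_that("ortholog mapping handles empty tables, funnels and round trips", {
  tab <- data.frame(mouse = paste0("Gene", 1:36),
                    human = paste0("GENE", 1:36))
  empty <- map_orthologs(paste0("Gene", 1:5), tab[0, ], from = "mouse",
                         to = "human")
  expect_length(empty$mapped, 0)
  expect_length(empty$unmapped, 5)
  # 30 of 36 mappable
  part <- tab[1:30, ]
  res <- map_orthologs(paste0("Gene", 1:36), part, from = "mouse", to = "human")
  expect_length(res$mapped, 30)
  expect_length(res$unmapped, 6)
  # one-to-one round trip
  back <- map_orthologs(res$mapped, part, from = "human", to = "mouse")
  expect_identical(back$mapped, paste0("Gene", 1:30))
  expect_error(map_orthologs("x", list(a = 1)), "two-column")
})

test_that("hvg_intersect is an order-preserving idempotent intersection", {
  g <- c("c", "a", "b")
  expect_identical(hvg_intersect(g, c("a", "b", "c")), g)
  expect_identical(hvg_intersect(g, "zz"), character(0))
  expect_identical(hvg_intersect(hvg_intersect(g, c("a", "c")), c("a", "c")),
                   hvg_intersect(g, c("a", "c")))
})

test_that("signature_score matches hand-computed fractions", {
  cts <- matrix(c(5, 5, 10, 0, 0, 10), 3, 2, byrow = TRUE,
                dimnames = list(paste0("c", 1:3), c("gene1", "gene2")))
  expect_equal(unname(signature_score(cts, "gene1")), c(0.5, 1, 0))
  expect_equal(unname(signature_score(cts, c("gene1", "gene2"))), rep(1, 3))
  expect_warning(s0 <- signature_score(cts, character(0)), NA) # empty: no warn
  expect_equal(unname(s0), rep(0, 3))
  expect_warning(signature_score(cts, c("gene1", "ghost")), "absent")
  cts0 <- rbind(cts, c0 = c(0, 0))
  expect_warning(sz <- signature_score(cts0, "gene1"), "zero total")
  expect_equal(unname(sz[4]), 0)
})

test_that("greedy augmentation respects the threshold and is deterministic", {
  pair <- make_species_pair(seed = 9)
  m2h <- setNames(pair$orthologs$human, pair$orthologs$mouse)
  h2m <- setNames(pair$orthologs$mouse, pair$orthologs$human)
  rec <- de_score(pair$mouse$norm, pair$mouse$labels)
  rec <- assign_unique(rec)
  kc <- rec[rec$cluster == "KC" & rec$score >= 10, ]
  kc$gene <- unname(m2h[kc$gene]); kc <- kc[!is.na(kc$gene), ]
  seed_only <- greedy_conserved_signature(
    kc, kc, pair$human$counts, pair$human$labels,
    pair$mouse$counts, pair$mouse$labels, "KC", map_b = h2m,
    specificity_threshold = Inf, seed_k = 3)
  expect_length(seed_only$signature, 3)
  g1 <- greedy_conserved_signature(kc, kc, pair$human$counts,
                                   pair$human$labels, pair$mouse$counts,
                                   pair$mouse$labels, "KC", map_b = h2m,
                                   seed_k = 5)
  g2 <- greedy_conserved_signature(kc, kc, pair$human$counts,
                                   pair$human$labels, pair$mouse$counts,
                                   pair$mouse$labels, "KC", map_b = h2m,
                                   seed_k = 5)
  expect_identical(g1$signature, g2$signature)
  expect_error(greedy_conserved_signature(kc[0, ], kc, pair$human$counts,
                                          pair$human$labels,
                                          pair$mouse$counts,
                                          pair$mouse$labels, "KC"),
               "empty candidate")
})

test_that("the full funnel recovers the planted conserved set with a
           monotone trace", {
  pair <- make_species_pair(seed = 5)
  res <- conserved_signature_pipeline(pair)
  expect_identical(sort(res$signature), sort(pair$truth$conserved))
  # funnel monotonicity within each species' staged lists
  stages <- res$trace$stages
  nm <- vapply(stages, `[[`, "", "name")
  hum <- stages[grep("^human: ", nm)]
  for (i in seq_len(length(hum) - 1)) {
    expect_true(all(hum[[i + 1]]$genes %in% hum[[i]]$genes))
  }
  mus <- stages[grep("^mouse: ", nm)]
  for (i in seq_len(length(mus) - 1)) {
    expect_true(all(mus[[i + 1]]$genes %in% mus[[i]]$genes))
  }
})
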