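test_that("generators are bit-exact reproducible", {
  r1 <- make_reference(3, 60, 150, 0.3, seed = 4)
  r2 <- make_reference(3, 60, 150, 0.3, seed = 4)
  expect_identical(r1, r2)
  s1 <- make_spots(r1$truth, n_spots = 40, seed = 9)
  s2 <- make_spots(r1$truth, n_spots = 40, seed = 9)
  expect_identical(s1, s2)
  p1 <- make_protein_panel(s1, n_proteins = 6, seed = 2)
  p2 <- make_protein_panel(s2, n_proteins = 6, seed = 2)
  expect_identical(p1, p2)
  sp1 <- make_species_pair(seed = 3)
  sp2 <- make_species_pair(seed = 3)
  expect_identical(sp1, sp2)
})

test_that("reference generator matches its own stored truth", {
  ref <- make_reference(5, 200, 2000, frac_nuclei = 0, seed = 1)
  # empirical per-type mean expression correlates with the planted profiles
  for (t in ref$celltypes) {
    sel <- ref$celltype == t
    emp <- colSums(ref$counts[sel, ]) / sum(rowSums(ref$counts[sel, ]))
    expect_gt(cor(emp, ref$truth$rho[t, ]), 0.9)
  }
})

test_that("frac_nuclei = 0 yields a cell-only assay", {
  ref <- make_reference(3, 60, 100, frac_nuclei = 0, seed = 2)
  expect_true(all(ref$assay == "cell"))
  ref2 <- make_reference(3, 60, 400, frac_nuclei = 1, seed = 2)
  expect_true(all(ref2$assay == "nucleus"))
})

test_that("spot dataset invariants hold", {
  ref <- make_reference(4, 80, 200, 0, seed = 5)
  sp <- make_spots(ref$truth, n_spots = 60, zonated_celltypes = "KC",
                   zonated_genes = 10, rbc_rate = 0.05, seed = 6)
  d <- sp$dataset
  expect_identical(d$lib, rowSums(d$counts))
  expect_true(all(d$counts == floor(d$counts)))
  expect_equal(rowSums(sp$truth$nu), rep(1, 60), tolerance = 1e-12)
  expect_true(all(sp$truth$z >= 0 & sp$truth$z <= 1))
})

test_that("rbc_rate = 0 leaves hemoglobin to the reference profiles", {
  ref <- make_reference(4, 80, 200, 0, seed = 5)
  sp0 <- make_spots(ref$truth, n_spots = 2000, rbc_rate = 0, seed = 6,
                    ambient_scale = 0, bias_sd = 0,
                    fg_shape1 = 1e6, fg_shape2 = 1e-6)
  hb <- intersect(hemoglobin_genes("mouse"), colnames(sp0$dataset$counts))
  emp <- colMeans(sp0$dataset$counts[, hb] / sp0$truth$lib)
  expect_equal(sum(sp0$truth$rbc_frac), 0)
  want <- colMeans(sp0$truth$nu %*% ref$truth$rho[, hb, drop = FALSE])
  expect_equal(unname(emp), unname(want), tolerance = 0.1)
})

test_that("a single cell type gives unit proportions", {
  ref <- make_reference(1, 60, 60, 0, seed = 7)
  sp <- make_spots(ref$truth, n_spots = 20, seed = 8)
  expect_equal(unname(sp$truth$nu[, 1]), rep(1, 20))
})

test_that("absent cell types get exactly zero abundance", {
  ref <- make_reference(4, 80, 200, 0, seed = 5)
  sp <- make_spots(ref$truth, n_spots = 30, absent_celltypes = "Stellate",
                   seed = 9)
  expect_true(all(sp$truth$nu[, "Stellate"] == 0))
})

test_that("law of large numbers: clean spots reproduce the mixed profiles", {
  ref <- make_reference(4, 100, 300, 0, seed = 10)
  sp <- make_spots(ref$truth, n_spots = 2000, seed = 11, ambient_scale = 0,
                   bias_sd = 0, fg_shape1 = 1e6, fg_shape2 = 1e-6)
  emp <- colMeans(sp$dataset$counts / sp$truth$lib)
  want <- colMeans(sp$truth$nu %*% ref$truth$rho)
  expect_gt(cor(emp, want), 0.999)
  expect_equal(unname(emp), unname(want), tolerance = 0.05)
})

test_that("protein panel contracts hold", {
  ref <- make_reference(4, 80, 200, 0, seed = 5)
  sp <- make_spots(ref$truth, n_spots = 1500, seed = 6)
  none <- make_protein_panel(sp, n_proteins = 0, seed = 1)
  expect_null(none$dataset$protein_counts)
  pp <- make_protein_panel(sp, n_proteins = 8, seed = 1, w_fg = 0)
  # w_fg = 0: counts are pure background NB with the stored parameters
  p1 <- pp$dataset$protein_counts[, 1]
  mu_bg <- pp$truth$protein$rho_bg[1] * pp$truth$protein$plib
  expect_lt(abs(mean(p1) - mean(mu_bg)) / max(mean(mu_bg), 1), 0.2)
  # and variance consistent with NB at the stored dispersion (not foreground)
  vr <- var(p1)
  want_var <- mean(mu_bg + mu_bg^2 / pp$truth$protein$theta) + var(mu_bg)
  expect_lt(abs(vr - want_var) / want_var, 0.35)
})

test_that("two-condition generator plants (only) the requested interaction", {
  ref <- make_reference(4, 80, 200, 0, seed = 5)
  null_pair <- make_two_condition(ref$truth, n_spots_per_condition = 50,
                                  interaction_celltypes = character(),
                                  seed = 12)
  expect_identical(null_pair$A$truth$zonation_curves,
                   null_pair$B$truth$zonation_curves)
  alt <- make_two_condition(ref$truth, n_spots_per_condition = 200,
                            interaction_celltypes = "KC", effect = 2,
                            seed = 12, zonated_celltypes = "KC")
  # pericentral KC abundance is boosted in condition B relative to A
  zB <- alt$B$truth$z
  peri <- zB > 0.8
  expect_gt(mean(alt$B$truth$nu[peri, "KC"]),
            mean(alt$A$truth$nu[alt$A$truth$z > 0.8, "KC"]))
  expect_equal(alt$interaction$effect, 2)
})

test_that("species pair plants recoverable conserved markers", {
  pair <- make_species_pair(seed = 2)
  # planted conserved markers score at the top of the KC cluster in both
  for (sp in c("human", "mouse")) {
    d <- pair[[sp]]
    rec <- de_score(d$norm, d$labels)
    kc <- rec[rec$cluster == "KC", ]
    kc <- kc[order(-kc$score), ]
    planted <- if (sp == "human") {
      c(pair$truth$conserved, pair$truth$private_human)
    } else {
      c(pair$truth$conserved_mouse, pair$truth$private_mouse)
    }
    expect_true(all(planted %in% head(kc$gene, length(planted) + 3)))
  }
  # private markers have no ortholog row
  expect_false(any(pair$truth$private_mouse %in% pair$orthologs$mouse))
  expect_false(any(pair$truth$private_human %in% pair$orthologs$human))
})

test_that("ortholog noise drops only non-marker rows", {
  pair <- make_species_pair(ortholog_noise = 0.3, seed = 4)
  expect_true(all(pair$truth$conserved_mouse %in% pair$orthologs$mouse))
  full <- make_species_pair(ortholog_noise = 0, seed = 4)
  expect_lt(nrow(pair$orthologs), nrow(full$orthologs))
})
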