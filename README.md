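# spotzone

Probabilistic models for spatial transcriptomics of zonated tissues.

Spatial capture arrays such as 10x Visium measure mixed transcriptomes: every
55-µm spot covers tens of cells, and in organs like the liver both cell-type
composition and per-cell expression vary continuously along an anatomical
axis (portal-vein → central-vein "zonation"). `spotzone` implements a family
of negative-binomial latent-variable models for this setting, fitted by
black-box variational inference, together with seeded synthetic-data
generators that carry complete ground truth, so every stage of the pipeline
can be validated end to end. It is aimed at computational biologists who
want a self-contained, dependency-light R implementation of:

- **Reference estimation** — per-cell-type mean expression ρ and dispersion
  θ from annotated scRNA-seq/snRNA-seq counts,
  `counts[c,g] ~ NB(lib_c · ρ_{t(c),g} · f_g^[nucleus], θ_{t(c),g})`,
  with a gene-specific nucleus correction factor `f_g` for single-nucleus
  material. Deconvolution uses the uncorrected (whole-cell) ρ.
- **Spot deconvolution** — per-spot cell-type proportions ν on the simplex
  under `μ_{s,g} = (Σ_t ν_{s,t} ρ_{t,g} e^{b_g}) · lib_s · fg_s + bg_g`,
  with per-gene capture bias `b_g ~ N(0,1)`, per-spot foreground
  `fg ∈ [0,1]`, additive ambient background, a red-blood-cell pseudo-type
  carried only by hemoglobin genes, and hepatocyte complement factors as
  free parameters. Cell-type presence per spot is called by a Monte-Carlo
  likelihood-ratio test at log-LR > 10.
- **Zonation** — a per-spot latent coordinate `z ~ Uniform(0,1)` driving
  per-gene log-expression through a Gaussian-basis spline (10 knots,
  σ = 0.05) with Gaussian-random-walk coefficient priors (per-gene step
  scale = 2 × sd of log1p expression). The variational parameters of `z`
  are amortized by an encoder (Linear(100)–BatchNorm–ReLU–Linear(100)–ReLU–
  Linear), so a trained model transfers zonation to new datasets.
- **Differential abundance along zonation** — binary presence as a
  Bernoulli-logit spline of `z` (unit random-walk steps), with a penalized
  likelihood-ratio test for zonation-by-condition interactions.
- **Cross-species conserved signatures** — the stepwise marker funnel:
  per-cluster DE score `mean1/mean2 × lfc`, unique cluster assignment,
  score ≥ 10 floor, 0.50/30% specificity screening (70% exemption),
  ortholog mapping, HVG intersection, and greedy signature augmentation
  constrained to stay enriched in the target population in both species.

Everything runs on plain R with `Matrix`, `yaml` and `jsonlite`; the
inference engine (Adam, diagonal-Normal guides, domain transforms,
reparameterized "sticking-the-landing" gradients, amortizer with manual
backpropagation) is part of the package.

## Worked example

Simulate a liver-like dataset with known ground truth, estimate a reference,
deconvolve, and infer zonation:

```r
library(spotzone)

ref  <- make_reference(n_celltypes = 5, n_genes = 150, n_cells = 1500,
                       frac_nuclei = 0.3, seed = 11)
prof <- estimate_reference(ref$counts, ref$celltype, ref$assay,
                           fit_config(n_steps = 400, seed = 3))
sp   <- make_spots(ref$truth, n_spots = 500, zonated_celltypes = "KC",
                   rbc_rate = 0.03, seed = 2)

model <- build_deconv_model(prof, sp$dataset, deconv_model_spec("mouse"))
fit   <- fit_deconvolution(model, fit_config(n_steps = 1500, seed = 1))

head(abundance_table(fit)[, 1:6], 3)
#>    barcode array_row array_col nu_Cholangiocyte nu_Hepatocyte  nu_KC
#> 1 spot0001         0         0           0.0388         0.313 0.0328
#> 2 spot0002         0         1           0.1488         0.167 0.1710
#> 3 spot0003         0         2           0.1521         0.174 0.2697

ct <- colnames(sp$truth$nu)
nu <- fit$nu[, ct] / rowSums(fit$nu[, ct])
mean(rowSums(abs(nu - sp$truth$nu)))   # mean per-spot L1 error vs truth
#> [1] 0.097
```

The proportions table carries one row per spot with expected proportions
(`nu_*`, summing to 1 including the RBC pseudo-type) and presence calls at
the log-LR > 10 rule. A mean L1 error of ~0.1 over five cell types means
each spot's composition is recovered to a few percent per type.

Zonation and transfer (on a dataset with zonated gene programs):

```r
spz <- make_spots(ref$truth, n_spots = 500, zonated_celltypes = c("KC", "LSEC"),
                  zonated_genes = 100, seed = 5)
zr  <- fit_zonation(spz$dataset, config = fit_config(n_steps = 2000, seed = 1))
abs(cor(zr$z_mu, spz$truth$z, method = "spearman"))
#> [1] 0.92   (orientation-free: the axis is identifiable up to reflection)

# a replicate of the same tissue shares the gene programs; transfer is a
# pure encoder evaluation, no refitting
sp2 <- make_spots(ref$truth, n_spots = 400, zonated_celltypes = c("KC", "LSEC"),
                  gene_modulation = spz$truth$gene_modulation, seed = 6)
tr  <- transfer_zonation(zr, sp2$dataset)
abs(cor(tr$z_mu, sp2$truth$z, method = "spearman"))
#> [1] 0.918
```

`orient_zonation()` fixes the reflection with portal/central anchor genes,
and `zonation_abundance_report()` joins presence calls with the zonation
axis per cell type (adding the interaction LRT when two conditions are
given). `run_pipeline(run_config(...))` chains all stages and writes
CSV/JSON artifacts plus the resolved configuration;
`inst/cli/spotzone.R` is a thin command-line wrapper around it.

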