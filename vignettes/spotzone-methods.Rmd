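---
title: "Models and methods in spotzone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in spotzone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models: the observation
model and its latent structure, the inference engine, the synthetic-data
generators and what they do and do not emulate, the numerical choices, and
the known limitations. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## Observation model

All count modalities are negative binomial with mean μ and dispersion θ,
variance `μ + μ²/θ`, so θ → ∞ recovers the Poisson and smaller θ means more
overdispersion. The mean is always a rate ρ times the spot's or cell's
empirical library size (row sum of counts), which is treated as a fixed
constant. Multiplexed antibody counts use a two-component NB mixture with a
shared dispersion: a foreground component tied to the signal of interest
and a background component for ambient capture; the mixing weight is a
learnable per-protein latent on [0, 1] with a uniform prior, since nothing
in the model family pins it a priori.

Inside the log-pmf the mean is floored at 1e-8: the degenerate μ = 0 case
then yields probability ~1 at k = 0 and a very large negative but finite
log-probability for k > 0, which keeps gradients defined when a mixture
component collapses.

## Inference engine

Posteriors are approximated by diagonal Normal distributions in
unconstrained space, pushed through fixed transforms: exp for positive
latents, row-wise softmax for simplex latents, the logistic for [0, 1]
latents. The softmax is an overparameterized map (K coordinates per
K-simplex row), so no Jacobian correction applies; with the flat Dirichlet
prior used everywhere, the practical effect is a mild implicit prior on the
unconstrained coordinates, which recovery tests show is negligible at the
data sizes involved.

The ELBO is maximized with Adam under split learning rates — 0.01 for
directly parameterized variational parameters, 0.001 for amortization
networks — using single-sample reparameterized gradients by default
(`n_mc_samples_elbo` is configurable). Gradients of the entropy term are
taken through the sample path with the score term dropped
("sticking the landing"), which is unbiased and has zero variance at a
Gaussian optimum; on the conjugate-Normal check this reproduces the
closed-form posterior mean and standard deviation to within fractions of a
percent. Adam uses β₂ = 0.99: the gradient scale drops by orders of
magnitude between early and late optimization, and a shorter second-moment
memory prevents the early large gradients from throttling late progress.
Fixed step budgets with an early stop on the relative change of the
windowed mean ELBO (1e-5 over 100 steps) bound the run time; there is no
stopping rule inherent to the model family, so this is a numerical choice.
Direct (non-amortized) parameters are averaged over the final 20% of steps
to damp stochastic-gradient jitter. A deterministic MAP mode (scales fixed,
no entropy) supports the penalized likelihood-ratio machinery below.

Models supply analytic gradients of their log-joint with respect to the
constrained latents; the engine backpropagates through the transforms. All
gradients are verified against central finite differences in the test
suite. Latents can be declared with `freeze_steps`: the deconvolution model
holds its per-gene/per-spot nuisance latents at their initialization for
the first 200 steps so that they do not absorb the early misfit of the
composition estimates — without this warm-up the additive background can
capture a large share of the mean counts and drag the foreground scale down
a weakly-curved ridge it then cannot leave.

## Reference estimation

`estimate_reference()` fits `counts[c,g] ~ NB(lib_c · ρ_{t(c),g} ·
f_g^[nucleus], θ_{t(c),g})`. Priors are broad Normal(0, 5²) on log-ρ and
log-θ in unconstrained space and log-Normal(0, 1) on the nucleus factor;
with these widths the posterior mode essentially tracks the MLE, which is
the intent — the prior exists for numerical regularization of empty cells
of the (type, gene) table. Locations are initialized at pooled
method-of-moments estimates (per-type summed counts over summed library),
so optimization starts near the answer and 400–500 steps suffice. With no
nucleus cells the factor latent is dropped entirely and reported as 1; with
very few nucleus cells its posterior retains most of its prior width, which
the tests assert rather than a point value. One θ per (type, gene) is
estimated, pooled across assays, since nothing distinguishes the assays'
dispersion a priori.

## Spot deconvolution

The mean model is
`μ_{s,g} = (Σ_t ν_{s,t} ρ_{t,g} e^{b_g}) · lib_s · fg_s + bg_g` with:

- ν on the simplex over the reference types plus a red-blood-cell
  pseudo-type whose ρ row is zero except for free parameters at the
  hemoglobin genes (`Hbb-bt`, `Hbb-bs`, `Hba-a1`, `Hba-a2` for mouse;
  `HBB`, `HBA1`, `HBA2` for human). If none of these genes are present the
  pseudo-type is disabled with a warning.
- hepatocyte complement factors (`C3`, `C2`, `C4b`/`C4B`) as free
  parameters, since their spatial expression deviates systematically from
  dissociation-based references.
- a per-gene capture bias with prior N(0, 1), applied multiplicatively as
  `e^{b_g}` shared across cell types — the standard reading of a per-gene
  scale correction between platforms.
- a per-spot foreground on [0, 1] (uniform prior through the logistic
  transform's Jacobian) and a per-gene additive background. The background
  must be a valid NB mean, hence it is constrained positive through the
  exponential transform even though unconstrained reals would be the naive
  parameterization.
- one free dispersion per gene, re-estimated at the spot level (the
  reference θ is per type and gene; a spot mixes types, so a per-gene θ is
  the coherent granularity here).

Two numerical devices matter. First, ν is initialized by 40 multiplicative
Kullback-Leibler updates of the library-normalized counts against the
reference (a tiny fixed-dictionary NMF), which places optimization in the
right basin. Second, the background carries an empirical prior
`log bg_g ~ N(log(f · mean_g), sd)` with `f = 0.02`, `sd = 0.5` by default,
where `mean_g` is the gene's mean observed count: the additive background
direction is weakly identified against a global scale shift of the
signal, and without an informative prior it absorbs expression that belongs
to the mixture. Ambient contamination in Visium libraries is a few percent,
which the default encodes; both constants are exposed in
`deconv_model_spec()` and should be raised for ambient-heavy preparations.
For analyses that focus on the background itself, the MAP point estimate is
the recommended readout — the variational point estimate of this
weakly-identified direction inflates under the entropy term.

`build_deconv_model(..., estimate_nuisances = FALSE)` fixes bias,
background, foreground and dispersion at neutral values, leaving the plain
linear-mixture model. This mode exists because per-gene nuisances are only
partially identifiable from few spots (a rank-3 composition spans only
three directions of the per-gene bias space), and it is the configuration
under which the proportion estimator is validated against a brute-force
grid-search ML oracle.

The presence test draws joint Monte-Carlo samples of all latents from the
fitted posterior and compares, per spot, the average likelihood of the
observed counts with and without the target cell type, renormalizing the
remaining proportions onto the simplex in the counterfactual (the
alternative — leaving the gap unnormalized — would conflate presence with
total signal loss). A cell type is called present at log-LR > 10. Drawing
all latents jointly, rather than holding nuisances at posterior means, was
chosen so that the test accounts for their uncertainty.

## Zonation

Each spot has `z ~ Uniform(0, 1)`. Per-gene log-expression rate is a
Gaussian-basis spline of z: 10 knots at (k − 0.5)/10 — the half-offset
avoids piling basis mass at the boundaries, where no convention is
canonical — with width σ = 0.05, and the spline acts on log-ρ (exponentiated
into the NB mean) so positivity is automatic; a spline on ρ directly would
need ad-hoc clipping. Coefficients carry a Gaussian random-walk prior with
per-gene step scale 2 × sd(log1p counts) over the whole dataset, floored at
1e-4 (a zero scale would be a degenerate prior; the floor collapses the
spline to a constant within the optimization's resolution). The first knot
gets a broad N(0, 10²) level prior.

The variational parameters of z are not free per spot but produced by an
amortization network over library-normalized log1p counts
(Linear(100)–BatchNorm–ReLU–Linear(100)–ReLU–Linear(2)), trained jointly at
the amortized learning rate. Raw counts are scale-sensitive, hence the
normalization — this is configurable in the features helper but the default
is deliberate. BatchNorm uses batch statistics during training and stored
running statistics at evaluation, so `transfer_zonation()` is a
deterministic function of the new counts: features are aligned by name,
missing features are zero-filled with a warning, and an overlap below 50%
is an error. Two regularizers make the encoder a transferable function
rather than a per-spot lookup table: 20% input-feature dropout during
training and an L2 weight decay of 1e-3 on the linear layers. Both were
chosen as standard values; without them the encoder memorizes training
spots (near-perfect training recovery, clearly degraded transfer).

The axis is identifiable only up to reflection — the likelihood is
invariant under z → 1 − z with mirrored coefficients — so recovery is
measured by absolute Spearman correlation and `orient_zonation()` fixes the
direction post hoc with portal/central anchor genes (reflecting iff the
portal anchors correlate positively with z; a flat anchor profile keeps the
orientation and warns).

Cross-modality transfer follows the design of the multiplexed-protein
Visium assay, which carries RNA alongside the antibody panel: the encoder
trained on RNA is applied to the protein-carrying replicate's RNA, and the
antibody counts are then read out along the transferred trajectory. Fitting
the zonation model de novo on a ~24-plex antibody panel alone was evaluated
and is unstable at realistic mixture-noise levels; this is documented as a
limitation rather than supported usage, although `fit_zonation()` accepts
any named count matrix.

## Differential abundance along zonation

Binary presence (from the deconvolution presence test) is modelled as
Bernoulli with `logit p = basis(z) · coefficients` under a random-walk
prior with unit steps. The model family nowhere names a link; the logit is
the canonical GLM choice. Fits are deterministic MAP runs through the same
engine. The interaction test fits shared versus condition-specific
coefficients on identical data and reports `log-LR = LL_sep − LL_shared`
(Bernoulli data log-likelihoods at the respective MAP estimates). Because
both fits are prior-penalized, this is a penalized LRT and a χ² reference
would be miscalibrated; instead the decision uses a fixed threshold of
log-LR > 10, mirroring the presence rule, with the raw log-LR always
reported. The separate fit is initialized from the shared solution so the
nesting inequality holds by construction; if numerical optimization still
leaves it below, the shared solution duplicated into both conditions is
returned (log-LR 0). The spline input is the spot-level zonation coordinate
(one could imagine cell-type-specific coordinates; the spot-level reading
is the one implemented and tested).

Calibration and power are established by simulation at the package's
declared study conditions: baseline presence probability 0.5, a pericentral
band (logistic edge at z = 0.6), a 2× odds effect in one condition, and
2000 spots per condition — pooled-slide Visium scale. Under these
conditions the null false-call rate at threshold 10 stays below 10% and the
2× effect is detected in over 80% of replicates; both are recomputed by the
acceptance script.

## Conserved-signature funnel

The per-cluster DE score is `mean1 / mean2 × lfc_mean` with `mean1`/`mean2`
the in-/out-of-cluster means of normalized expression, `mean2` floored at
1e-9 in the ratio, and `lfc_mean` the in-cluster mean of
`log2((x + ε)/(mean2 + ε))` with ε = 1e-4 — the upstream tooling this
mirrors does not print its exact formula, so this convention is pinned here
and exercised by a hand-computed oracle test. Stage semantics are strict
where the funnel's prose is strict: score < 10 is removed (10.0 survives);
a gene is removed when *more than* 30% of a non-target cluster's cells
exceed a scaled value of 0.50 (exactly 30% survives), with exempt clusters
allowed up to 70%. Scaled values are per-gene quantile scaling to [0, 1] at
the 0.99 quantile. Ties in the unique-cluster assignment break
lexicographically with a warning. The greedy step seeds with the top-k
(default 10) species-B markers and adds species-A candidates in score order
while the signature score (fraction of counts in signature genes) stays
enriched in the target cluster of both species — mean target score over the
best other cluster's mean above a threshold of 2. Hand-curated additions in
any particular study are not replicated; `force_include` is the hook for
them.

## Synthetic data: what it emulates, and what not

The generators are pure functions of their arguments and a seed, and every
stochastic quantity is returned in the truth object. Chosen emulation
targets, with the reasoning:

- Cell-type profiles: log-normal around a shared baseline with per-type
  deviations of sd 1.0 and planted marker blocks (8×, covering ~30% of
  genes across types). Real cell types differ strongly across most of the
  transcriptome, and a 150-gene deconvolution panel is in practice
  marker-rich; an early draft with sd 0.3 produced types correlated at
  r ≈ 0.84, which makes composition recovery information-starved for any
  method — verified with a fixed-nuisance per-spot ML oracle.
- Spot composition: Dirichlet with total concentration 10, modulated per
  zonated cell type by a stored logistic curve of z (midpoint, steepness,
  direction, floor all recorded). A logistic family is the simplest smooth
  monotone choice and is what the differential-abundance power analysis
  assumes.
- Zonated genes: multiplicative log-scale logistic modulation with
  amplitudes 1–2 and stored midpoints. Replicate datasets of one tissue
  must share this program — `gene_modulation` is passed explicitly — since
  the gene programs are a property of the biology, not of the capture.
- Depth and noise: spot libraries log-normal (meanlog 9, sdlog 0.3;
  ~8,000 UMIs median), spot-level NB dispersion around 30 — near-Poisson,
  as UMI noise at the spot level largely averages over tens of cells —
  while the single-cell reference uses dispersion around 3, reflecting
  genuine cell-to-cell variability. Capture bias sd 0.2, foreground
  Beta(18, 2), ambient background mean 0.2 counts/gene by default.
- Contamination: red-blood-cell signal as extra hemoglobin counts at a
  per-spot fraction of the library; antibody panels as NB mixtures whose
  foreground tracks a designated cell type's true abundance (w_fg = 0.8,
  background a tenth of the foreground base rate, dispersion 10 — typical
  ADT-like noise).

Not emulated: spatial autocorrelation beyond the zonation axis, histology,
segmentation artifacts, batch or slide effects beyond independent bias
draws, doublet structure in the reference, and ambient RNA with a
composition profile (the background is gene-independent exponential).
Passing recovery tests on these generators therefore demonstrates
correctness of the inference machinery under the model's own assumptions,
not robustness to every artifact of real tissue sections.

## Problem sizes and numerical settings used in validation

The shipped validation uses: reference recovery at 5 types × 200 genes ×
2000 cells (30% nuclei, 400 optimization steps); deconvolution at 500 spots
× 150 genes × 5 types with an estimated reference (1500 steps);
presence-test calibration on 500 spots with one planted-absent type
(100 Monte-Carlo draws); zonation at 500 spots × 120 genes with 100 zonated
genes (2000 steps), transferred to 400-spot replicates; the interaction
LRT at 2000 spots per condition over 60 null and 20 alternative
replicates; and the signature funnel at 300 genes × 4 clusters × 60 cells
per cluster per species, 3 seeds. These sizes were chosen as the smallest
at which the corresponding statistical claims are stable across seeds.

## Known limitations

- The diagonal-Normal guide understates posterior correlations; the
  deconvolution proportions of similar cell types are anti-correlated in
  truth, and the presence test inherits the approximation.
- The background/foreground/global-scale directions are weakly identified;
  the defaults encode low-ambient Visium and misreport genuinely
  ambient-heavy data unless reconfigured.
- The amortizer transfers within the feature space it was trained on;
  cross-panel transfer requires the new data to carry the training
  features (by name), and a disjoint antibody panel cannot reuse an
  RNA-trained encoder.
- The penalized LRT threshold of 10 is a convention, not a calibrated
  size; the null simulations show it is conservative at the declared study
  conditions, and the raw log-LR is always reported for users who want a
  permutation calibration.
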