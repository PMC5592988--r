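---
title: "From mtDNA haplotypes to methylation phenotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From mtDNA haplotypes to methylation phenotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplomethyl)
```

# The scientific setting

Cybrid-style embryonic stem cell panels carry one fixed chromosomal genome on
several divergent mitochondrial DNA (mtDNA) haplotypes, so any phenotypic
difference between lines is attributable to the mitochondrial genome and its
crosstalk with the nucleus. The measurable consequences span several assay
families, and this package implements the computational arm of each:

* genome-wide DNA methylation differences read out on two-channel MeDIP
  CpG-island microarrays;
* mtDNA copy number, relative expression and immunoprecipitation enrichment
  read out by qPCR;
* a composite *replicative efficiency* statistic combining copy number with
  the 5mC/5hmC balance at the *PolgA* exon-2 CpG island, the switch locus for
  differentiation-coupled mtDNA replication;
* plate-reader enzyme assays (alpha-ketoglutarate, MDH2) that connect the TCA
  cycle to TET-mediated demethylation;
* whole-mtDNA phylogenetics that place the haplotypes on a time axis via a
  rodent fossil calibration.

Every stage has a synthetic-data generator with planted truth, so the entire
pipeline can be validated end to end without any external download.

# MeDIP array differential methylation

## Model

Each array hybridises Cy3-labelled input DNA against the Cy5-labelled
methylated (5mC-immunoprecipitated) fraction of the same sample. The analysis
unit is the probe log ratio

$$r = \log_2 \frac{\max(\mathrm{Cy5}, f)}{\max(\mathrm{Cy3}, f)},$$

with an intensity floor $f$ (default 1 arbitrary unit) guarding
background-subtracted zeros. The orientation is methylated/input, so positive
ratios mean methylation enrichment; the package treats this as a declared
convention, and swapping the channels provably negates every ratio and
mirrors every hyper/hypo label.

A probe is *differentially methylated* between a line and the remaining lines
when two filters agree:

1. **Fourfold filter.** The difference of group-mean log ratios exceeds 2 in
   absolute value (a fourfold ratio change).
2. **Z filter.** The probe's mean Z-score in the *driving* group (the group
   with the larger mean absolute ratio) exceeds 5 in absolute value, where
   Z-scores are computed within melting-temperature (Tm) bins: probes with
   similar Tm form the Gaussian reference population against which a probe's
   log ratio is standardised.

Both cutoffs are strict conjunctions; raising either can only shrink the
called set, a property the test suite checks.

## Why the Z-score has two estimators

`compute_tm_binned_zscores()` offers `method = "sample"` (classical
mean/SD standardisation within each of 10 equal-count Tm quantile bins) and
`method = "robust"` (median and 1.4826·MAD). The pipeline default is
**robust**, and the reason is structural rather than cosmetic. With $n$
probes per bin of which $k$ are genuinely shifted, the sample-SD Z-score of a
shifted probe is bounded near $\sqrt{n/k}$ no matter how large the shift,
because the shifted probes inflate their own reference SD. At realistic
densities (1000 probes, two probes per gene, 20 planted genes per line, 10
bins) that bound sits almost exactly at the cutoff of 5, so a sample-SD
filter misses true positives essentially at random. Estimating the bin's
Gaussian from its bulk (median/MAD) removes the self-contamination: a clean
background then yields $|Z| \approx \text{shift}/\text{noise SD}$, and in the
noiseless limit displaced probes get $\pm\infty$ while background probes get
exactly 0, which is what makes zero-noise planted truth recoverable exactly.
The sample estimator remains available (and is the single-operation default)
because it is the textbook formula and the right tool when the input is known
to be overwhelmingly null.

## Gene aggregation and exclusivity

Called probes vote for their gene (interval-overlap annotation on 0-based
half-open coordinates, or a direct probe-to-gene map); conflicting directions
resolve by majority with ties reported as unchanged plus a conflict flag. A
gene is *exclusive* to a line when it is called in that line and unchanged in
all others; exclusive sets are pairwise disjoint by construction and genes
called in several lines land in a shared-intersection table. No
multiple-testing correction is applied: the cascade is threshold-based, and
the package mirrors that design.

```{r medip-example}
cfg <- sim_config(n_genes = 200, probes_per_gene = 2, noise_sd = 0.3,
                  n_replicates = 2, rng_seed = 11L)
set.seed(11)
truth <- sim_array_truth(cfg, n_per_line = 8, shift = 3)
sim <- sim_cpg_arrays(cfg, truth)
res <- medip_pipeline(sim$arrays, sim$annotation)
res$line_specific$summary
```

## What the generator does and does not emulate

The generator plants additive log2 shifts (default magnitude 3, comfortably
past the fourfold cutoff) on a baseline of 0, adds i.i.d. Gaussian probe
noise, draws Tm uniformly on [70, 90] °C once per probe, and fixes Cy3 at
1000 units. It deliberately does **not** model spatial array artefacts,
intensity-dependent (MA-curvature) bias, probe-sequence affinity differences,
Tm-correlated variance, or correlated replicate noise. Passing tests
therefore demonstrate that the cascade logic is correct and well calibrated
for exchangeable Gaussian noise — not that real Agilent arrays are free of
the systematic effects that feature-extraction software corrects upstream.
The replicate count per line is a free parameter (default 2), as array
studies of this design rarely fix it.

# qPCR quantities

Standard curves are ordinary least-squares fits of Ct against log10 copies
(at least 3 dilution points; a non-negative slope is rejected as an inverted
curve), with amplification efficiency $10^{-1/\text{slope}} - 1$ flagged
outside $(0, 1.1]$. Quantification inverts the line exactly, so
curve-then-invert is the identity — one of the package's acceptance
properties. Copies per cell reference mtDNA quantity to the beta-actin locus
at a declared 2 copies per diploid genome (`actin_copies_per_cell`
configurable, since conventions differ between laboratories). Relative
expression uses $2^{-\Delta\Delta Ct}$; enrichment uses percent input,
$100 \cdot f \cdot 2^{Ct_{\mathrm{input}} - Ct_{\mathrm{IP}}}$ with the input
fraction $f$ defaulting to 0.1 — the field-standard readout, chosen because
the assay description specifies only "enrichment against input". Replicate
Cts are averaged arithmetically before any transform; non-detects are dropped
from means and imputed (to a configurable Ct ceiling, default 40) only in the
Fluidigm matrix, where a missing value must still occupy a cell.

The Fluidigm stage normalises every gene to 18S rRNA within sample
($\Delta Ct$), clusters genes and samples by average-linkage hierarchical
clustering on euclidean distances (the distance is part of the assay
convention; the linkage is this package's choice, verified in tests against a
brute-force agglomeration oracle), and pairs the matrix with a plain Welch
two-sample *t* per gene, labelled `welch_t` in the output to make clear it is
not a moderated (limma-style) statistic.

# Replicative efficiency

The composite statistic is isolated in one pure function:

$$\mathrm{efficiency} = \frac{\text{copies per cell}}{5mC/5hmC}
  = \text{copies per cell} \cdot \frac{e_{5hmC}}{e_{5mC}},$$

with both enrichments measured at the *PolgA* exon-2 amplicon. "Expressed as
a function of the ratio" admits more than one functional form; division by
the methylation/demethylation ratio is the reading consistent with the
statistic's use (high methylation at the replication switch suppresses
apparent efficiency), and because the whole choice lives in
`replicative_efficiency()` an alternative form is a one-line swap. The
statistic is invariant to common rescaling of the two enrichments, strictly
monotone in each argument, undefined (`NA`) at zero 5mC and an error at
non-positive 5hmC. `efficiency_timecourse()` arranges per-line, per-day
values (days 0/3/12/21 in the motivating design) and ranks lines within day.

# Enzyme assays

Alpha-KG amounts invert the kit's standard line as
$(A - \text{intercept})/\text{slope}$ — the printed kit formula is
typographically ambiguous about parenthesisation, and the standard
linear-curve inversion is the only reading that makes the units work. The
`blank` handling is left to the caller (corrected absorbance in, nmol out);
whether a blank well or a time-zero read is subtracted differs between kit
protocols and is not guessed here.

MDH2 specific activity applies
$U = (r_A \cdot V_{\mathrm{cuvette}}) / (l \cdot \xi \cdot V_{\mathrm{sample}}
\cdot \rho)$ with the reagent-dye extinction coefficient $\xi = 37$ per mM
per cm, $\rho$ interpreted as the protein mass concentration of the loaded
lysate so that $U$ is per-mg specific activity.

The kinetic rate $r_A$ comes from the maximal initial prefix of the trace
whose OLS fit reaches $R^2 \ge$ `r2_threshold`. The threshold defaults to
0.998: on the default 61-point grid (30 min sampled every 30 s) a window that
has crept far enough past a saturation kink to bias the slope by ~5% still
fits with $R^2 \approx 0.99$, whereas 0.998 stops within a couple of points
of the kink and keeps the recovered rate within ~2% of the generating rate at
realistic noise (SD 0.005 AU). If no prefix qualifies the full-trace slope is
returned with a warning rather than failing the sample.

# Phylogenetics and divergence dating

## Distances

Pairwise distances are maximum-likelihood estimates under GTR(+Γ) with one
alignment-wide parameterisation: empirical base frequencies, five
exchangeabilities (GT fixed at 1) maximising the *sum* of pairwise
log-likelihoods with each pair's distance profiled out — the composite
convention of estimating model parameters once from the whole alignment and
sharing them across pairs. Each pair's distance is then the root of the
analytic score function (derivative of the pairwise log-likelihood), located
by bisection to ~1e-12, which is why the uniform-rates/uniform-frequencies
special case reproduces the Jukes–Cantor closed form
$-\tfrac34\ln(1 - \tfrac43 p)$ to nine decimals in the tests. Among-site rate
variation uses the equal-probability discrete gamma (category means; shape
default 0.3734, 5 categories, the parameterisation conventional for rodent
mtDNA data of this kind). Gap/ambiguity sites are excluded pairwise; a pair
whose score never crosses zero before 500 substitutions/site is reported
saturated (`Inf`) with a warning; pairs need at least 100 complete sites.

## Trees, support, ages

Tree search is neighbor-joining (`ape::nj`) on the distance matrix, with taxa
pre-sorted by label so ties resolve deterministically. Support comes from
nonparametric bootstrap over alignment columns (`ape::boot.phylo`), NJ-ing
each replicate under the *fixed* fitted model — refitting exchangeabilities
per replicate would multiply runtime by orders of magnitude for no measurable
change in supports on data of this size.

Divergence dating uses a relative-rate normalisation: after rooting on the
outgroup, each node's relative height is the average over its children of
(child height + connecting branch), computed bottom-up. Averaging sister
lineages at every node is what absorbs lineage-specific rate differences, and
at the root the average is invariant to where the root subdivides the
outgroup branch. On ultrametric input the heights equal the input heights
exactly. Heights are scaled so the calibrated outgroup/ingroup split sits at
the calibration midpoint (10 Mya for the rodent interval [8, 12]); the
endpoints propagate multiplicatively to per-node bounds. A genuinely
unconstrained absolute estimate does not exist without a second calibration,
so the midpoint rule is applied unconditionally. This is a documented
approximation of relative-rate dating, not a reimplementation of any
specific program's update equations; on clock-like simulated data (16.3 kb,
true ages 1.82/3.88/6.44/10 Mya) it recovers ages within a few percent, and
that recovery — not agreement with any published point estimate — is what
the acceptance checks assert.

```{r phylo-example}
tre <- ape::read.tree(text =
  "((((mus:1.82,spretus:1.82):2.06,dunni:3.88):2.56,pahari:6.44):3.56,rattus:10);")
m <- gtr_model(c(1, 8, 1, 1, 16, 1), c(0.31, 0.29, 0.12, 0.28))
sim <- sim_clock_alignment(tre, m, n_sites = 4000, clock_rate = 0.01, seed = 3L)
d <- pairwise_distances(sim$alignment, m)
dt <- divergence_times(nj_tree(d), "rattus", calibration = c(8, 12))
dt$ages[, c("clade", "age", "age_lower", "age_upper")]
```

## Simulation model

The sequence generator draws a stationary root, assigns each site a gamma
rate category, and propagates characters through exact eigendecomposed
transition matrices edge by edge. It emulates clock-like evolution with
i.i.d. sites; it does not model indels, rate autocorrelation along the
genome, base-composition drift between lineages, or alignment error, so
phylogenetic tests certify estimator correctness under the model, not
robustness to alignment artefacts.

# Numerical choices and problem sizes

* Array simulations in the tests use 100–500 genes at 2 probes per gene;
  the full cascade over 8 arrays of 1000 probes runs in well under a second.
* The qPCR error-propagation check uses 200 unknowns at 6 replicate wells and
  compares the Monte-Carlo mean relative error against the delta-method
  prediction $\sqrt{2/\pi}\,\ln 10\,\sigma / (\sqrt{n}\,|s|)$.
* The kinetic-slope bias check runs 1000 seeded traces against the OLS
  variance formula.
* Age-recovery simulations use 16,300 sites (a mouse mtDNA's worth) with
  1000 bootstrap replicates; the whole acceptance run completes in about half
  a minute on one CPU.
* All generators take explicit seeds and are reproducible bit for bit; all
  tolerance-based assertions use either machine-precision bounds (algebraic
  identities), 3-standard-error bounds (Monte-Carlo), or the explicit
  percent bounds stated above.

# Interfaces and limitations

The package's interface is its exported functions plus this vignette;
analyses of this kind are driven from R scripts, so no shell wrapper is
shipped. File-level interchange uses plain text: TSV probe tables
(`ProbeID/Chr/Start/End/Tm/Cy3/Cy5`, 0-based half-open coordinates), BED-like
probe-to-gene annotations, CSV Ct tables, FASTA alignments (via `ape`), and
Newick trees/dendrograms.

Known limitations, beyond the generator caveats above: the cascade's
behaviour on real arrays depends on upstream feature extraction that is out
of scope here; the exact Z-score used by vendor software is unpublished, so
the two estimators provided bracket the reasonable choices; the
percent-input convention and the diploid reference-locus factor are declared
defaults that must be matched to the laboratory's bookkeeping before
absolute numbers are compared across studies; and the dating method is a
relative-rate approximation whose absolute ages inherit the full width of
the calibration interval.
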