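---
title: "Methods: lysis profiling from paired rRNA fractions"
author: "morsR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lysis profiling from paired rRNA fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morsR)
```

# The measurement model

Seawater filtered at 0.22 µm separates ribosomal RNA into a cell-associated
fraction (ca-rRNA, retained cells — the living community) and a cell-free
fraction (cf-rRNA, the filtrate — ribosomes released by recent cell lysis).
Both fractions are amplicon-sequenced (18S V4), denoised into ASVs and
counted. Because cf-rRNA decays within hours to days, a taxon whose relative
abundance is *higher* in the dissolved fraction than in the cellular
fraction is being lysed faster than the community average; a taxon depleted
in the dissolved fraction is comparatively intact.

`morsR` starts from the ASV count table (it does not re-implement read
denoising or taxonomy assignment) and computes:

* **CLI**, the cell-lysis index: the log2 fold change of an ASV between the
  cf and ca fractions within one depth layer. Positive = preferentially
  lysed.
* **EEI**, the epipelagic enrichment index: the log2 fold change of an
  ASV's ca-rRNA between the epipelagic (surface + subsurface chlorophyll
  maximum) and mesopelagic layers. Positive = surface-preferring.

Both indices are per-contrast GLM coefficients, so all of the machinery
below applies to each of the three contrasts (`CLI_EPI`, `CLI_MES`, `EEI`).

# Preprocessing

The pipeline applies, in order: removal of non-protist ASVs (metazoan,
prokaryote and unclassified labels carry `protist = FALSE` in the taxonomy
table), removal of rare ASVs (total < 10 reads, or nonzero in < 2 samples —
"found in only one sample" is interpreted as prevalence, not as
concentration of reads in one sample), and rarefaction of every sample to
exactly 25,878 reads.

Rarefaction is multivariate-hypergeometric: reads are subsampled *without*
replacement within each sample, so a rarefied cell can never exceed its
original count and zeros are preserved. Samples below the target depth are
dropped with a warning rather than resampled with replacement — the
standard conservative choice. The subsampling seed is a required, logged
argument.

A second prevalence filter (nonzero in >= 4 samples) applies *within the
samples each contrast selects*, not globally. Whether this filter should be
global is genuinely ambiguous; per-contrast is the default because a filter
meant to stabilise a GLM should see the same samples the GLM sees, and the
alternative is one flag away (`minPrevalence`).

# The differential-abundance stack

The stack is a native reimplementation (R with a compiled IRLS core), not a
wrapper around an existing DA package; the established packages are used as
independent cross-checks in the test suite.

**TMM normalisation.** Library sizes are corrected by the trimmed mean of
M-values: against a reference sample (upper-quartile rule), per-ASV log
ratios `M` are doubly trimmed (30% on `M`, 5% on the average abundance `A`)
and averaged with inverse-asymptotic-variance weights; factors are rescaled
to geometric mean 1. TMM assumes most features are non-differential between
the compared samples — see the generator notes below for why this matters.

**Dispersion.** Counts are modelled as NB with variance `mu + phi mu^2`.
For each candidate `phi` on a 19-point log grid spanning `[1e-6, 10]`, an
NB GLM is fitted per ASV and the Cox-Reid adjusted profile likelihood
`APL_g(phi) = l_g(beta_hat) - 0.5 log det(X'WX)` is recorded. The common
dispersion maximises the mean APL (quadratic interpolation between grid
points); tagwise dispersions maximise `(df * APL_g + priorDf * meanAPL) /
(df + priorDf)` with `priorDf = 10`, an empirical-Bayes compromise that
reproduces the common value as `priorDf` grows. No abundance-dispersion
trend is fitted: at the scale of a single amplicon survey the trend adds
complexity without changing behaviour, and the validation here is by
simulation against known truth rather than numerical equality with any
particular package.

**GLM and LRT.** Each ASV is fitted by IRLS (log link, offset = log
effective library size; at most 50 iterations, deviance change < 1e-8, step
halving on non-decrease; coefficients initialised from least squares on
`log(y + 0.5) - offset`). The likelihood-ratio statistic compares the
two-group model against the intercept-only model on chi-square(1).
Fold-change shrinkage: the reported logFC is re-estimated after adding a
prior count of 0.125 (apportioned across samples proportionally to
effective library size) so ASVs with zeros in one group get finite
estimates; the p-value always comes from the unaugmented fit, because the
prior count exists to stabilise the estimate, not the test. Non-converged
fits surface as `PValue = NA` and are never called significant.

**Calls.** Benjamini-Hochberg FDR is applied per contrast (three separate
families). An ASV is `up`/`down` when FDR < 0.1 *and* |logFC| > 2, both
strict.

# Habitat classification

Per ASV, the EEI call maps directly: `up` -> EPI, `down` -> MES, `ns` ->
BOTH (ubiquitous). Per lineage (subdivision rank), the density of EEI
values is examined for multimodality: a Gaussian KDE with Silverman's
rule-of-thumb bandwidth on a 512-point grid spanning the data range
extended by three bandwidths; local maxima are candidate modes; each mode's
mass is the integrated density over its basin (delimited by the flanking
local minima); modes holding < 10% of the area are merged into the adjacent
larger basin. The basin-split definition of "mode area" is one of several
possible conventions — it is the one that makes masses sum to one exactly,
which the tests assert. A mode located above zero counts as epipelagic,
below zero as mesopelagic; a mode at exactly zero counts as neither (the
sign is the only depth mapping the indices define). A lineage with modes on
both sides is multi-habitat; lineages with fewer than five ASVs are
reported as `insufficient_data` rather than classified.

# Linkage, ecology, decay

ASVs lacking a computable result in either contrast being linked (filtered
by prevalence, or all-zero in a compared group) are excluded from all joint
statistics; with a prior count an exact-zero logFC has probability zero, so
"no computable value" is the operative meaning of a missing measure. The
joined set feeds the DA intersection (reported as percentages of each DA
set, rounded half-up to one decimal), the habitat x lysis Sankey
contingency, Spearman's rank correlation (Pearson on mid-ranks, two-sided t
approximation) and Wilcoxon rank-sum comparisons (exact enumeration below
group size 8, otherwise normal approximation with tie and continuity
corrections).

Community structure: Bray-Curtis dissimilarity on rarefied counts (equal
depth makes count and proportion versions equivalent; a flag exposes the
choice), Ward.D2 agglomeration via the Lance-Williams recursion (returns a
standard `hclust` object), and ANOSIM with mid-ranked dissimilarities, `R =
(mean between-group rank - mean within-group rank) / (M/2)`, and a
permutation p-value `(1 + #{R* >= R}) / (1 + nPerm)` that includes the
identity permutation and is therefore never below `1/(nPerm + 1)`.

Decay kinetics use the first-order model `Ct = C0 exp(-kt)`. The primary
estimator is the two-point form `k = ln(C0/Ct)/t` computed per replicate
and averaged arithmetically, with half-lives summarised as harmonic means —
the harmonic mean of `ln2/k_i` equals `ln2/mean(k_i)` exactly, which the
package asserts. A log-linear regression over all timepoints is provided as
an alternative; note that `k` from the mean ratio differs from the mean of
per-replicate `k` by Jensen's inequality, so the replicate-first order of
operations matters and is the default.

# The synthetic community generator

No generative model accompanies field data, so the generator defines one —
the minimal model reproducing the compositional contrasts the pipeline
measures:

1. each ASV draws a lognormal baseline relative abundance (sdlog 1.5), a
   habitat class and a lineage from a fixed PR2-like catalogue;
2. the expected ca composition of a layer boosts ASVs whose habitat matches
   it by `2^depth_effect_log2` (default 4; BOTH-habitat ASVs get no boost,
   which keeps the EEI sign interpretable against truth) and renormalises;
3. the expected cf composition reweights the ca composition by
   `2^lysis_log2fc` (default 3) for ASVs designated lysed in that layer and
   renormalises — lysis is compositional enrichment of the dissolved pool,
   exactly what CLI measures;
4. counts are NB with dispersion 0.1 around composition x library size
   (60,000 reads before rarefaction to 25,878), one ca and one cf sample
   per station x sublayer (5 stations; surface 10 m, SCM 50 m, mesopelagic
   300 m).

Default proportions: habitat mix EPI 0.25 / MES 0.15 / BOTH 0.60; lysed
fractions 3% (epipelagic) and 5% (mesopelagic) of ASVs. Two defaults
deserve justification. First, the depth-indifferent class is the majority
because TMM normalisation *assumes* most features are non-differential;
a generator whose majority class is differential would violate the
normaliser's documented assumption in every contrast and test nothing but
that violation (with a majority-differential mix the trimmed mean sits on
differential ASVs and shifts every index by a constant). Second, lysed
ASVs are drawn from ASVs above a baseline-abundance floor (5e-4), because a
spike below the detection floor of a 25,878-read library is unobservable by
construction. By default the mesopelagic lysed set is drawn from
EPI-habitat ASVs and the epipelagic lysed set from BOTH-habitat ASVs,
mirroring the field observation the pipeline is designed to detect; both
links and the floor are configuration options, and setting the source
habitats to `NA` gives unbiased designation.

What the generator does *not* emulate: sequencing error and chimeras,
read-level structure, taxon-correlated abundances, heterogeneous per-ASV
effect sizes, station effects, or mechanistic virus/grazer dynamics.
Passing tests therefore demonstrate that the inference machinery recovers
known compositional structure under the stated noise model — not that field
data satisfy that model.

# Numerical choices and limitations

Problem sizes in the tests and the acceptance script (1,000-1,500 ASVs, 30
samples, 5-20 simulation replicates, 999-9,999 permutations) are chosen to
exercise the study design at full width while keeping a complete run in
minutes on one CPU. Dispersions are clamped to `[1e-6, 10]`; IRLS
non-convergence is flagged per ASV and propagates as non-significance;
zero-variance KDE input returns a single mode of mass one; a sample sharing
no positive ASVs with the TMM reference receives factor 1 with a warning.
The Spearman p-value uses the t approximation (adequate for the n here, not
for n < 10 with many ties); the mode-area convention is basin integration,
not curvature-based alternatives; and ANOSIM R values from the synthetic
community should not be read as predictions of field effect sizes — they
validate the machinery, not the ocean.
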