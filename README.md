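# morsR

Cell-lysis profiling of marine microeukaryotes from paired cell-free and
cell-associated rRNA metabarcoding.

## The problem

When a protist cell is lysed — by viral infection, sloppy feeding or
parasitism — its ribosomes are released into seawater. Ribosomal RNA in the
dissolved fraction (< 0.22 µm, "cell-free" or cf-rRNA) is labile, with a
half-life of hours, so its taxonomic composition is a snapshot of *recent*
cell death, while rRNA retained on the filter ("cell-associated", ca-rRNA)
reflects the living community. Comparing the two fractions taxon by taxon —
the Mortality by Ribosomal Sequencing (MoRS) idea — turns a pair of 18S
amplicon count tables into a per-taxon cell-lysis assay.

`morsR` implements this analysis end to end for an oceanographic survey
design (stations × depth layers × two rRNA fractions), with a synthetic
community generator carrying known ground truth so that every stage is
testable without field data.

## The statistics at the core

For each amplicon sequence variant (ASV), abundance differences between two
sample groups are tested with a TMM-normalised negative-binomial GLM and a
likelihood-ratio test (all reimplemented natively in this package):

* counts `y_gi ~ NB(mu_gi, phi_g)` with `log mu_gi = log(N_i f_i) + x_i b_g`,
  where `N_i f_i` is the TMM-corrected effective library size;
* dispersions `phi_g` estimated by Cox–Reid adjusted profile likelihood
  (common value plus empirical-Bayes tagwise shrinkage);
* per-ASV LRT against chi-square(1), Benjamini–Hochberg FDR, and a call of
  `up` / `down` / `ns` at FDR < 0.1 and |log2 fold change| > 2.

Three contrasts define the two indices:

* **CLI** (cell-lysis index): cf vs ca within a depth layer
  (`CLI_EPI`, `CLI_MES`); positive = enriched in the dissolved fraction,
  i.e. preferentially lysed;
* **EEI** (epipelagic enrichment index): epipelagic vs mesopelagic ca-rRNA;
  positive = surface-preferring.

Habitat preference is classified per ASV from the EEI call
(EPI / MES / BOTH) and per lineage by Gaussian-KDE mode analysis (modes with
at least 10% of the distribution area, on either side of zero). Linkage
statistics (DA-set intersections, Sankey habitat × lysis contingency,
Spearman rank correlation, Wilcoxon rank-sum) connect where taxa live to
where they die. Community structure is summarised with Bray–Curtis
dissimilarity, Ward.D2 clustering and a native permutation ANOSIM, and
extracellular-rRNA decay experiments are fitted with first-order kinetics
`Ct = C0 exp(-k t)`, `t1/2 = ln 2 / k`.

## Worked example

```r
library(morsR)

## simulate a survey: 5 stations x {surface, SCM, mesopelagic} x {ca, cf},
## 1000 ASVs with known habitat and lysis ground truth
sim  <- simulateMorsExperiment(simConfig(n_asvs = 1000, seed = 42))
mors <- rarefy(sim$mors, depth = 25878, seed = 9)

cliMes <- runContrast(mors, "CLI_MES")   # lysis at depth
eei    <- runContrast(mors, "EEI")       # habitat preference
cliMes
#> ContrastResults: CLI_MES ( cell_free vs cell_associated )
#>    876 ASVs tested; 51 up, 6 down at FDR < 0.1, |logFC| > 2
#>    common dispersion: 0.099

## where do the depth-lysed taxa live?
hab    <- assignAsvHabitat(eei)
joined <- zeroValueFilter(cliMes, eei)
upMes  <- cliMes$asv_id[cliMes$call == "up"]
habOf  <- hab$habitat[match(intersect(joined$asv_id, upMes), hab$asv_id)]
round(100 * mean(habOf == "EPI"), 1)
#> [1] 98
```

51 of 876 tested ASVs are significantly cf-enriched (lysed) in the
mesopelagic zone, and ~98% of them are classified as epipelagic-habitat
taxa — the simulated signature of surface cells sinking and being lysed at
depth, recovered by the pipeline from counts alone.

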