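---
title: "Methods: eQTL mapping in doubled-haploid populations with dheqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eQTL mapping in doubled-haploid populations with dheqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dheqtl)
```

# Scope and model

`dheqtl` implements an expression-QTL analysis for a biparental
doubled-haploid (DH) population, the design used for immortalized mapping
panels in *Brassica napus* and other crops. In a DH population every locus is
homozygous for one of the two parental alleles (coded A and B), segregating
1:1, which reduces interval mapping to a two-genotype regression problem and
makes the recombination fraction between two loci directly estimable as the
fraction of discordant lines.

The pipeline stages are:

1. **Marker filtering and bin division.** Markers are dropped when their
   missing fraction exceeds `max_missing` (default 0.2) or when a 1-df
   chi-square test rejects 1:1 segregation at `distortion_alpha` (default
   0.001). Consecutive markers on a chromosome whose genotype vectors agree
   on every line where both are observed are collapsed into one bin,
   represented by the member with the smallest physical position. These two
   defaults are common DH-map practice; the upstream variant-calling filters
   of a real study are out of scope here, so both are configurable.
2. **Genetic-map construction.** Marker order is taken from the physical
   coordinates (one linkage group per chromosome). The cM position is the
   cumulative Kosambi distance of adjacent-pair estimates
   $\hat r$, with $d = 25\,\ln\frac{1+2r}{1-2r}$ and its exact inverse
   $r = \tfrac12\tanh(2d/100)$. $\hat r$ is capped at 0.4999 to stay inside
   the Kosambi domain; an interval with no line informative at both ends
   borrows the nearest informative adjacent-pair estimate on the same
   chromosome (logged as a warning). De-novo marker ordering is deliberately
   not implemented: the analysis assumes a genome-collinear map.
3. **LOD scan (Haley–Knott composite interval mapping).** At every grid
   position (all marker positions plus a `step_cm` lattice, default 2 cM)
   the probability of the A genotype is computed for each line from its
   nearest non-missing flanking markers via the inverse Kosambi function; at
   an observed marker it is exactly 0 or 1, with no informative flank it is
   the DH prior 0.5. The LOD is
   $\frac{n}{2}\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$ for the regression
   of the (transformed) trait on $P(A)$, with forward-selected cofactor
   markers as covariates; cofactors within `cofactor_window_cm` (default
   10 cM) of the test position are dropped. Cofactors enter by partial
   F-test at `entry_alpha` 0.01 up to `max_cofactors` 5 — WinQTLCart-like
   defaults, since the original method names CIM without its settings. At a
   fully typed marker with no cofactors the scan LOD equals the closed-form
   single-marker regression LOD, which the test suite checks to 1e-8.
4. **Permutation thresholds.** Trait values are permuted across lines
   (`n_permutations`, default 1000) and the genome-wide maximum LOD of each
   cofactor-free scan is collected; the threshold is the type-7
   $(1-\alpha)$ quantile with $\alpha = 0.05$ (the permutation count is part
   of the original design; the significance level is not stated there, and
   0.05 is the conventional genome-wide choice).
5. **QTL calling.** Supra-threshold local maxima become records. A second
   peak on the same linkage group is reported separately only when it is at
   least one cofactor window away from every accepted peak *and* separated
   from it by a dip below (peak − `lod_drop`). Requiring both conditions
   matters: with the disjunctive reading, noise wiggles a window-width from
   a broad peak become spurious extra records (nine records for two planted
   QTLs in our testing), whereas the conjunctive rule reproduces the
   intended behaviour (one record per planted QTL, two records for two QTLs
   60 cM apart). The support interval is the contiguous region with LOD
   within `lod_drop` (default 1.5) of the peak, converted to bp by linear
   interpolation between flanking markers. Explained variance is
   $1-\mathrm{RSS}_1/\mathrm{RSS}_0$ of the single-QTL model at the peak,
   and the additive effect is half the difference of the predicted-A and
   predicted-B group means (positive = A allele increases the value),
   assigning lines by $P(A) \ge 0.5$.
6. **cis/trans classification and eGene partition.** An eQTL is cis when its
   peak is on the eGene's chromosome and $|\text{peak bp} -
   \text{gene start}|$ is strictly below 1 Mb; exactly 1 Mb is trans, per
   the strict "<1 Mb" rule. The gene start is the anchor (strand is ignored
   throughout). eGenes partition into cis-only / trans-only / both.
7. **Trans-eQTL hotspots.** Trans-eQTL peak density is computed in 1-Mb
   windows sliding by 100 kb; the threshold is the genome-wide type-7 95%
   quantile of all window counts, *including* zero-count windows (the
   density is defined over the full tiling; a per-chromosome or
   nonzero-only variant is a configuration choice). Windows strictly above
   the threshold that overlap or are book-ended merge into hotspots;
   hotspots with fewer than `min_members` (default 2) member trans-eQTLs
   are suppressed as singleton artifacts at desk scale. Hotspot intervals
   are intersected with trait-QTL support intervals for colocalization.
8. **RC.eQTL enrichment null.** To test whether eQTL–eGene pairs coincide
   with 3D-genome interaction anchors more often than chance, randomly
   created eQTLs are drawn matched to the observed architecture: sampled
   genes receive region counts resampled from the observed per-eGene count
   distribution and region lengths resampled from the observed
   support-interval length distribution, placed uniformly (chromosomes
   weighted by length). A record is "aligned" with an interaction when its
   eQTL interval overlaps one anchor and its eGene body overlaps the other
   (either orientation); because the published phrasing is ambiguous, an
   `alignment_mode = "eqtl_only"` switch implements the one-ended reading.
   A single random draw cannot yield a significance statement, so the null
   is replicated (`n_replicates`, default 100) and the one-sided empirical
   p-value is $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + R)$.
9. **Candidate prioritization.** The published intersection logic — genes
   inside a target interval, carrying a cis-eQTL, and significantly
   correlated with each focal trait in *every* microenvironment (P < 0.01)
   — is implemented directly with per-gene Pearson correlations on
   log2(x+1) expression. The original analysis reached the gene lists
   through a WGCNA co-expression step; the module-detection machinery is
   out of scope here and the all-environments P < 0.01 correlation filter,
   which is what actually selects the candidate, is applied per gene.
   Candidates are ranked by cis-eQTL status, then maximum |r|, ties broken
   by position.

# The synthetic-data generator

Every downstream stage is validated against populations with known planted
truth. `sim_config()` defaults mirror the target study design: 156 DH lines,
19 chromosomes (A01–A10, C01–C09) of 154.37 cM each (2,933 cM total) and 211
markers each (~4,000 bins), 20,000 expression traits with 5% planted cis
effects, one master-regulator hotspot near the end of chrA09 with 300 trans
targets, and SOC/SCC/SLC-like traits driven by a pleiotropic locus at the
hotspot in two microenvironments.

Genotypes are generated as independent recombinant gametes: A/B with
probability 1/2 at the first marker, then a switch between adjacent markers
with the Kosambi-implied recombination fraction of the cM gap, independent
across intervals — crossover interference beyond the map function itself is
not modelled, which is sufficient for testing the scan and mapping stages.
Missing genotypes are inserted uniformly at random (no informative
missingness mechanism is assumed).

Expression is generated on the analysis scale as
$z = \text{baseline} + \sum\beta\,g + \varepsilon$ with
$\beta = 2\sigma\sqrt{f/(1-f)}$ so that a planted effect explains the
variance fraction $f$ under 1:1 segregation, then mapped to the FPKM-like
scale as $2^z - 1$ (clamped non-negative). The default log2(x+1) transform
of the scan therefore recovers the planted additive model exactly. This is
an additive-Gaussian stand-in, not a count model: passing tests demonstrate
correct inference under the model the scan assumes, not robustness to
RNA-seq count noise, library-size artifacts, batch structure, or real LD
beyond the map model. Epistasis is not planted.

# Numerical choices

* LOD values on numerically perfect fits are capped at `lod_ceiling`
  (default 50) to avoid infinities while preserving ranking.
* All quantiles (permutation threshold, hotspot threshold) are type-7, R's
  default.
* Cofactor selection ties are broken by chromosome then bp, making selection
  deterministic; permutation seeds are derived per trait from a hash of the
  trait id, so scan results are independent of trait order and of how traits
  are batched.
* A zero-variance trait yields an all-zero LOD profile with a warning, not
  an error; traits with fewer than `min_individuals` (20) informative lines
  are skipped.
* Genes expressed (non-zero) in fewer than 10% of lines are not scanned.
* Coordinates are 1-based closed everywhere except on-disk BEDPE (0-based
  half-open, converted on read); distances use the gene start.
* Writers emit deterministic byte streams (fixed column order, `%.6g`
  floats), so outputs are diffable across runs.

# Problem sizes in the test suite

The validation studies are scaled to run on a single CPU in minutes, a size
chosen to keep the binomial error of each recovery rate well inside the
asserted bounds: cis-recovery and type-I use 500 genes (50 planted at
r² = 0.2) on a 10 × 100 cM genome with 200 permutations at n = 150; hotspot
recovery plants 100 trans targets; RC-null calibration uses 50 independent
interaction draws against 100-replicate nulls; prioritization recovery uses
50 seeds. The generator and scan accept the full-design sizes unchanged.

# Known limitations

* Marker order is trusted from physical coordinates; genotyping-error
  correction and multipoint ML ordering are not implemented.
* The scan fits a two-genotype (DH) model only — no F2/backcross
  three-genotype codes, no epistasis, no multiple-QTL model fitting.
* The explained variance reported per record is from the single-QTL model at
  the peak, not the full cofactor model, which matters when background
  variance is large.
* Hotspot naming/ordering is positional and not comparable across datasets.
* The enrichment test conditions on the observed eQTL architecture; it does
  not model uncertainty in the eQTL calls themselves.
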