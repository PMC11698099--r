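# dheqtl — expression QTL mapping in doubled-haploid populations

`dheqtl` is an R package for genome-wide expression-QTL (eQTL) analysis in
biparental doubled-haploid (DH) populations, the immortalized mapping panels
used in *Brassica napus* and other crop genetics. It is aimed at
quantitative geneticists who have a DH genotype matrix, an expression matrix
and phenotypic traits, and want to go from raw markers to classified eQTLs,
trans-eQTL hotspots, 3D-genome enrichment tests and prioritized candidate
genes in one reproducible pipeline.

## What it computes

* **Genetic map**: marker filtering (missingness, 1:1 segregation-distortion
  chi-square), bin division of redundant markers, and a Kosambi map over the
  physical order — d = 25 ln((1+2r)/(1−2r)) cM with r̂ estimated from
  discordant line fractions.
* **LOD scan** (Haley–Knott composite interval mapping): at each genome
  position, LOD = (n/2) log₁₀(RSS₀/RSS₁) for the regression of the trait on
  P(A | flanking markers), with forward-selected cofactor markers excluded
  within a 10 cM window of the test position; genome-wide significance from
  permutation thresholds (1 − α quantile of the per-permutation maximum
  LOD, default α = 0.05, 1000 permutations).
* **eQTL records**: peak, 1.5-LOD support interval in cM and bp, explained
  variance r², additive effect (positive = A allele increases the value),
  and cis/trans class (cis = same chromosome and < 1 Mb from the gene
  start).
* **Trans-eQTL hotspots**: sliding-window density (1 Mb window, 100 kb
  step), genome-wide 95%-quantile threshold, merged supra-threshold
  windows; colocalization with trait-QTL intervals.
* **RC.eQTL enrichment null**: randomly created eQTLs matched to the
  observed interval-length and per-eGene count distributions, giving an
  empirical p for the overlap of eQTL–eGene pairs with genome-interaction
  anchor pairs (BEDPE input).
* **Candidate prioritization**: genes in a target interval ∩ cis-eQTL
  status ∩ trait–expression correlation significant (P < 0.01) in every
  microenvironment.
* **Synthetic-data generator**: DH populations with planted cis/trans
  effects, master-regulator hotspots and pleiotropic trait loci, so every
  stage can be validated against known truth.

## Worked example

Simulate a 150-line DH population on five 100-cM chromosomes with ten
planted cis eQTLs (r² = 0.3) and a 100-target master regulator on chr03,
then run the map → scan → classify → hotspot stages:

```r
library(dheqtl)

cfg <- sim_config(n_individuals = 150, n_chromosomes = 5,
                  markers_per_chromosome = 100, chromosome_length_bp = 4e7,
                  chromosome_length_cM = 100, n_genes = 130,
                  planted_cis = data.frame(gene = 1:10, r2 = rep(0.3, 10)),
                  hotspot_locus = list(chrom = "chr03", bp = 2e7),
                  hotspot_n_targets = 100, seed = 42)
pop  <- simulate_population(cfg)
geno <- bin_markers(filter_markers(pop$genotypes))$genotypes
map  <- build_map(geno)
map
#> Genetic map: 303 markers, 5 linkage group(s), 503.95 cM

es   <- scan_all(pop$expression, map, geno,
                 scan_config(step_cm = 1, n_permutations = 200, seed = 42))
recs <- classify_cis_trans(es$records, pop$expression$genes)
attr(categorize_egenes(recs), "counts")
#>   cis_only trans_only       both
#>          9        103          1

hs <- call_hotspots(window_density(recs, chromosome_sizes(map)), recs)
hs$hotspots[4, 1:6]
#>     hotspot chrom    start      end n_members n_egenes
#> 4 hotspot04 chr03 17000001 24000000        89       89

head(recs[order(-recs$lod), c("trait", "chrom", "peak_bp", "lod", "r2", "a", "class")], 3)
#>        trait chrom  peak_bp      lod        r2         a class
#> 94 gene00097 chr03 19852771 16.57807 0.3631355 0.7641976   cis
#> 7  gene00007 chr05  6891590 15.91833 0.3865833 0.7815949   cis
#> 73 gene00075 chr03 19404407 15.34688 0.3417780 0.7048385 trans
```

The scan recovers 126 eQTLs for 113 eGenes: all ten planted cis genes are
called with cis records, the planted regulator appears as `hotspot04`
holding 89 trans-eQTLs spanning the planted locus (chr03:20 Mb), and the
top records show the planted effect sizes (r² ≈ 0.35–0.39 against the
planted 0.3, with positive additive effects: the A allele raises
expression). The small two-member hotspots are desk-scale satellites of
scattered trans false positives; at realistic eQTL counts the
`min_members` filter and the 95% threshold suppress them.

A command-line interface wraps the same stages
(`simulate`, `map`, `scan`, `annotate`, `hotspots`, `enrich`, `prioritize`,
`run-all`), each taking `--config <yaml> --seed <int> --out <dir>`:

```sh
Rscript inst/exec/dheqtl simulate --config config.yaml --out fixtures/
Rscript inst/exec/dheqtl run-all  --config config.yaml --out results/
```

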