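# Shared small fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

# hand-built 2-chromosome genotype fixture with known structure
tiny_geno <- function(n = 40, seed = 99) {
  withr::with_seed(seed, {
    markers <- data.frame(
      marker = sprintf("m%02d", 1:6),
      chrom = rep(c("chrA01", "chrC01"), each = 3),
      bp = rep(c(1e6, 5e6, 9e6), 2))
    geno <- matrix(rbinom(6 * n, 1, 0.5), 6, n)
    dh_geno(markers, geno, sprintf("DH%03d", 1:n))
  })
}

# small simulated population shared by several test files
small_pop <- function() memo("small_pop", function() {
  cfg <- sim_config(n_individuals = 120, n_chromosomes = 3,
                    markers_per_chromosome = 20, chromosome_length_bp = 30e6,
                    chromosome_length_cM = 80, n_genes = 40,
                    planted_cis = data.frame(gene = 1:4, r2 = rep(0.3, 4)),
                    hotspot_n_targets = 0, missing_rate = 0.02, seed = 2024)
  c(simulate_population(cfg), list(config = cfg))
})

# synthetic eQTL-like records placed uniformly, matching the RC placement
# mechanics, for enrichment-calibration tests
make_records <- function(n_genes_pool, chrom_sizes, n_egenes = 120, seed = 1) {
  withr::with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes_pool))
    eg <- sample(genes, n_egenes)
    k <- 1 + stats::rpois(n_egenes, 0.5)
    gene <- rep(eg, k)
    total <- length(gene)
    len <- round(stats::rexp(total, 1 / 4e5)) + 5e4
    chrom <- sample(names(chrom_sizes), total, replace = TRUE, prob = chrom_sizes)
    len <- pmin(len, chrom_sizes[chrom] - 1)
    start <- floor(runif(total, 1, chrom_sizes[chrom] - len + 1))
    data.frame(trait = gene, chrom = chrom, peak_bp = start + len %/% 2,
               ci_lo_bp = start, ci_hi_bp = start + len - 1,
               lod = runif(total, 3, 12), r2 = runif(total, 0.05, 0.4),
               class = "trans", eqtl_id = sprintf("eq%05d", seq_len(total)),
               stringsAsFactors = FALSE)
  })
}

# gene table on the same chromosomes
make_genes <- function(n, chrom_sizes, seed = 2, len = 3000) {
  withr::with_seed(seed, {
    chrom <- sample(names(chrom_sizes), n, replace = TRUE, prob = chrom_sizes)
    start <- floor(runif(n, 1, chrom_sizes[chrom] - len))
    data.frame(gene = sprintf("g%04d", seq_len(n)), chrom = chrom,
               start = start, end = start + len - 1, stringsAsFactors = FALSE)
  })
}
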