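no_plant <- function(...) {
  sim_config(..., planted_cis = data.frame(gene = integer(0), r2 = numeric(0)),
             hotspot_n_targets = 0)
}

test_that("simulated maps anchor chromosome ends and are reproducible", {
  cfg <- no_plant(n_chromosomes = 2, markers_per_chromosome = 3,
                  chromosome_length_cM = 100, chromosome_length_bp = 1e7,
                  n_genes = 1, seed = 5)
  map <- simulate_map(cfg)
  expect_equal(nrow(map), 6)
  for (g in 1:2) {
    cm <- map$cm[map$lg == g]
    expect_equal(cm[1], 0)
    expect_equal(cm[3], 100)
    expect_true(cm[2] > 0 && cm[2] < 100)
  }
  expect_identical(as.data.frame(simulate_map(cfg)), as.data.frame(map))
  expect_error(no_plant(chromosome_length_bp = -1, n_genes = 1), "positive")
})

test_that("a 19 x 207-marker, 154-cM-per-chromosome map totals ~2926 cM", {
  cfg <- no_plant(n_chromosomes = 19, markers_per_chromosome = 207,
                  chromosome_length_cM = 154, n_genes = 1, seed = 3)
  map <- simulate_map(cfg)
  expect_equal(total_map_length(map), 19 * 154)  # = 2926, ends anchored
  expect_equal(length(unique(map$lg)), 19)
})

test_that("DH genotypes are two-class, 1:1, with Kosambi-consistent switching", {
  # zero cM gap: columns identical
  map0 <- genetic_map(data.frame(marker = c("a", "b"), lg = 1, cm = c(0, 0),
                                 chrom = "c1", bp = c(1e5, 2e5)))
  cfg <- no_plant(n_individuals = 200, n_genes = 1, missing_rate = 0, seed = 8)
  g0 <- simulate_dh_genotypes(map0, cfg)
  expect_identical(g0$geno[1, ], g0$geno[2, ])
  # no heterozygotes ever
  expect_true(all(g0$geno %in% c(0L, 1L)))

  # r = 0.2 gap: observed discordance 0.2 +/- 0.01 at n = 10,000
  map2 <- genetic_map(data.frame(marker = c("a", "b"), lg = 1,
                                 cm = c(0, kosambi_cm(0.2)),
                                 chrom = "c1", bp = c(1e5, 2e6)))
  cfg2 <- no_plant(n_individuals = 10000, n_genes = 1, missing_rate = 0, seed = 9)
  g2 <- simulate_dh_genotypes(map2, cfg2)
  disc <- mean(g2$geno[1, ] != g2$geno[2, ])
  expect_equal(disc, 0.2, tolerance = 0.01 / 0.2)

  # allele frequency 0.5 within 3 SE at every marker, n = 1,000
  cfg3 <- no_plant(n_individuals = 1000, n_chromosomes = 2,
                   markers_per_chromosome = 15, n_genes = 1,
                   missing_rate = 0, seed = 10)
  g3 <- simulate_dh_genotypes(simulate_map(cfg3), cfg3)
  freq <- rowMeans(g3$geno)
  # per-marker binomial CI, widened to 4 SE for the maximum over 30 markers
  expect_true(all(abs(freq - 0.5) < 4 * sqrt(0.25 / 1000)))
  expect_equal(mean(freq), 0.5, tolerance = 0.02)

  # determinism including missingness pattern
  cfg4 <- no_plant(n_individuals = 50, n_chromosomes = 1,
                   markers_per_chromosome = 10, n_genes = 1,
                   missing_rate = 0.1, seed = 12)
  m <- simulate_map(cfg4)
  expect_identical(simulate_dh_genotypes(m, cfg4)$geno,
                   simulate_dh_genotypes(m, cfg4)$geno)
})

test_that("empirical adjacent r recovers the inverse-Kosambi of the cM gap", {
  cfg <- no_plant(n_individuals = 2000, n_chromosomes = 1,
                  markers_per_chromosome = 8, chromosome_length_cM = 70,
                  n_genes = 1, missing_rate = 0, seed = 21)
  map <- simulate_map(cfg)
  geno <- simulate_dh_genotypes(map, cfg)
  for (j in 1:7) {
    r_true <- inverse_kosambi(map$cm[j + 1] - map$cm[j])
    r_hat <- estimate_r(geno$geno[j, ], geno$geno[j + 1, ])
    se <- sqrt(max(r_true * (1 - r_true), 1e-4) / 2000)
    expect_lt(abs(r_hat - r_true), 4 * se)
  }
})

test_that("expression carries the planted architecture on the analysis scale", {
  # no effects, no noise: constant per gene
  cfg0 <- no_plant(n_individuals = 30, n_chromosomes = 1,
                   markers_per_chromosome = 5, n_genes = 6, noise_sd = 0,
                   missing_rate = 0, seed = 30)
  map <- simulate_map(cfg0)
  geno <- simulate_dh_genotypes(map, cfg0)
  e0 <- simulate_expression(geno, map, cfg0)
  expect_true(all(apply(e0$expr, 1, function(z) diff(range(z))) < 1e-9))
  expect_true(all(e0$expr >= 0))

  # one cis effect with variance fraction 0.5: R^2 ~ 0.5 at n = 1,000
  cfg1 <- sim_config(n_individuals = 1000, n_chromosomes = 1,
                     markers_per_chromosome = 30, chromosome_length_bp = 2e7,
                     n_genes = 5, planted_cis = data.frame(gene = 2, r2 = 0.5),
                     hotspot_n_targets = 0, missing_rate = 0, seed = 31)
  map1 <- simulate_map(cfg1)
  g1 <- simulate_dh_genotypes(map1, cfg1)
  e1 <- simulate_expression(g1, map1, cfg1)
  truth <- attr(e1, "truth")
  gv <- g1$geno[match(truth$causal_marker, g1$markers$marker), ]
  r2 <- cor(log2(e1$expr[2, ] + 1), gv)^2
  expect_equal(r2, 0.5, tolerance = 0.1)

  # hotspot: every target correlated with the regulator-locus genotype
  cfg2 <- sim_config(n_individuals = 1000, n_chromosomes = 2,
                     markers_per_chromosome = 20, chromosome_length_bp = 2e7,
                     n_genes = 25,
                     planted_cis = data.frame(gene = 1, r2 = 0.2),
                     hotspot_locus = list(chrom = "chr02", bp = 1e7),
                     hotspot_n_targets = 20, missing_rate = 0, seed = 32)
  map2 <- simulate_map(cfg2)
  g2 <- simulate_dh_genotypes(map2, cfg2)
  e2 <- simulate_expression(g2, map2, cfg2)
  tr2 <- attr(e2, "truth")
  tgt <- tr2[tr2$type == "trans", ]
  expect_equal(nrow(tgt), 20)
  expect_equal(length(unique(tgt$causal_marker)), 1)  # one shared regulator
  gv2 <- g2$geno[match(tgt$causal_marker[1], g2$markers$marker), ]
  cors <- abs(cor(t(log2(e2$expr[match(tgt$gene, e2$genes$gene), ] + 1)), gv2))
  expect_true(all(cors > 0.15))  # planted r2 >= 0.1 -> |cor| >= ~0.32

  expect_error(
    simulate_expression(g2, map2, sim_config(
      n_genes = 25, planted_trans = data.frame(gene = 1, chrom = "chr09",
                                               bp = 1e6, r2 = 0.2))),
    "bounds|chromosome")
})

test_that("traits share one genetic component across microenvironments", {
  cfg <- sim_config(n_individuals = 400, n_chromosomes = 1,
                    markers_per_chromosome = 10, n_genes = 2,
                    planted_cis = data.frame(gene = 1, r2 = 0.2),
                    hotspot_n_targets = 0,
                    pleiotropic_trait_locus = list(
                      chrom = "chr01", bp = 5e6,
                      effects = c(SOC = 0.4, SLC = -0.4)),
                    noise_sd = 1, missing_rate = 0, seed = 44)
  map <- simulate_map(cfg)
  geno <- simulate_dh_genotypes(map, cfg)
  tt <- simulate_traits(geno, map, cfg)
  truth <- attr(tt, "truth")
  gv <- geno$geno[match(truth$causal_marker[1], geno$markers$marker), ]
  soc1 <- tt$value[tt$trait == "SOC" & tt$microenvironment == "E1"]
  soc2 <- tt$value[tt$trait == "SOC" & tt$microenvironment == "E2"]
  slc1 <- tt$value[tt$trait == "SLC" & tt$microenvironment == "E1"]
  expect_gt(cor(soc1, gv), 0.4)
  expect_gt(cor(soc2, gv), 0.4)   # same genetic component in both environments
  expect_lt(cor(slc1, gv), -0.4)  # negative effect direction

  # zero pleiotropic effect: trait uncorrelated with the locus genotype
  cfg0 <- cfg
  cfg0$pleiotropic_trait_locus$effects <- c(SOC = 0)
  tt0 <- simulate_traits(geno, map, cfg0)
  v0 <- tt0$value[tt0$microenvironment == "E1"]
  expect_lt(abs(cor(v0, gv)), 3 / sqrt(400))
  # determinism
  expect_identical(simulate_traits(geno, map, cfg)$value, tt$value)
})

test_that("interactions and annotations have the declared structure", {
  sizes <- c(chr01 = 1e7, chr02 = 2e7)
  genes <- make_genes(300, sizes, seed = 5)
  pairs <- data.frame(chrom = "chr02", bp = 5e6, gene = genes$gene[1:10])
  ints <- simulate_interactions(genes, sizes, pairs = pairs, n_random = 50,
                                seed = 6)
  expect_s3_class(ints, "interaction_pairs")
  expect_equal(nrow(ints), 60)
  expect_true(all(ints$label %in% c("common", "unique")))
  expect_true(all(ints$end1 <= sizes[ints$chrom1] & ints$start1 >= 1))
  # linked rows span the locus and the target gene
  linked <- ints[51:60, ]
  expect_true(all(linked$chrom1 == "chr02" & linked$start1 <= 5e6 &
                    linked$end1 >= 5e6))
  expect_true(all(linked$chrom2 == genes$chrom[1:10]))
  expect_identical(
    simulate_interactions(genes, sizes, pairs = pairs, n_random = 50, seed = 6),
    ints)

  ann <- simulate_gene_annotations(genes, seed = 7)
  expect_setequal(unique(ann$seq_varied), c("varied", "consistent"))
  expect_setequal(unique(ann$compartment), c("A", "B"))
  # a planted association is detectable
  genes2 <- make_genes(4000, sizes, seed = 8)
  status <- rep(c(TRUE, FALSE), 2000)
  ann2 <- simulate_gene_annotations(genes2, egene = status, assoc = 0.3, seed = 9)
  res <- chi_square_association(status, ann2$seq_varied)
  expect_lt(res$p_value, 1e-6)
})
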