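# single-marker regression LOD, the closed-form oracle
marker_lod <- function(y, g) {
  ok <- !is.na(y) & !is.na(g)
  n <- sum(ok)
  (n / 2) * log10(1 / (1 - cor(y[ok], g[ok])^2))
}

test_that("genotype probabilities are exact at markers and 0.5 when uninformed", {
  g <- tiny_geno(n = 10, seed = 1)
  g$geno[, 1] <- NA  # individual 1 typed nowhere
  g$geno[2, 2] <- NA # individual 2 missing the middle marker of chrA01
  map <- build_map(g)
  pos <- data.frame(lg = 1, cm = map$cm[1:3])
  P <- genotype_probabilities(map, g, pos)
  expect_true(all(P[1, ] == 0.5))
  typed <- !is.na(g$geno[1:3, ])
  expect_equal(unname(P[, 1][typed[1, ]]), unname(as.numeric(g$geno[1, typed[1, ]])))
  # interior probability for flanks A,A at the midpoint of a 20 cM interval
  map2 <- genetic_map(data.frame(marker = c("a", "b"), lg = 1, cm = c(0, 20),
                                 chrom = "c1", bp = c(1, 2e6)))
  g2 <- dh_geno(map2[, c("marker", "chrom", "bp")],
                matrix(c(1L, 1L, 0L, 0L, 1L, 0L), 2, 3), c("i1", "i2", "i3"))
  P2 <- genotype_probabilities(map2, g2, data.frame(lg = 1, cm = 10))
  r <- inverse_kosambi(10)
  expect_equal(unname(P2[1, 1]), (1 - r)^2 / ((1 - r)^2 + r^2))   # A,A
  expect_equal(unname(P2[2, 1]), r^2 / ((1 - r)^2 + r^2))         # B,B
  expect_equal(unname(P2[3, 1]), 0.5)                             # A,B: symmetric
  expect_error(genotype_probabilities(map2, g2, data.frame(lg = 1, cm = 30)),
               "outside")
})

test_that("scan LOD equals the closed-form marker regression at marker positions", {
  withr::with_seed(101, {
    g <- tiny_geno(n = 80, seed = 55)
    map <- build_map(g)
    y <- rnorm(80) + 0.8 * g$geno[4, ]
    names(y) <- g$individuals
    cfg <- scan_config(step_cm = 5, n_permutations = 100)
    sc <- scan_prep(map, g, cfg)
    res <- scan_hk(y, config = cfg, scanner = sc)
    for (j in 1:6) {
      col <- sc$marker_col[j]
      expect_equal(res$table$lod[col], marker_lod(y, g$geno[j, ]),
                   tolerance = 1e-10)
    }
    # r2 at a marker equals the squared correlation
    expect_equal(res$table$r2[sc$marker_col[4]], cor(y, g$geno[4, ])^2,
                 tolerance = 1e-10)
  })
})

test_that("degenerate traits are handled: zero variance warns, perfect fit caps", {
  g <- tiny_geno(n = 50, seed = 2)
  map <- build_map(g)
  cfg <- scan_config(n_permutations = 100)
  sc <- scan_prep(map, g, cfg)
  expect_warning(res <- scan_hk(rep(3, 50), config = cfg, scanner = sc),
                 "zero variance")
  expect_true(all(res$table$lod == 0))
  # trait identical to a marker genotype: LOD hits the ceiling there
  y <- as.numeric(g$geno[1, ])
  res2 <- scan_hk(y, config = cfg, scanner = sc)
  expect_equal(max(res2$table$lod), cfg$lod_ceiling)
  expect_error(scan_hk(c(rep(NA, 45), rnorm(5)), config = cfg, scanner = sc),
               "informative individuals")
})

test_that("permutation thresholds behave as a genome-wide null quantile", {
  withr::with_seed(7, {
    cfg0 <- sim_config(n_individuals = 150, n_chromosomes = 4,
                       markers_per_chromosome = 50, chromosome_length_cM = 250,
                       n_genes = 1, planted_cis = data.frame(gene = 1, r2 = 0.2),
                       hotspot_n_targets = 0, missing_rate = 0, seed = 61)
    map <- simulate_map(cfg0)
    g <- simulate_dh_genotypes(map, cfg0)
    cfg <- scan_config(step_cm = 2, n_permutations = 1000, alpha = 0.05, seed = 3)
    sc <- scan_prep(map, g, cfg)
    y <- rnorm(150)
    th <- permutation_threshold(y, config = cfg, scanner = sc)
    expect_gt(th, 2.5)  # expected envelope for ~200 markers, n = 150
    expect_lt(th, 4.5)
    # invariance to adding a constant
    expect_equal(permutation_threshold(y + 100, config = cfg, scanner = sc), th)
    # constant trait: all-zero null maxima
    expect_equal(suppressWarnings(
      permutation_threshold(rep(1, 150), config = cfg, scanner = sc)), 0)
    # a pure-noise scan stays mostly below threshold
    res <- suppressWarnings(scan_hk(y, config = cfg, scanner = sc))
    expect_lt(max(res$table$lod), 4.5)
  })
})

test_that("cofactor selection is deterministic, bounded and signal-seeking", {
  pop <- small_pop()
  cfg <- scan_config(n_permutations = 100, max_cofactors = 5)
  sc <- scan_prep(pop$map, pop$genotypes, cfg)
  truth <- pop$truth$expression
  y <- log2(pop$expression$expr[1, ] + 1)  # gene 1 has a planted cis eQTL
  cof <- select_cofactors(y, config = cfg, scanner = sc)
  expect_gt(length(cof), 0)
  first <- pop$map[pop$map$marker == cof[1], ]
  expect_equal(first$chrom, truth$causal_chrom[1])
  expect_lt(abs(first$bp - truth$causal_bp[1]), 3e6)
  expect_lte(length(cof), 5)
  # max_cofactors = 0 degenerates to simple interval mapping
  cfg0 <- scan_config(n_permutations = 100, max_cofactors = 0)
  expect_identical(select_cofactors(y, config = cfg0, scanner = sc), character(0))
  # null trait at strict entry alpha: no cofactors
  withr::with_seed(77, {
    cfgs <- scan_config(n_permutations = 100, entry_alpha = 0.001)
    expect_identical(select_cofactors(rnorm(120), config = cfgs, scanner = sc),
                     character(0))
  })
})

test_that("QTL calling separates peaks and brackets the causal locus", {
  cfg0 <- sim_config(n_individuals = 200, n_chromosomes = 1,
                     markers_per_chromosome = 40, chromosome_length_cM = 120,
                     chromosome_length_bp = 4e7, n_genes = 1,
                     planted_cis = data.frame(gene = 1, r2 = 0.2),
                     hotspot_n_targets = 0, missing_rate = 0, seed = 71)
  map <- simulate_map(cfg0)
  g <- simulate_dh_genotypes(map, cfg0)
  cfg <- scan_config(step_cm = 2, n_permutations = 100)
  sc <- scan_prep(map, g, cfg)
  # two planted QTLs ~60 cM apart on one chromosome
  i1 <- which.min(abs(map$cm - 20))
  i2 <- which.min(abs(map$cm - 80))
  withr::with_seed(72, {
    y <- rnorm(200) + 1.2 * g$geno[i1, ] + 1.2 * g$geno[i2, ]
  })
  # the CIM scan: cofactors absorb the other QTL and suppress ghost peaks
  cof <- select_cofactors(y, config = cfg, scanner = sc)
  res <- scan_hk(y, config = cfg, cofactors = cof, scanner = sc)
  recs <- call_qtls(res, threshold = 3, cfg)
  expect_equal(nrow(recs), 2)
  expect_true(all(recs$ci_lo_cm <= recs$peak_cm & recs$peak_cm <= recs$ci_hi_cm))
  # each planted locus is near one called peak
  expect_lt(min(abs(recs$peak_cm - map$cm[i1])), 8)
  expect_lt(min(abs(recs$peak_cm - map$cm[i2])), 8)
  expect_true(all(recs$lod >= 3))
  # the cofactor-free scan of a single strong QTL covers the true locus
  y1 <- withr::with_seed(73, rnorm(200) + 1.2 * g$geno[i1, ])
  recs1 <- call_qtls(scan_hk(y1, config = cfg, scanner = sc), threshold = 3, cfg)
  expect_equal(nrow(recs1), 1)
  expect_true(recs1$ci_lo_bp <= map$bp[i1] && map$bp[i1] <= recs1$ci_hi_bp)
  # profile entirely below threshold: no records
  expect_equal(nrow(call_qtls(res, threshold = 1e6, cfg)), 0)
})

test_that("peak LOD is monotone in the planted effect size (same noise draw)", {
  g <- tiny_geno(n = 100, seed = 13)
  map <- build_map(g)
  cfg <- scan_config(n_permutations = 100)
  sc <- scan_prep(map, g, cfg)
  noise <- withr::with_seed(14, rnorm(100))
  causal_col <- sc$marker_col[3]
  peak <- vapply(seq(0.5, 2.5, by = 0.25), function(beta) {
    res <- scan_hk(noise + beta * g$geno[3, ], config = cfg, scanner = sc)
    res$table$lod[causal_col]
  }, 0)
  expect_true(all(diff(peak) >= -1e-9))
})

test_that("planted additive effect is recovered with small bias", {
  cfg0 <- sim_config(n_individuals = 150, n_chromosomes = 1,
                     markers_per_chromosome = 30, chromosome_length_cM = 90,
                     n_genes = 1, planted_cis = data.frame(gene = 1, r2 = 0.2),
                     hotspot_n_targets = 0, missing_rate = 0.02, seed = 81)
  map <- simulate_map(cfg0)
  g <- simulate_dh_genotypes(map, cfg0)
  cfg <- scan_config(step_cm = 3, n_permutations = 100)
  sc <- scan_prep(map, g, cfg)
  mk <- 15
  beta <- 2 * sqrt(0.3 / 0.7)  # variance fraction 0.3, noise sd 1
  gv <- g$geno[mk, ]
  gv[is.na(gv)] <- withr::with_seed(82, rbinom(sum(is.na(gv)), 1, 0.5))
  a_hat <- withr::with_seed(83, vapply(1:200, function(i) {
    y <- rnorm(150) + beta * gv
    res <- scan_hk(y, config = cfg, scanner = sc)
    res$table$a[which.max(res$table$lod)]
  }, 0))
  expect_lt(abs(mean(a_hat) - beta / 2) / (beta / 2), 0.1)
})

test_that("scan_all is order-invariant, filters unexpressed genes, checks ids", {
  pop <- small_pop()
  cfg <- scan_config(step_cm = 4, n_permutations = 100, seed = 5)
  es <- scan_all(pop$expression, pop$map, pop$genotypes, cfg)
  expect_gt(nrow(es$records), 0)
  # shuffled gene order yields the identical record set
  ex <- pop$expression
  o <- withr::with_seed(6, sample(nrow(ex$genes)))
  shuf <- expr_set(ex$genes[o, ], ex$expr[o, , drop = FALSE], ex$individuals)
  es2 <- scan_all(shuf, pop$map, pop$genotypes, cfg)
  key <- function(r) {
    d <- r[order(r$trait, r$lg, r$peak_cm), setdiff(names(r), "eqtl_id")]
    rownames(d) <- NULL
    d
  }
  expect_equal(key(es2$records), key(es$records))

  # empty matrix: empty records
  e0 <- expr_set(ex$genes[0, ], ex$expr[0, , drop = FALSE], ex$individuals)
  expect_equal(nrow(scan_all(e0, pop$map, pop$genotypes, cfg)$records), 0)

  # an unexpressed gene is filtered, not scanned
  ex2 <- ex
  ex2$expr[5, ] <- 0
  es3 <- scan_all(ex2, pop$map, pop$genotypes, cfg)
  expect_false(ex$genes$gene[5] %in% es3$thresholds$trait)

  bad <- expr_set(ex$genes, ex$expr,
                  individuals = paste0("x", seq_along(ex$individuals)))
  expect_error(scan_all(bad, pop$map, pop$genotypes, cfg), "individual ids")
})
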