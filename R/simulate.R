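#' Simulation configuration for a synthetic DH population
#'
#' The defaults emulate the study design the pipeline targets: a biparental
#' doubled-haploid population of 156 lines genotyped at ~4,000 binned markers
#' on 19 chromosomes (A01-A10, C01-C09) spanning ~2,933 cM, with tens of
#' thousands of expression traits carrying planted cis effects, a
#' master-regulator trans hotspot near the end of chrA09, and seed-quality
#' style traits (SOC/SCC/SLC-like) driven by a pleiotropic locus at the
#' hotspot, measured in two microenvironments.
#'
#' Planted effect sizes are expressed as the fraction of trait variance
#' explained at infinite sample size; loci are placed at the marker nearest
#' the requested bp.
#'
#' @param n_individuals number of DH lines (default 156)
#' @param n_chromosomes number of chromosomes (default 19)
#' @param markers_per_chromosome markers per chromosome (default 211)
#' @param chromosome_length_bp physical length per chromosome (default 45 Mb)
#' @param chromosome_length_cM genetic length per chromosome (default 154.37)
#' @param n_genes number of expression traits (default 20000)
#' @param planted_cis data.frame(gene, r2): gene indices receiving a cis
#'   effect and the variance fraction; `NULL` plants 5% of genes with r2
#'   uniform on (0.05, 0.35)
#' @param planted_trans data.frame(gene, chrom, bp, r2): trans effects from
#'   the stated regulator locus; `NULL` plants `hotspot_n_targets` targets at
#'   `hotspot_locus`
#' @param hotspot_locus list(chrom, bp): the master-regulator locus (default
#'   chrA09 at 42 Mb)
#' @param hotspot_n_targets number of trans targets of the hotspot regulator
#'   (default 300)
#' @param pleiotropic_trait_locus list(chrom, bp, effects) where `effects` is
#'   a named vector of per-trait variance fractions (sign = direction of the
#'   A-allele effect)
#' @param n_microenvironments number of microenvironments for traits
#' @param noise_sd residual SD on the analysis (log2) scale (default 1)
#' @param missing_rate genotype missingness fraction (default 0.02)
#' @param gene_length_bp gene body length (default 3000)
#' @param seed integer seed; fully determines all simulated outputs
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_individuals = 156,
                       n_chromosomes = 19,
                       markers_per_chromosome = 211,
                       chromosome_length_bp = 45e6,
                       chromosome_length_cM = 154.37,
                       n_genes = 20000,
                       planted_cis = NULL,
                       planted_trans = NULL,
                       hotspot_locus = list(chrom = NULL, bp = 42e6),
                       hotspot_n_targets = 300,
                       pleiotropic_trait_locus = NULL,
                       n_microenvironments = 2,
                       noise_sd = 1,
                       missing_rate = 0.02,
                       gene_length_bp = 3000,
                       seed = 1L) {
  n_individuals <- as.numeric(n_individuals)
  n_chromosomes <- as.numeric(n_chromosomes)
  markers_per_chromosome <- as.numeric(markers_per_chromosome)
  chromosome_length_bp <- as.numeric(chromosome_length_bp)
  chromosome_length_cM <- as.numeric(chromosome_length_cM)
  n_genes <- as.numeric(n_genes)
  noise_sd <- as.numeric(noise_sd)
  missing_rate <- as.numeric(missing_rate)
  if (!is.null(hotspot_locus$bp)) hotspot_locus$bp <- as.numeric(hotspot_locus$bp)
  if (chromosome_length_bp <= 0 || chromosome_length_cM <= 0)
    .stopf("chromosome lengths must be positive")
  if (missing_rate < 0 || missing_rate >= 1) .stopf("missing_rate must be in [0, 1)")
  chroms <- if (n_chromosomes == 19)
    c(sprintf("chrA%02d", 1:10), sprintf("chrC%02d", 1:9))
  else sprintf("chr%02d", seq_len(n_chromosomes))
  if (is.null(hotspot_locus$chrom))
    hotspot_locus$chrom <- if (n_chromosomes == 19) "chrA09" else chroms[length(chroms)]
  hotspot_locus$bp <- min(hotspot_locus$bp, chromosome_length_bp)
  if (is.null(planted_cis)) {
    n_cis <- max(1L, round(0.05 * n_genes))
    planted_cis <- withr::with_seed(seed + 11L, data.frame(
      gene = sample.int(n_genes, n_cis),
      r2 = runif(n_cis, 0.05, 0.35)))
  }
  if (is.null(planted_trans) && hotspot_n_targets > 0) {
    pool <- setdiff(seq_len(n_genes), planted_cis$gene)
    tgt <- withr::with_seed(seed + 13L,
                            sample(pool, min(hotspot_n_targets, length(pool))))
    planted_trans <- withr::with_seed(seed + 17L, data.frame(
      gene = tgt, chrom = hotspot_locus$chrom, bp = hotspot_locus$bp,
      r2 = runif(length(tgt), 0.1, 0.3)))
  }
  if (is.null(pleiotropic_trait_locus))
    pleiotropic_trait_locus <- list(chrom = hotspot_locus$chrom,
                                    bp = hotspot_locus$bp,
                                    effects = c(SOC = 0.4, SCC = 0.4, SLC = -0.4))
  for (df in list(planted_cis, planted_trans)) {
    if (!is.null(df) && nrow(df)) {
      if (any(df$gene < 1 | df$gene > n_genes)) .stopf("planted gene index out of range")
      if (any(abs(df$r2) <= 0 | abs(df$r2) >= 1)) .stopf("effect-size fractions must lie in (0, 1)")
    }
  }
  if (!is.null(planted_trans) && nrow(planted_trans)) {
    if (!all(planted_trans$chrom %in% chroms) || any(planted_trans$bp > chromosome_length_bp))
      .stopf("planted trans locus outside chromosome bounds")
  }
  structure(list(n_individuals = n_individuals, n_chromosomes = n_chromosomes,
                 markers_per_chromosome = markers_per_chromosome,
                 chromosome_length_bp = chromosome_length_bp,
                 chromosome_length_cM = chromosome_length_cM,
                 n_genes = n_genes, planted_cis = planted_cis,
                 planted_trans = planted_trans, hotspot_locus = hotspot_locus,
                 pleiotropic_trait_locus = pleiotropic_trait_locus,
                 n_microenvironments = n_microenvironments,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 gene_length_bp = gene_length_bp, chroms = chroms,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genetic map
#'
#' Markers are placed uniformly at random along each chromosome (first marker
#' at bp 1, last at the chromosome end) and cM positions are assigned by a
#' linear monotone bp -> cM scaling anchored at 0 for the first marker and at
#' `chromosome_length_cM` for the last.
#'
#' @param config a [sim_config()]
#' @return a [genetic_map()]
#' @export
simulate_map <- function(config) {
  withr::with_seed(config$seed + 1L, {
    out <- vector("list", config$n_chromosomes)
    for (ci in seq_len(config$n_chromosomes)) {
      k <- config$markers_per_chromosome
      bp <- if (k <= 2) c(1, config$chromosome_length_bp)[seq_len(k)]
      else sort(c(1, round(runif(k - 2, 2, config$chromosome_length_bp - 1)),
                  config$chromosome_length_bp))
      bp <- bp + cumsum(c(0, diff(bp) == 0))  # de-duplicate collisions
      cm <- (bp - bp[1]) / (bp[length(bp)] - bp[1]) * config$chromosome_length_cM
      out[[ci]] <- data.frame(
        marker = sprintf("%s_m%04d", config$chroms[ci], seq_len(k)),
        lg = ci, cm = cm, chrom = config$chroms[ci], bp = bp,
        stringsAsFactors = FALSE)
    }
    genetic_map(do.call(rbind, out))
  })
}

#' Simulate DH genotypes along a map
#'
#' Each individual is one recombinant gamete: the genotype at the first
#' marker of a linkage group is A or B with probability 1/2, and between
#' adjacent markers the genotype switches with the Kosambi-implied
#' recombination fraction of the cM gap, independently across intervals and
#' individuals (no residual interference). Missing values are inserted
#' uniformly at random at `missing_rate`.
#'
#' @param map a [genetic_map()]
#' @param config a [sim_config()]
#' @return a [dh_geno()]
#' @export
simulate_dh_genotypes <- function(map, config) {
  stopifnot(nrow(map) > 0)
  n <- config$n_individuals
  withr::with_seed(config$seed + 2L, {
    geno <- matrix(NA_integer_, nrow(map), n)
    for (g in unique(map$lg)) {
      idx <- which(map$lg == g)
      r <- inverse_kosambi(diff(map$cm[idx]))
      G <- matrix(0L, length(idx), n)
      G[1, ] <- rbinom(n, 1, 0.5)
      if (length(idx) > 1) {
        sw <- matrix(rbinom((length(idx) - 1) * n, 1, rep(r, n)),
                     length(idx) - 1, n)
        cs <- apply(sw, 2, cumsum)
        if (is.null(dim(cs))) cs <- matrix(cs, 1, n)
        G[-1, ] <- (matrix(G[1, ], length(idx) - 1, n, byrow = TRUE) + cs) %% 2L
      }
      geno[idx, ] <- G
    }
    if (config$missing_rate > 0)
      geno[runif(length(geno)) < config$missing_rate] <- NA_integer_
    dh_geno(map[, c("marker", "chrom", "bp")], geno,
            sprintf("DH%04d", seq_len(n)))
  })
}

# index of the map marker nearest a (chrom, bp) locus
.nearest_marker <- function(map, chrom, bp) {
  idx <- which(map$chrom == chrom)
  if (!length(idx)) .stopf("no marker on chromosome %s", chrom)
  idx[which.min(abs(map$bp[idx] - bp))]
}

# imputed 0/1 genotype at a marker (missing -> random A/B, keeps 1:1)
.complete_geno <- function(geno_row) {
  miss <- is.na(geno_row)
  if (any(miss)) geno_row[miss] <- rbinom(sum(miss), 1, 0.5)
  geno_row
}

# effect coefficient giving variance fraction f against noise_sd, with a
# 0/1 genotype of variance 1/4 under 1:1 segregation
.effect_beta <- function(f, noise_sd) sign(f) * 2 * noise_sd * sqrt(abs(f) / (1 - abs(f)))

#' Simulate an expression matrix with planted eQTL architecture
#'
#' Each gene's expression is generated on the analysis (log2) scale as
#' baseline + sum of planted genotype effects + Gaussian noise, then mapped
#' to the FPKM-like scale as `2^z - 1` (clamped non-negative), so that the
#' default `log2(x + 1)` transform of the scan recovers the planted additive
#' model exactly. cis-planted genes have their causal locus at the marker
#' nearest their own position; trans-planted genes take theirs from the
#' stated regulator locus.
#'
#' @param genotypes a [dh_geno()]
#' @param map a [genetic_map()]
#' @param config a [sim_config()]
#' @return an [expr_set()]; the planted truth table (gene, type, causal
#'   marker/chrom/bp, r2) is attached as attribute `"truth"`
#' @export
simulate_expression <- function(genotypes, map, config) {
  n <- length(genotypes$individuals)
  ng <- config$n_genes
  withr::with_seed(config$seed + 3L, {
    chrom <- sample(config$chroms, ng, replace = TRUE)
    start <- round(runif(ng, 1, config$chromosome_length_bp - config$gene_length_bp))
    genes <- data.frame(gene = sprintf("gene%05d", seq_len(ng)), chrom = chrom,
                        start = start, end = start + config$gene_length_bp - 1,
                        stringsAsFactors = FALSE)
    baseline <- runif(ng, 3, 8)
    z <- matrix(rnorm(ng * n, 0, config$noise_sd), ng, n) + baseline
    truth <- NULL
    plant <- function(df, type) {
      if (is.null(df) || !nrow(df)) return(NULL)
      rows <- lapply(seq_len(nrow(df)), function(i) {
        gi <- df$gene[i]
        mi <- if (type == "cis") .nearest_marker(map, genes$chrom[gi], genes$start[gi])
        else .nearest_marker(map, df$chrom[i], df$bp[i])
        gmk <- match(map$marker[mi], genotypes$markers$marker)
        gvec <- .complete_geno(genotypes$geno[gmk, ])
        z[gi, ] <<- z[gi, ] + .effect_beta(df$r2[i], config$noise_sd) * gvec
        data.frame(gene = genes$gene[gi], type = type,
                   causal_marker = map$marker[mi], causal_chrom = map$chrom[mi],
                   causal_bp = map$bp[mi], r2 = df$r2[i], stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
    truth <- rbind(plant(config$planted_cis, "cis"),
                   plant(config$planted_trans, "trans"))
    expr <- pmax(2^pmax(z, 0) - 1, 0)
    out <- expr_set(genes, expr, genotypes$individuals)
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate phenotypic traits across microenvironments
#'
#' Every trait shares one genetic component, the pleiotropic-locus effect
#' (identical across microenvironments); each microenvironment adds its own
#' offset and independent Gaussian noise.
#'
#' @param genotypes a [dh_geno()]
#' @param map a [genetic_map()]
#' @param config a [sim_config()]
#' @return a [trait_table()]
#' @export
simulate_traits <- function(genotypes, map, config) {
  loc <- config$pleiotropic_trait_locus
  effects <- loc$effects
  withr::with_seed(config$seed + 4L, {
    mi <- .nearest_marker(map, loc$chrom, loc$bp)
    gmk <- match(map$marker[mi], genotypes$markers$marker)
    gvec <- .complete_geno(genotypes$geno[gmk, ])
    n <- length(gvec)
    rows <- list()
    for (ti in seq_along(effects)) {
      genetic <- .effect_beta(effects[ti], config$noise_sd) * gvec
      for (e in seq_len(config$n_microenvironments)) {
        env <- sprintf("E%d", e)
        val <- genetic + rnorm(1, 0, 2) + rnorm(n, 0, config$noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          individual = genotypes$individuals, microenvironment = env,
          trait = names(effects)[ti], value = val, stringsAsFactors = FALSE)
      }
    }
    out <- trait_table(do.call(rbind, rows))
    attr(out, "truth") <- data.frame(trait = names(effects),
                                     causal_marker = map$marker[mi],
                                     causal_chrom = map$chrom[mi],
                                     causal_bp = map$bp[mi], r2 = unname(effects))
    out
  })
}

#' Simulate 3D-genome interaction anchor pairs
#'
#' Generates `n_random` pairs of anchors placed uniformly at random, plus one
#' "linked" pair per row of `pairs`, whose first anchor spans a planted
#' eQTL locus and whose second anchor spans the target gene body. Labels
#' (common / unique parental set) are assigned at random in the given
#' proportion.
#'
#' @param genes gene table (`gene`, `chrom`, `start`, `end`)
#' @param chrom_sizes named vector of chromosome sizes (bp)
#' @param pairs optional data.frame(chrom, bp, gene) of planted
#'   (locus, target gene) pairs to span
#' @param n_random number of random anchor pairs (default 200)
#' @param anchor_bp anchor width (default 20 kb)
#' @param prop_common fraction labelled "common" (default 0.5)
#' @param seed integer seed
#' @return an [interaction_pairs()] table (1-based closed coordinates)
#' @export
simulate_interactions <- function(genes, chrom_sizes, pairs = NULL,
                                  n_random = 200, anchor_bp = 2e4,
                                  prop_common = 0.5, seed = 1L) {
  withr::with_seed(seed, {
    mk_anchor <- function(chrom, center) {
      s <- pmax(1, round(center - anchor_bp / 2))
      data.frame(chrom = chrom, start = s,
                 end = pmin(s + anchor_bp - 1, chrom_sizes[chrom]))
    }
    out <- list()
    if (n_random > 0) {
      cs <- names(chrom_sizes)
      c1 <- sample(cs, n_random, replace = TRUE, prob = chrom_sizes)
      c2 <- sample(cs, n_random, replace = TRUE, prob = chrom_sizes)
      a1 <- mk_anchor(c1, runif(n_random, 1, chrom_sizes[c1]))
      a2 <- mk_anchor(c2, runif(n_random, 1, chrom_sizes[c2]))
      out$random <- data.frame(chrom1 = a1$chrom, start1 = a1$start, end1 = a1$end,
                               chrom2 = a2$chrom, start2 = a2$start, end2 = a2$end)
    }
    if (!is.null(pairs) && nrow(pairs)) {
      gi <- match(pairs$gene, genes$gene)
      if (anyNA(gi)) .stopf("linked pair references unknown gene")
      a1 <- mk_anchor(pairs$chrom, pairs$bp)
      a2 <- mk_anchor(genes$chrom[gi], (genes$start[gi] + genes$end[gi]) / 2)
      out$linked <- data.frame(chrom1 = a1$chrom, start1 = a1$start, end1 = a1$end,
                               chrom2 = a2$chrom, start2 = a2$start, end2 = a2$end)
    }
    df <- do.call(rbind, out)
    if (is.null(df) || !nrow(df)) .stopf("no interactions generated")
    df$label <- ifelse(runif(nrow(df)) < prop_common, "common", "unique")
    rownames(df) <- NULL
    interaction_pairs(df)
  })
}

#' Simulate per-gene binary annotations
#'
#' Draws a sequence-variation flag and an A/B chromatin-compartment class per
#' gene. When an eGene status vector and a non-zero `assoc` are supplied, the
#' probability of carrying the annotation is shifted by `assoc` for eGenes,
#' creating a planted association that the chi-square test should detect.
#'
#' @param genes gene table
#' @param egene optional logical vector (is the gene an eGene), length
#'   `nrow(genes)`
#' @param assoc probability shift added for eGenes (default 0 = independent)
#' @param base_rate baseline annotation probability (default 0.4)
#' @param seed integer seed
#' @return data.frame(gene, seq_varied, compartment)
#' @export
simulate_gene_annotations <- function(genes, egene = NULL, assoc = 0,
                                      base_rate = 0.4, seed = 1L) {
  withr::with_seed(seed, {
    p <- rep(base_rate, nrow(genes))
    if (!is.null(egene)) p <- pmin(pmax(p + assoc * egene, 0.01), 0.99)
    data.frame(gene = genes$gene,
               seq_varied = ifelse(runif(nrow(genes)) < p, "varied", "consistent"),
               compartment = ifelse(runif(nrow(genes)) < p, "A", "B"),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete synthetic population
#'
#' Convenience wrapper chaining [simulate_map()], [simulate_dh_genotypes()],
#' [simulate_expression()] and [simulate_traits()].
#'
#' @param config a [sim_config()]
#' @return list with `map`, `genotypes`, `expression`, `traits`, `truth`
#' @export
simulate_population <- function(config) {
  map <- simulate_map(config)
  geno <- simulate_dh_genotypes(map, config)
  expr <- simulate_expression(geno, map, config)
  traits <- simulate_traits(geno, map, config)
  list(map = map, genotypes = geno, expression = expr, traits = traits,
       truth = list(expression = attr(expr, "truth"),
                    traits = attr(traits, "truth")))
}
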