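#' Scan configuration
#'
#' Tuning parameters for the composite-interval-mapping LOD scan. Defaults:
#' genome-wide significance 0.05 from 1000 permutations of the trait; forward
#' selection of at most 5 cofactor markers at entry alpha 0.01, cofactors
#' within 10 cM of the test position dropped; 1.5-LOD support intervals; a
#' LOD ceiling of 50 on numerically perfect fits; expression transformed as
#' log2(x + 1) and genes expressed (non-zero) in fewer than 10% of lines
#' skipped.
#'
#' @param step_cm evaluation grid step in cM (marker positions are always
#'   included)
#' @param n_permutations permutations for the genome-wide threshold
#' @param alpha genome-wide significance level
#' @param max_cofactors maximum number of CIM cofactor markers
#' @param cofactor_window_cm exclusion window around the test position
#' @param entry_alpha partial-F entry threshold for cofactor selection
#' @param lod_drop LOD drop defining the support interval
#' @param lod_ceiling cap applied to the LOD on (near-)perfect fits
#' @param transform expression transform, `"log2"` (log2(x+1)) or `"none"`
#' @param min_expressed_fraction minimum fraction of lines with non-zero
#'   expression for a gene to be scanned
#' @param min_individuals minimum informative individuals per trait
#' @param seed integer seed for the permutation null
#' @return list of class `scan_config`
#' @export
scan_config <- function(step_cm = 2, n_permutations = 1000, alpha = 0.05,
                        max_cofactors = 5, cofactor_window_cm = 10,
                        entry_alpha = 0.01, lod_drop = 1.5, lod_ceiling = 50,
                        transform = c("log2", "none"),
                        min_expressed_fraction = 0.1, min_individuals = 20,
                        seed = 1L) {
  stopifnot(step_cm > 0, n_permutations >= 100, alpha > 0, alpha < 1,
            max_cofactors >= 0, lod_drop > 0)
  structure(list(step_cm = step_cm, n_permutations = as.integer(n_permutations),
                 alpha = alpha, max_cofactors = as.integer(max_cofactors),
                 cofactor_window_cm = cofactor_window_cm,
                 entry_alpha = entry_alpha, lod_drop = lod_drop,
                 lod_ceiling = lod_ceiling, transform = match.arg(transform),
                 min_expressed_fraction = min_expressed_fraction,
                 min_individuals = as.integer(min_individuals),
                 seed = as.integer(seed)),
            class = "scan_config")
}

# evaluation grid: union of marker positions and a regular cM lattice, with
# bp linearly interpolated between flanking markers
scan_grid <- function(map, step_cm) {
  out <- lapply(unique(map$lg), function(g) {
    mk <- map[map$lg == g, ]
    cm <- sort(unique(c(mk$cm, seq(0, max(mk$cm), by = step_cm))))
    keep <- !duplicated(mk$cm)
    bp <- if (sum(keep) > 1)
      approx(mk$cm[keep], mk$bp[keep], xout = cm, rule = 2)$y
    else rep(mk$bp[1], length(cm))
    data.frame(lg = g, cm = cm, chrom = mk$chrom[1], bp = round(bp))
  })
  grid <- do.call(rbind, out)
  rownames(grid) <- NULL
  grid
}

#' Conditional probability of the A genotype along the genome
#'
#' For every individual and every queried position, the probability of
#' carrying the A allele given the nearest non-missing flanking markers, with
#' inter-locus recombination fractions from [inverse_kosambi()]. At an
#' observed marker the probability is exactly 0 or 1; with no informative
#' flank on either side it is the DH prior 0.5.
#'
#' @param map a [genetic_map()]
#' @param genotypes a [dh_geno()] with the map's markers
#' @param positions data.frame with columns `lg`, `cm` (one row per queried
#'   position)
#' @return numeric matrix, individuals x positions, of P(A)
#' @export
genotype_probabilities <- function(map, genotypes, positions) {
  idx <- match(map$marker, genotypes$markers$marker)
  if (anyNA(idx)) .stopf("map markers missing from genotype matrix")
  G <- genotypes$geno[idx, , drop = FALSE]
  n <- ncol(G)
  P <- matrix(0.5, n, nrow(positions))
  for (g in unique(positions$lg)) {
    mrows <- which(map$lg == g)
    gcols <- which(positions$lg == g)
    cmm <- map$cm[mrows]
    cmq <- positions$cm[gcols]
    if (any(cmq < min(cmm) - 1e-9 | cmq > max(cmm) + 1e-9))
      .stopf("queried position outside the cM range of group %s", g)
    Glg <- G[mrows, , drop = FALSE]
    for (i in seq_len(n)) {
      obs <- which(!is.na(Glg[, i]))
      if (!length(obs)) next
      gv <- Glg[obs, i]
      cmo <- cmm[obs]
      li <- findInterval(cmq, cmo)
      K <- length(obs)
      hasL <- li >= 1L
      hasR <- li < K
      lidx <- pmax(li, 1L)
      ridx <- pmin(li + 1L, K)
      r1 <- inverse_kosambi(pmax(cmq - cmo[lidx], 0))
      r2 <- inverse_kosambi(pmax(cmo[ridx] - cmq, 0))
      t1 <- ifelse(gv[lidx] == 1L, 1 - r1, r1)
      t2 <- ifelse(gv[ridx] == 1L, 1 - r2, r2)
      u1 <- 1 - t1
      u2 <- 1 - t2
      p <- rep(0.5, length(cmq))
      b <- hasL & hasR
      den <- t1 * t2 + u1 * u2
      p[b] <- ifelse(den[b] > 0, (t1 * t2)[b] / den[b], 0.5)
      p[hasL & !hasR] <- t1[hasL & !hasR]
      p[!hasL & hasR] <- t2[!hasL & hasR]
      P[i, gcols] <- p
    }
  }
  dimnames(P) <- list(genotypes$individuals, NULL)
  P
}

#' Precompute the scan machinery for a dataset
#'
#' Builds the evaluation grid and the individuals x positions P(A) matrix
#' once, so that many traits can be scanned against the same genome.
#'
#' @param map a [genetic_map()]
#' @param genotypes a [dh_geno()]
#' @param config a [scan_config()]
#' @return list of class `scanner` with elements `grid`, `P`, `marker_col`
#'   (grid column of every map marker), `map`
#' @export
scan_prep <- function(map, genotypes, config = scan_config()) {
  grid <- scan_grid(map, config$step_cm)
  P <- genotype_probabilities(map, genotypes, grid)
  key_g <- paste(grid$lg, round(grid$cm, 9))
  marker_col <- match(paste(map$lg, round(map$cm, 9)), key_g)
  structure(list(grid = grid, P = P, marker_col = marker_col, map = map),
            class = "scanner")
}

# core Haley-Knott LOD profile; y complete (no NA), P already subset to the
# same individuals. cof_cols are columns of P used as cofactors.
.hk_lod <- function(y, P, grid, config, cof_cols = integer()) {
  n <- length(y)
  m <- nrow(grid)
  if (var(y) == 0) {
    warning("trait has zero variance; returning an all-zero LOD profile", call. = FALSE)
    return(numeric(m))
  }
  lod <- numeric(m)
  if (length(cof_cols)) {
    cof_lg <- grid$lg[cof_cols]
    cof_cm <- grid$cm[cof_cols]
    drop_mat <- vapply(seq_along(cof_cols), function(j)
      grid$lg == cof_lg[j] & abs(grid$cm - cof_cm[j]) < config$cofactor_window_cm,
      logical(m))
    key <- apply(drop_mat, 1, function(z) paste(which(z), collapse = ","))
  } else key <- rep("", m)
  for (k in unique(key)) {
    cols <- which(key == k)
    dropped <- if (nzchar(k)) as.integer(strsplit(k, ",")[[1]]) else integer(0)
    keep_cof <- setdiff(seq_along(cof_cols), dropped)
    X <- cbind(rep(1, n), P[, cof_cols[keep_cof], drop = FALSE])
    qx <- qr(X)
    yr <- qr.resid(qx, y)
    rss0 <- sum(yr^2)
    Pr <- qr.resid(qx, P[, cols, drop = FALSE])
    den <- colSums(Pr^2)
    num <- colSums(Pr * yr)^2
    rss1 <- rss0 - ifelse(den > 1e-12, num / pmax(den, 1e-12), 0)
    rss1 <- pmax(rss1, rss0 * 1e-300)
    lod[cols] <- pmin((n / 2) * log10(rss0 / rss1), config$lod_ceiling)
  }
  pmax(lod, 0)
}

# per-position single-QTL r2 and additive effect (no cofactors)
.single_qtl_stats <- function(y, P) {
  n <- length(y)
  yc <- y - mean(y)
  ssy <- sum(yc^2)
  Pc <- sweep(P, 2, colMeans(P))
  den <- colSums(Pc^2)
  num <- colSums(Pc * yc)^2
  r2 <- ifelse(den > 1e-12 & ssy > 0, num / (den * ssy), 0)
  A <- P >= 0.5
  cA <- colSums(A)
  sA <- colSums(A * y)
  a <- ifelse(cA > 0 & cA < n, (sA / cA - (sum(y) - sA) / (n - cA)) / 2, NA_real_)
  list(r2 = pmin(r2, 1), a = a)
}

#' Haley-Knott interval-mapping scan of one trait
#'
#' At every grid position the LOD is (n/2) log10(RSS0 / RSS1), with RSS1 from
#' regressing the trait on P(A) (plus any admitted cofactor markers, those
#' within `cofactor_window_cm` of the test position excluded) and RSS0 from
#' the same model without P(A). Individuals with a missing trait value are
#' dropped. Per-position single-QTL explained variance and additive effect
#' (positive = A allele increases the value) are computed alongside.
#'
#' @param trait named numeric vector of trait values (names = individual ids)
#'   or unnamed vector aligned with the genotype individuals
#' @param map a [genetic_map()]
#' @param genotypes a [dh_geno()]
#' @param config a [scan_config()]
#' @param cofactors character vector of cofactor marker ids (or NULL)
#' @param scanner optional precomputed [scan_prep()] object
#' @param trait_id identifier stored in the result
#' @return list of class `scan_result`: `trait`, `table` (lg, cm, chrom, bp,
#'   lod, r2, a), `cofactors`, `n`
#' @export
scan_hk <- function(trait, map, genotypes, config = scan_config(),
                    cofactors = NULL, scanner = NULL, trait_id = "trait") {
  if (is.null(scanner)) scanner <- scan_prep(map, genotypes, config)
  y <- .align_trait(trait, rownames(scanner$P))
  cc <- which(!is.na(y))
  if (length(cc) < config$min_individuals)
    .stopf("trait '%s': only %d informative individuals (need >= %d)",
           trait_id, length(cc), config$min_individuals)
  yv <- y[cc]
  P <- scanner$P[cc, , drop = FALSE]
  cof_cols <- if (length(cofactors)) {
    mi <- match(cofactors, scanner$map$marker)
    if (anyNA(mi)) .stopf("unknown cofactor marker(s)")
    scanner$marker_col[mi]
  } else integer(0)
  lod <- .hk_lod(yv, P, scanner$grid, config, cof_cols)
  st <- .single_qtl_stats(yv, P)
  tab <- cbind(scanner$grid,
               data.frame(lod = lod, r2 = st$r2, a = st$a))
  structure(list(trait = trait_id, table = tab,
                 cofactors = as.character(cofactors %||% character(0)),
                 n = length(cc)),
            class = "scan_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.align_trait <- function(trait, individuals) {
  if (!is.null(names(trait))) {
    y <- trait[match(individuals, names(trait))]
  } else {
    if (length(trait) != length(individuals))
      .stopf("unnamed trait vector length differs from individual count")
    y <- trait
  }
  as.numeric(y)
}

#' Forward selection of CIM cofactor markers
#'
#' Greedy forward selection over all map markers by partial F-test: at each
#' step the candidate with the smallest p-value enters if p < `entry_alpha`,
#' up to `max_cofactors` markers. Ties are broken by chromosome then bp, so
#' the result is deterministic.
#'
#' @inheritParams scan_hk
#' @return character vector of selected marker ids (possibly empty)
#' @export
select_cofactors <- function(trait, map, genotypes, config = scan_config(),
                             scanner = NULL) {
  if (config$max_cofactors == 0) return(character(0))
  if (is.null(scanner)) scanner <- scan_prep(map, genotypes, config)
  y <- .align_trait(trait, rownames(scanner$P))
  cc <- which(!is.na(y))
  if (length(cc) < config$min_individuals)
    .stopf("too few informative individuals for cofactor selection")
  y <- y[cc]
  if (var(y) == 0) return(character(0))
  Pm <- scanner$P[cc, scanner$marker_col, drop = FALSE]
  n <- length(y)
  ord_chrom <- match(scanner$map$chrom, unique(scanner$map$chrom))
  sel <- integer(0)
  X <- matrix(1, n, 1)
  repeat {
    if (length(sel) >= config$max_cofactors) break
    qx <- qr(X)
    yr <- qr.resid(qx, y)
    rss <- sum(yr^2)
    Xr <- qr.resid(qx, Pm)
    den <- colSums(Xr^2)
    num <- ifelse(den > 1e-10, colSums(Xr * yr)^2 / pmax(den, 1e-10), 0)
    num[sel] <- 0
    df2 <- n - ncol(X) - 1
    if (df2 < 1) break
    Fst <- num / pmax((rss - num) / df2, 1e-300)
    p <- pf(Fst, 1, df2, lower.tail = FALSE)
    best <- order(p, ord_chrom, scanner$map$bp)[1]
    if (p[best] >= config$entry_alpha) break
    sel <- c(sel, best)
    X <- cbind(X, Pm[, best])
  }
  scanner$map$marker[sel]
}

#' Permutation-based genome-wide LOD threshold
#'
#' Permutes the trait across individuals `n_permutations` times, rescans the
#' genome without cofactors, and returns the (1 - alpha) type-7 quantile of
#' the per-permutation genome-wide maximum LOD.
#'
#' @inheritParams scan_hk
#' @param seed integer seed for the permutations (default `config$seed`)
#' @return LOD threshold (numeric scalar)
#' @export
permutation_threshold <- function(trait, map, genotypes, config = scan_config(),
                                  scanner = NULL, seed = config$seed) {
  if (is.null(scanner)) scanner <- scan_prep(map, genotypes, config)
  y <- .align_trait(trait, rownames(scanner$P))
  cc <- which(!is.na(y))
  if (length(cc) < config$min_individuals)
    .stopf("too few informative individuals for permutation threshold")
  y <- y[cc]
  P <- scanner$P[cc, , drop = FALSE]
  n <- length(y)
  withr::with_seed(seed, {
    Y <- vapply(seq_len(config$n_permutations), function(i) sample(y), y)
    C <- suppressWarnings(cor(Y, P))
    C[is.na(C)] <- 0
    r2max <- apply(C^2, 1, max)
    lodmax <- pmin((n / 2) * log10(1 / pmax(1 - r2max, 1e-300)), config$lod_ceiling)
    quantile(lodmax, 1 - config$alpha, type = 7, names = FALSE)
  })
}

#' Call QTLs from a LOD profile
#'
#' Supra-threshold local maxima become QTL records. Two peaks on the same
#' linkage group are reported separately when they are at least
#' `cofactor_window_cm` apart or separated by a dip below (smaller peak -
#' `lod_drop`). The support interval is the contiguous region around the peak
#' with LOD >= peak - `lod_drop`; bp bounds come from the grid's interpolated
#' physical positions. Explained variance and additive effect are the
#' single-QTL (no cofactor) statistics at the peak.
#'
#' @param result a [scan_hk()] result
#' @param threshold genome-wide LOD threshold
#' @param config a [scan_config()]
#' @return data.frame of eQTL/QTL records (possibly 0 rows): trait, lg,
#'   chrom, peak_cm, peak_bp, ci_lo_cm, ci_hi_cm, ci_lo_bp, ci_hi_bp, lod,
#'   r2, a, threshold, class
#' @export
call_qtls <- function(result, threshold, config = scan_config()) {
  tab <- result$table
  recs <- list()
  for (g in unique(tab$lg)) {
    t <- tab[tab$lg == g, ]
    lod <- t$lod
    m <- length(lod)
    supra <- which(lod > threshold)
    if (!length(supra)) next
    is_max <- vapply(supra, function(i) {
      (i == 1 || lod[i] >= lod[i - 1]) && (i == m || lod[i] >= lod[i + 1])
    }, TRUE)
    cand <- supra[is_max]
    cand <- cand[order(-lod[cand], t$cm[cand])]
    acc <- integer(0)
    for (i in cand) {
      # a new peak must be both >= one cofactor window away from every
      # accepted peak and separated from it by a dip below (peak - lod_drop)
      sep <- all(vapply(acc, function(j) {
        far <- abs(t$cm[i] - t$cm[j]) >= config$cofactor_window_cm
        path <- seq(min(i, j), max(i, j))
        far && min(lod[path]) < lod[i] - config$lod_drop
      }, TRUE))
      if (sep) acc <- c(acc, i)
    }
    for (i in sort(acc)) {
      lo <- i
      while (lo > 1 && lod[lo - 1] >= lod[i] - config$lod_drop) lo <- lo - 1
      hi <- i
      while (hi < m && lod[hi + 1] >= lod[i] - config$lod_drop) hi <- hi + 1
      recs[[length(recs) + 1L]] <- data.frame(
        trait = result$trait, lg = g, chrom = t$chrom[1],
        peak_cm = t$cm[i], peak_bp = t$bp[i],
        ci_lo_cm = t$cm[lo], ci_hi_cm = t$cm[hi],
        ci_lo_bp = min(t$bp[lo], t$bp[hi]), ci_hi_bp = max(t$bp[lo], t$bp[hi]),
        lod = lod[i], r2 = t$r2[i], a = t$a[i], threshold = threshold,
        class = "unclassified", stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) return(empty_records())
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' @rdname call_qtls
#' @export
empty_records <- function() {
  data.frame(trait = character(0), lg = integer(0), chrom = character(0),
             peak_cm = numeric(0), peak_bp = numeric(0),
             ci_lo_cm = numeric(0), ci_hi_cm = numeric(0),
             ci_lo_bp = numeric(0), ci_hi_bp = numeric(0),
             lod = numeric(0), r2 = numeric(0), a = numeric(0),
             threshold = numeric(0), class = character(0),
             stringsAsFactors = FALSE)
}

#' Scan every trait of an expression matrix or trait table
#'
#' For an [expr_set()], applies the configured transform (default
#' log2(x + 1)), drops genes expressed in fewer than
#' `min_expressed_fraction` of lines, then for each gene runs cofactor
#' selection, the CIM scan, a permutation threshold (cofactor-free, with a
#' per-trait seed derived from the trait id so results are independent of
#' trait order) and QTL calling. For a [trait_table()], each
#' (trait, microenvironment) combination is scanned untransformed under the
#' name `trait@microenvironment`.
#'
#' @param x an [expr_set()] or [trait_table()]
#' @param map a [genetic_map()]
#' @param genotypes a [dh_geno()]
#' @param config a [scan_config()]
#' @param verbose print progress every 100 traits
#' @return list of class `scan_set`: `records` (row-bound [call_qtls()]
#'   records with an `eqtl_id` column), `thresholds` (per-trait threshold,
#'   sample size, cofactor count), `skipped` (character vector)
#' @export
scan_all <- function(x, map, genotypes, config = scan_config(), verbose = FALSE) {
  if (inherits(x, "expr_set")) {
    mism <- c(setdiff(x$individuals, genotypes$individuals),
              setdiff(genotypes$individuals, x$individuals))
    if (length(mism))
      .stopf("individual ids differ between expression and genotypes: %s",
             paste(unique(mism), collapse = ", "))
    M <- x$expr
    expressed <- rowMeans(M > 0, na.rm = TRUE) >= config$min_expressed_fraction
    M <- M[expressed, , drop = FALSE]
    if (config$transform == "log2") M <- log2(M + 1)
    traits <- split(M, row(M))
    names(traits) <- rownames(M)
    traits <- lapply(traits, function(v) setNames(v, colnames(M)))
  } else if (inherits(x, "trait_table")) {
    mism <- setdiff(unique(x$individual), genotypes$individuals)
    if (length(mism))
      .stopf("individual ids in trait table unknown to genotypes: %s",
             paste(mism, collapse = ", "))
    combos <- unique(x[, c("trait", "microenvironment")])
    traits <- lapply(seq_len(nrow(combos)), function(i) {
      sub <- x[x$trait == combos$trait[i] &
                 x$microenvironment == combos$microenvironment[i], ]
      setNames(sub$value, sub$individual)
    })
    names(traits) <- paste0(combos$trait, "@", combos$microenvironment)
  } else .stopf("scan_all expects an expr_set or trait_table")

  scanner <- scan_prep(map, genotypes, config)
  records <- list()
  thr <- list()
  skipped <- character(0)
  for (ti in seq_along(traits)) {
    id <- names(traits)[ti]
    y <- traits[[ti]]
    if (sum(!is.na(.align_trait(y, rownames(scanner$P)))) < config$min_individuals) {
      skipped <- c(skipped, id)
      next
    }
    cof <- select_cofactors(y, config = config, scanner = scanner)
    res <- scan_hk(y, config = config, cofactors = cof, scanner = scanner,
                   trait_id = id)
    seed_t <- (config$seed + .hash31(id)) %% 2147483647L
    th <- permutation_threshold(y, config = config, scanner = scanner,
                                seed = seed_t)
    rec <- call_qtls(res, th, config)
    records[[id]] <- rec
    thr[[id]] <- data.frame(trait = id, threshold = th, n = res$n,
                            n_cofactors = length(cof), stringsAsFactors = FALSE)
    if (verbose && ti %% 100 == 0)
      message(sprintf("scanned %d / %d traits", ti, length(traits)))
  }
  recs <- if (length(records)) do.call(rbind, records) else empty_records()
  rownames(recs) <- NULL
  if (nrow(recs)) recs$eqtl_id <- sprintf("eqtl%06d", seq_len(nrow(recs)))
  else recs$eqtl_id <- character(0)
  structure(list(records = recs,
                 thresholds = if (length(thr)) do.call(rbind, thr)
                 else data.frame(trait = character(0), threshold = numeric(0),
                                 n = integer(0), n_cofactors = integer(0)),
                 skipped = skipped),
            class = "scan_set")
}
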