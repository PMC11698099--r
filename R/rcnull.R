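#' Configuration of the matched-resampling (RC.eQTL) null
#'
#' @param n_replicates number of RC.eQTL replicate sets (default 100)
#' @param n_genes_sampled genes sampled per replicate (default 1000)
#' @param alignment_mode `"pair"` (eQTL interval must overlap one anchor AND
#'   the eGene body the other) or `"eqtl_only"` (eQTL interval overlapping
#'   either anchor suffices)
#' @param seed integer seed
#' @return list of class `rc_null_config`
#' @export
rc_null_config <- function(n_replicates = 100, n_genes_sampled = 1000,
                           alignment_mode = c("pair", "eqtl_only"), seed = 1L) {
  stopifnot(n_replicates >= 1, n_genes_sampled >= 1)
  structure(list(n_replicates = as.integer(n_replicates),
                 n_genes_sampled = as.integer(n_genes_sampled),
                 alignment_mode = match.arg(alignment_mode),
                 seed = as.integer(seed)),
            class = "rc_null_config")
}

#' Generate one set of randomly created eQTLs (RC.eQTLs)
#'
#' Random genomic regions matched to the observed eQTL architecture:
#' `n_genes_sampled` genes are chosen at random, each receives k regions with
#' k resampled from the observed per-eGene eQTL-count distribution, each
#' region's length is resampled from the observed support-interval length
#' distribution, and regions are placed uniformly across chromosomes
#' (weighted by length, clipped to fit).
#'
#' @param records observed eQTL records (uses `trait`, `ci_lo_bp`, `ci_hi_bp`)
#' @param genes gene table
#' @param chrom_sizes named vector of chromosome sizes in bp
#' @param config an [rc_null_config()]
#' @param seed overrides `config$seed`
#' @return data.frame (rc_id, gene, chrom, start, end), one row per RC region
#' @export
sample_rc_eqtls <- function(records, genes, chrom_sizes,
                            config = rc_null_config(), seed = config$seed) {
  stopifnot(nrow(records) > 0)
  lens <- records$ci_hi_bp - records$ci_lo_bp + 1
  if (min(lens) > max(chrom_sizes))
    .stopf("observed eQTL regions are longer than every chromosome")
  kdist <- as.integer(table(records$trait))
  withr::with_seed(seed, {
    gsel <- sample(genes$gene, config$n_genes_sampled,
                   replace = config$n_genes_sampled > nrow(genes))
    k <- sample(kdist, length(gsel), replace = TRUE)
    gene <- rep(gsel, k)
    total <- length(gene)
    len <- sample(lens, total, replace = TRUE)
    chrom <- character(total)
    start <- numeric(total)
    for (i in seq_len(total)) {
      feas <- chrom_sizes[chrom_sizes >= len[i]]
      if (!length(feas)) .stopf("RC region longer than every chromosome")
      ch <- sample(names(feas), 1, prob = feas)
      chrom[i] <- ch
      start[i] <- floor(runif(1, 1, chrom_sizes[[ch]] - len[i] + 2))
    }
    data.frame(rc_id = sprintf("rc%06d", seq_len(total)), gene = gene,
               chrom = chrom, start = start, end = start + len - 1,
               stringsAsFactors = FALSE)
  })
}

# index pairs (a_i, b_j) of overlapping intervals across two tables with
# chrom/start/end columns (1-based closed)
.overlap_pairs <- function(a, b) {
  out <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(a$start[ia], a$end[ia]),
      IRanges::IRanges(b$start[ib], b$end[ib]))
    if (length(hits))
      out[[ch]] <- cbind(ia[S4Vectors::queryHits(hits)],
                         ib[S4Vectors::subjectHits(hits)])
  }
  if (!length(out)) matrix(integer(0), 0, 2) else do.call(rbind, out)
}

# normalize observed records / RC records to (chrom, start, end, gene)
.as_regions <- function(records) {
  if (all(c("ci_lo_bp", "ci_hi_bp") %in% names(records)))
    data.frame(chrom = records$chrom, start = records$ci_lo_bp,
               end = records$ci_hi_bp, gene = records$trait,
               stringsAsFactors = FALSE)
  else
    data.frame(chrom = records$chrom, start = records$start,
               end = records$end, gene = records$gene, stringsAsFactors = FALSE)
}

#' Fraction of eQTLs aligned with interaction anchors
#'
#' Under the default `"pair"` rule a record is aligned with an interaction
#' when its eQTL bp interval overlaps one anchor and its eGene body overlaps
#' the other anchor (either orientation), for any interaction carrying the
#' requested label. Under `"eqtl_only"` the eQTL interval overlapping either
#' anchor suffices.
#'
#' @param records observed eQTL records or RC regions ([sample_rc_eqtls()])
#' @param genes gene table
#' @param interactions an [interaction_pairs()] table
#' @param label `"common"` or `"unique"`
#' @param mode alignment rule (see above)
#' @return fraction of records aligned, in `[0, 1]`
#' @export
overlap_fraction <- function(records, genes, interactions, label,
                             mode = c("pair", "eqtl_only")) {
  mode <- match.arg(mode)
  q <- .as_regions(records)
  if (!nrow(q)) return(0)
  ints <- interactions[interactions$label == label, , drop = FALSE]
  if (!nrow(ints)) return(0)
  a1 <- data.frame(chrom = ints$chrom1, start = ints$start1, end = ints$end1)
  a2 <- data.frame(chrom = ints$chrom2, start = ints$start2, end = ints$end2)
  if (mode == "eqtl_only") {
    h1 <- .overlap_pairs(q, a1)
    h2 <- .overlap_pairs(q, a2)
    return(length(unique(c(h1[, 1], h2[, 1]))) / nrow(q))
  }
  gi <- match(q$gene, genes$gene)
  if (anyNA(gi)) .stopf("record gene(s) missing from gene table")
  gb <- data.frame(chrom = genes$chrom[gi], start = genes$start[gi],
                   end = genes$end[gi])
  pair_keys <- function(qa, ga) {
    hq <- .overlap_pairs(qa$q, qa$anchor)
    hg <- .overlap_pairs(ga$g, ga$anchor)
    intersect(paste(hq[, 1], hq[, 2]), paste(hg[, 1], hg[, 2]))
  }
  fwd <- pair_keys(list(q = q, anchor = a1), list(g = gb, anchor = a2))
  rev <- pair_keys(list(q = q, anchor = a2), list(g = gb, anchor = a1))
  aligned <- unique(as.integer(sub(" .*", "", c(fwd, rev))))
  length(aligned) / nrow(q)
}

#' Enrichment of eQTL-eGene pairs in 3D-genome interactions
#'
#' Compares the observed aligned fraction per interaction label against the
#' matched-resampling RC.eQTL null: `n_replicates` RC sets are drawn with
#' [sample_rc_eqtls()] and the one-sided empirical enrichment p-value is
#' (1 + #\{null >= observed\}) / (1 + n_replicates).
#'
#' @inheritParams overlap_fraction
#' @param chrom_sizes named vector of chromosome sizes
#' @param config an [rc_null_config()]
#' @return list of class `rc_null_result`: `observed`, `null` (replicates x
#'   labels matrix), `p`, `config`
#' @export
enrichment_test <- function(records, genes, interactions, chrom_sizes,
                            config = rc_null_config()) {
  labels <- intersect(c("common", "unique"), unique(interactions$label))
  if (!length(labels)) .stopf("no interaction labels present")
  obs <- vapply(labels, function(l)
    overlap_fraction(records, genes, interactions, l, config$alignment_mode), 0)
  null <- matrix(NA_real_, config$n_replicates, length(labels),
                 dimnames = list(NULL, labels))
  for (r in seq_len(config$n_replicates)) {
    rc <- sample_rc_eqtls(records, genes, chrom_sizes, config,
                          seed = (config$seed + 7919L * r) %% 2147483647L)
    null[r, ] <- vapply(labels, function(l)
      overlap_fraction(rc, genes, interactions, l, config$alignment_mode), 0)
  }
  p <- vapply(labels, function(l)
    (1 + sum(null[, l] >= obs[l])) / (1 + config$n_replicates), 0)
  structure(list(observed = obs, null = null, p = p, config = config),
            class = "rc_null_result")
}

#' @export
print.rc_null_result <- function(x, ...) {
  for (l in names(x$observed))
    cat(sprintf("%s: observed %.4f, null mean %.4f (sd %.4f), p = %.4g\n",
                l, x$observed[l], mean(x$null[, l]), sd(x$null[, l]), x$p[l]))
  invisible(x)
}
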