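#' Per-gene trait-expression correlation across microenvironments
#'
#' For each microenvironment separately, the Pearson correlation between
#' every gene's (transformed) expression and the trait, with a two-sided
#' t-test p-value; a gene passes when p < alpha in EVERY microenvironment.
#'
#' @param expression an [expr_set()]
#' @param traits a [trait_table()]
#' @param trait_name which trait to correlate against
#' @param alpha per-environment significance level (default 0.01)
#' @param transform `"log2"` (log2(x+1), default) or `"none"`
#' @return data.frame of class `trait_verdicts`: gene, one `r_<env>` and
#'   `p_<env>` column per microenvironment, `max_abs_r`, `pass`
#' @export
trait_expression_correlation <- function(expression, traits, trait_name,
                                         alpha = 0.01,
                                         transform = c("log2", "none")) {
  transform <- match.arg(transform)
  tt <- traits[traits$trait == trait_name, , drop = FALSE]
  if (!nrow(tt)) .stopf("trait '%s' not present in the trait table", trait_name)
  envs <- sort(unique(tt$microenvironment))
  E <- expression$expr
  if (transform == "log2") E <- log2(E + 1)
  out <- data.frame(gene = expression$genes$gene, stringsAsFactors = FALSE)
  pass <- rep(TRUE, nrow(out))
  for (env in envs) {
    sub <- tt[tt$microenvironment == env, ]
    shared <- intersect(expression$individuals, sub$individual)
    if (length(shared) < 3)
      .stopf("fewer than 3 shared individuals in microenvironment %s", env)
    y <- sub$value[match(shared, sub$individual)]
    X <- E[, match(shared, expression$individuals), drop = FALSE]
    r <- suppressWarnings(as.vector(cor(t(X), y)))
    r[is.na(r)] <- 0
    n <- length(shared)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
    p <- 2 * pt(-abs(tstat), n - 2)
    out[[paste0("r_", env)]] <- r
    out[[paste0("p_", env)]] <- p
    pass <- pass & (p < alpha)
  }
  rcols <- grep("^r_", names(out))
  out$max_abs_r <- apply(abs(as.matrix(out[rcols])), 1, max)
  out$pass <- pass
  structure(out, class = c("trait_verdicts", "data.frame"),
            alpha = alpha, environments = envs, trait = trait_name)
}

#' Prioritize candidate genes within a target interval
#'
#' Candidates are the genes whose body overlaps the interval AND that pass
#' the all-microenvironments correlation filter for every supplied trait.
#' Each candidate is flagged for carrying a cis-eQTL, and the list is ranked
#' by (has cis-eQTL, max |r| across traits and environments) descending, ties
#' broken by bp.
#'
#' @param interval list or vector with `chrom`, `start`, `end` (bp, 1-based
#'   closed)
#' @param genes gene table
#' @param cis_records classified eQTL records (only rows with
#'   `class == "cis"` are used)
#' @param verdicts a [trait_expression_correlation()] result or a list of
#'   them (one per required trait)
#' @return ranked data.frame: gene, chrom, start, end, has_cis_eqtl,
#'   max_abs_r, rank
#' @export
prioritize <- function(interval, genes, cis_records, verdicts) {
  chrom <- as.character(interval[["chrom"]])
  start <- as.numeric(interval[["start"]])
  end <- as.numeric(interval[["end"]])
  if (is.na(start) || is.na(end) || start > end)
    .stopf("invalid interval: need chrom, start <= end")
  if (inherits(verdicts, "trait_verdicts")) verdicts <- list(verdicts)
  inside <- genes$chrom == chrom & genes$start <= end & genes$end >= start
  cand <- genes[inside, , drop = FALSE]
  if (!nrow(cand)) return(.empty_candidates())
  keep <- rep(TRUE, nrow(cand))
  max_r <- rep(0, nrow(cand))
  for (v in verdicts) {
    vi <- match(cand$gene, v$gene)
    keep <- keep & !is.na(vi) & v$pass[vi]
    max_r <- pmax(max_r, ifelse(is.na(vi), 0, v$max_abs_r[vi]))
  }
  cand <- cand[keep, , drop = FALSE]
  max_r <- max_r[keep]
  if (!nrow(cand)) return(.empty_candidates())
  cis_genes <- unique(cis_records$trait[cis_records$class == "cis"])
  has_cis <- cand$gene %in% cis_genes
  o <- order(-has_cis, -max_r, cand$start)
  out <- data.frame(gene = cand$gene[o], chrom = cand$chrom[o],
                    start = cand$start[o], end = cand$end[o],
                    has_cis_eqtl = has_cis[o], max_abs_r = max_r[o],
                    rank = seq_along(o), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.empty_candidates <- function() {
  data.frame(gene = character(0), chrom = character(0), start = numeric(0),
             end = numeric(0), has_cis_eqtl = logical(0),
             max_abs_r = numeric(0), rank = integer(0))
}
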