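#' Classify eQTLs as cis or trans
#'
#' An eQTL is cis when its peak lies on the same chromosome as its eGene and
#' the distance |peak bp - gene start| is strictly below 1 Mb; otherwise it
#' is trans (a distance of exactly 1 Mb is trans). Distance is measured from
#' the gene start; strand is ignored.
#'
#' @param records eQTL record data.frame from [scan_all()] / [call_qtls()];
#'   the `trait` column must name genes present in `genes`
#' @param genes gene table (`gene`, `chrom`, `start`, `end`)
#' @param cis_bp cis distance bound in bp (default 1e6)
#' @return the records with `class` set to "cis"/"trans" and a
#'   `distance_bp` column (NA across chromosomes)
#' @export
classify_cis_trans <- function(records, genes, cis_bp = 1e6) {
  if (!nrow(records)) {
    records$distance_bp <- numeric(0)
    return(records)
  }
  gi <- match(records$trait, genes$gene)
  if (anyNA(gi))
    .stopf("eGene(s) missing from the gene table: %s",
           paste(unique(records$trait[is.na(gi)]), collapse = ", "))
  same <- records$chrom == genes$chrom[gi]
  dist <- ifelse(same, abs(records$peak_bp - genes$start[gi]), NA_real_)
  records$class <- ifelse(same & dist < cis_bp, "cis", "trans")
  records$distance_bp <- dist
  records
}

#' Partition eGenes by the class of their eQTLs
#'
#' Each distinct eGene falls in exactly one category: regulated by cis-eQTLs
#' only, by trans-eQTLs only, or by both.
#'
#' @param records classified eQTL records
#' @return data.frame (egene, category) with a named count vector in
#'   attribute `"counts"`
#' @export
categorize_egenes <- function(records) {
  if (!nrow(records)) {
    out <- data.frame(egene = character(0), category = character(0))
    attr(out, "counts") <- c(cis_only = 0L, trans_only = 0L, both = 0L)
    return(out)
  }
  if (any(records$class == "unclassified"))
    .stopf("records must be classified before partitioning (run classify_cis_trans)")
  has <- table(records$trait, records$class)
  cis <- if ("cis" %in% colnames(has)) has[, "cis"] > 0 else rep(FALSE, nrow(has))
  trans <- if ("trans" %in% colnames(has)) has[, "trans"] > 0 else rep(FALSE, nrow(has))
  category <- ifelse(cis & trans, "both", ifelse(cis, "cis_only", "trans_only"))
  out <- data.frame(egene = rownames(has), category = category,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "counts") <- c(cis_only = sum(category == "cis_only"),
                           trans_only = sum(category == "trans_only"),
                           both = sum(category == "both"))
  out
}

#' Summarize the genomic distribution of eQTLs
#'
#' @param records classified eQTL records
#' @param map a [genetic_map()] (unused except for chromosome ordering;
#'   optional)
#' @param genes gene table
#' @return list: per-chromosome count table, per-class A/C sub-genome
#'   fractions, median support-interval widths (cM, bp), distribution of
#'   eQTLs per eGene, mean explained variance
#' @export
summarize_eqtls <- function(records, map = NULL, genes = NULL) {
  if (!nrow(records)) .stopf("no records to summarize")
  sub <- ifelse(grepl("A[0-9]", records$chrom), "A",
                ifelse(grepl("C[0-9]", records$chrom), "C", NA))
  per_chrom <- as.data.frame(table(chrom = records$chrom, class = records$class),
                             stringsAsFactors = FALSE)
  subg <- tapply(sub, records$class, function(z) {
    c(A = mean(z == "A", na.rm = TRUE), C = mean(z == "C", na.rm = TRUE))
  })
  per_egene <- table(table(records$trait))
  list(n_eqtls = nrow(records),
       n_egenes = length(unique(records$trait)),
       per_chromosome = per_chrom,
       subgenome_fraction = subg,
       median_width_cm = stats::median(records$ci_hi_cm - records$ci_lo_cm),
       median_width_bp = stats::median(records$ci_hi_bp - records$ci_lo_bp + 1),
       eqtls_per_egene = per_egene,
       mean_r2 = mean(records$r2))
}

#' Chi-square association between eGene status and a gene annotation
#'
#' Pearson chi-square on the R x C contingency table, without continuity
#' correction by default.
#'
#' @param egene_status per-gene logical (or factor) eGene status
#' @param annotation per-gene category (factor/character)
#' @param correct apply the Yates continuity correction (default FALSE)
#' @return list of class `chisq_result`: `statistic`, `df`, `p_value`,
#'   `table`
#' @export
chi_square_association <- function(egene_status, annotation, correct = FALSE) {
  stopifnot(length(egene_status) == length(annotation))
  tab <- table(egene_status, annotation)
  if (nrow(tab) < 2 || ncol(tab) < 2 ||
      any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    .stopf("degenerate contingency table: a row or column margin is zero")
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value, table = tab),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4g, df = %d, p = %.4g\n", x$statistic, x$df, x$p_value))
  print(x$table)
  invisible(x)
}
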