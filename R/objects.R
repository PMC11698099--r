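#' Construct a DH genotype matrix
#'
#' Bundles marker metadata with a markers x individuals genotype matrix for a
#' biparental doubled-haploid population. Genotypes are stored internally as
#' integers: `1` = A (first-parent allele), `0` = B (second-parent allele),
#' `NA` = missing. Heterozygotes do not exist in a DH population and are
#' rejected.
#'
#' @param markers data.frame with columns `marker`, `chrom`, `bp` (1-based
#'   physical position).
#' @param geno integer (or character "A"/"B"/NA) matrix, markers in rows,
#'   individuals in columns.
#' @param individuals character vector of individual ids; defaults to the
#'   column names of `geno`.
#' @return An object of class `dh_geno`: a list with elements `markers`,
#'   `geno`, `individuals`.
#' @export
dh_geno <- function(markers, geno, individuals = colnames(geno)) {
  stopifnot(is.data.frame(markers), all(c("marker", "chrom", "bp") %in% names(markers)))
  if (is.character(geno)) {
    bad <- setdiff(unique(as.vector(geno)), c("A", "B", "-", NA))
    if (length(bad)) .stopf("unknown genotype code(s): %s", paste(bad, collapse = ", "))
    g <- matrix(NA_integer_, nrow(geno), ncol(geno))
    g[geno == "A"] <- 1L
    g[geno == "B"] <- 0L
    geno <- g
  }
  geno <- matrix(as.integer(geno), nrow(geno), ncol(geno))
  if (any(!geno %in% c(0L, 1L, NA))) .stopf("genotype codes must be 0/1/NA after decoding")
  if (nrow(geno) != nrow(markers)) .stopf("geno rows (%d) != markers rows (%d)", nrow(geno), nrow(markers))
  if (is.null(individuals)) individuals <- sprintf("ind%03d", seq_len(ncol(geno)))
  if (anyDuplicated(individuals)) .stopf("duplicated individual ids")
  if (anyDuplicated(markers$marker)) .stopf("duplicated marker ids")
  if (any(markers$bp < 1) || any(markers$bp != floor(markers$bp)))
    .stopf("marker bp must be positive integers")
  markers$marker <- as.character(markers$marker)
  markers$chrom <- as.character(markers$chrom)
  markers$bp <- as.numeric(markers$bp)
  rownames(markers) <- NULL
  dimnames(geno) <- list(markers$marker, individuals)
  structure(list(markers = markers, geno = geno, individuals = individuals),
            class = "dh_geno")
}

#' @export
print.dh_geno <- function(x, ...) {
  cat(sprintf("DH genotype matrix: %d markers x %d individuals on %d chromosome(s)\n",
              nrow(x$markers), length(x$individuals), length(unique(x$markers$chrom))))
  cat(sprintf("missing genotype fraction: %.4f\n", mean(is.na(x$geno))))
  invisible(x)
}

# order markers by chromosome then bp; stable within ties
sort_geno <- function(g) {
  o <- order(g$markers$chrom, g$markers$bp)
  dh_geno(g$markers[o, , drop = FALSE], g$geno[o, , drop = FALSE], g$individuals)
}

#' Construct an expression set
#'
#' Gene metadata plus a genes x individuals expression matrix on the FPKM-like
#' (non-negative) scale.
#'
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based, closed).
#' @param expr numeric matrix, genes in rows, individuals in columns.
#' @param individuals character vector of individual ids.
#' @return Object of class `expr_set`.
#' @export
expr_set <- function(genes, expr, individuals = colnames(expr)) {
  stopifnot(is.data.frame(genes), all(c("gene", "chrom", "start", "end") %in% names(genes)))
  if (anyDuplicated(genes$gene)) .stopf("duplicated gene ids")
  if (any(genes$start < 1) || any(genes$end < genes$start))
    .stopf("gene coordinates must satisfy 1 <= start <= end")
  if (nrow(expr) != nrow(genes)) .stopf("expr rows != genes rows")
  if (is.null(individuals)) individuals <- sprintf("ind%03d", seq_len(ncol(expr)))
  genes$gene <- as.character(genes$gene)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  rownames(genes) <- NULL
  dimnames(expr) <- list(genes$gene, individuals)
  structure(list(genes = genes, expr = expr, individuals = individuals),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("Expression set: %d genes x %d individuals\n",
              nrow(x$genes), length(x$individuals)))
  invisible(x)
}

#' Construct a genetic map
#'
#' One linkage group per chromosome; markers ordered by position, cM
#' non-decreasing within a group and anchored at 0 for the first marker.
#'
#' @param df data.frame with columns `marker`, `lg` (integer linkage group),
#'   `cm`, `chrom`, `bp`.
#' @return Object of class `genetic_map` (a data.frame).
#' @export
genetic_map <- function(df) {
  stopifnot(all(c("marker", "lg", "cm", "chrom", "bp") %in% names(df)))
  if (anyDuplicated(df$marker)) .stopf("duplicated marker ids in map")
  for (g in unique(df$lg)) {
    cm <- df$cm[df$lg == g]
    if (length(cm) && abs(cm[1]) > 1e-9) .stopf("first marker of group %s not at 0 cM", g)
    if (is.unsorted(cm)) .stopf("cM not non-decreasing in group %s", g)
  }
  df$marker <- as.character(df$marker)
  df$chrom <- as.character(df$chrom)
  df$lg <- as.integer(df$lg)
  df$cm <- as.numeric(df$cm)
  df$bp <- as.numeric(df$bp)
  rownames(df) <- NULL
  structure(df, class = c("genetic_map", "data.frame"))
}

#' @export
print.genetic_map <- function(x, ...) {
  len <- total_map_length(x)
  cat(sprintf("Genetic map: %d markers, %d linkage group(s), %.2f cM\n",
              nrow(x), length(unique(x$lg)), len))
  invisible(x)
}

#' Total genetic length of a map (sum of per-group spans)
#' @param map a `genetic_map`
#' @return length in cM
#' @export
total_map_length <- function(map) {
  sum(tapply(map$cm, map$lg, function(z) max(z) - min(z)))
}

#' Chromosome sizes implied by a set of coordinates
#'
#' Returns the largest observed bp per chromosome, or passes through a named
#' vector unchanged. Used as a fallback when true sizes are not supplied.
#' @param x a `genetic_map`, `dh_geno`, `expr_set` or named numeric vector
#' @return named numeric vector of sizes in bp
#' @export
chromosome_sizes <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) return(x)
  df <- if (inherits(x, "genetic_map")) x
  else if (inherits(x, "dh_geno")) x$markers
  else if (inherits(x, "expr_set")) data.frame(chrom = x$genes$chrom, bp = x$genes$end)
  else .stopf("cannot derive chromosome sizes from class %s", class(x)[1])
  tapply(df$bp, df$chrom, max)
}

#' Validate a long-form trait table
#'
#' @param df data.frame with columns `individual`, `microenvironment`,
#'   `trait`, `value`; one row per combination.
#' @return the validated data.frame, class `trait_table`
#' @export
trait_table <- function(df) {
  stopifnot(all(c("individual", "microenvironment", "trait", "value") %in% names(df)))
  key <- paste(df$individual, df$microenvironment, df$trait)
  if (anyDuplicated(key)) .stopf("duplicated (individual, microenvironment, trait) rows")
  rownames(df) <- NULL
  structure(df, class = c("trait_table", "data.frame"))
}

#' Validate an interaction-pair table (1-based closed coordinates)
#'
#' @param df data.frame with columns `chrom1,start1,end1,chrom2,start2,end2,label`;
#'   labels must be "common" or "unique".
#' @return data.frame of class `interaction_pairs`
#' @export
interaction_pairs <- function(df) {
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "label")
  stopifnot(all(need %in% names(df)))
  if (any(df$start1 > df$end1) || any(df$start2 > df$end2))
    .stopf("interaction anchors must satisfy start <= end")
  bad <- setdiff(unique(df$label), c("common", "unique"))
  if (length(bad)) .stopf("unknown interaction label(s): %s", paste(bad, collapse = ", "))
  for (col in c("start1", "end1", "start2", "end2")) df[[col]] <- as.numeric(df[[col]])
  rownames(df) <- NULL
  structure(df, class = c("interaction_pairs", "data.frame"))
}
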