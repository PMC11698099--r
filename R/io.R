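# All TSV writers emit deterministic byte streams: fixed column order and
# floats formatted with 6 significant digits (%.6g). Coordinates are 1-based
# closed everywhere except BEDPE, which keeps its native 0-based half-open
# convention on disk and is converted on read/write.

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == floor(x) & abs(x) < 1e15, format(x, scientific = FALSE, trim = TRUE),
                sprintf("%.6g", x)))
}

.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
    if (is.logical(out[[j]])) out[[j]] <- ifelse(out[[j]], "TRUE", "FALSE")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.check_bp <- function(x, what, path) {
  if (any(is.na(x)) || any(x < 1) || any(x != floor(x)))
    .stopf("%s: %s positions must be positive integers", path, what)
}

#' Read / write a genotype TSV
#'
#' Rows are markers: `marker`, `chrom`, `bp`, then one column per individual
#' with codes `A` (first-parent allele), `B` (second-parent allele), `-`
#' (missing). Heterozygote codes are invalid in the DH dialect and raise a
#' parse error naming the offending row and column.
#'
#' @param path file path
#' @return a [dh_geno()]
#' @export
read_genotypes <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 4) .stopf("%s: expected marker, chrom, bp plus individuals", path)
  .check_bp(df$bp, "marker bp", path)
  if (anyDuplicated(df$marker))
    .stopf("%s: duplicated marker identifier(s): %s", path,
           paste(unique(df$marker[duplicated(df$marker)]), collapse = ", "))
  codes <- as.matrix(df[, -(1:3), drop = FALSE])
  bad <- which(matrix(!(codes %in% c("A", "B", "-")), nrow(codes)), arr.ind = TRUE)
  if (nrow(bad))
    .stopf("%s: unknown genotype code '%s' at marker %s, individual %s",
           path, codes[bad[1, 1], bad[1, 2]], df$marker[bad[1, 1]],
           colnames(codes)[bad[1, 2]])
  geno <- matrix(NA_integer_, nrow(codes), ncol(codes))
  geno[codes == "A"] <- 1L
  geno[codes == "B"] <- 0L
  dh_geno(df[, c("marker", "chrom", "bp")], geno, colnames(codes))
}

#' @rdname read_genotypes
#' @param g a [dh_geno()]
#' @export
write_genotypes <- function(g, path) {
  codes <- matrix("-", nrow(g$geno), ncol(g$geno))
  codes[!is.na(g$geno) & g$geno == 1L] <- "A"
  codes[!is.na(g$geno) & g$geno == 0L] <- "B"
  colnames(codes) <- g$individuals
  .write_tsv(cbind(g$markers[, c("marker", "chrom", "bp")],
                   as.data.frame(codes, stringsAsFactors = FALSE)), path)
}

#' Read / write an expression TSV
#'
#' Rows are genes: `gene`, `chrom`, `start`, `end`, then one numeric column
#' per individual (FPKM-like values).
#'
#' @param path file path
#' @return an [expr_set()]
#' @export
read_expression <- function(path) {
  df <- .read_tsv(path)
  if (anyDuplicated(df$gene)) .stopf("%s: duplicated gene identifier(s)", path)
  .check_bp(df$start, "gene start", path)
  .check_bp(df$end, "gene end", path)
  expr <- as.matrix(df[, -(1:4), drop = FALSE])
  storage.mode(expr) <- "double"
  expr_set(df[, c("gene", "chrom", "start", "end")], expr, colnames(expr))
}

#' @rdname read_expression
#' @param x an [expr_set()]
#' @export
write_expression <- function(x, path) {
  .write_tsv(cbind(x$genes[, c("gene", "chrom", "start", "end")],
                   as.data.frame(x$expr)), path)
}

#' Read / write a genetic-map TSV (`marker`, `lg`, `cm`, `chrom`, `bp`)
#' @param path file path
#' @return a [genetic_map()]
#' @export
read_map <- function(path) {
  df <- .read_tsv(path)
  .check_bp(df$bp, "marker bp", path)
  genetic_map(df[, c("marker", "lg", "cm", "chrom", "bp")])
}

#' @rdname read_map
#' @param map a [genetic_map()]
#' @export
write_map <- function(map, path) {
  .write_tsv(as.data.frame(map)[, c("marker", "lg", "cm", "chrom", "bp")], path)
}

#' Read / write a long-form trait TSV
#' (`individual`, `microenvironment`, `trait`, `value`)
#' @param path file path
#' @return a [trait_table()]
#' @export
read_traits <- function(path) {
  trait_table(.read_tsv(path))
}

#' @rdname read_traits
#' @param traits a [trait_table()]
#' @export
write_traits <- function(traits, path) {
  .write_tsv(as.data.frame(traits)[, c("individual", "microenvironment",
                                       "trait", "value")], path)
}

#' Read / write interaction anchors as 7-column BEDPE
#'
#' On disk BEDPE is 0-based half-open; in memory coordinates are 1-based
#' closed (`start = start0 + 1`). The 7th column is the parental set label
#' (`common` / `unique`).
#'
#' @param path file path
#' @return an [interaction_pairs()] table
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 7) .stopf("%s: expected 7-column BEDPE", path)
  names(df)[1:7] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "label")
  for (k in c(1, 2)) {
    s <- df[[paste0("start", k)]]; e <- df[[paste0("end", k)]]
    if (any(e <= s)) .stopf("%s: BEDPE anchor with end <= start", path)
  }
  df$start1 <- df$start1 + 1
  df$start2 <- df$start2 + 1
  interaction_pairs(df[, 1:7])
}

#' @rdname read_interactions
#' @param ints an [interaction_pairs()] table
#' @export
write_interactions <- function(ints, path) {
  out <- as.data.frame(ints)[, c("chrom1", "start1", "end1",
                                 "chrom2", "start2", "end2", "label")]
  out$start1 <- out$start1 - 1
  out$start2 <- out$start2 - 1
  for (j in seq_along(out)) if (is.numeric(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write a gene annotation TSV (`gene`, `seq_varied`, `compartment`)
#' @param path file path
#' @return data.frame
#' @export
read_annotations <- function(path) {
  df <- .read_tsv(path)
  if (anyDuplicated(df$gene)) .stopf("%s: duplicated gene identifier(s)", path)
  df
}

#' @rdname read_annotations
#' @param ann annotation data.frame
#' @export
write_annotations <- function(ann, path) .write_tsv(ann, path)

#' Write an eQTL record table as TSV
#' @param records record data.frame
#' @param path file path
#' @export
write_records <- function(records, path) .write_tsv(records, path)

#' @rdname write_records
#' @export
read_records <- function(path) .read_tsv(path)

#' Write hotspot calls as TSV plus a BED of the intervals
#' @param hs a [call_hotspots()] result
#' @param path TSV path; a `.bed` file with the same stem is written next to
#'   it
#' @export
write_hotspots <- function(hs, path) {
  h <- hs$hotspots
  h$members <- vapply(h$hotspot, function(id) paste(hs$members[[id]], collapse = ","), "")
  .write_tsv(h, path)
  bed <- data.frame(chrom = h$chrom, start = h$start - 1, end = h$end,
                    name = h$hotspot)
  for (j in 2:3) bed[[j]] <- .fmt_num(bed[[j]])
  write.table(bed, sub("\\.tsv$", ".bed", path), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
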