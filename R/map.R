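#' Kosambi map function
#'
#' Converts a recombination fraction to additive genetic distance under
#' moderate crossover interference: d = 25 ln((1 + 2r) / (1 - 2r)) cM.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`
#' @return genetic distance(s) in cM
#' @seealso [inverse_kosambi()]
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) .stopf("recombination fraction must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi map function
#'
#' r = (e^{4d/100} - 1) / (2 (e^{4d/100} + 1)), the exact inverse of
#' [kosambi_cm()].
#'
#' @param d genetic distance(s) in cM, non-negative
#' @return recombination fraction(s) in `[0, 0.5)`
#' @export
inverse_kosambi <- function(d) {
  if (any(d < 0)) .stopf("map distance must be non-negative")
  0.5 * tanh(2 * d / 100)
}

#' Estimate the recombination fraction between two DH markers
#'
#' In a DH population the recombination fraction between two loci is the
#' fraction of individuals with discordant genotypes among those non-missing
#' at both. The estimate is capped at 0.4999 so it stays inside the Kosambi
#' domain.
#'
#' @param m1,m2 genotype vectors (1 = A, 0 = B, NA missing) of equal length
#' @return estimated recombination fraction
#' @export
estimate_r <- function(m1, m2) {
  stopifnot(length(m1) == length(m2))
  ok <- !is.na(m1) & !is.na(m2)
  n <- sum(ok)
  if (n == 0) .stopf("undefined recombination fraction: no individual informative at both markers")
  min(sum(m1[ok] != m2[ok]) / n, 0.4999)
}

#' Filter markers on missingness and segregation distortion
#'
#' Retains markers whose missing fraction is at most `max_missing` and whose
#' A:B ratio does not deviate from the 1:1 DH expectation at significance
#' `distortion_alpha` (1-df chi-square on the non-missing counts).
#'
#' @param g a [dh_geno()] object
#' @param max_missing maximum tolerated missing fraction (default 0.2)
#' @param distortion_alpha significance level for the segregation-distortion
#'   test (default 0.001)
#' @return filtered `dh_geno`; the per-marker report (missing fraction,
#'   chi-square, p, retained flag, reason) is attached as attribute `"report"`
#' @export
filter_markers <- function(g, max_missing = 0.2, distortion_alpha = 0.001) {
  stopifnot(max_missing >= 0, max_missing < 1)
  nA <- rowSums(g$geno == 1L, na.rm = TRUE)
  nB <- rowSums(g$geno == 0L, na.rm = TRUE)
  n <- nA + nB
  missf <- 1 - n / ncol(g$geno)
  chisq <- ifelse(n > 0, (nA - nB)^2 / n, NA_real_)
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  keep_miss <- missf <= max_missing
  keep_seg <- !is.na(p) & p >= distortion_alpha
  keep <- keep_miss & keep_seg
  reason <- ifelse(keep, "", ifelse(!keep_miss, "missingness",
                                    ifelse(!keep_seg, "segregation_distortion", "")))
  report <- data.frame(marker = g$markers$marker, missing_fraction = missf,
                       chisq = chisq, p = p, retained = keep, reason = reason,
                       stringsAsFactors = FALSE)
  if (!any(keep)) .stopf("no markers survive filtering")
  out <- dh_geno(g$markers[keep, , drop = FALSE], g$geno[keep, , drop = FALSE],
                 g$individuals)
  attr(out, "report") <- report
  out
}

# TRUE if two genotype vectors agree wherever both are observed
.compatible <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  all(a[ok] == b[ok])
}

#' Collapse runs of redundant markers into bins
#'
#' Consecutive markers on the same chromosome whose genotype vectors are
#' identical on every individual where both are non-missing are merged into a
#' single bin represented by the member with the smallest bp.
#'
#' @param g a [dh_geno()] object, markers sorted by (chrom, bp)
#' @return list with `genotypes` (binned `dh_geno`, one representative per
#'   bin) and `bins` (data.frame mapping every input marker to its bin id and
#'   representative)
#' @export
bin_markers <- function(g) {
  g <- sort_geno(g)
  m <- nrow(g$markers)
  bin <- integer(m)
  rep_idx <- integer(0)
  cur <- 0L
  for (i in seq_len(m)) {
    new_bin <- i == 1L ||
      g$markers$chrom[i] != g$markers$chrom[rep_idx[cur]] ||
      !.compatible(g$geno[i, ], g$geno[rep_idx[cur], ])
    if (new_bin) {
      cur <- cur + 1L
      rep_idx <- c(rep_idx, i)
    }
    bin[i] <- cur
  }
  bins <- data.frame(marker = g$markers$marker, bin = bin,
                     representative = g$markers$marker[rep_idx[bin]],
                     stringsAsFactors = FALSE)
  out <- dh_geno(g$markers[rep_idx, , drop = FALSE],
                 g$geno[rep_idx, , drop = FALSE], g$individuals)
  list(genotypes = out, bins = bins)
}

#' Build a Kosambi genetic map over the physical marker order
#'
#' Marker order is taken from the physical coordinates (one linkage group per
#' chromosome); the cM position is the cumulative Kosambi distance of
#' adjacent-pair recombination-fraction estimates, starting at 0. Intervals
#' where r is undefined (no individual informative at both ends) borrow the
#' nearest informative adjacent-pair estimate on the same chromosome, with a
#' warning.
#'
#' @param g a [dh_geno()] object (typically filtered and binned)
#' @return a [genetic_map()]
#' @export
build_map <- function(g) {
  g <- sort_geno(g)
  chroms <- unique(g$markers$chrom)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    idx <- which(g$markers$chrom == chroms[ci])
    k <- length(idx)
    r <- rep(NA_real_, max(k - 1L, 0L))
    if (k > 1L) for (j in seq_len(k - 1L)) {
      r[j] <- tryCatch(estimate_r(g$geno[idx[j], ], g$geno[idx[j + 1L], ]),
                       error = function(e) NA_real_)
    }
    if (anyNA(r)) {
      if (all(is.na(r))) .stopf("no informative adjacent pair on chromosome %s", chroms[ci])
      warning(sprintf("chromosome %s: %d interval(s) with undefined r interpolated from nearest informative pair",
                      chroms[ci], sum(is.na(r))), call. = FALSE)
      ok <- which(!is.na(r))
      for (j in which(is.na(r))) r[j] <- r[ok[which.min(abs(ok - j))]]
    }
    cm <- cumsum(c(0, kosambi_cm(r)))
    out[[ci]] <- data.frame(marker = g$markers$marker[idx], lg = ci, cm = cm,
                            chrom = chroms[ci], bp = g$markers$bp[idx],
                            stringsAsFactors = FALSE)
  }
  genetic_map(do.call(rbind, out))
}

#' Summarize a genetic map
#'
#' Mean adjacent spacing is total length / (number of markers - number of
#' groups), i.e. total length over the number of adjacent intervals.
#' "Integrity" is the fraction of adjacent gaps below `gap_threshold` cM.
#'
#' @param map a [genetic_map()]
#' @param gap_threshold gap size (cM) above which an interval is counted as a
#'   break in map integrity (default 5)
#' @return list with `n_markers`, `n_groups`, `total_cm`,
#'   `mean_spacing_cm`, `max_gap_cm`, `integrity` and a per-group data.frame
#'   `groups`
#' @export
map_summary <- function(map, gap_threshold = 5) {
  stopifnot(nrow(map) > 0)
  gl <- split(map$cm, map$lg)
  gaps <- unlist(lapply(gl, function(z) if (length(z) > 1) diff(z) else numeric(0)))
  total <- sum(vapply(gl, function(z) max(z) - min(z), 0))
  n <- nrow(map)
  k <- length(gl)
  groups <- data.frame(
    lg = as.integer(names(gl)),
    chrom = vapply(split(map$chrom, map$lg), `[`, "", 1),
    n_markers = lengths(gl),
    length_cm = vapply(gl, function(z) max(z) - min(z), 0),
    max_gap_cm = vapply(gl, function(z) if (length(z) > 1) max(diff(z)) else 0, 0))
  rownames(groups) <- NULL
  list(n_markers = n, n_groups = k, total_cm = total,
       mean_spacing_cm = if (n > k) total / (n - k) else NA_real_,
       max_gap_cm = if (length(gaps)) max(gaps) else 0,
       integrity = if (length(gaps)) mean(gaps < gap_threshold) else NA_real_,
       groups = groups)
}
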