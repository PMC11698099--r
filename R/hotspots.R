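#' Hotspot detection configuration
#'
#' Defaults follow the sliding-window density rule: 1-Mb windows advanced in
#' 100-kb steps, with the genome-wide 95% quantile of window counts as the
#' threshold and hotspots required to hold at least 2 member trans-eQTLs.
#'
#' @param window_bp window size in bp
#' @param step_bp step size in bp (must be <= window)
#' @param quantile quantile of the window-count distribution used as
#'   threshold (strict exceedance)
#' @param min_members minimum member trans-eQTLs per reported hotspot
#' @return list of class `hotspot_config`
#' @export
hotspot_config <- function(window_bp = 1e6, step_bp = 1e5, quantile = 0.95,
                           min_members = 2) {
  stopifnot(step_bp <= window_bp, quantile > 0, quantile < 1)
  structure(list(window_bp = window_bp, step_bp = step_bp, quantile = quantile,
                 min_members = min_members),
            class = "hotspot_config")
}

#' Sliding-window trans-eQTL density
#'
#' Windows of `window_bp` tile each chromosome at `step_bp` (the last window
#' is clipped at the chromosome end); a record is counted in a window when
#' its peak bp lies inside the window.
#'
#' @param records trans-classified eQTL records (rows with `class != "trans"`
#'   are ignored)
#' @param chrom_sizes named vector of chromosome sizes in bp
#' @param config a [hotspot_config()]
#' @return data.frame (chrom, start, end, count), one row per window
#' @export
window_density <- function(records, chrom_sizes, config = hotspot_config()) {
  records <- records[records$class == "trans", , drop = FALSE]
  if (nrow(records)) {
    sz <- chrom_sizes[records$chrom]
    if (anyNA(sz)) .stopf("record chromosome missing from chrom_sizes")
    if (any(records$peak_bp > sz))
      .stopf("record peak bp beyond its chromosome size")
  }
  out <- lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    starts <- seq(1, L, by = config$step_bp)
    ends <- pmin(starts + config$window_bp - 1, L)
    peaks <- sort(records$peak_bp[records$chrom == ch])
    count <- findInterval(ends, peaks) - findInterval(starts - 1, peaks)
    data.frame(chrom = ch, start = starts, end = ends, count = count,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Call trans-eQTL hotspots from window densities
#'
#' The threshold is the type-7 `quantile` of all window counts genome-wide
#' (zero-count windows included). Windows with count strictly above the
#' threshold that overlap or are book-ended on the same chromosome are merged
#' into one hotspot spanning their union; members are the trans-eQTLs whose
#' peaks fall inside the merged interval.
#'
#' @param counts output of [window_density()]
#' @param records the same trans-classified records
#' @param config a [hotspot_config()]
#' @return list of class `hotspot_set`: `hotspots` (data.frame: hotspot,
#'   chrom, start, end, n_members, n_egenes, peak_count), `members` (list of
#'   eqtl_id vectors), `egenes` (list of eGene id vectors), `threshold`
#' @export
call_hotspots <- function(counts, records, config = hotspot_config()) {
  records <- records[records$class == "trans", , drop = FALSE]
  threshold <- quantile(counts$count, config$quantile, type = 7, names = FALSE)
  sel <- counts[counts$count > threshold, , drop = FALSE]
  hs <- list(); members <- list(); egenes <- list()
  for (ch in unique(sel$chrom)) {
    s <- sel[sel$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    cur_s <- s$start[1]; cur_e <- s$end[1]; cur_max <- s$count[1]
    flush <- function(cs, ce, cmx) {
      inside <- records$chrom == ch & records$peak_bp >= cs & records$peak_bp <= ce
      if (sum(inside) < config$min_members) return()
      hs[[length(hs) + 1L]] <<- data.frame(
        chrom = ch, start = cs, end = ce, n_members = sum(inside),
        n_egenes = length(unique(records$trait[inside])), peak_count = cmx,
        stringsAsFactors = FALSE)
      members[[length(members) + 1L]] <<- records$eqtl_id[inside]
      egenes[[length(egenes) + 1L]] <<- unique(records$trait[inside])
    }
    if (nrow(s) > 1) for (i in 2:nrow(s)) {
      if (s$start[i] <= cur_e + 1) {
        cur_e <- max(cur_e, s$end[i])
        cur_max <- max(cur_max, s$count[i])
      } else {
        flush(cur_s, cur_e, cur_max)
        cur_s <- s$start[i]; cur_e <- s$end[i]; cur_max <- s$count[i]
      }
    }
    flush(cur_s, cur_e, cur_max)
  }
  hotspots <- if (length(hs)) do.call(rbind, hs) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               n_members = integer(0), n_egenes = integer(0),
               peak_count = numeric(0))
  if (nrow(hotspots)) {
    o <- order(hotspots$chrom, hotspots$start)
    hotspots <- hotspots[o, , drop = FALSE]
    members <- members[o]
    egenes <- egenes[o]
    hotspots <- cbind(hotspot = sprintf("hotspot%02d", seq_len(nrow(hotspots))),
                      hotspots)
    names(members) <- names(egenes) <- hotspots$hotspot
  }
  rownames(hotspots) <- NULL
  structure(list(hotspots = hotspots, members = members, egenes = egenes,
                 threshold = threshold),
            class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("%d trans-eQTL hotspot(s), window-count threshold %.3g\n",
              nrow(x$hotspots), x$threshold))
  if (nrow(x$hotspots)) print(x$hotspots)
  invisible(x)
}

#' Colocalize hotspots with trait-QTL support intervals
#'
#' For every (hotspot, trait QTL) pair on the same chromosome, reports the
#' bp intersection of the hotspot interval with the QTL support interval.
#'
#' @param hotspots a [call_hotspots()] result
#' @param trait_qtls QTL records from a trait scan (uses `ci_lo_bp`,
#'   `ci_hi_bp`)
#' @return data.frame (hotspot, trait, chrom, overlap_bp, colocated)
#' @export
colocalize <- function(hotspots, trait_qtls) {
  h <- hotspots$hotspots
  out <- list()
  for (i in seq_len(nrow(h))) for (j in seq_len(nrow(trait_qtls))) {
    if (h$chrom[i] != trait_qtls$chrom[j]) next
    ov <- min(h$end[i], trait_qtls$ci_hi_bp[j]) -
      max(h$start[i], trait_qtls$ci_lo_bp[j]) + 1
    out[[length(out) + 1L]] <- data.frame(
      hotspot = h$hotspot[i], trait = trait_qtls$trait[j], chrom = h$chrom[i],
      overlap_bp = max(ov, 0), colocated = ov > 0, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(hotspot = character(0), trait = character(0),
                                      chrom = character(0), overlap_bp = numeric(0),
                                      colocated = logical(0)))
  do.call(rbind, out)
}
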