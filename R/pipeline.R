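#' Run the full eQTL pipeline from a configuration list
#'
#' Stages: read inputs (or take in-memory objects), filter and bin markers,
#' build the Kosambi map, scan expression and traits, classify cis/trans,
#' partition eGenes, summarize, detect trans-eQTL hotspots, colocalize with
#' trait QTLs, test interaction enrichment against the RC.eQTL null, run the
#' chi-square annotation associations, and (if a target interval is
#' configured) prioritize candidate genes. Any stage whose inputs are absent
#' is skipped.
#'
#' @param cfg a list (typically from [read_pipeline_config()]) with elements
#'   `genotypes`, `expression`, `traits`, `interactions`, `annotations`
#'   (paths or objects), optional `scan`, `hotspot`, `rc_null` parameter
#'   lists, optional `target_interval` (chrom, start, end) and
#'   `focal_traits`, `out_dir`, `seed`
#' @param verbose print stage progress
#' @return list with every computed stage result
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- as.integer(cfg$seed %||% 1L)
  get_in <- function(x, reader) {
    if (is.null(x)) NULL else if (is.character(x)) reader(x) else x
  }
  geno <- get_in(cfg$genotypes, read_genotypes)
  expr <- get_in(cfg$expression, read_expression)
  traits <- get_in(cfg$traits, read_traits)
  ints <- get_in(cfg$interactions, read_interactions)
  ann <- get_in(cfg$annotations, read_annotations)
  if (is.null(geno)) .stopf("pipeline requires genotypes")

  say("filtering %d markers", nrow(geno$markers))
  filt <- do.call(filter_markers, c(list(geno),
                                    cfg$filter %||% list()))
  binned <- bin_markers(filt)
  say("%d markers retained, %d bins", nrow(filt$markers),
      nrow(binned$genotypes$markers))
  map <- build_map(binned$genotypes)
  msum <- map_summary(map)
  say("map: %.1f cM over %d groups", msum$total_cm, msum$n_groups)

  scfg <- do.call(scan_config, c(cfg$scan %||% list(),
                                 if (is.null(cfg$scan$seed)) list(seed = seed)))
  out <- list(map = map, map_summary = msum, bins = binned$bins,
              genotypes = binned$genotypes, scan_config = scfg)

  if (!is.null(expr)) {
    say("scanning %d expression traits", nrow(expr$genes))
    es <- scan_all(expr, map, binned$genotypes, scfg)
    recs <- classify_cis_trans(es$records, expr$genes)
    out$eqtl <- es
    out$records <- recs
    out$egene_partition <- categorize_egenes(recs)
    if (nrow(recs)) out$summary <- summarize_eqtls(recs, map, expr$genes)
    hcfg <- do.call(hotspot_config, cfg$hotspot %||% list())
    sizes <- pmax(chromosome_sizes(map), chromosome_sizes(expr))
    dens <- window_density(recs, sizes, hcfg)
    out$hotspots <- call_hotspots(dens, recs, hcfg)
    say("%d hotspot(s) detected", nrow(out$hotspots$hotspots))
    if (!is.null(ints)) {
      rcfg <- do.call(rc_null_config,
                      c(cfg$rc_null %||% list(),
                        if (is.null(cfg$rc_null$seed)) list(seed = seed)))
      out$enrichment <- enrichment_test(recs, expr$genes, ints, sizes, rcfg)
    }
    if (!is.null(ann)) {
      eg <- unique(recs$trait)
      status <- expr$genes$gene %in% eg
      ai <- match(expr$genes$gene, ann$gene)
      out$associations <- lapply(
        setdiff(names(ann), "gene"),
        function(col) chi_square_association(status, ann[[col]][ai]))
      names(out$associations) <- setdiff(names(ann), "gene")
    }
  }
  if (!is.null(traits)) {
    say("scanning phenotypic traits")
    ts <- scan_all(traits, map, binned$genotypes, scfg)
    out$trait_qtl <- ts
    if (!is.null(out$hotspots) && nrow(ts$records))
      out$colocalization <- colocalize(out$hotspots, ts$records)
  }
  if (!is.null(cfg$target_interval) && !is.null(expr) && !is.null(traits)) {
    focal <- cfg$focal_traits %||% unique(traits$trait)
    verdicts <- lapply(focal, function(tn)
      trait_expression_correlation(expr, traits, tn,
                                   alpha = cfg$correlation_alpha %||% 0.01))
    out$verdicts <- setNames(verdicts, focal)
    out$candidates <- prioritize(cfg$target_interval, expr$genes,
                                 out$records %||% empty_records(), verdicts)
    say("%d candidate(s) in the target interval", nrow(out$candidates))
  }
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

#' Write the standard TSV reports of a pipeline run
#' @param out a [run_pipeline()] result
#' @param dir output directory (created if needed)
#' @export
write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_map(out$map, file.path(dir, "genetic_map.tsv"))
  if (!is.null(out$records)) write_records(out$records, file.path(dir, "eqtls.tsv"))
  if (!is.null(out$egene_partition))
    .write_tsv(out$egene_partition, file.path(dir, "egene_partition.tsv"))
  if (!is.null(out$hotspots)) write_hotspots(out$hotspots, file.path(dir, "hotspots.tsv"))
  if (!is.null(out$trait_qtl))
    write_records(out$trait_qtl$records, file.path(dir, "trait_qtls.tsv"))
  if (!is.null(out$colocalization))
    .write_tsv(out$colocalization, file.path(dir, "colocalization.tsv"))
  if (!is.null(out$enrichment)) {
    e <- out$enrichment
    .write_tsv(data.frame(label = names(e$observed), observed = e$observed,
                          null_mean = colMeans(e$null),
                          null_sd = apply(e$null, 2, sd), p = e$p),
               file.path(dir, "enrichment.tsv"))
  }
  if (!is.null(out$candidates))
    .write_tsv(out$candidates, file.path(dir, "candidates.tsv"))
  invisible(dir)
}

#' Read a YAML pipeline configuration
#' @param path YAML file
#' @return config list for [run_pipeline()]
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  yaml::read_yaml(path)
}
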