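# End-to-end orchestration: filter -> annotate -> MK tables ->
# selection estimates (-> orthology / caste statistics), with a run
# manifest whose stage counts reconcile.

#' Variant records to MK tables
#'
#' The core analysis chain on in-memory objects: per-species site
#' filters, two-species merge, triallelic removal, gene warnings and
#' disqualifying-effect exclusion, gene coverage filter, site
#' classification and MK-table construction.
#'
#' @param genome named character vector of chromosome sequences.
#' @param genes list of `gene_model`s (warnings need not be attached;
#'   they are recomputed against the genome).
#' @param focal_records,outgroup_records lists of `variant_record`s.
#' @param depth per-base depth data.frame (chrom, pos, depth) for the
#'   gene coverage rule; NULL skips that rule.
#' @param focal_config,outgroup_config [filter_config()]s.
#' @param n_focal,n_outgroup diploid sample counts.
#' @return list(tables, excluded = data.frame(gene_id, reason),
#'   site_logs, counts = named stage-count vector).
#' @export
mk_tables_from_records <- function(genome, genes, focal_records,
                                   outgroup_records, depth = NULL,
                                   focal_config = filter_config(),
                                   outgroup_config = filter_config(max_missing_fraction = 0),
                                   n_focal = 10, n_outgroup = 2) {
  genes <- annotate_gene_warnings(genes, genome)
  # SNVs only: MK counts are per nucleotide site
  snv_f <- Filter(is_snv, focal_records)
  snv_o <- Filter(is_snv, outgroup_records)
  ff <- apply_site_filters(snv_f, focal_config)
  fo <- apply_site_filters(snv_o, outgroup_config)
  merged <- merge_species_sites(ff$kept, fo$kept, n_focal, n_outgroup)
  tri <- drop_triallelic(merged)

  # gene-level exclusions: structural warnings, disqualifying effects,
  # poor CDS coverage
  excluded <- list()
  warned <- character()
  for (g in genes) {
    if (length(g$warnings)) {
      excluded[[length(excluded) + 1]] <-
        data.frame(gene_id = g$gene_id,
                   reason = gene_exclusion(g, data.frame())$reason,
                   stringsAsFactors = FALSE)
      warned <- c(warned, g$gene_id)
    }
  }
  healthy <- genes[!vapply(genes, function(g) g$gene_id %in% warned,
                           logical(1))]
  # per-ALT effects of every surviving site, for the exclusion rules;
  # triallelic sites are likely sequencing error and are already
  # discarded, so their alleles do not drive gene exclusion either
  kept_sites <- paste(tri$kept$chrom, tri$kept$pos)
  all_kept <- c(ff$kept, fo$kept)
  all_kept <- all_kept[paste(vapply(all_kept, `[[`, character(1), "chrom"),
                             vapply(all_kept, `[[`, integer(1), "pos")) %in%
                         kept_sites]
  for (g in healthy) {
    effs <- list()
    for (rec in all_kept) {
      if (rec$chrom != g$chrom || is.na(cds_offset(g, rec$pos))) next
      # only alleles with >= 1 called copy count as observed
      observed_alts <- setdiff(unique(as.vector(rec$gt)), c(NA, 0L))
      for (ai in observed_alts) {
        e <- predict_effect(rec, g, genome, alt_index = ai)
        if (!is.null(e)) effs[[length(effs) + 1]] <- e
      }
    }
    effs <- if (length(effs)) do.call(rbind, effs) else
      data.frame(effect = character())
    ex <- gene_exclusion(g, effs)
    if (!ex$keep)
      excluded[[length(excluded) + 1]] <-
        data.frame(gene_id = g$gene_id, reason = ex$reason,
                   stringsAsFactors = FALSE)
  }
  effect_excluded <- if (length(excluded))
    do.call(rbind, excluded)$gene_id else character()
  surviving <- Filter(function(g) !g$gene_id %in% effect_excluded, genes)
  if (!is.null(depth)) {
    cov_out <- gene_coverage_filter(surviving, depth, focal_config)
    for (gid in cov_out)
      excluded[[length(excluded) + 1]] <-
        data.frame(gene_id = gid, reason = "gene_low_coverage",
                   stringsAsFactors = FALSE)
    surviving <- Filter(function(g) !g$gene_id %in% cov_out, surviving)
  }
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(gene_id = character(), reason = character(),
               stringsAsFactors = FALSE)

  classified <- classify_sites(tri$kept, surviving, genome)
  tables <- build_mk_tables(surviving, classified)
  counts <- c(sites_focal_in = length(snv_f),
              sites_focal_removed = nrow(ff$log),
              sites_outgroup_in = length(snv_o),
              sites_outgroup_removed = nrow(fo$log),
              sites_merged = nrow(merged),
              sites_triallelic_removed = nrow(tri$removed),
              genes_in = length(genes),
              genes_excluded = nrow(excluded),
              genes_kept = length(surviving))
  list(tables = tables, excluded = excluded,
       site_logs = list(focal = ff$log, outgroup = fo$log,
                        triallelic = tri$removed),
       classified = classified, counts = counts)
}

#' Run the full pipeline on a synthetic dataset
#'
#' Generates a complete two-species dataset (genome, gene models, two
#' VCFs, homology mask, per-base depth, caste expression table and
#' cross-species hit tables), writes it under `out_dir`, reads
#' everything back through the file readers, and runs filtering,
#' annotation, MK-table construction, hierarchical selection inference,
#' reciprocal-best orthology and the caste-bias statistics. All stages
#' are seeded; reruns with the same seed give identical outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for every stage.
#' @param n_clean_genes clean genes in the fixture.
#' @param estimator passed to [mk_model_config()].
#' @return list(manifest, tables, estimates, caste, orthologs,
#'   comparison); also writes mk_tables.tsv, estimates.tsv and
#'   manifest.tsv under `out_dir`.
#' @export
run_pipeline <- function(out_dir, seed = 1, n_clean_genes = 25,
                         estimator = "empirical_bayes") {
  sim <- simulate_two_species_vcf(seed = seed,
                                  n_clean_genes = n_clean_genes,
                                  out_dir = out_dir)
  # read everything back from disk: the file layer is part of the run
  genome <- read_fasta(sim$paths$genome)
  genes <- read_gff(sim$paths$gff)
  focal <- read_vcf(sim$paths$focal)
  outgroup <- read_vcf(sim$paths$outgroup)
  mask <- read_bed(sim$paths$mask)
  depth <- read_table(sim$paths$depth, schema = c("chrom", "pos", "depth"))
  focal_config <- sim$focal_config; focal_config$mask_intervals <- mask
  outgroup_config <- sim$outgroup_config
  outgroup_config$mask_intervals <- mask

  stage <- mk_tables_from_records(genome, genes, focal, outgroup, depth,
                                  focal_config, outgroup_config,
                                  n_focal = sim$n_focal,
                                  n_outgroup = sim$n_outgroup)
  config <- mk_model_config(n = 2L * sim$n_focal, estimator = estimator,
                            seed = seed)
  estimates <- fit_hierarchical_mk(stage$tables, config)
  write_table(stage$tables, file.path(out_dir, "mk_tables.tsv"))
  write_table(estimates, file.path(out_dir, "estimates.tsv"))

  # caste expression over the analysed genes
  gene_ids <- stage$tables$gene_id
  expr <- simulate_expression(length(gene_ids),
                              n_queen_biased = max(2, length(gene_ids) %/% 8),
                              n_worker_biased = max(2, length(gene_ids) %/% 6),
                              seed = seed + 10L, gene_ids = gene_ids)
  write_table(expr$expression, file.path(out_dir, "expression.tsv"))
  caste <- classify_caste_bias(expr$expression)
  pos <- classify_positive(estimates)
  caste_pos <- positive_fraction(caste, pos)

  # orthology against a sibling species with planted reciprocal bests
  hits <- simulate_hit_tables(n_shared = max(5, length(gene_ids) %/% 2),
                              n_a_only = 4, n_b_only = 4,
                              seed = seed + 20L)
  write_table(hits$hits_ab, file.path(out_dir, "hits_ab.tsv"))
  write_table(hits$hits_ba, file.path(out_dir, "hits_ba.tsv"))
  orthologs <- reciprocal_best(best_hits(hits$hits_ab),
                               best_hits(hits$hits_ba))

  manifest <- list(seed = seed, software_version = as.character(
    utils::packageVersion("mkgamma")),
    config = list(focal = unclass(focal_config),
                  outgroup = unclass(outgroup_config),
                  model = unclass(config)),
    counts = c(stage$counts,
               genes_estimated = sum(!estimates$no_gamma),
               genes_positive = length(pos),
               ortholog_pairs = nrow(orthologs)))
  write_table(data.frame(key = names(manifest$counts),
                         value = unname(manifest$counts)),
              file.path(out_dir, "manifest.tsv"))
  list(manifest = manifest, tables = stage$tables, excluded = stage$excluded,
       estimates = estimates, caste = caste, caste_positive = caste_pos,
       orthologs = orthologs, site_logs = stage$site_logs)
}
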