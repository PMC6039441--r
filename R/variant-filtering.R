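#' Site- and gene-level filter configuration
#'
#' Bundles the quality filters applied to variant records before effect
#' annotation. Hard-filter defaults follow the GATK germline hard-filter
#' recommendations for SNVs; depth and missingness limits are
#' dataset-level choices and are always echoed into run manifests.
#'
#' @param hard_filters named list, metric -> `c(comparator, value)` with
#'   comparator `"lt"` (fail when metric < value) or `"gt"` (fail when
#'   metric > value). A metric absent from a record passes.
#' @param depth_lower lower limit on per-site mean depth (also the
#'   per-base "low coverage" limit for the gene rule).
#' @param depth_upper upper limit on per-site mean depth; `NULL` means
#'   2x the dataset-wide median, computed at filter time.
#' @param max_missing_fraction maximum tolerated fraction of missing
#'   genotypes at a site.
#' @param mask_intervals data.frame chrom/start/end (1-based inclusive)
#'   of high-homology regions to exclude, or NULL.
#' @param gene_low_coverage_max_fraction genes whose CDS has strictly
#'   more than this fraction of low-coverage bases are removed
#'   (default 0.1).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(hard_filters = list(QD = c("lt", 2.0),
                                              FS = c("gt", 60.0),
                                              MQ = c("lt", 40.0),
                                              MQRankSum = c("lt", -12.5),
                                              ReadPosRankSum = c("lt", -8.0)),
                          depth_lower = 8,
                          depth_upper = NULL,
                          max_missing_fraction = 0.2,
                          mask_intervals = NULL,
                          gene_low_coverage_max_fraction = 0.1) {
  if (!is.null(depth_upper) && depth_lower > depth_upper)
    stop("depth_lower > depth_upper")
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1,
            gene_low_coverage_max_fraction >= 0,
            gene_low_coverage_max_fraction <= 1)
  structure(list(hard_filters = hard_filters,
                 depth_lower = depth_lower,
                 depth_upper = depth_upper,
                 max_missing_fraction = max_missing_fraction,
                 mask_intervals = mask_intervals,
                 gene_low_coverage_max_fraction = gene_low_coverage_max_fraction),
            class = "filter_config")
}

# One record's first failing hard filter, or NA.
.hard_filter_fail <- function(rec, hard_filters) {
  for (metric in names(hard_filters)) {
    if (!metric %in% names(rec$info)) next # absent metric passes
    cmp <- hard_filters[[metric]][1]
    val <- as.numeric(hard_filters[[metric]][2])
    x <- rec$info[[metric]]
    fail <- switch(cmp, lt = x < val, gt = x > val,
                   stop("unknown comparator: ", cmp))
    if (isTRUE(fail)) return(paste0("hard_", metric))
  }
  NA_character_
}

.in_mask <- function(rec, mask) {
  if (is.null(mask) || nrow(mask) == 0) return(FALSE)
  any(mask$chrom == rec$chrom & rec$pos >= mask$start & rec$pos <= mask$end)
}

#' Apply site-level quality filters
#'
#' Removes records that fail, in fixed order: (1) any hard-filter
#' metric, (2) mean depth outside `[depth_lower, depth_upper]`,
#' (3) missing-genotype fraction above `max_missing_fraction`,
#' (4) overlap with a homology-mask interval. Each removal is logged
#' with the first failing rule, so reason codes are deterministic.
#' Filtering is a pure partition: records are never mutated, and
#' `kept` + `removed` reconstitute the input.
#'
#' @param records list of `variant_record`s.
#' @param config a [filter_config()].
#' @return list with `kept` (records), `removed` (records) and `log`
#'   (data.frame chrom, pos, reason).
#' @export
apply_site_filters <- function(records, config) {
  stopifnot(inherits(config, "filter_config"))
  depth_upper <- config$depth_upper
  mean_depths <- vapply(records, function(r) mean(r$dp), numeric(1))
  if (is.null(depth_upper))
    depth_upper <- 2 * stats::median(mean_depths)
  reasons <- vapply(seq_along(records), function(i) {
    rec <- records[[i]]
    hf <- .hard_filter_fail(rec, config$hard_filters)
    if (!is.na(hf)) return(hf)
    if (mean_depths[i] < config$depth_lower) return("depth_low")
    if (mean_depths[i] > depth_upper) return("depth_high")
    miss <- mean(is.na(rec$gt[, 1]) | is.na(rec$gt[, 2]))
    if (miss > config$max_missing_fraction) return("missing")
    if (.in_mask(rec, config$mask_intervals)) return("mask")
    NA_character_
  }, character(1))
  keep <- is.na(reasons)
  log <- data.frame(
    chrom = vapply(records[!keep], `[[`, character(1), "chrom"),
    pos = vapply(records[!keep], `[[`, integer(1), "pos"),
    reason = reasons[!keep],
    stringsAsFactors = FALSE)
  list(kept = records[keep], removed = records[!keep], log = log)
}

#' Remove genes with poorly covered coding sequence
#'
#' A CDS base is low-coverage when its mean depth across samples falls
#' below `depth_lower`; a gene is excluded when the fraction of such
#' bases is strictly greater than `gene_low_coverage_max_fraction`
#' (default 0.1, i.e. exactly 10% low coverage is still kept). Bases
#' absent from the depth table count as depth 0.
#'
#' @param genes list of `gene_model`s.
#' @param per_base_depth data.frame with columns chrom, pos, depth
#'   (mean across samples).
#' @param config a [filter_config()].
#' @return character vector of excluded gene ids.
#' @export
gene_coverage_filter <- function(genes, per_base_depth, config) {
  stopifnot(inherits(config, "filter_config"),
            all(c("chrom", "pos", "depth") %in% names(per_base_depth)))
  key <- paste(per_base_depth$chrom, per_base_depth$pos)
  depth_lookup <- stats::setNames(per_base_depth$depth, key)
  excluded <- character()
  for (g in genes) {
    len <- cds_length(g)
    if (len == 0) stop("gene '", g$gene_id, "' has zero CDS length")
    d <- depth_lookup[paste(g$chrom, cds_positions(g))]
    d[is.na(d)] <- 0
    frac_low <- mean(d < config$depth_lower)
    if (frac_low > config$gene_low_coverage_max_fraction)
      excluded <- c(excluded, g$gene_id)
  }
  excluded
}
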