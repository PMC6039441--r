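#' Classify a biallelic site as polymorphism or fixed divergence
#'
#' Unpolarized two-species MK classification on called genotype copies:
#' \itemize{
#'   \item more than two alleles across both species: `remove_triallelic`
#'   \item either species segregating (>= 2 alleles among its called
#'     copies): `polymorphism`
#'   \item both species fixed for the same allele: `remove_same_fixed`
#'   \item both species fixed for different alleles: `divergence`
#'   \item single allele equal to the reference everywhere: `invariant`
#' }
#' Segregation in either species takes precedence over divergence: once
#' only biallelic sites survive, a fixed difference requires both
#' species monomorphic and unequal.
#'
#' @param focal_bases,outgroup_bases character vectors of called allele
#'   bases (with multiplicity) in each species.
#' @param ref reference base, used only to distinguish `invariant`
#'   (monomorphic reference in both species) from `remove_same_fixed`
#'   (monomorphic shared non-reference allele).
#' @return character scalar, one of the five classes above.
#' @export
classify_site <- function(focal_bases, outgroup_bases, ref = NULL) {
  if (length(focal_bases) == 0 || length(outgroup_bases) == 0)
    stop("uncallable site: a species has zero called copies ",
         "(should have been removed by the missingness filter)")
  fu <- unique(focal_bases)
  ou <- unique(outgroup_bases)
  all_u <- unique(c(fu, ou))
  if (length(all_u) > 2) return("remove_triallelic")
  if (length(fu) > 1 || length(ou) > 1) return("polymorphism")
  if (fu == ou) {
    if (!is.null(ref) && fu == ref) return("invariant")
    return("remove_same_fixed")
  }
  "divergence"
}

# The two alleles involved at a classified site (1 or 2 bases).
site_alleles <- function(focal_bases, outgroup_bases) {
  unique(c(unique(focal_bases), unique(outgroup_bases)))
}

#' Classify all merged sites and attach synonymous/non-synonymous labels
#'
#' Runs [classify_site()] over a merged two-species site table, maps
#' each site to its host gene, and determines the mutation type of the
#' allele pair (via [effect_between()], which handles the occasional
#' site where both observed alleles are non-reference).
#'
#' @param merged output of [merge_species_sites()] (post
#'   [drop_triallelic()]).
#' @param genes list of `gene_model`s.
#' @param genome named character vector of chromosome sequences.
#' @return data.frame: chrom, pos, gene_id (NA outside any CDS), class,
#'   mutation_type ("synonymous"/"nonsynonymous"/NA).
#' @export
classify_sites <- function(merged, genes, genome) {
  gene_of <- function(chrom, pos) {
    for (g in genes) {
      if (g$chrom == chrom && !is.na(cds_offset(g, pos))) return(g$gene_id)
    }
    NA_character_
  }
  gene_ids <- stats::setNames(vapply(genes, `[[`, character(1), "gene_id"),
                              vapply(genes, `[[`, character(1), "gene_id"))
  n <- nrow(merged)
  cls <- character(n); gid <- character(n); mt <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cls[i] <- classify_site(merged$focal_bases[[i]],
                            merged$outgroup_bases[[i]], merged$ref[i])
    gid[i] <- gene_of(merged$chrom[i], merged$pos[i])
    if (!is.na(gid[i]) && cls[i] %in% c("polymorphism", "divergence")) {
      al <- site_alleles(merged$focal_bases[[i]], merged$outgroup_bases[[i]])
      g <- genes[[match(gid[i], vapply(genes, `[[`, character(1), "gene_id"))]]
      mt[i] <- effect_between(g, genome, merged$pos[i], al[1], al[2])
    }
  }
  data.frame(chrom = merged$chrom, pos = merged$pos, gene_id = gid,
             class = cls, mutation_type = mt, stringsAsFactors = FALSE)
}

#' Build per-gene McDonald-Kreitman count tables
#'
#' Cross-tabulates classified sites into the four MK cells: PN/PS
#' (non-synonymous / synonymous polymorphisms, both species pooled) and
#' DN/DS (non-synonymous / synonymous fixed differences). Removed and
#' invariant sites contribute nothing; their per-gene removal counts are
#' carried along. Genes with zero surviving sites are retained with an
#' `all_zero` flag (estimators skip them but they are never silently
#' dropped).
#'
#' @param genes list of `gene_model`s (defines the output rows).
#' @param classified output of [classify_sites()].
#' @return data.frame: gene_id, PN, PS, DN, DS, n_removed_triallelic,
#'   n_removed_same_fixed, all_zero.
#' @export
build_mk_tables <- function(genes, classified) {
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  out <- data.frame(gene_id = gene_ids, PN = 0L, PS = 0L, DN = 0L, DS = 0L,
                    n_removed_triallelic = 0L, n_removed_same_fixed = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(classified))) {
    gid <- classified$gene_id[i]
    if (is.na(gid)) next
    j <- match(gid, out$gene_id)
    if (is.na(j)) next
    cl <- classified$class[i]
    if (cl == "remove_triallelic") {
      out$n_removed_triallelic[j] <- out$n_removed_triallelic[j] + 1L
    } else if (cl == "remove_same_fixed") {
      out$n_removed_same_fixed[j] <- out$n_removed_same_fixed[j] + 1L
    } else if (cl %in% c("polymorphism", "divergence")) {
      nonsyn <- classified$mutation_type[i] == "nonsynonymous"
      col <- if (cl == "polymorphism") {
        if (nonsyn) "PN" else "PS"
      } else {
        if (nonsyn) "DN" else "DS"
      }
      out[[col]][j] <- out[[col]][j] + 1L
    }
  }
  out$all_zero <- out$PN + out$PS + out$DN + out$DS == 0L
  out
}
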