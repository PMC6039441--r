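#' Predict the coding effect of a single-nucleotide variant
#'
#' Substitutes the alternate base into the reference codon
#' (strand-aware: for minus-strand genes the substituted base is the
#' reverse complement of the VCF allele) and compares amino acids under
#' the standard nuclear genetic code. Effect classes:
#' \describe{
#'   \item{synonymous / nonsynonymous}{amino acid unchanged / changed}
#'   \item{stop_gained}{ref aa != `*`, alt aa == `*`}
#'   \item{stop_lost}{ref aa == `*`, alt aa != `*`}
#'   \item{start_lost}{codon 0, ATG destroyed into a non-initiator}
#'   \item{nonsyn_start}{codon 0, ATG changed into an alternative
#'     initiator codon (GTG/TTG/CTG)}
#' }
#' Genes whose CDS length is not divisible by 3 are flagged
#' `incomplete_transcript` and yield no effects (error), matching the
#' annotation-warning exclusion route.
#'
#' @param variant a `variant_record` with a single ALT allele (pass
#'   `alt_index` to pick one allele of a multi-allelic record).
#' @param gene a `gene_model`.
#' @param genome named character vector of chromosome sequences.
#' @param alt_index which ALT allele to evaluate (default 1).
#' @return one-row data.frame (gene_id, chrom, pos, ref_allele,
#'   alt_allele, effect, codon_index, within_codon_pos, aa_ref, aa_alt),
#'   or NULL when the position lies outside the gene's CDS.
#' @export
predict_effect <- function(variant, gene, genome, alt_index = 1L) {
  stopifnot(inherits(variant, "variant_record"), inherits(gene, "gene_model"))
  alt <- variant$alts[alt_index]
  if (nchar(variant$ref) != 1 || nchar(alt) != 1)
    stop("predict_effect requires an SNV")
  if (variant$chrom != gene$chrom) return(NULL)
  offset <- cds_offset(gene, variant$pos)
  if (is.na(offset)) return(NULL)
  if (cds_length(gene) %% 3 != 0)
    stop("gene '", gene$gene_id,
         "' CDS length not divisible by 3 (incomplete_transcript)")
  cds <- extract_cds(gene, genome)
  ref_base <- if (gene$strand == "+") variant$ref else revcomp(variant$ref)
  alt_base <- if (gene$strand == "+") alt else revcomp(alt)
  if (substr(cds, offset + 1, offset + 1) != ref_base)
    stop("REF allele mismatch with genome at ", variant$chrom, ":",
         variant$pos, " (gene ", gene$gene_id, ")")
  codon_index <- offset %/% 3L
  within <- offset %% 3L
  codon_start <- codon_index * 3L + 1L
  ref_codon <- substr(cds, codon_start, codon_start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, within + 1L, within + 1L) <- alt_base
  aa_ref <- codon_aa(ref_codon)
  aa_alt <- codon_aa(alt_codon)
  effect <- if (codon_index == 0L && toupper(ref_codon) == "ATG") {
    if (toupper(alt_codon) %in% c("GTG", "TTG", "CTG")) "nonsyn_start"
    else "start_lost"
  } else if (aa_ref != "*" && aa_alt == "*") {
    "stop_gained"
  } else if (aa_ref == "*" && aa_alt != "*") {
    "stop_lost"
  } else if (aa_ref == aa_alt) {
    "synonymous"
  } else {
    "nonsynonymous"
  }
  data.frame(gene_id = gene$gene_id, chrom = variant$chrom,
             pos = variant$pos, ref_allele = variant$ref,
             alt_allele = alt, effect = effect,
             codon_index = codon_index, within_codon_pos = within,
             aa_ref = aa_ref, aa_alt = aa_alt,
             stringsAsFactors = FALSE)
}

#' Is a substitution between two alleles at a CDS site synonymous?
#'
#' Compares the amino acids obtained by substituting each of two bases
#' into the same reference codon. Used for the rare sites where the two
#' observed alleles are both non-reference.
#'
#' @inheritParams predict_effect
#' @param pos genomic position. @param base_a,base_b the two alleles
#'   (genome strand).
#' @return "synonymous" or "nonsynonymous" (stop changes count as
#'   nonsynonymous here; disqualifying effects are handled per-ALT by
#'   [predict_effect()]).
#' @export
effect_between <- function(gene, genome, pos, base_a, base_b) {
  offset <- cds_offset(gene, pos)
  if (is.na(offset)) stop("position not in CDS of ", gene$gene_id)
  cds <- extract_cds(gene, genome)
  if (gene$strand == "-") { base_a <- revcomp(base_a); base_b <- revcomp(base_b) }
  codon_index <- offset %/% 3L
  within <- offset %% 3L
  codon_start <- codon_index * 3L + 1L
  codon <- substr(cds, codon_start, codon_start + 2L)
  ca <- codon; substr(ca, within + 1L, within + 1L) <- base_a
  cb <- codon; substr(cb, within + 1L, within + 1L) <- base_b
  if (codon_aa(ca) == codon_aa(cb)) "synonymous" else "nonsynonymous"
}

#' Gene-level exclusion from annotation warnings and variant effects
#'
#' A gene is removed when its model carries any structural warning
#' (incomplete transcript, multiple stop codons, no start codon) or when
#' any variant in it - both species pooled - is annotated stop_lost,
#' stop_gained, start_lost or nonsyn_start. The reported reason is the
#' first matching rule in that order.
#'
#' @param gene a `gene_model` (warnings attached).
#' @param effects data.frame of [predict_effect()] rows for this gene.
#' @return list(keep = logical, reason = character or NA).
#' @export
gene_exclusion <- function(gene, effects) {
  for (w in c("incomplete_transcript", "multiple_stop_codons",
              "no_start_codon")) {
    if (w %in% gene$warnings) return(list(keep = FALSE, reason = w))
  }
  for (e in c("stop_lost", "stop_gained", "start_lost", "nonsyn_start")) {
    if (nrow(effects) && e %in% effects$effect)
      return(list(keep = FALSE, reason = e))
  }
  list(keep = TRUE, reason = NA_character_)
}

# Bases (A/C/G/T) carried by called genotype copies of a record,
# with multiplicity.
called_bases <- function(rec) {
  alleles <- c(rec$ref, rec$alts)
  idx <- as.vector(rec$gt)
  idx <- idx[!is.na(idx)]
  alleles[idx + 1L]
}

#' Merge focal and outgroup records by site
#'
#' Aligns the two species' call sets on (chrom, pos). A site present in
#' only one species is assumed homozygous reference in the other (both
#' call sets are made against the same focal reference genome), with
#' the missing species represented by all-reference genotypes.
#'
#' @param focal,outgroup lists of `variant_record`s.
#' @param n_focal,n_outgroup diploid sample counts used to synthesize
#'   all-reference genotypes for absent sites.
#' @return data.frame with columns chrom, pos, ref and list-columns
#'   focal_bases / outgroup_bases (called allele bases per species).
#' @export
merge_species_sites <- function(focal, outgroup, n_focal, n_outgroup) {
  key <- function(r) paste(r$chrom, r$pos, sep = ":")
  fk <- vapply(focal, key, character(1))
  ok <- vapply(outgroup, key, character(1))
  all_keys <- union(fk, ok)
  rows <- lapply(all_keys, function(k) {
    fi <- match(k, fk); oi <- match(k, ok)
    rec <- if (!is.na(fi)) focal[[fi]] else outgroup[[oi]]
    if (!is.na(fi) && !is.na(oi) &&
        focal[[fi]]$ref != outgroup[[oi]]$ref)
      stop("REF disagreement between species at ", k)
    fb <- if (!is.na(fi)) called_bases(focal[[fi]])
          else rep(rec$ref, 2L * n_focal)
    ob <- if (!is.na(oi)) called_bases(outgroup[[oi]])
          else rep(rec$ref, 2L * n_outgroup)
    list(chrom = rec$chrom, pos = rec$pos, ref = rec$ref,
         focal_bases = fb, outgroup_bases = ob)
  })
  df <- data.frame(
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    pos = vapply(rows, `[[`, integer(1), "pos"),
    ref = vapply(rows, `[[`, character(1), "ref"),
    stringsAsFactors = FALSE)
  df$focal_bases <- lapply(rows, `[[`, "focal_bases")
  df$outgroup_bases <- lapply(rows, `[[`, "outgroup_bases")
  df[order(df$chrom, df$pos), , drop = FALSE]
}

#' Discard sites with more than two observed alleles
#'
#' The allele union at a site is the set of bases carried by at least
#' one called genotype copy in either species (an ALT listed in the VCF
#' but never called does not count). Sites whose union exceeds two
#' alleles are removed as likely sequencing error. Order-independent.
#'
#' @param merged output of [merge_species_sites()].
#' @return list with `kept` (data.frame) and `removed` (data.frame with
#'   chrom, pos, n_alleles).
#' @export
drop_triallelic <- function(merged) {
  n_alleles <- vapply(seq_len(nrow(merged)), function(i)
    length(unique(c(merged$focal_bases[[i]], merged$outgroup_bases[[i]]))),
    integer(1))
  keep <- n_alleles <= 2
  list(kept = merged[keep, , drop = FALSE],
       removed = data.frame(chrom = merged$chrom[!keep],
                            pos = merged$pos[!keep],
                            n_alleles = n_alleles[!keep],
                            stringsAsFactors = FALSE))
}
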