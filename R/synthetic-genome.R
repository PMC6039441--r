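# Two-species genome/VCF fixture generator.
#
# Builds a toy focal-species genome with annotated CDS genes, plants a
# known number of synonymous/non-synonymous polymorphisms and fixed
# differences per gene, and plants one exemplar of every filtering and
# exclusion rule the pipeline implements, recording everything in a
# manifest so tests can audit that each planted violation is removed by
# exactly the rule that targets it.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# random non-stop codon (optionally excluding some codons)
.rand_codon <- function(exclude = character()) {
  bases <- c("A", "C", "G", "T")
  repeat {
    cod <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    if (!cod %in% c(STOP_CODONS, exclude)) return(cod)
  }
}

# genomic position of a 0-based offset within the spliced CDS
.pos_of_offset <- function(gene, offset) {
  iv <- gene$cds_intervals
  lens <- iv[, "end"] - iv[, "start"] + 1L
  cum <- c(0L, cumsum(lens))
  plus_offset <- if (gene$strand == "+") offset
                 else cds_length(gene) - 1L - offset
  k <- findInterval(plus_offset, cum, rightmost.closed = FALSE)
  iv[k, "start"] + (plus_offset - cum[k])
}

# Find an unused codon hosting a substitution with the requested coding
# effect. Returns list(codon, within, offset, pos, ref, alt) where
# ref/alt are genome-strand alleles, or errors if the CDS is too short.
.find_substitution <- function(gene, genome, target, used_codons) {
  cds <- extract_cds(gene, genome)
  n_cod <- nchar(cds) %/% 3
  codon_range <- switch(target,
    stop_lost = n_cod - 1L,
    start_lost = 0L,
    nonsyn_start = 0L,
    seq.int(1L, n_cod - 2L)) # internal codons for syn/nonsyn/stop_gained
  for (ci in codon_range) {
    if (ci %in% used_codons) next
    codon <- substr(cds, ci * 3 + 1, ci * 3 + 3)
    for (within in 0:2) {
      ref_b <- substr(codon, within + 1, within + 1)
      for (alt_b in setdiff(c("A", "C", "G", "T"), ref_b)) {
        alt_codon <- codon
        substr(alt_codon, within + 1, within + 1) <- alt_b
        aa_r <- codon_aa(codon); aa_a <- codon_aa(alt_codon)
        eff <- if (ci == 0L && toupper(codon) == "ATG") {
          if (toupper(alt_codon) %in% c("GTG", "TTG", "CTG"))
            "nonsyn_start" else "start_lost"
        } else if (aa_r != "*" && aa_a == "*") "stop_gained"
        else if (aa_r == "*" && aa_a != "*") "stop_lost"
        else if (aa_r == aa_a) "synonymous" else "nonsynonymous"
        if (eff != target) next
        offset <- ci * 3L + within
        pos <- .pos_of_offset(gene, offset)
        if (gene$strand == "-") {
          ref_g <- revcomp(ref_b); alt_g <- revcomp(alt_b)
        } else {
          ref_g <- ref_b; alt_g <- alt_b
        }
        return(list(codon = ci, within = within, offset = offset,
                    pos = pos, ref = ref_g, alt = alt_g))
      }
    }
  }
  stop("CDS of ", gene$gene_id, " too short to host a planted '",
       target, "' variant")
}

.gt_matrix <- function(n_samples, pattern) {
  # pattern: "het_k" = k heterozygotes rest hom-ref; "fixed_alt";
  # "miss_k" = k missing rest het/ref mix
  matrix(pattern, ncol = 2)
}

#' Simulate a two-species variant-calling fixture with known truth
#'
#' Generates a toy genome (one chromosome), a set of CDS gene models on
#' both strands (some multi-exon), and focal + outgroup variant call
#' sets in which every gene's MK counts (PN, PS, DN, DS) are planted
#' and recorded. On top of the clean signal, the generator plants one
#' exemplar of every removal rule: GATK-style hard-filter failures
#' (QD, FS, MQ), low and high depth, high missingness, a
#' homology-masked site, a triallelic site, a shared fixed allele, a
#' gene with >10% low-coverage CDS, genes carrying stop-gain,
#' stop-loss, start-loss and non-synonymous-start variants, and one
#' gene model per structural warning. The manifest records every plant
#' so the pipeline can be audited end-to-end.
#'
#' @param seed RNG seed; identical seeds give identical fixtures.
#' @param n_clean_genes number of clean (analysable) genes.
#' @param n_codons codons per gene (including start and stop).
#' @param n_focal,n_outgroup diploid sample counts (10 + 2 by default,
#'   i.e. 20 + 4 haploid genomes).
#' @param out_dir if non-NULL, writes genome.fasta, genes.gff3,
#'   focal.vcf, outgroup.vcf, mask.bed, depth.tsv, expected_mk.tsv and
#'   manifest.tsv there.
#' @return list with genome, genes, focal_records, outgroup_records,
#'   mask, depth, expected_mk, excluded_genes, manifest, focal_config,
#'   outgroup_config, and (when written) paths.
#' @export
simulate_two_species_vcf <- function(seed = 1, n_clean_genes = 25,
                                     n_codons = 40, n_focal = 10,
                                     n_outgroup = 2, out_dir = NULL) {
  stopifnot(n_clean_genes >= 9, n_codons >= 25)
  set.seed(seed)
  chrom <- "chr1"

  ## ---- gene and genome construction ----------------------------------
  specials <- c("g_stopgain", "g_stoploss", "g_startloss", "g_nonsynstart",
                "g_warn_incomplete", "g_warn_multistop", "g_warn_nostart",
                "g_lowcov")
  gene_names <- c(sprintf("g%02d", seq_len(n_clean_genes)), specials)
  cursor <- 1L
  seq_parts <- list()
  genes <- list()
  for (gi in seq_along(gene_names)) {
    gid <- gene_names[gi]
    spacer <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                    collapse = "")
    seq_parts[[length(seq_parts) + 1]] <- spacer
    cursor <- cursor + 60L
    n_cod <- n_codons
    start_codon <- "ATG"
    internal <- replicate(n_cod - 2L, .rand_codon(exclude = "ATG"))
    if (gid == "g_stopgain") {
      internal[5] <- "TGG" # Trp: one hit from TGA
    } else if (gid == "g_warn_multistop") {
      internal[c(5, 10)] <- "TAA"
    } else if (gid == "g_warn_nostart") {
      start_codon <- "GGG"
    }
    cds <- paste(c(start_codon, internal, "TAA"), collapse = "")
    if (gid == "g_warn_incomplete") cds <- substr(cds, 1, nchar(cds) - 1)
    strand <- if (gi %% 5 == 0) "-" else "+"
    gseq <- if (strand == "+") cds else revcomp(cds)
    two_exon <- gi %% 7 == 3 && gid %in% gene_names[seq_len(n_clean_genes)]
    if (two_exon) {
      cut <- 50L
      intron <- paste(sample(c("A", "C", "T"), 30, replace = TRUE),
                      collapse = "") # no G run: avoids accidental splice
      iv <- rbind(c(cursor, cursor + cut - 1L),
                  c(cursor + cut + 30L, cursor + nchar(gseq) + 30L - 1L))
      seq_parts[[length(seq_parts) + 1]] <-
        paste0(substr(gseq, 1, cut), intron,
               substr(gseq, cut + 1, nchar(gseq)))
      cursor <- cursor + nchar(gseq) + 30L
    } else {
      iv <- matrix(c(cursor, cursor + nchar(gseq) - 1L), ncol = 2)
      seq_parts[[length(seq_parts) + 1]] <- gseq
      cursor <- cursor + nchar(gseq)
    }
    genes[[gid]] <- gene_model(gid, chrom, strand, iv)
  }
  seq_parts[[length(seq_parts) + 1]] <-
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  genome <- stats::setNames(paste(unlist(seq_parts), collapse = ""), chrom)
  genes <- annotate_gene_warnings(genes, genome)

  ## ---- variant planting ----------------------------------------------
  pass_info <- c(QD = 10, FS = 5, MQ = 60)
  focal_plan <- list(); outgroup_plan <- list()
  manifest <- list()
  used <- stats::setNames(vector("list", length(genes)), names(genes))
  add_rec <- function(plan, gid, sub, gt, dp, info, alts = NULL) {
    rec <- variant_record(chrom, sub$pos, sub$ref,
                          if (is.null(alts)) sub$alt else alts,
                          gt, dp, info)
    plan[[length(plan) + 1]] <- rec
    plan
  }
  note <- function(gid, sub, rule) {
    manifest[[length(manifest) + 1]] <<-
      data.frame(chrom = chrom, pos = sub$pos, gene_id = gid,
                 rule = rule, stringsAsFactors = FALSE)
  }
  gt_het <- function(ns, k) {
    g <- matrix(0L, ns, 2); g[seq_len(k), 2] <- 1L; g
  }
  gt_fixed <- function(ns) matrix(1L, ns, 2)
  gt_ref <- function(ns) matrix(0L, ns, 2)
  dp_ok_f <- rep(30, n_focal); dp_ok_o <- rep(30, n_outgroup)

  plant <- function(gid, target, kind) {
    # kind: focal_poly / outgroup_poly / divergence_out / divergence_focal
    g <- genes[[gid]]
    sub <- .find_substitution(g, genome, target, used[[gid]])
    used[[gid]] <<- c(used[[gid]], sub$codon)
    if (kind == "focal_poly") {
      focal_plan <<- add_rec(focal_plan, gid, sub,
                             gt_het(n_focal, 1L + sub$codon %% 4L),
                             dp_ok_f, pass_info)
    } else if (kind == "outgroup_poly") {
      outgroup_plan <<- add_rec(outgroup_plan, gid, sub,
                                gt_het(n_outgroup, 1L), dp_ok_o, pass_info)
    } else if (kind == "divergence_out") {
      outgroup_plan <<- add_rec(outgroup_plan, gid, sub,
                                gt_fixed(n_outgroup), dp_ok_o, pass_info)
    } else if (kind == "divergence_focal") {
      focal_plan <<- add_rec(focal_plan, gid, sub, gt_fixed(n_focal),
                             dp_ok_f, pass_info)
    }
    sub
  }

  # clean-gene planted MK counts
  clean <- gene_names[seq_len(n_clean_genes)]
  counts <- data.frame(gene_id = clean,
                       PN = seq_len(n_clean_genes) %% 4L,
                       PS = seq_len(n_clean_genes) %% 3L + 1L,
                       DN = seq_len(n_clean_genes) %% 2L + 1L,
                       DS = seq_len(n_clean_genes) %% 5L,
                       stringsAsFactors = FALSE)
  if (n_clean_genes >= 7) # the worked-example gene
    counts[7, c("PN", "PS", "DN", "DS")] <- c(3L, 5L, 2L, 4L)
  poly_counter <- 0L
  for (i in seq_len(n_clean_genes)) {
    gid <- clean[i]
    for (k in seq_len(counts$PN[i])) {
      poly_counter <- poly_counter + 1L
      plant(gid, "nonsynonymous",
            if (poly_counter %% 4L == 0L) "outgroup_poly" else "focal_poly")
    }
    for (k in seq_len(counts$PS[i])) {
      poly_counter <- poly_counter + 1L
      plant(gid, "synonymous",
            if (poly_counter %% 4L == 0L) "outgroup_poly" else "focal_poly")
    }
    for (k in seq_len(counts$DN[i]))
      plant(gid, "nonsynonymous",
            if (i == 1 && k == 1) "divergence_focal" else "divergence_out")
    if (counts$DS[i] > 0)
      for (k in seq_len(counts$DS[i]))
        plant(gid, "synonymous", "divergence_out")
  }
  # multi-allelic record whose second ALT is never called: still
  # biallelic in practice; counts as one extra PS in gene g02
  sub <- .find_substitution(genes[["g02"]], genome, "synonymous",
                            used[["g02"]])
  used[["g02"]] <- c(used[["g02"]], sub$codon)
  extra_alt <- setdiff(c("A", "C", "G", "T"), c(sub$ref, sub$alt))[1]
  focal_plan <- add_rec(focal_plan, "g02", sub, gt_het(n_focal, 2L),
                        dp_ok_f, pass_info, alts = c(sub$alt, extra_alt))
  counts$PS[counts$gene_id == "g02"] <- counts$PS[counts$gene_id == "g02"] + 1L

  ## ---- planted violations --------------------------------------------
  viol_host <- clean[1:9]
  vsub <- function(gid) {
    s <- .find_substitution(genes[[gid]], genome, "synonymous", used[[gid]])
    used[[gid]] <<- c(used[[gid]], s$codon)
    s
  }
  s <- vsub(viol_host[1])
  focal_plan <- add_rec(focal_plan, viol_host[1], s, gt_het(n_focal, 3L),
                        dp_ok_f, c(QD = 1.0, FS = 5, MQ = 60))
  note(viol_host[1], s, "hard_QD")
  s <- vsub(viol_host[2])
  focal_plan <- add_rec(focal_plan, viol_host[2], s, gt_het(n_focal, 3L),
                        dp_ok_f, c(QD = 10, FS = 80, MQ = 60))
  note(viol_host[2], s, "hard_FS")
  s <- vsub(viol_host[3])
  focal_plan <- add_rec(focal_plan, viol_host[3], s, gt_het(n_focal, 3L),
                        dp_ok_f, c(QD = 10, FS = 5, MQ = 30))
  note(viol_host[3], s, "hard_MQ")
  s <- vsub(viol_host[4])
  focal_plan <- add_rec(focal_plan, viol_host[4], s, gt_het(n_focal, 3L),
                        rep(3, n_focal), pass_info)
  note(viol_host[4], s, "depth_low")
  s <- vsub(viol_host[5])
  focal_plan <- add_rec(focal_plan, viol_host[5], s, gt_het(n_focal, 3L),
                        rep(300, n_focal), pass_info)
  note(viol_host[5], s, "depth_high")
  s <- vsub(viol_host[6])
  gmiss <- gt_het(n_focal, 3L); gmiss[6:10, ] <- NA_integer_
  focal_plan <- add_rec(focal_plan, viol_host[6], s, gmiss,
                        c(rep(30, 5), rep(0, 5)), pass_info)
  note(viol_host[6], s, "missing")
  s <- vsub(viol_host[7])
  focal_plan <- add_rec(focal_plan, viol_host[7], s, gt_het(n_focal, 3L),
                        dp_ok_f, pass_info)
  mask <- data.frame(chrom = chrom, start = s$pos - 2L, end = s$pos + 2L,
                     stringsAsFactors = FALSE)
  note(viol_host[7], s, "mask")
  s <- vsub(viol_host[8]) # triallelic across species
  third <- setdiff(c("A", "C", "G", "T"), c(s$ref, s$alt))[1]
  focal_plan <- add_rec(focal_plan, viol_host[8], s, gt_het(n_focal, 3L),
                        dp_ok_f, pass_info)
  outgroup_plan <- add_rec(outgroup_plan, viol_host[8], s,
                           gt_fixed(n_outgroup), dp_ok_o, pass_info,
                           alts = third)
  note(viol_host[8], s, "triallelic")
  s <- vsub(viol_host[9]) # both species fixed for the same ALT
  focal_plan <- add_rec(focal_plan, viol_host[9], s, gt_fixed(n_focal),
                        dp_ok_f, pass_info)
  outgroup_plan <- add_rec(outgroup_plan, viol_host[9], s,
                           gt_fixed(n_outgroup), dp_ok_o, pass_info)
  note(viol_host[9], s, "same_fixed")

  # disqualifying-effect genes (as focal polymorphisms)
  for (spec in list(c("g_stopgain", "stop_gained"),
                    c("g_stoploss", "stop_lost"),
                    c("g_startloss", "start_lost"),
                    c("g_nonsynstart", "nonsyn_start"))) {
    s <- plant(spec[1], spec[2], "focal_poly")
    note(spec[1], s, spec[2])
    # plus an innocent variant that must vanish with the gene
    plant(spec[1], "synonymous", "focal_poly")
  }
  # a variant inside warned gene models (skipped wholesale downstream)
  for (gid in c("g_warn_multistop", "g_warn_nostart")) {
    s <- plant(gid, "synonymous", "focal_poly")
    note(gid, s, paste0("warning_",
                        sub("^g_warn_", "", gid)))
  }
  # low-coverage gene: ordinary variants, poor per-base depth
  plant("g_lowcov", "synonymous", "focal_poly")
  plant("g_lowcov", "nonsynonymous", "divergence_out")

  ## ---- per-base depth table ------------------------------------------
  depth_rows <- lapply(names(genes), function(gid) {
    pos <- cds_positions(genes[[gid]])
    d <- rep(30, length(pos))
    if (gid == "g_lowcov") {
      n_low <- ceiling(0.12 * length(pos))
      d[seq_len(n_low)] <- 2
    }
    data.frame(chrom = chrom, pos = pos, depth = d,
               stringsAsFactors = FALSE)
  })
  depth <- do.call(rbind, depth_rows)

  ## ---- assemble -------------------------------------------------------
  by_pos <- function(plan) plan[order(vapply(plan, `[[`, integer(1), "pos"))]
  focal_records <- by_pos(focal_plan)
  outgroup_records <- by_pos(outgroup_plan)
  manifest <- do.call(rbind, manifest)
  excluded <- data.frame(
    gene_id = c("g_warn_incomplete", "g_warn_multistop", "g_warn_nostart",
                "g_stopgain", "g_stoploss", "g_startloss", "g_nonsynstart",
                "g_lowcov"),
    reason = c("incomplete_transcript", "multiple_stop_codons",
               "no_start_codon", "stop_gained", "stop_lost", "start_lost",
               "nonsyn_start", "gene_low_coverage"),
    stringsAsFactors = FALSE)
  focal_config <- filter_config(depth_upper = 100,
                                max_missing_fraction = 0.2,
                                mask_intervals = mask)
  outgroup_config <- filter_config(depth_upper = 100,
                                   max_missing_fraction = 0,
                                   mask_intervals = mask)
  out <- list(genome = genome, genes = genes,
              focal_records = focal_records,
              outgroup_records = outgroup_records,
              mask = mask, depth = depth, expected_mk = counts,
              excluded_genes = excluded, manifest = manifest,
              focal_config = focal_config,
              outgroup_config = outgroup_config,
              n_focal = n_focal, n_outgroup = n_outgroup)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_fasta(genome, p("genome.fasta"))
    write_gff(genes, p("genes.gff3"))
    write_vcf(focal_records, p("focal.vcf"),
              sprintf("focal%02d", seq_len(n_focal)))
    write_vcf(outgroup_records, p("outgroup.vcf"),
              sprintf("outgroup%02d", seq_len(n_outgroup)))
    write_bed(mask, p("mask.bed"))
    write_table(depth, p("depth.tsv"))
    write_table(counts, p("expected_mk.tsv"))
    write_table(manifest, p("manifest.tsv"))
    out$paths <- list(genome = p("genome.fasta"), gff = p("genes.gff3"),
                      focal = p("focal.vcf"), outgroup = p("outgroup.vcf"),
                      mask = p("mask.bed"), depth = p("depth.tsv"))
  }
  out
}
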