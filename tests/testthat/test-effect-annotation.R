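# Codon-level effect prediction and the gene/site exclusion rules.

test_that("textbook codon substitutions are classified correctly", {
  # gene: ATG GCT TGG TAA on the plus strand starting at position 6
  genome <- c(chrT = paste0("AAAAA", "ATGGCTTGGTAA", "CCCCC"))
  gene <- gene_model("g1", "chrT", "+", matrix(c(6, 17), ncol = 2))
  eff <- function(pos, ref, alt)
    predict_effect(rec1("chrT", pos, ref, alt, c(0, 1)), gene, genome)
  # GCT -> GCC: Ala/Ala
  e <- eff(11, "T", "C")
  expect_equal(e$effect, "synonymous")
  expect_equal(e$codon_index, 1)
  expect_equal(e$within_codon_pos, 2)
  # GCT -> GTT: Ala -> Val
  expect_equal(eff(10, "C", "T")$effect, "nonsynonymous")
  # TGG -> TGA: Trp -> stop
  expect_equal(eff(14, "G", "A")$effect, "stop_gained")
  # TAA -> TAC: stop -> Tyr
  expect_equal(eff(17, "A", "C")$effect, "stop_lost")
  # ATG -> ATA: start destroyed
  expect_equal(eff(8, "G", "A")$effect, "start_lost")
  # ATG -> GTG: alternative initiator codon
  expect_equal(eff(6, "A", "G")$effect, "nonsyn_start")
  # outside the CDS
  expect_null(eff(2, "A", "G"))
})

test_that("minus-strand effects are computed on the reverse complement", {
  # same CDS but encoded on the minus strand
  cds <- "ATGGCTTGGTAA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  genome <- c(chrT = paste0("AAAAA", rc, "CCCCC"))
  gene <- gene_model("g1", "chrT", "-", matrix(c(6, 17), ncol = 2))
  # GCT -> GCC third codon position: CDS offset 5 = genomic pos 6+11-5=12
  e <- predict_effect(rec1("chrT", 12, "A", "G", c(0, 1)), gene, genome)
  expect_equal(e$effect, "synonymous")
  expect_equal(e$codon_index, 1)
})

test_that("effect prediction agrees with a whole-protein translation oracle", {
  set.seed(42)
  n_checked <- 0
  for (rep in 1:40) {
    strand <- sample(c("+", "-"), 1)
    fx <- random_gene_fixture(n_codons = 25, strand = strand,
                              two_exon = rep %% 3 == 0)
    pos_all <- mkgamma:::cds_positions(fx$gene)
    for (k in 1:25) {
      pos <- sample(pos_all, 1)
      ref <- substr(fx$genome[[1]], pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      e <- predict_effect(rec1("chrT", pos, ref, alt, c(0, 1)),
                          fx$gene, fx$genome)
      o <- oracle_protein_diff(fx$gene, fx$genome, pos, alt)
      if (e$codon_index == 0) next # start-codon labels are policy, not protein diff
      if (o$kind == "synonymous") {
        expect_equal(e$effect, "synonymous",
                     label = sprintf("pos %d %s>%s strand %s", pos, ref,
                                     alt, strand))
      } else {
        expect_equal(e$codon_index, o$codon_index)
        expect_equal(e$aa_alt, o$aa_alt)
        expect_true(e$effect %in% c("nonsynonymous", "stop_gained",
                                    "stop_lost"))
        if (o$aa_alt == "*") expect_equal(e$effect, "stop_gained")
      }
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 900)
})

test_that("strand mirror symmetry: a gene and its mirrored copy agree", {
  set.seed(7)
  fx <- random_gene_fixture(n_codons = 20, strand = "+")
  L <- nchar(fx$genome[[1]])
  mirror_seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fx$genome[[1]])))
  mgenome <- c(chrT = mirror_seq)
  iv <- fx$gene$cds_intervals
  miv <- cbind(L - iv[, "end"] + 1L, L - iv[, "start"] + 1L)
  mgene <- gene_model("g1m", "chrT", "-", miv)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (pos in sample(mkgamma:::cds_positions(fx$gene), 30)) {
    ref <- substr(fx$genome[[1]], pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      e1 <- predict_effect(rec1("chrT", pos, ref, alt, c(0, 1)),
                           fx$gene, fx$genome)
      mpos <- L - pos + 1L
      e2 <- predict_effect(rec1("chrT", mpos, comp[[ref]], comp[[alt]],
                                c(0, 1)), mgene, mgenome)
      expect_equal(e2$effect, e1$effect)
      expect_equal(e2$codon_index, e1$codon_index)
    }
  }
})

test_that("incomplete transcripts refuse per-variant annotation", {
  genome <- c(chrT = paste0("AAAAA", "ATGGCTTGGTA", "CCCCC")) # 11 nt CDS
  gene <- gene_model("g1", "chrT", "+", matrix(c(6, 16), ncol = 2))
  expect_error(predict_effect(rec1("chrT", 10, "C", "T", c(0, 1)),
                              gene, genome), "incomplete_transcript")
})

test_that("gene exclusion fires on warnings then effects, in order", {
  g_ok <- gene_model("g", "c", "+", matrix(c(1, 12), ncol = 2))
  g_warn <- gene_model("g", "c", "+", matrix(c(1, 12), ncol = 2),
                       warnings = "multiple_stop_codons")
  effs <- data.frame(effect = c("synonymous", "nonsynonymous"))
  expect_true(gene_exclusion(g_ok, effs)$keep)
  ex <- gene_exclusion(g_warn, effs)
  expect_false(ex$keep)
  expect_equal(ex$reason, "multiple_stop_codons")
  ex2 <- gene_exclusion(g_ok, data.frame(effect = c("synonymous",
                                                    "stop_gained")))
  expect_false(ex2$keep)
  expect_equal(ex2$reason, "stop_gained")
})

test_that("triallelic removal uses called alleles only and ignores order", {
  mk_merged <- function(focal, outgroup, ref = "A") {
    df <- data.frame(chrom = "chr1", pos = 100L, ref = ref,
                     stringsAsFactors = FALSE)
    df$focal_bases <- list(focal)
    df$outgroup_bases <- list(outgroup)
    df
  }
  # {A,G} focal + {A,T} outgroup -> three alleles -> removed
  out <- drop_triallelic(mk_merged(c("A", "G"), c("A", "T")))
  expect_equal(nrow(out$kept), 0)
  expect_equal(out$removed$n_alleles, 3)
  # {A,G} in both -> kept
  out2 <- drop_triallelic(mk_merged(c("A", "G"), c("G", "G")))
  expect_equal(nrow(out2$kept), 1)
  # order independence across multiple sites
  m <- rbind(mk_merged(c("A", "G"), c("A", "T")),
             mk_merged(c("A", "G"), c("G", "G")))
  m$pos <- c(100L, 200L)
  r1 <- drop_triallelic(m)
  r2 <- drop_triallelic(m[2:1, ])
  expect_setequal(r1$kept$pos, r2$kept$pos)
})

test_that("an ALT with zero called copies does not make a site triallelic", {
  # the declared T allele is never called in either species
  rec <- rec1("chr1", 100, "A", c("G", "T"), c(0, 1, 0, 0, 0, 0))
  out_rec <- rec1("chr1", 100, "A", c("G", "T"), c(0, 0, 0, 0))
  merged <- merge_species_sites(list(rec), list(out_rec), 3, 2)
  expect_false("T" %in% unlist(c(merged$focal_bases, merged$outgroup_bases)))
  out <- drop_triallelic(merged)
  expect_equal(nrow(out$kept), 1)
})

test_that("species merge fills absent sites with homozygous reference", {
  f <- rec1("chr1", 100, "A", "G", c(0, 1, 0, 0))
  o <- rec1("chr1", 200, "C", "T", c(1, 1, 1, 1))
  merged <- merge_species_sites(list(f), list(o), 2, 2)
  expect_equal(nrow(merged), 2)
  i200 <- which(merged$pos == 200)
  expect_equal(merged$focal_bases[[i200]], rep("C", 4)) # synthesized ref
  expect_equal(merged$outgroup_bases[[i200]], rep("T", 4))
  i100 <- which(merged$pos == 100)
  expect_equal(sort(unique(merged$focal_bases[[i100]])), c("A", "G"))
  expect_equal(merged$outgroup_bases[[i100]], rep("A", 4))
})
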