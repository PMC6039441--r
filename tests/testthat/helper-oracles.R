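# Independent oracles used across the suite. These deliberately avoid
# the code paths they check: direct hypergeometric enumeration instead
# of fisher.test/phyper, Riemann sums instead of adaptive quadrature,
# whole-protein translation instead of codon arithmetic.

# Two-sided Fisher p for [[DN, DS], [PN, PS]] by enumerating all tables
# with the observed margins and summing probabilities <= P(observed).
enum_fisher_two_sided <- function(dn, ds, pn, ps) {
  r1 <- dn + ds; c1 <- dn + pn; N <- dn + ds + pn + ps
  if (N == 0) return(NA_real_)
  a_range <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, N - c1, r1)
  p_obs <- stats::dhyper(dn, c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Upper-tail overlap probability P(X >= k) by direct summation.
enum_hyper_upper <- function(k, size_a, size_b, N) {
  x <- k:min(size_a, size_b)
  sum(stats::dhyper(x, size_a, N - size_a, size_b))
}

# Midpoint Riemann sum for the PRF polymorphism integral.
riemann_Q <- function(gamma, n, npts = 1e6) {
  x <- (seq_len(npts) - 0.5) / npts
  f1 <- if (abs(gamma) < 1e-12) 1 - x
        else (-expm1(-gamma * (1 - x))) / (-expm1(-gamma))
  sum(f1 * (1 - x^n - (1 - x)^n) / (x * (1 - x))) / npts
}

# Uncorrected Pearson chi-squared from the textbook closed form.
chisq_closed_form <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Tukey-Kramer adjusted p for one pairwise contrast, from ptukey.
tukey_pair_p <- function(x1, x2, mse, df_err, n_groups) {
  se <- sqrt(mse / 2 * (1 / length(x1) + 1 / length(x2)))
  q <- abs(mean(x1) - mean(x2)) / se
  stats::ptukey(q, n_groups, df_err, lower.tail = FALSE)
}

# A random clean gene (ATG + non-stop codons + TAA) embedded in a
# random genome, on either strand, optionally split in two exons.
random_gene_fixture <- function(n_codons = 30, strand = "+",
                                two_exon = FALSE, flank = 25) {
  bases <- c("A", "C", "G", "T")
  repeat {
    internal <- replicate(n_codons - 2, paste(sample(bases, 3, TRUE),
                                              collapse = ""))
    if (!any(internal %in% c("TAA", "TAG", "TGA"))) break
  }
  cds <- paste(c("ATG", internal, "TAA"), collapse = "")
  gseq <- if (strand == "+") cds else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  left <- paste(sample(bases, flank, TRUE), collapse = "")
  right <- paste(sample(bases, flank, TRUE), collapse = "")
  if (two_exon) {
    cut <- (nchar(gseq) %/% 2) + 1L
    intron <- paste(sample(bases, 20, TRUE), collapse = "")
    chrom_seq <- paste0(left, substr(gseq, 1, cut), intron,
                        substr(gseq, cut + 1, nchar(gseq)), right)
    iv <- rbind(c(flank + 1, flank + cut),
                c(flank + cut + 21, flank + nchar(gseq) + 20))
  } else {
    chrom_seq <- paste0(left, gseq, right)
    iv <- matrix(c(flank + 1, flank + nchar(gseq)), ncol = 2)
  }
  genome <- stats::setNames(chrom_seq, "chrT")
  gene <- gene_model("gt1", "chrT", strand, iv)
  list(gene = gene, genome = genome, cds = cds)
}

# Whole-protein oracle: substitute the allele into the genome, re-extract
# the full CDS, translate, and report the protein difference.
oracle_protein_diff <- function(gene, genome, pos, alt) {
  mutant <- genome
  substr(mutant[[gene$chrom]], pos, pos) <- alt
  tr <- function(g) as.character(
    Biostrings::translate(Biostrings::DNAString(extract_cds(gene, g))))
  p_ref <- tr(genome); p_alt <- tr(mutant)
  if (p_ref == p_alt) return(list(kind = "synonymous"))
  aa_r <- strsplit(p_ref, "")[[1]]; aa_a <- strsplit(p_alt, "")[[1]]
  i <- which(aa_r != aa_a)[1]
  list(kind = "changed", codon_index = i - 1L,
       aa_ref = aa_r[i], aa_alt = aa_a[i])
}

# Attach a mask to a filter config (fixture plumbing).
within_mask <- function(cfg, mask) {
  cfg$mask_intervals <- mask
  cfg
}

# One variant record shared by several tests.
rec1 <- function(chrom, pos, ref, alts, gt, dp = NULL, info = numeric()) {
  gt <- matrix(as.integer(gt), ncol = 2, byrow = TRUE)
  if (is.null(dp)) dp <- rep(30, nrow(gt))
  variant_record(chrom, pos, ref, alts, gt, dp, info)
}
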