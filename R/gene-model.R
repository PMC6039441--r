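#' Construct a gene model
#'
#' A gene model is a single-transcript CDS structure: an ordered set of
#' non-overlapping genomic intervals (1-based, inclusive, ascending
#' genome order) on one strand of one chromosome. All internal
#' coordinates in the package are 1-based inclusive; conversions happen
#' only at I/O boundaries.
#'
#' @param gene_id character scalar.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param cds_intervals two-column matrix (start, end), 1-based
#'   inclusive, sorted ascending, non-overlapping.
#' @param warnings character vector, subset of
#'   `c("incomplete_transcript", "multiple_stop_codons", "no_start_codon")`.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, cds_intervals,
                       warnings = character()) {
  stopifnot(is.character(gene_id), length(gene_id) == 1,
            strand %in% c("+", "-"))
  cds_intervals <- matrix(as.integer(cds_intervals), ncol = 2,
                          dimnames = list(NULL, c("start", "end")))
  if (any(cds_intervals[, "end"] < cds_intervals[, "start"]))
    stop("gene_model '", gene_id, "': interval end < start")
  o <- order(cds_intervals[, "start"])
  cds_intervals <- cds_intervals[o, , drop = FALSE]
  if (nrow(cds_intervals) > 1) {
    gaps <- cds_intervals[-1, "start"] - cds_intervals[-nrow(cds_intervals), "end"]
    if (any(gaps <= 0)) stop("gene_model '", gene_id, "': overlapping intervals")
  }
  known <- c("incomplete_transcript", "multiple_stop_codons", "no_start_codon")
  if (!all(warnings %in% known))
    stop("unknown warning: ", paste(setdiff(warnings, known), collapse = ", "))
  if (sum(cds_intervals[, "end"] - cds_intervals[, "start"] + 1L) <= 0)
    stop("gene_model '", gene_id, "': zero CDS length")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 cds_intervals = cds_intervals,
                 warnings = unique(warnings)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s %s:%s %s, %d exon(s), %d bp CDS%s>\n",
              x$gene_id, x$chrom,
              paste(range(x$cds_intervals), collapse = "-"), x$strand,
              nrow(x$cds_intervals), cds_length(x),
              if (length(x$warnings))
                paste0(", warnings: ", paste(x$warnings, collapse = ","))
              else ""))
  invisible(x)
}

#' Total CDS length of a gene model
#' @param gene a `gene_model`.
#' @return integer, summed interval lengths.
#' @export
cds_length <- function(gene) {
  sum(gene$cds_intervals[, "end"] - gene$cds_intervals[, "start"] + 1L)
}

# All genomic positions covered by the CDS, ascending.
cds_positions <- function(gene) {
  unlist(lapply(seq_len(nrow(gene$cds_intervals)), function(i)
    seq.int(gene$cds_intervals[i, "start"], gene$cds_intervals[i, "end"])))
}

#' Extract the spliced CDS sequence of a gene (5' to 3')
#'
#' @param gene a `gene_model`.
#' @param genome named character vector of chromosome sequences (as
#'   returned by [read_fasta()]).
#' @return character scalar: the coding sequence read 5' to 3' (reverse
#'   complemented for minus-strand genes).
#' @export
extract_cds <- function(gene, genome) {
  chrom_seq <- genome[[gene$chrom]]
  if (is.null(chrom_seq)) stop("chromosome not in genome: ", gene$chrom)
  if (max(gene$cds_intervals) > nchar(chrom_seq))
    stop("gene '", gene$gene_id, "' extends past end of ", gene$chrom)
  parts <- apply(gene$cds_intervals, 1, function(iv)
    substr(chrom_seq, iv[1], iv[2]))
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") s <- revcomp(s)
  s
}

# Reverse complement via Biostrings (handles only ACGTN here).
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Map a genomic position to a 0-based offset within the spliced CDS
# (5' end = 0). Returns NA if the position is not in the CDS.
cds_offset <- function(gene, pos) {
  iv <- gene$cds_intervals
  cum <- c(0L, cumsum(iv[, "end"] - iv[, "start"] + 1L))
  hit <- which(pos >= iv[, "start"] & pos <= iv[, "end"])
  if (length(hit) == 0) return(NA_integer_)
  plus_offset <- cum[hit] + (pos - iv[hit, "start"])
  if (gene$strand == "+") plus_offset
  else cds_length(gene) - 1L - plus_offset
}

#' Compute SnpEff-style structural warnings for gene models
#'
#' Inspects each model's CDS against the genome sequence and attaches
#' warnings: `incomplete_transcript` (CDS length not divisible by 3),
#' `no_start_codon` (first codon is not ATG), `multiple_stop_codons`
#' (more than one stop codon in the translation; a healthy model carries
#' exactly one terminal stop).
#'
#' @param genes list of `gene_model`s.
#' @param genome named character vector of chromosome sequences.
#' @return the list with `warnings` fields filled in.
#' @export
annotate_gene_warnings <- function(genes, genome) {
  lapply(genes, function(g) {
    w <- character()
    s <- extract_cds(g, genome)
    if (nchar(s) %% 3 != 0) {
      w <- c(w, "incomplete_transcript")
    } else {
      aa <- translate_cds(s)
      if (sum(strsplit(aa, "")[[1]] == "*") > 1)
        w <- c(w, "multiple_stop_codons")
    }
    if (toupper(substr(s, 1, 3)) != "ATG") w <- c(w, "no_start_codon")
    g$warnings <- w
    g
  })
}

# Translate a CDS (length divisible by 3) with the standard nuclear
# genetic code; stops as "*".
translate_cds <- function(s) {
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X"))
}

# Single-codon lookup, standard code.
codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}
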