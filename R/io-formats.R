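#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector, one uppercased sequence per header
#'   (first whitespace-delimited token of the header is the id), in file
#'   order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1])
  if (any(Biostrings::width(ss) == 0)) {
    stop("empty sequence for id: ", ids[which(Biostrings::width(ss) == 0)[1]])
  }
  out <- toupper(as.character(ss))
  names(out) <- ids
  out
}

#' Write a named character vector as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Construct a single variant record
#'
#' The in-memory unit consumed by filtering, annotation and MK-table
#' construction. Genotypes are diploid allele-index pairs (0 = REF,
#' k = k-th ALT, NA = missing).
#'
#' @param chrom chromosome. @param pos 1-based position.
#' @param ref reference allele. @param alts character vector of ALT
#'   alleles.
#' @param gt integer matrix, samples x 2, allele indices (NA missing).
#' @param dp per-sample read depth (non-negative).
#' @param info named numeric vector of site metrics (e.g. QD, FS, MQ);
#'   absent metrics are treated as passing by the filters.
#' @return object of class `variant_record`.
#' @export
variant_record <- function(chrom, pos, ref, alts, gt, dp,
                           info = numeric()) {
  gt <- matrix(as.integer(gt), ncol = 2)
  stopifnot(pos >= 1, nchar(ref) >= 1, length(alts) >= 1,
            nrow(gt) >= 1, length(dp) == nrow(gt), all(dp >= 0, na.rm = TRUE))
  if (any(gt > length(alts), na.rm = TRUE))
    stop("genotype allele index exceeds ALT count at ", chrom, ":", pos)
  structure(list(chrom = chrom, pos = as.integer(pos),
                 ref = toupper(ref), alts = toupper(alts),
                 gt = gt, dp = as.numeric(dp), info = info),
            class = "variant_record")
}

#' @export
print.variant_record <- function(x, ...) {
  cat(sprintf("<variant %s:%d %s>%s, %d sample(s)\n", x$chrom, x$pos,
              x$ref, paste(x$alts, collapse = ","), nrow(x$gt)))
  invisible(x)
}

# TRUE if the record is a single-nucleotide variant.
is_snv <- function(rec) {
  nchar(rec$ref) == 1 && all(nchar(rec$alts) == 1) &&
    all(strsplit(paste(c(rec$ref, rec$alts), collapse = ""), "")[[1]] %in%
          c("A", "C", "G", "T"))
}

#' Read a VCF file into a list of variant records
#'
#' Parses a VCF v4.x text file via \pkg{vcfR}. Multi-allelic ALTs are
#' retained as a list (the triallelic filter acts later); missing
#' genotypes (`./.`) are represented as NA allele indices, never an
#' error. Indels are ingested untouched; [apply_site_filters()] and the
#' annotation layer only consume SNVs.
#'
#' @param path VCF file (plain text).
#' @return list of `variant_record`s, in file order.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) return(list())
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp_raw <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  info_fields <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR")
  info_mat <- sapply(info_fields, function(f)
    suppressWarnings(vcfR::extract.info(v, element = f, as.numeric = TRUE)))
  if (is.null(dim(info_mat))) info_mat <- matrix(info_mat, nrow = n,
                                                 dimnames = list(NULL, info_fields))
  n_samples <- ncol(v@gt) - 1L
  lapply(seq_len(n), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    gts <- gt_raw[i, ]
    if (length(gts) != n_samples)
      stop("sample count mismatch at line ", i)
    gt <- t(vapply(gts, function(g) {
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(c(NA_integer_, NA_integer_))
      parts <- strsplit(g, "[/|]")[[1]]
      if (length(parts) == 1) parts <- c(parts, parts) # haploid call
      if (length(parts) != 2) stop("malformed genotype '", g, "' at line ", i)
      suppressWarnings(ai <- as.integer(ifelse(parts == ".", NA, parts)))
      ai
    }, integer(2)))
    dp <- dp_raw[i, ]
    dp[is.na(dp)] <- 0
    info <- info_mat[i, ]
    info <- info[!is.na(info)]
    variant_record(fix[i, "CHROM"], as.integer(fix[i, "POS"]),
                   fix[i, "REF"], alts, gt, dp, info)
  })
}

#' Write variant records as a minimal VCF v4.2 file
#'
#' Emits CHROM..FORMAT plus GT:DP per sample and the site metrics in
#' INFO. Companion writer for the synthetic-data generators; round-trips
#' through [read_vcf()].
#'
#' @param records list of `variant_record`s.
#' @param path output file.
#' @param sample_names sample column names.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample_names = NULL) {
  n_samples <- if (length(records)) nrow(records[[1]]$gt) else 0L
  if (is.null(sample_names))
    sample_names <- sprintf("sample%02d", seq_len(n_samples))
  stopifnot(length(sample_names) == n_samples)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mkgamma",
           '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
           '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias">',
           '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
           '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="MQ rank sum">',
           '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read pos rank sum">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_names), collapse = "\t"))
  body <- vapply(records, function(r) {
    info <- if (length(r$info))
      paste(sprintf("%s=%s", names(r$info), format(r$info, trim = TRUE)),
            collapse = ";") else "."
    gts <- apply(r$gt, 1, function(a)
      paste(ifelse(is.na(a), ".", a), collapse = "/"))
    samp <- paste(gts, round(r$dp), sep = ":")
    paste(c(r$chrom, r$pos, ".", r$ref, paste(r$alts, collapse = ","),
            ".", ".", info, "GT:DP", samp), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' CDS features are grouped into one model per gene using the `ID`
#' attribute (falling back to `Parent`). GFF's 1-based inclusive
#' coordinates are kept as-is (the internal convention).
#'
#' @param path GFF3 file.
#' @return list of `gene_model`s (warnings empty; attach with
#'   [annotate_gene_warnings()]).
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  ids <- as.character(gr$ID)
  if (all(is.na(ids)) && !is.null(gr$Parent))
    ids <- vapply(gr$Parent, function(p) as.character(p)[1], character(1))
  if (anyNA(ids)) stop("CDS feature without ID/Parent attribute")
  split_idx <- split(seq_along(gr), ids)
  out <- lapply(names(split_idx), function(gid) {
    idx <- split_idx[[gid]]
    strand <- unique(as.character(GenomicRanges::strand(gr[idx])))
    if (length(strand) != 1 || !strand %in% c("+", "-"))
      stop("gene '", gid, "': unknown or mixed strand")
    gene_model(gid,
               as.character(GenomicRanges::seqnames(gr[idx]))[1],
               strand,
               cbind(GenomicRanges::start(gr[idx]),
                     GenomicRanges::end(gr[idx])))
  })
  names(out) <- names(split_idx)
  out
}

#' Write gene models as GFF3
#' @param genes list of `gene_model`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes) {
    iv <- g$cds_intervals
    lines <- c(lines,
               sprintf("%s\tmkgamma\tgene\t%d\t%d\t.\t%s\t.\tID=%s_gene",
                       g$chrom, min(iv), max(iv), g$strand, g$gene_id),
               sprintf("%s\tmkgamma\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;Parent=%s_gene",
                       g$chrom, iv[, "start"], iv[, "end"], g$strand,
                       g$gene_id, g$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file into 1-based inclusive intervals
#'
#' BED's 0-based half-open coordinates are converted to the internal
#' 1-based inclusive convention: `(start0, end0]` becomes
#' `[start0 + 1, end0]`.
#'
#' @param path BED file (>= 3 columns).
#' @return data.frame with columns chrom, start, end (1-based inclusive).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (any(df[[3]] < df[[2]])) stop("BED interval with end < start")
  data.frame(chrom = as.character(df[[1]]),
             start = as.integer(df[[2]]) + 1L,
             end = as.integer(df[[3]]),
             stringsAsFactors = FALSE)
}

#' Write 1-based inclusive intervals as BED
#' @param intervals data.frame chrom/start/end, 1-based inclusive.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  utils::write.table(
    data.frame(intervals$chrom, intervals$start - 1L, intervals$end),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a TSV table with a header row
#'
#' `read_table` optionally checks that a set of schema columns is
#' present; `write_table` then round-trips those columns exactly.
#'
#' @param path TSV file.
#' @param schema optional character vector of required column names.
#' @return data.frame.
#' @export
read_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    missing <- setdiff(schema, names(df))
    if (length(missing))
      stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' @rdname read_table
#' @param rows data.frame to write.
#' @export
write_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
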