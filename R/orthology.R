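#' Best hits per query from a protein-similarity table
#'
#' Deduplicates hits on (query, subject) keeping the maximum bitscore,
#' discards hits with E-value above the threshold, and returns for each
#' query the set of subjects attaining its maximum bitscore. Tied best
#' hits are all retained (multiple best matches are considered;
#' reciprocity decides later).
#'
#' @param hits data.frame with query_id, subject_id, evalue, bitscore.
#' @param threshold_evalue inclusive E-value cutoff (default 1e-10).
#' @return named list: query -> character vector of best subjects.
#' @export
best_hits <- function(hits, threshold_evalue = 1e-10) {
  stopifnot(all(c("query_id", "subject_id", "evalue", "bitscore") %in%
                  names(hits)))
  if (nrow(hits) == 0) return(list())
  stopifnot(all(hits$evalue >= 0), all(hits$bitscore > 0))
  # dedupe (query, subject) on max bitscore
  o <- order(hits$query_id, hits$subject_id, -hits$bitscore)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(hits[, c("query_id", "subject_id")]), ,
               drop = FALSE]
  hits <- hits[hits$evalue <= threshold_evalue, , drop = FALSE]
  if (nrow(hits) == 0) return(list())
  out <- lapply(split(hits, hits$query_id), function(h)
    sort(h$subject_id[h$bitscore == max(h$bitscore)]))
  out[order(names(out))]
}

#' Reciprocal-best-hit ortholog map between two species
#'
#' A pair (a, b) is an ortholog candidate iff b is among a's best hits
#' and a is among b's best hits. Bitscore ties can produce one-to-many
#' candidates; all reciprocal candidates are kept and flagged
#' ambiguous, and downstream set statistics count genes rather than
#' pairs.
#'
#' @param best_ab,best_ba outputs of [best_hits()] for the A->B and
#'   B->A searches.
#' @param threshold_evalue recorded on the result.
#' @return object of class `ortholog_map`: data.frame(gene_a, gene_b,
#'   ambiguous) with the threshold as an attribute.
#' @export
reciprocal_best <- function(best_ab, best_ba, threshold_evalue = 1e-10) {
  pairs <- list()
  for (a in names(best_ab)) {
    for (b in best_ab[[a]]) {
      if (!is.null(best_ba[[b]]) && a %in% best_ba[[b]])
        pairs[[length(pairs) + 1]] <- c(a, b)
    }
  }
  if (length(pairs) == 0) {
    df <- data.frame(gene_a = character(), gene_b = character(),
                     ambiguous = logical(), stringsAsFactors = FALSE)
  } else {
    m <- do.call(rbind, pairs)
    df <- data.frame(gene_a = m[, 1], gene_b = m[, 2],
                     stringsAsFactors = FALSE)
    df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
    df$ambiguous <- df$gene_a %in% df$gene_a[duplicated(df$gene_a)] |
      df$gene_b %in% df$gene_b[duplicated(df$gene_b)]
    rownames(df) <- NULL
  }
  structure(df, class = c("ortholog_map", "data.frame"),
            threshold_evalue = threshold_evalue)
}

#' Cycle-consistent three-way ortholog sets
#'
#' A triple (a, b, c) is retained iff (a, b), (b, c) and (a, c) are all
#' present in the respective pairwise reciprocal-best maps. Genes
#' entering more than one triple (via tied best hits) are flagged
#' ambiguous.
#'
#' @param map_ab,map_bc,map_ac `ortholog_map`s for A-B, B-C and A-C.
#' @return data.frame(gene_a, gene_b, gene_c, ambiguous).
#' @export
threeway_orthologs <- function(map_ab, map_bc, map_ac) {
  ac_key <- paste(map_ac$gene_a, map_ac$gene_b, sep = "\r")
  rows <- list()
  for (i in seq_len(nrow(map_ab))) {
    a <- map_ab$gene_a[i]; b <- map_ab$gene_b[i]
    cs <- map_bc$gene_b[map_bc$gene_a == b]
    for (cc in cs) {
      if (paste(a, cc, sep = "\r") %in% ac_key)
        rows[[length(rows) + 1]] <- c(a, b, cc)
    }
  }
  if (length(rows) == 0)
    return(data.frame(gene_a = character(), gene_b = character(),
                      gene_c = character(), ambiguous = logical(),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, rows)
  df <- data.frame(gene_a = m[, 1], gene_b = m[, 2], gene_c = m[, 3],
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b, df$gene_c), , drop = FALSE]
  df$ambiguous <- df$gene_a %in% df$gene_a[duplicated(df$gene_a)] |
    df$gene_b %in% df$gene_b[duplicated(df$gene_b)] |
    df$gene_c %in% df$gene_c[duplicated(df$gene_c)]
  rownames(df) <- NULL
  df
}
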