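#' Draw gene-specific scaled selection coefficients from a mixture
#'
#' Two-component mixture emulating a genome where most genes evolve
#' neutrally or under weak purifying selection and a minority is under
#' positive selection: with probability `1 - frac_positive`,
#' gamma ~ Normal(-2, 1.5); with probability `frac_positive`,
#' gamma ~ shift + Exponential(mean 3). With the defaults
#' (`frac_positive = 0.12`, `shift = 0`) the analytic share of genes
#' with gamma > 1 is about 10.6%, comparable to empirical estimates in
#' social insects.
#'
#' @param n_genes number of genes.
#' @param frac_positive mixture weight of the positive component.
#' @param seed RNG seed.
#' @param shift location shift of the exponential component.
#' @return numeric vector of gamma values. Attribute
#'   `"p_gt1_analytic"` carries the exact mixture P(gamma > 1).
#' @export
simulate_gamma_mixture <- function(n_genes, frac_positive = 0.12, seed = 1,
                                   shift = 0) {
  stopifnot(frac_positive >= 0, frac_positive <= 1, n_genes >= 1)
  set.seed(seed)
  pos <- stats::runif(n_genes) < frac_positive
  gamma <- numeric(n_genes)
  gamma[!pos] <- stats::rnorm(sum(!pos), mean = -2, sd = 1.5)
  gamma[pos] <- shift + stats::rexp(sum(pos), rate = 1 / 3)
  p_gt1 <- frac_positive *
    stats::pexp(pmax(1 - shift, 0), rate = 1 / 3, lower.tail = FALSE) +
    (1 - frac_positive) * stats::pnorm(1, -2, 1.5, lower.tail = FALSE)
  if (shift >= 1) p_gt1 <- frac_positive + (1 - frac_positive) *
      stats::pnorm(1, -2, 1.5, lower.tail = FALSE)
  attr(gamma, "p_gt1_analytic") <- p_gt1
  gamma
}

#' Simulation truth parameters for the PRF count generator
#'
#' Holds the gene-level ground truth the count generator draws from.
#' Defaults mirror a two-species resequencing design with ten diploid
#' focal samples (n = 20 haploid) and two diploid outgroup samples
#' (n = 4 haploid), a non-synonymous/synonymous opportunity ratio
#' z = 2.5, divergence scale d = 1, and synonymous intensities
#' theta_s drawn log-normally (median 6, sdlog 1.2) to emulate the
#' spread of gene CDS lengths.
#'
#' @param gamma_true numeric vector of scaled selection coefficients.
#' @param theta_s synonymous polymorphism intensity per gene (recycled).
#' @param d divergence intensity multiplier (recycled).
#' @param z non-synonymous/synonymous opportunity ratio (recycled).
#' @param n_focal,n_outgroup haploid sample sizes.
#' @return object of class `simulation_truth` (a data.frame plus sizes).
#' @export
simulation_truth <- function(gamma_true, theta_s, d = 1, z = 2.5,
                             n_focal = 20, n_outgroup = 4) {
  stopifnot(all(theta_s > 0), all(d > 0), all(z > 0),
            n_focal >= 2, n_outgroup >= 2)
  g <- length(gamma_true)
  df <- data.frame(gene_id = sprintf("g%04d", seq_len(g)),
                   gamma_true = gamma_true,
                   theta_s = rep_len(theta_s, g),
                   d = rep_len(d, g), z = rep_len(z, g),
                   stringsAsFactors = FALSE)
  structure(list(genes = df, n_focal = n_focal, n_outgroup = n_outgroup),
            class = "simulation_truth")
}

#' Simulate per-gene MK count tables under the PRF model
#'
#' Generates, for gene i with truth (gamma_i, theta_i, d_i, z_i):
#' \deqn{PS \sim Pois(\theta_i), \quad
#'   PN \sim Pois(\theta_i z_i Qratio(\gamma_i, n)),}
#' \deqn{DS \sim Pois(\theta_i d_i), \quad
#'   DN \sim Pois(\theta_i d_i z_i H(\gamma_i)).}
#' This is exactly the generative counterpart of the hierarchical
#' model's PRF link, so parameter recovery is well-posed. Identical
#' seeds give identical tables.
#'
#' @param truth a [simulation_truth()] (or NULL to build one).
#' @param n_genes used only when `truth` is NULL: number of genes, with
#'   gammas from [simulate_gamma_mixture()] and log-normal theta_s.
#' @param seed RNG seed.
#' @param frac_positive passed to the gamma mixture when building truth.
#' @return list(tables = MK data.frame, truth = gene-level truth
#'   data.frame, n_focal, n_outgroup).
#' @export
simulate_mk_counts <- function(truth = NULL, n_genes = 500, seed = 1,
                               frac_positive = 0.12) {
  if (is.null(truth)) {
    gamma <- simulate_gamma_mixture(n_genes, frac_positive, seed = seed)
    set.seed(seed + 1L)
    theta <- stats::rlnorm(n_genes, meanlog = log(6), sdlog = 1.2)
    truth <- simulation_truth(gamma, theta)
  }
  stopifnot(inherits(truth, "simulation_truth"))
  tg <- truth$genes
  n <- truth$n_focal
  q0 <- prf_Q(0, n)
  qr <- vapply(tg$gamma_true, function(g) prf_Q(g, n) / q0, numeric(1))
  h <- prf_H(tg$gamma_true)
  rates <- cbind(PS = tg$theta_s,
                 PN = tg$theta_s * tg$z * qr,
                 DS = tg$theta_s * tg$d,
                 DN = tg$theta_s * tg$d * tg$z * h)
  if (any(!is.finite(rates))) {
    bad <- tg$gene_id[which(rowSums(!is.finite(rates)) > 0)[1]]
    stop("non-finite Poisson rate for gene ", bad)
  }
  set.seed(seed + 2L)
  counts <- matrix(stats::rpois(length(rates), as.vector(rates)),
                   ncol = 4, dimnames = list(NULL, colnames(rates)))
  tables <- data.frame(gene_id = tg$gene_id,
                       PN = counts[, "PN"], PS = counts[, "PS"],
                       DN = counts[, "DN"], DS = counts[, "DS"],
                       stringsAsFactors = FALSE)
  list(tables = tables, truth = tg, n_focal = truth$n_focal,
       n_outgroup = truth$n_outgroup)
}

#' Simulate a caste differential-expression results table
#'
#' Emulates a queen/worker DE table thresholded at FDR < 0.05 and
#' FPKM > 1: biased genes receive a sub-threshold FDR and expression
#' above 1 in the biased direction; the rest receive either a
#' non-significant FDR or sub-threshold expression. A small number of
#' loci can be flagged as merge conflicts (ambiguous after transcript
#' merging), which the classifier must drop.
#'
#' @param n_genes total genes.
#' @param n_queen_biased,n_worker_biased planted label counts.
#' @param seed RNG seed.
#' @param n_merge_conflict genes flagged as merge conflicts (drawn from
#'   the non-DEG pool).
#' @param gene_ids optional ids (default g0001..).
#' @return list(expression = data.frame(gene_id, fdr, fpkm_queen,
#'   fpkm_worker, merge_conflict), labels = data.frame(gene_id, label)).
#' @export
simulate_expression <- function(n_genes, n_queen_biased, n_worker_biased,
                                seed = 1, n_merge_conflict = 0,
                                gene_ids = NULL) {
  stopifnot(n_queen_biased + n_worker_biased + n_merge_conflict <= n_genes)
  set.seed(seed)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(n_genes))
  label <- rep("non_deg", n_genes)
  label[seq_len(n_queen_biased)] <- "queen_biased"
  label[n_queen_biased + seq_len(n_worker_biased)] <- "worker_biased"
  perm <- sample.int(n_genes)
  gene_ids <- gene_ids[perm] # decouple label from id order
  fdr <- stats::runif(n_genes, 0.05, 1)
  fq <- stats::rlnorm(n_genes, log(5), 1)
  fw <- stats::rlnorm(n_genes, log(5), 1)
  qb <- label == "queen_biased"
  wb <- label == "worker_biased"
  fdr[qb | wb] <- stats::runif(sum(qb | wb), 0, 0.049)
  fq[qb] <- pmax(fw[qb], 1.01) * stats::runif(sum(qb), 1.5, 4)
  fw[wb] <- pmax(fq[wb], 1.01) * stats::runif(sum(wb), 1.5, 4)
  # some non-DEGs are "significant" but below the FPKM floor
  nd <- which(!qb & !wb)
  low <- nd[seq_len(min(length(nd), max(1, n_genes %/% 20)))]
  fdr[low] <- stats::runif(length(low), 0, 0.049)
  fq[low] <- stats::runif(length(low), 0, 0.9)
  fw[low] <- stats::runif(length(low), 0, 0.9)
  conflict <- rep(FALSE, n_genes)
  if (n_merge_conflict > 0) {
    pool <- setdiff(nd, low)
    conflict[pool[seq_len(n_merge_conflict)]] <- TRUE
  }
  expr <- data.frame(gene_id = gene_ids, fdr = fdr, fpkm_queen = fq,
                     fpkm_worker = fw, merge_conflict = conflict,
                     stringsAsFactors = FALSE)
  labels <- data.frame(gene_id = gene_ids[!conflict],
                       label = label[!conflict], stringsAsFactors = FALSE)
  list(expression = expr, labels = labels)
}

#' Simulate reciprocal protein-similarity hit tables
#'
#' Builds blastp-outfmt6-like hit tables between species A and B with a
#' known reciprocal-best-hit structure: `n_shared` true ortholog pairs
#' (mutual best hits with E-value <= 1e-10) plus decoys - one-sided
#' best hits, hits above the E-value threshold, and optionally a
#' tied-bitscore second-best partner that reciprocity must reject.
#'
#' @param n_shared true ortholog pairs.
#' @param n_a_only,n_b_only species-private genes whose best hits are
#'   one-directional or above threshold.
#' @param seed RNG seed.
#' @param tie_pairs how many shared pairs also receive a tied-bitscore
#'   decoy subject in the A->B direction.
#' @return list(hits_ab, hits_ba = data.frames(query_id, subject_id,
#'   evalue, bitscore), true_pairs = data.frame(gene_a, gene_b)).
#' @export
simulate_hit_tables <- function(n_shared, n_a_only = 0, n_b_only = 0,
                                seed = 1, tie_pairs = 0) {
  set.seed(seed)
  stopifnot(tie_pairs <= n_shared)
  a_shared <- sprintf("A_%04d", seq_len(n_shared))
  b_shared <- sprintf("B_%04d", seq_len(n_shared))
  mk_hit <- function(q, s, e, b) data.frame(
    query_id = q, subject_id = s, evalue = e, bitscore = b,
    stringsAsFactors = FALSE)
  hits_ab <- list(); hits_ba <- list()
  if (n_shared > 0) {
    best_bits <- round(stats::runif(n_shared, 150, 400))
    hits_ab[[length(hits_ab) + 1]] <-
      mk_hit(a_shared, b_shared, 10^-stats::runif(n_shared, 20, 100), best_bits)
    hits_ba[[length(hits_ba) + 1]] <-
      mk_hit(b_shared, a_shared, 10^-stats::runif(n_shared, 20, 100), best_bits)
    # weaker secondary hits to a shifted partner
    sec <- c(b_shared[-1], b_shared[1])
    hits_ab[[length(hits_ab) + 1]] <-
      mk_hit(a_shared, sec, 10^-stats::runif(n_shared, 11, 15),
             pmax(best_bits - 80, 40))
  }
  if (tie_pairs > 0) {
    # tied decoy: same bitscore as the true best, but not reciprocated
    idx <- seq_len(tie_pairs)
    decoy <- sprintf("B_tie%03d", idx)
    hits_ab[[length(hits_ab) + 1]] <-
      mk_hit(a_shared[idx], decoy, 1e-40, hits_ab[[1]]$bitscore[idx])
    hits_ba[[length(hits_ba) + 1]] <- # decoy's own best is elsewhere
      mk_hit(decoy, sprintf("A_%04d", (idx %% max(n_shared, 1)) + 1L),
             1e-60, 500)
  }
  if (n_a_only > 0) {
    a_only <- sprintf("Aonly_%03d", seq_len(n_a_only))
    half <- n_a_only %/% 2
    if (half > 0) # one-directional best: B never hits back
      hits_ab[[length(hits_ab) + 1]] <-
        mk_hit(a_only[seq_len(half)],
               sprintf("B_decoy%03d", seq_len(half)), 1e-30, 120)
    if (n_a_only > half) # above-threshold E-value
      hits_ab[[length(hits_ab) + 1]] <-
        mk_hit(a_only[(half + 1):n_a_only],
               sprintf("B_weak%03d", seq_len(n_a_only - half)), 1e-5, 45)
  }
  if (n_b_only > 0) {
    b_only <- sprintf("Bonly_%03d", seq_len(n_b_only))
    hits_ba[[length(hits_ba) + 1]] <-
      mk_hit(b_only, sprintf("A_decoy%03d", seq_len(n_b_only)), 1e-25, 110)
  }
  empty <- data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE)
  list(hits_ab = if (length(hits_ab)) do.call(rbind, hits_ab) else empty,
       hits_ba = if (length(hits_ba)) do.call(rbind, hits_ba) else empty,
       true_pairs = data.frame(gene_a = a_shared, gene_b = b_shared,
                               stringsAsFactors = FALSE))
}
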