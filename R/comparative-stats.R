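# Cross-species and caste-bias statistical battery.

#' Classify genes as queen-biased, worker-biased or non-DEG
#'
#' Threshold rule on a differential-expression results table: after
#' dropping merge-conflicted loci, a gene is queen-biased iff
#' FDR < 0.05, queen FPKM > 1 and queen FPKM exceeds worker FPKM;
#' worker-biased symmetrically; everything else is non-DEG.
#'
#' @param rows data.frame with gene_id, fdr, fpkm_queen, fpkm_worker
#'   and optionally merge_conflict.
#' @return data.frame(gene_id, label) with label in
#'   queen_biased/worker_biased/non_deg.
#' @export
classify_caste_bias <- function(rows) {
  stopifnot(all(c("gene_id", "fdr", "fpkm_queen", "fpkm_worker") %in%
                  names(rows)))
  stopifnot(all(rows$fdr >= 0 & rows$fdr <= 1))
  if ("merge_conflict" %in% names(rows))
    rows <- rows[!rows$merge_conflict, , drop = FALSE]
  sig <- rows$fdr < 0.05
  queen <- sig & rows$fpkm_queen > 1 & rows$fpkm_queen > rows$fpkm_worker
  worker <- sig & rows$fpkm_worker > 1 & rows$fpkm_worker > rows$fpkm_queen
  label <- ifelse(queen, "queen_biased",
                  ifelse(worker, "worker_biased", "non_deg"))
  data.frame(gene_id = rows$gene_id, label = label,
             stringsAsFactors = FALSE)
}

#' Overlap enrichment of two gene sets by one-tailed Fisher test
#'
#' Cross-classifies the universe by membership in A and B and tests for
#' over-representation of the overlap with the upper-tail
#' hypergeometric probability P(X >= observed overlap).
#'
#' @param set_a,set_b character vectors of gene ids (subsets of
#'   `universe`).
#' @param universe character vector, the eligible genes (e.g. orthologs
#'   with selection estimates in both species).
#' @return list(table 2x2, overlap, odds_ratio, p_value, test = "fisher
#'   one-tail"); an empty set gives p = 1 and an undefined odds ratio.
#' @export
overlap_fisher <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("sets must be subsets of the universe")
  N <- length(universe)
  ka <- length(set_a); kb <- length(set_b)
  k <- length(intersect(set_a, set_b))
  tab <- matrix(c(k, kb - k, ka - k, N - ka - kb + k), nrow = 2,
                dimnames = list(in_a = c("yes", "no"),
                                in_b = c("yes", "no")))
  if (ka == 0 || kb == 0)
    return(list(table = tab, overlap = k, odds_ratio = NA_real_,
                p_value = 1, test = "fisher one-tail"))
  p <- stats::phyper(k - 1, ka, N - ka, kb, lower.tail = FALSE)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(table = tab, overlap = k, odds_ratio = or, p_value = p,
       test = "fisher one-tail")
}

#' Compare two proportions
#'
#' Builds the 2x2 table `[[k1, n1 - k1], [k2, n2 - k2]]` and tests
#' equality of proportions by Pearson chi-squared (with or without the
#' Yates continuity correction) or Fisher's exact test. The default is
#' the uncorrected Pearson chi-squared,
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.
#'
#' @param k1,n1,k2,n2 successes and totals in the two groups.
#' @param method "chisq", "chisq_yates" or "fisher".
#' @return list(statistic, df, p_value, odds_ratio, method).
#' @export
compare_two_proportions <- function(k1, n1, k2, n2,
                                    method = c("chisq", "chisq_yates",
                                               "fisher")) {
  method <- match.arg(method)
  stopifnot(k1 <= n1, k2 <= n2, k1 >= 0, k2 >= 0)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (method == "fisher") {
    ft <- stats::fisher.test(tab)
    return(list(statistic = NA_real_, df = NA_integer_,
                p_value = ft$p.value,
                odds_ratio = unname(ft$estimate), method = method))
  }
  ct <- suppressWarnings(
    stats::chisq.test(tab, correct = method == "chisq_yates"))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, odds_ratio = or, method = method)
}

#' Three-way gene-set overlap against independence
#'
#' Cross-classifies the universe into the 8 cells of (in A) x (in B) x
#' (in C) and compares observed counts to the expectations under
#' mutual independence of the three memberships (margins estimated
#' from the data), with a chi-squared statistic on
#' df = 8 - 1 - 3 = 4. Also reports the observed triple overlap and
#' its independence expectation N (|A|/N)(|B|/N)(|C|/N).
#'
#' @inheritParams overlap_fisher
#' @param set_c third gene set.
#' @return list(observed = triple-overlap count, expected, chi2, df,
#'   p_value, cells = 2x2x2 observed table).
#' @export
threeway_overlap_test <- function(set_a, set_b, set_c, universe) {
  universe <- unique(universe)
  N <- length(universe)
  ina <- universe %in% set_a
  inb <- universe %in% set_b
  inc <- universe %in% set_c
  obs <- table(factor(ina, c(FALSE, TRUE)), factor(inb, c(FALSE, TRUE)),
               factor(inc, c(FALSE, TRUE)))
  pa <- mean(ina); pb <- mean(inb); pc <- mean(inc)
  pmarg <- function(p, dim) if (dim) p else 1 - p
  exp_cells <- array(0, dim = c(2, 2, 2))
  for (i in 0:1) for (j in 0:1) for (k in 0:1)
    exp_cells[i + 1, j + 1, k + 1] <-
      N * pmarg(pa, i) * pmarg(pb, j) * pmarg(pc, k)
  # a cell with zero expectation under independence can only hold zero
  # observations (a degenerate margin); it contributes nothing
  terms <- (obs - exp_cells)^2 / exp_cells
  chi2 <- sum(terms[exp_cells > 0])
  df <- 4L
  list(observed = sum(ina & inb & inc), expected = N * pa * pb * pc,
       chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       cells = obs)
}

#' Mean selection coefficient by caste-bias class
#'
#' One-way fixed-effects ANOVA of per-gene gamma across caste classes
#' (queen-biased, worker-biased, non-DEG) followed by Tukey-Kramer HSD
#' pairwise comparisons (exact for unequal group sizes), plus group
#' means with standard errors.
#'
#' @param estimates data.frame with gene_id and gamma (NA gammas are
#'   dropped).
#' @param labels data.frame with gene_id and label.
#' @return list(groups = data.frame(label, n, mean, sem), anova_F,
#'   df1, df2, anova_p, tukey = data.frame(comparison, diff, p_adj)).
#' @export
gamma_by_class <- function(estimates, labels) {
  d <- merge(estimates[, c("gene_id", "gamma")], labels, by = "gene_id")
  d <- d[!is.na(d$gamma), , drop = FALSE]
  tab <- table(d$label)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 members")
  d$label <- factor(d$label)
  groups <- do.call(rbind, lapply(split(d$gamma, d$label), function(x)
    data.frame(n = length(x), mean = mean(x),
               sem = stats::sd(x) / sqrt(length(x)))))
  groups <- cbind(label = rownames(groups), groups)
  rownames(groups) <- NULL
  fit <- stats::aov(gamma ~ label, data = d)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$label
  list(groups = groups,
       anova_F = s[1, "F value"], df1 = s[1, "Df"], df2 = s[2, "Df"],
       anova_p = s[1, "Pr(>F)"],
       tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE))
}

# round half away from zero to `digits` decimals (display convention
# for reported percentages; R's round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Fraction of positively selected genes per caste class
#'
#' For each class, counts members of `positive_set` and reports the
#' percentage 100 k / n rounded half-up to one decimal (the display
#' convention for reported percentages).
#'
#' @param labels data.frame(gene_id, label).
#' @param positive_set character vector of positively selected gene
#'   ids.
#' @return data.frame(label, k, n, percent).
#' @export
positive_fraction <- function(labels, positive_set) {
  out <- do.call(rbind, lapply(split(labels$gene_id, labels$label),
                               function(g)
    data.frame(k = sum(g %in% positive_set), n = length(g))))
  out <- cbind(label = rownames(out), out)
  rownames(out) <- NULL
  out$percent <- round_half_up(100 * out$k / pmax(out$n, 1), 1)
  out
}
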