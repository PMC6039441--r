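# Caste classification, overlap enrichment, proportion tests, ANOVA.

test_that("caste labels follow the FDR/FPKM threshold rule", {
  rows <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    fdr = c(0.01, 0.2, 0.01, 0.04, 0.001),
    fpkm_queen = c(5, 50, 0.5, 2, 3),
    fpkm_worker = c(1.2, 1, 0.2, 9, 3.5),
    merge_conflict = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  lab <- classify_caste_bias(rows)
  expect_equal(lab$label[lab$gene_id == "a"], "queen_biased")
  expect_equal(lab$label[lab$gene_id == "b"], "non_deg") # fdr too high
  expect_equal(lab$label[lab$gene_id == "c"], "non_deg") # fpkm too low
  expect_equal(lab$label[lab$gene_id == "d"], "worker_biased")
  expect_false("e" %in% lab$gene_id) # merge conflict dropped
})

test_that("overlap enrichment equals exhaustive hypergeometric sums", {
  universe <- sprintf("u%03d", 1:100)
  res <- overlap_fisher(universe[1:30], universe[c(1:12, 60:67)], universe)
  expect_equal(res$overlap, 12)
  expect_equal(res$p_value, enum_hyper_upper(12, 30, 20, 100),
               tolerance = 1e-12)
  # random small universes
  set.seed(8)
  for (i in 1:25) {
    N <- sample(10:60, 1)
    u <- sprintf("g%02d", 1:N)
    a <- sample(u, sample(0:N, 1))
    b <- sample(u, sample(0:N, 1))
    res <- overlap_fisher(a, b, u)
    if (length(a) == 0 || length(b) == 0) {
      expect_equal(res$p_value, 1)
    } else {
      expect_equal(res$p_value,
                   enum_hyper_upper(res$overlap, length(a), length(b), N),
                   tolerance = 1e-12)
    }
  }
  # an overlap exactly at its independence expectation is unsurprising
  u <- sprintf("x%03d", 1:100)
  res <- overlap_fisher(u[1:20], u[c(1:4, 21:36)], u) # overlap 4 = 20*20/100
  expect_gt(res$p_value, 0.5)
})

test_that("two-proportion chi-squared equals the closed form", {
  set.seed(3)
  for (i in 1:20) {
    n1 <- sample(20:300, 1); n2 <- sample(20:300, 1)
    k1 <- sample(1:(n1 - 1), 1); k2 <- sample(1:(n2 - 1), 1)
    r <- compare_two_proportions(k1, n1, k2, n2, method = "chisq")
    expect_equal(r$statistic,
                 chisq_closed_form(k1, n1 - k1, k2, n2 - k2),
                 tolerance = 1e-10)
    expect_equal(r$df, 1)
  }
  # equal proportions: statistic 0, p 1
  r0 <- compare_two_proportions(10, 50, 20, 100)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # tiny symmetric table under Fisher
  rf <- compare_two_proportions(1, 2, 1, 2, method = "fisher")
  expect_equal(rf$p_value, 1)
  # the three conventions differ in the expected direction
  ry <- compare_two_proportions(22, 114, 32, 287, method = "chisq_yates")
  rp <- compare_two_proportions(22, 114, 32, 287, method = "chisq")
  expect_lt(ry$statistic, rp$statistic)
})

test_that("three-way overlap test is exact on degenerate input and monotone", {
  u <- sprintf("g%03d", 1:200)
  res <- threeway_overlap_test(u, u, u, u)
  expect_equal(res$observed, 200)
  expect_equal(res$expected, 200)
  expect_equal(res$chi2, 0)
  # enrichment scan: a larger planted triple overlap raises chi-squared
  set.seed(5)
  base <- lapply(1:3, function(i) sample(u, 60))
  chi <- vapply(c(0, 10, 20, 30), function(extra) {
    core <- u[1:extra]
    threeway_overlap_test(union(core, base[[1]]), union(core, base[[2]]),
                          union(core, base[[3]]), u)$chi2
  }, numeric(1))
  expect_true(all(diff(chi) > 0))
})

test_that("gamma-by-class ANOVA and Tukey match closed forms", {
  # identical group contents: no between-group variance at all
  est <- data.frame(gene_id = sprintf("g%02d", 1:12),
                    gamma = rep(c(1, 2, 3, 4), 3))
  lab <- data.frame(gene_id = est$gene_id,
                    label = rep(c("queen_biased", "worker_biased",
                                  "non_deg"), each = 4))
  r <- gamma_by_class(est, lab)
  expect_equal(r$anova_F, 0)
  expect_equal(r$anova_p, 1)
  # equal group sizes: Tukey-Kramer reduces to classic Tukey (ptukey)
  set.seed(11)
  est2 <- data.frame(gene_id = sprintf("h%03d", 1:60),
                     gamma = stats::rnorm(60))
  lab2 <- data.frame(gene_id = est2$gene_id,
                     label = rep(c("a", "b", "c"), each = 20))
  r2 <- gamma_by_class(est2, lab2)
  d <- merge(est2, lab2, by = "gene_id")
  fit <- stats::aov(gamma ~ label, data = d)
  mse <- summary(fit)[[1]][2, "Mean Sq"]
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    p_oracle <- tukey_pair_p(d$gamma[d$label == pair[1]],
                             d$gamma[d$label == pair[2]], mse, 57, 3)
    row <- grepl(pair[1], r2$tukey$comparison) &
      grepl(pair[2], r2$tukey$comparison)
    expect_equal(r2$tukey$p_adj[row], p_oracle, tolerance = 1e-10)
  }
})

test_that("a planted queen-ward shift is detected with high power", {
  # study-like group sizes and dispersions; +0.15 shift in queens
  sizes <- c(queen = 114, worker = 287, non_deg = 7211)
  sigma <- c(queen = 0.0493 * sqrt(114), worker = 0.0268 * sqrt(287),
             non_deg = 0.00517 * sqrt(7211))
  set.seed(17)
  n_rep <- 300
  hit <- logical(n_rep)
  ids <- sprintf("g%05d", seq_len(sum(sizes)))
  lab <- data.frame(gene_id = ids,
                    label = rep(names(sizes), sizes))
  for (r in seq_len(n_rep)) {
    gam <- c(stats::rnorm(sizes[1], 0.15, sigma[1]),
             stats::rnorm(sizes[2], 0, sigma[2]),
             stats::rnorm(sizes[3], 0, sigma[3]))
    res <- gamma_by_class(data.frame(gene_id = ids, gamma = gam), lab)
    row <- res$tukey$comparison == "queen-non_deg"
    hit[r] <- res$tukey$p_adj[row] < 0.05
  }
  expect_gte(mean(hit), 0.8)
})

test_that("positive fractions reproduce display-rounded percentages", {
  lab <- data.frame(
    gene_id = c(sprintf("q%03d", 1:114), sprintf("w%03d", 1:287),
                sprintf("n%03d", 1:10)),
    label = c(rep("queen_biased", 114), rep("worker_biased", 287),
              rep("non_deg", 10)))
  pos <- c(sprintf("q%03d", 1:22), sprintf("w%03d", 1:32))
  pf <- positive_fraction(lab, pos)
  expect_equal(pf$percent[pf$label == "queen_biased"], 19.3)
  expect_equal(pf$percent[pf$label == "worker_biased"], 11.1)
  expect_equal(pf$percent[pf$label == "non_deg"], 0)
  pf2 <- positive_fraction(
    data.frame(gene_id = sprintf("b%03d", 1:192),
               label = rep("worker_biased", 192)),
    sprintf("b%03d", 1:34))
  expect_equal(pf2$percent, 17.7)
})
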