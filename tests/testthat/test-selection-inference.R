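# MK statistics and the hierarchical selection model.

test_that("the MK Fisher test matches hypergeometric enumeration", {
  t1 <- list(PN = 2, PS = 42, DN = 7, DS = 17)
  r <- mk_fisher(t1)
  expect_equal(r$p_two_sided, enum_fisher_two_sided(7, 17, 2, 42),
               tolerance = 1e-10)
  expect_equal(r$p_two_sided, 0.007327, tolerance = 1e-4)
  bal <- mk_fisher(list(PN = 5, PS = 5, DN = 5, DS = 5))
  expect_equal(bal$p_two_sided, 1)
  expect_equal(bal$odds_ratio, 1, tolerance = 1e-9)
  z <- mk_fisher(list(PN = 0, PS = 0, DN = 0, DS = 0))
  expect_false(z$defined)
  # random spot checks across table shapes
  set.seed(1)
  for (i in 1:50) {
    tb <- as.list(stats::setNames(stats::rpois(4, 6),
                                  c("PN", "PS", "DN", "DS")))
    if (sum(unlist(tb)) == 0) next
    expect_equal(mk_fisher(tb)$p_two_sided,
                 enum_fisher_two_sided(tb$DN, tb$DS, tb$PN, tb$PS),
                 tolerance = 1e-9)
  }
})

test_that("neutrality index and alpha follow their definitions", {
  r <- neutrality_stats(list(PN = 2, PS = 42, DN = 7, DS = 17))
  expect_equal(r$NI, (2 / 42) / (7 / 17), tolerance = 1e-12)
  expect_equal(r$NI, 0.1156, tolerance = 1e-3)
  expect_equal(r$alpha, 1 - r$NI)
  expect_false(neutrality_stats(list(PN = 1, PS = 2, DN = 3, DS = 0))$defined)
  # under neutral simulation NI is centred near 1
  tr <- simulation_truth(rep(0, 4000), theta_s = 60, z = 1)
  sim <- simulate_mk_counts(truth = tr, seed = 3)
  nis <- vapply(seq_len(4000), function(i)
    neutrality_stats(sim$tables[i, ])$NI, numeric(1))
  expect_equal(mean(nis, na.rm = TRUE), 1, tolerance = 0.03)
})

test_that("per-gene PRF MLE recovers gamma from expected counts", {
  # plant the rounded expected counts at gamma = 2
  n <- 20; z <- 2.5; d <- 1; theta <- 40
  tb <- list(PS = round(theta), PN = round(theta * z * prf_Qratio(2, n)),
             DS = round(theta * d), DN = round(theta * d * z * prf_H(2)))
  est <- per_gene_prf_mle(tb, n, z, d)
  expect_lt(abs(est$gamma_mle - 2), 0.2)
  # neutral ratios give gamma ~ 0
  tb0 <- list(PS = 40, PN = 100, DS = 40, DN = 100)
  expect_lt(abs(per_gene_prf_mle(tb0, n, z = 2.5)$gamma_mle), 0.05)
  expect_false(per_gene_prf_mle(list(PS = 0, PN = 3, DS = 2, DN = 1),
                                n)$defined)
})

test_that("hierarchical fit recovers simulated selection coefficients", {
  sim <- simulate_mk_counts(n_genes = 500, seed = 1)
  est <- fit_hierarchical_mk(sim$tables, mk_model_config())
  rho <- stats::cor(est$gamma, sim$truth$gamma_true, method = "spearman",
                    use = "complete.obs")
  expect_gte(rho, 0.8)
  # interval sanity: point estimate inside its own interval
  ok <- !est$no_gamma
  expect_true(all(est$ci_low[ok] <= est$gamma[ok] + 1e-8))
  expect_true(all(est$gamma[ok] <= est$ci_high[ok] + 1e-8))
  # classification is the strict gamma > 1 rule
  expect_identical(classify_positive(est),
                   est$gene_id[ok][est$gamma[ok] > 1])
})

test_that("hierarchical shrinkage beats the per-gene MLE on sparse genes", {
  sim <- simulate_mk_counts(n_genes = 500, seed = 1)
  est <- fit_hierarchical_mk(sim$tables, mk_model_config())
  tot <- sim$tables$PN + sim$tables$PS + sim$tables$DN + sim$tables$DS
  low <- which(tot < 10 & sim$tables$PS > 0)
  expect_gt(length(low), 10)
  mle <- vapply(low, function(i)
    per_gene_prf_mle(sim$tables[i, ], 20)$gamma_mle, numeric(1))
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(est$gamma[low], sim$truth$gamma_true[low]),
            rmse(mle, sim$truth$gamma_true[low]))
})

test_that("an all-neutral genome yields almost no positive calls", {
  tr <- simulation_truth(rep(0, 500),
                         theta_s = stats::rlnorm(500, log(6), 1.2))
  sim <- simulate_mk_counts(truth = tr, seed = 2)
  est <- fit_hierarchical_mk(sim$tables, mk_model_config())
  expect_lte(mean(est$gamma > 1, na.rm = TRUE), 0.02)
})

test_that("label symmetry: swapping syn and nonsyn roles flips mean S", {
  # z = 1 so the mutational opportunity is label-symmetric; a positive
  # mean selection regime must look equally negative after exchanging
  # PN<->PS and DN<->DS. Exact per-gene negation is not implied: the
  # swapped counts correspond to a model with a gene-level divergence
  # effect this one deliberately does not carry.
  set.seed(13)
  tr <- simulation_truth(stats::rnorm(300, 0.8, 1), theta_s = 25, z = 1)
  sim <- simulate_mk_counts(truth = tr, seed = 13)
  swapped <- sim$tables
  names(swapped)[match(c("PN", "PS", "DN", "DS"), names(swapped))] <-
    c("PS", "PN", "DS", "DN")
  e1 <- fit_hierarchical_mk(sim$tables, mk_model_config())
  e2 <- fit_hierarchical_mk(swapped, mk_model_config())
  m1 <- mean(e1$S, na.rm = TRUE); m2 <- mean(e2$S, na.rm = TRUE)
  expect_gt(m1, 0)
  expect_lt(m2, 0)
  expect_lt(abs(m1 + m2), 0.5 * max(abs(m1), abs(m2)))
})

test_that("all-zero genes are flagged no_gamma, never silently dropped", {
  sim <- simulate_mk_counts(n_genes = 60, seed = 21)
  sim$tables[5, c("PN", "PS", "DN", "DS")] <- 0L
  est <- fit_hierarchical_mk(sim$tables, mk_model_config())
  expect_equal(nrow(est), 60)
  expect_true(est$no_gamma[5])
  expect_true(is.na(est$gamma[5]))
  expect_false(any(est$no_gamma[-5]))
})

test_that("the MCMC estimator is reproducible and agrees with EB", {
  sim <- simulate_mk_counts(n_genes = 80, seed = 5)
  cfg <- mk_model_config(estimator = "mcmc", chains = 2,
                         iterations = 1000, warmup = 500, seed = 7)
  m1 <- fit_hierarchical_mk(sim$tables, cfg)
  m2 <- fit_hierarchical_mk(sim$tables, cfg)
  expect_identical(m1$gamma, m2$gamma)
  eb <- fit_hierarchical_mk(sim$tables, mk_model_config())
  expect_gt(stats::cor(m1$gamma, eb$gamma, use = "complete.obs"), 0.98)
  # posterior tail probabilities are proper probabilities
  expect_true(all(m1$p_positive >= 0 & m1$p_positive <= 1, na.rm = TRUE))
})

test_that("too few genes for the hierarchy is an explicit error", {
  sim <- simulate_mk_counts(n_genes = 10, seed = 1)
  expect_error(fit_hierarchical_mk(sim$tables, mk_model_config()),
               ">= 20 genes")
})
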