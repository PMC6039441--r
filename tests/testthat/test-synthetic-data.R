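# Generators: deterministic, and faithful to their target distributions.

test_that("gamma mixture hits its analytic gamma > 1 share", {
  g0 <- simulate_gamma_mixture(2000, frac_positive = 0, seed = 1)
  expect_true(all(g0 <= stats::qnorm(1 - 1e-9, -2, 1.5)))
  expect_lt(mean(g0 > 1), 0.05)
  g1 <- simulate_gamma_mixture(2000, frac_positive = 1, seed = 1, shift = 1.5)
  expect_true(all(g1 > 1))
  gm <- simulate_gamma_mixture(10000, frac_positive = 0.12, seed = 3)
  # within +-2 percentage points of the analytic exceedance
  expect_lt(abs(mean(gm > 1) - attr(gm, "p_gt1_analytic")), 0.02)
  expect_identical(gm, simulate_gamma_mixture(10000, 0.12, seed = 3))
})

test_that("PRF count generator matches its analytic rates", {
  # gamma = 2, z = 1: mean DN/DS ratio approaches H(2) ~ 2.313
  n_rep <- 10000
  tr <- simulation_truth(rep(2, n_rep), theta_s = 20, z = 1)
  sim <- simulate_mk_counts(truth = tr, seed = 11)
  h2 <- prf_H(2)
  # Monte-Carlo check of each cell mean against its Poisson rate,
  # within 3 standard errors
  for (cell in c("PS", "PN", "DS", "DN")) {
    rate <- switch(cell, PS = 20, DS = 20,
                   PN = 20 * prf_Qratio(2, 20), DN = 20 * h2)
    se <- sqrt(rate / n_rep)
    expect_lt(abs(mean(sim$tables[[cell]]) - rate), 3 * se)
  }
  expect_equal(sum(sim$tables$DN) / sum(sim$tables$DS), h2,
               tolerance = 0.02)
})

test_that("neutral symmetry: gamma = 0, z = 1 makes all four cells equal", {
  tr <- simulation_truth(rep(0, 8000), theta_s = 15, z = 1)
  sim <- simulate_mk_counts(truth = tr, seed = 5)
  m <- colMeans(sim$tables[, c("PN", "PS", "DN", "DS")])
  expect_equal(unname(m["PN"] / m["PS"]), 1, tolerance = 0.03)
  expect_equal(unname(m["DN"] / m["DS"]), 1, tolerance = 0.03)
})

test_that("count generator is deterministic and validates rates", {
  s1 <- simulate_mk_counts(n_genes = 50, seed = 9)
  s2 <- simulate_mk_counts(n_genes = 50, seed = 9)
  expect_identical(s1$tables, s2$tables)
  bad <- simulation_truth(c(0, 0), theta_s = c(10, Inf))
  expect_error(simulate_mk_counts(truth = bad, seed = 1), "non-finite")
})

test_that("expression generator plants recoverable caste labels", {
  sim <- simulate_expression(1000, n_queen_biased = 114,
                             n_worker_biased = 287, seed = 2,
                             n_merge_conflict = 10)
  got <- classify_caste_bias(sim$expression)
  expect_equal(sum(got$label == "queen_biased"), 114)
  expect_equal(sum(got$label == "worker_biased"), 287)
  merged <- merge(got, sim$labels, by = "gene_id")
  expect_true(all(merged$label.x == merged$label.y))
  # merge-conflicted loci are dropped before labelling
  expect_equal(nrow(got), 990)
  expect_identical(sim$expression,
                   simulate_expression(1000, 114, 287, seed = 2,
                                       n_merge_conflict = 10)$expression)
})

test_that("all-non-DEG expression yields zero biased genes", {
  sim <- simulate_expression(200, 0, 0, seed = 4)
  got <- classify_caste_bias(sim$expression)
  expect_equal(sum(got$label != "non_deg"), 0)
})

test_that("hit-table generator plants an exact reciprocal-best structure", {
  sim <- simulate_hit_tables(n_shared = 50, n_a_only = 20, n_b_only = 10,
                             seed = 6, tie_pairs = 5)
  ortho <- reciprocal_best(best_hits(sim$hits_ab), best_hits(sim$hits_ba))
  expect_equal(nrow(ortho), 50)
  expect_setequal(paste(ortho$gene_a, ortho$gene_b),
                  paste(sim$true_pairs$gene_a, sim$true_pairs$gene_b))
  empty <- simulate_hit_tables(n_shared = 0, seed = 1)
  expect_equal(nrow(reciprocal_best(best_hits(empty$hits_ab),
                                    best_hits(empty$hits_ba))), 0)
})

test_that("the VCF fixture is deterministic under a fixed seed", {
  a <- simulate_two_species_vcf(seed = 8)
  b <- simulate_two_species_vcf(seed = 8)
  expect_identical(a$genome, b$genome)
  expect_identical(a$expected_mk, b$expected_mk)
  expect_identical(a$manifest, b$manifest)
  expect_identical(lapply(a$focal_records, unclass),
                   lapply(b$focal_records, unclass))
})
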