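#' Classic McDonald-Kreitman Fisher exact test
#'
#' Exact test of independence on the 2x2 table
#' `[[DN, DS], [PN, PS]]` (divergence vs polymorphism by
#' non-synonymous vs synonymous).
#'
#' @param table one-row data.frame or list with PN, PS, DN, DS.
#' @return list(odds_ratio, p_two_sided, p_one_sided, defined). The
#'   one-sided tail is the adaptive direction (excess non-synonymous
#'   divergence). An all-zero table is flagged `defined = FALSE`.
#' @export
mk_fisher <- function(table) {
  m <- matrix(c(table$DN, table$PN, table$DS, table$PS), nrow = 2)
  if (sum(m) == 0)
    return(list(odds_ratio = NA_real_, p_two_sided = NA_real_,
                p_one_sided = NA_real_, defined = FALSE))
  two <- stats::fisher.test(m)
  one <- stats::fisher.test(m, alternative = "greater")
  list(odds_ratio = unname(two$estimate), p_two_sided = two$p.value,
       p_one_sided = one$p.value, defined = TRUE)
}

#' Neutrality index and adaptive fraction
#'
#' `NI = (PN/PS) / (DN/DS)`; `alpha = 1 - NI`. NI < 1 (alpha > 0)
#' indicates an excess of non-synonymous divergence, i.e. adaptive
#' protein evolution.
#'
#' @inheritParams mk_fisher
#' @return list(NI, alpha, defined); `defined = FALSE` when PS or DS or
#'   DN is zero.
#' @export
neutrality_stats <- function(table) {
  if (table$PS == 0 || table$DS == 0 || table$DN == 0)
    return(list(NI = NA_real_, alpha = NA_real_, defined = FALSE))
  ni <- (table$PN / table$PS) / (table$DN / table$DS)
  list(NI = ni, alpha = 1 - ni, defined = TRUE)
}

#' Model configuration for the hierarchical MK fit
#'
#' @param n haploid sample size for the PRF polymorphism integral
#'   (default 20: ten diploid focal samples).
#' @param estimator "empirical_bayes" (Poisson GLMM via \pkg{lme4};
#'   fast, deterministic) or "mcmc" (Gibbs sampling via \pkg{rjags}).
#' @param chains,iterations,warmup MCMC settings (per chain; `warmup`
#'   is adaptation + burn-in discarded before `iterations` kept draws).
#' @param seed RNG seed for the MCMC chains.
#' @param prior_sd_fixed Normal prior SD on the four fixed effects.
#' @param prior_sd_sigma half-Normal prior SD on the three
#'   random-effect standard deviations.
#' @return object of class `mk_model_config`.
#' @export
mk_model_config <- function(n = 20, estimator = c("empirical_bayes", "mcmc"),
                            chains = 4, iterations = 2000, warmup = 1000,
                            seed = 1, prior_sd_fixed = 5,
                            prior_sd_sigma = 1) {
  estimator <- match.arg(estimator)
  stopifnot(n >= 2, iterations > 0, warmup >= 0, chains >= 1)
  structure(list(n = n, estimator = estimator, chains = chains,
                 iterations = iterations, warmup = warmup, seed = seed,
                 prior_sd_fixed = prior_sd_fixed,
                 prior_sd_sigma = prior_sd_sigma),
            class = "mk_model_config")
}

# MK tables -> long Poisson data (4 rows per gene).
# R = 1 for non-synonymous, F = 1 for fixed (divergence).
mk_long_data <- function(tables) {
  g <- seq_len(nrow(tables))
  data.frame(
    gene = factor(rep(tables$gene_id, each = 4),
                  levels = tables$gene_id),
    count = as.vector(t(as.matrix(tables[, c("PS", "PN", "DS", "DN")]))),
    R = rep(c(0, 1, 0, 1), nrow(tables)),
    F = rep(c(0, 0, 1, 1), nrow(tables)))
}

#' Hierarchical Bayesian McDonald-Kreitman fit
#'
#' Fits the Poisson log-linear model
#' \deqn{Y_{iRF} \sim Pois(\mu_{iRF}), \quad
#'   \log \mu = \beta_0 + b_i + (\beta_R + r_i) R + \beta_F F +
#'   (\beta_{RF} + s_i) R F}
#' with R = 1 for non-synonymous counts, F = 1 for fixed differences,
#' and independent gene-level random effects
#' \eqn{b_i \sim N(0, \sigma_b^2)}, \eqn{r_i \sim N(0, \sigma_r^2)},
#' \eqn{s_i \sim N(0, \sigma_s^2)}. The gene-level selection effect is
#' \eqn{S_i = \beta_{RF} + s_i}; it is mapped to the scaled selection
#' coefficient via the PRF link \eqn{e^{S} = H(\gamma)/Qratio(\gamma, n)}
#' (see [gamma_from_effect()]), and genes with posterior-mean
#' \eqn{\gamma > 1} are classified as positively selected.
#'
#' Two estimators are provided: `empirical_bayes` maximizes the GLMM
#' likelihood with [lme4::glmer()] and uses the conditional normal
#' approximation for intervals; `mcmc` draws from the full posterior
#' (Normal(0, 5^2) priors on fixed effects, half-Normal(1) on the
#' sigmas) with JAGS, seeded per chain so runs are reproducible
#' draw-for-draw.
#'
#' Genes whose four counts are all zero carry no information about S
#' and are excluded from the fit; they are returned with NA estimates
#' and `no_gamma = TRUE`, mirroring real datasets where gamma is only
#' computable for a subset of annotated genes.
#'
#' @param tables MK table data.frame (gene_id, PN, PS, DN, DS).
#' @param config an [mk_model_config()].
#' @return data.frame: gene_id, S, gamma, ci_low, ci_high, p_positive,
#'   classified_positive, no_gamma, converged. Attribute "fit" carries
#'   estimator internals; attribute "sigma" the random-effect SDs.
#' @export
fit_hierarchical_mk <- function(tables, config = mk_model_config()) {
  stopifnot(inherits(config, "mk_model_config"))
  if (nrow(tables) < 20)
    stop("hierarchical fit needs >= 20 genes (got ", nrow(tables), ")")
  informative <- tables$PN + tables$PS + tables$DN + tables$DS > 0
  fit_tab <- tables[informative, , drop = FALSE]
  res <- if (config$estimator == "empirical_bayes") {
    .fit_mk_eb(fit_tab, config)
  } else {
    .fit_mk_mcmc(fit_tab, config)
  }
  out <- data.frame(gene_id = tables$gene_id, S = NA_real_,
                    gamma = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p_positive = NA_real_,
                    classified_positive = NA, no_gamma = !informative,
                    converged = res$converged, stringsAsFactors = FALSE)
  j <- match(fit_tab$gene_id, out$gene_id)
  out$S[j] <- res$S
  # the PRF link is monotone, so quantiles of S map to quantiles of gamma
  g <- gamma_from_effect_safe(res$S, config$n)
  out$gamma[j] <- g
  out$ci_low[j] <- gamma_from_effect_safe(res$ci_low, config$n)
  out$ci_high[j] <- gamma_from_effect_safe(res$ci_high, config$n)
  out$p_positive[j] <- res$p_positive
  out$classified_positive <- !out$no_gamma & !is.na(out$gamma) &
    out$gamma > 1
  attr(out, "sigma") <- res$sigma
  attr(out, "fit") <- res$fit
  out
}

# Empirical-Bayes route: Poisson GLMM by Laplace approximation.
.fit_mk_eb <- function(tables, config) {
  d <- mk_long_data(tables)
  d$RF <- d$R * d$F
  fit <- lme4::glmer(
    count ~ R * F + (1 | gene) + (0 + R | gene) + (0 + RF | gene),
    data = d, family = stats::poisson(),
    control = lme4::glmerControl(check.conv.singular = "ignore"))
  beta_rf <- unname(lme4::fixef(fit)["R:F"])
  se_beta <- sqrt(as.matrix(stats::vcov(fit))["R:F", "R:F"])
  re <- lme4::ranef(fit, condVar = TRUE)$gene
  s_i <- re[levels(d$gene), "RF"]
  pv <- attr(re, "postVar")
  # postVar is a named list (one 1x1xG array per term) when the random
  # effects are specified as separate terms on the same grouping factor
  cond_var <- if (is.list(pv)) as.vector(pv[["RF"]]) else as.vector(pv)
  stopifnot(length(cond_var) == length(s_i))
  S <- beta_rf + s_i
  sd_S <- sqrt(se_beta^2 + cond_var)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma <- stats::setNames(vc$sdcor[match(c("(Intercept)", "R", "RF"),
                                          vc$var1)], c("b", "r", "s"))
  list(S = S, ci_low = S - 1.96 * sd_S, ci_high = S + 1.96 * sd_S,
       p_positive = stats::pnorm(S / sd_S), sigma = sigma,
       converged = length(fit@optinfo$conv$lme4$messages) == 0 ||
         !any(grepl("failed", fit@optinfo$conv$lme4$messages)),
       fit = fit)
}

.mk_jags_model <- "
model {
  for (k in 1:K) {
    y[k] ~ dpois(mu[k])
    log(mu[k]) <- b0 + b[g[k]] + (bR + r[g[k]]) * R[k] + bF * F[k] +
                  (bRF + s[g[k]]) * R[k] * F[k]
  }
  for (i in 1:G) {
    b[i] ~ dnorm(0, tau_b)
    r[i] ~ dnorm(0, tau_r)
    s[i] ~ dnorm(0, tau_s)
  }
  b0  ~ dnorm(0, prec_fixed)
  bR  ~ dnorm(0, prec_fixed)
  bF  ~ dnorm(0, prec_fixed)
  bRF ~ dnorm(0, prec_fixed)
  sig_b ~ dnorm(0, prec_sigma) T(0,)
  sig_r ~ dnorm(0, prec_sigma) T(0,)
  sig_s ~ dnorm(0, prec_sigma) T(0,)
  tau_b <- 1 / (sig_b * sig_b)
  tau_r <- 1 / (sig_r * sig_r)
  tau_s <- 1 / (sig_s * sig_s)
}
"

# Full-posterior route via JAGS; seeded per chain for reproducibility.
.fit_mk_mcmc <- function(tables, config) {
  d <- mk_long_data(tables)
  G <- nlevels(d$gene)
  data_list <- list(y = d$count, R = d$R, F = d$F,
                    g = as.integer(d$gene), K = nrow(d), G = G,
                    prec_fixed = 1 / config$prior_sd_fixed^2,
                    prec_sigma = 1 / config$prior_sd_sigma^2)
  inits <- lapply(seq_len(config$chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = config$seed + ch))
  jm <- rjags::jags.model(textConnection(.mk_jags_model), data = data_list,
                          inits = inits, n.chains = config$chains,
                          n.adapt = max(200, config$warmup %/% 2),
                          quiet = TRUE)
  stats::update(jm, n.iter = config$warmup, progress.bar = "none")
  samp <- rjags::coda.samples(
    jm, variable.names = c("b0", "bR", "bF", "bRF", "s",
                           "sig_b", "sig_r", "sig_s"),
    n.iter = config$iterations, progress.bar = "none")
  draws <- do.call(rbind, lapply(samp, as.matrix))
  s_cols <- paste0("s[", seq_len(G), "]")
  S_draws <- draws[, s_cols, drop = FALSE] + draws[, "bRF"]
  S <- colMeans(S_draws)
  ci <- apply(S_draws, 2, stats::quantile, probs = c(0.025, 0.975))
  converged <- TRUE
  if (config$chains >= 2) {
    fixed <- samp[, c("b0", "bR", "bF", "bRF", "sig_b", "sig_r", "sig_s")]
    gd <- try(coda::gelman.diag(fixed, autoburnin = FALSE,
                                multivariate = FALSE), silent = TRUE)
    if (!inherits(gd, "try-error"))
      converged <- all(gd$psrf[, 1] < 1.05, na.rm = TRUE)
  }
  sigma <- c(b = mean(draws[, "sig_b"]), r = mean(draws[, "sig_r"]),
             s = mean(draws[, "sig_s"]))
  list(S = unname(S), ci_low = unname(ci[1, ]), ci_high = unname(ci[2, ]),
       p_positive = unname(colMeans(S_draws > 0)), sigma = sigma,
       converged = converged, fit = NULL)
}

#' Per-gene PRF maximum-likelihood estimate of gamma
#'
#' Independent no-pooling estimator used to benchmark the hierarchical
#' fit: maximizes the product-Poisson likelihood of the generative PRF
#' model (PS ~ Pois(theta), PN ~ Pois(theta z Qratio(gamma, n)),
#' DS ~ Pois(theta d), DN ~ Pois(theta d z H(gamma))) over
#' (theta, gamma) with z and d held fixed, by coarse grid search
#' followed by golden-section refinement. theta profiles out in closed
#' form at each gamma.
#'
#' @inheritParams mk_fisher
#' @param n haploid sample size. @param z non-synonymous/synonymous
#'   mutational opportunity ratio. @param d divergence intensity
#'   multiplier.
#' @return list(gamma_mle, theta_mle, defined); `defined = FALSE` when
#'   PS = 0.
#' @export
per_gene_prf_mle <- function(table, n, z = 2.5, d = 1) {
  if (table$PS == 0)
    return(list(gamma_mle = NA_real_, theta_mle = NA_real_,
                defined = FALSE))
  counts <- c(table$PS, table$PN, table$DS, table$DN)
  q0 <- prf_Q(0, n)
  negll <- function(g) {
    qr <- prf_Q(g, n) / q0
    h <- prf_H(g)
    w <- c(1, z * qr, d, d * z * h) # rates / theta
    theta <- sum(counts) / sum(w)
    mu <- theta * w
    -sum(stats::dpois(counts, mu, log = TRUE))
  }
  grid <- seq(-30, 30, by = 1)
  vals <- vapply(grid, negll, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(negll, c(lo, hi), tol = 1e-8)
  g <- opt$minimum
  qr <- prf_Q(g, n) / q0
  w <- c(1, z * qr, d, d * prf_H(g) * z)
  list(gamma_mle = g, theta_mle = sum(counts) / sum(w), defined = TRUE)
}

#' Genes classified as positively selected
#'
#' Strict threshold on the posterior-mean scaled selection coefficient:
#' gamma > 1 (gamma exactly 1 is not called positive).
#'
#' @param estimates output of [fit_hierarchical_mk()].
#' @return character vector of gene ids with gamma > 1.
#' @export
classify_positive <- function(estimates) {
  estimates$gene_id[!is.na(estimates$gamma) & estimates$gamma > 1]
}
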