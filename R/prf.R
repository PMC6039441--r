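#' Poisson random field relative fixation rate
#'
#' Relative rate of fixation of new semidominant mutations with
#' population-scaled selection coefficient \eqn{\gamma = 2 N_e s},
#' relative to neutral mutations:
#' \deqn{H(\gamma) = \gamma / (1 - e^{-\gamma})}
#' with the continuous extension \eqn{H(0) = 1}. \eqn{H} is strictly
#' increasing and satisfies \eqn{H(\gamma)/H(-\gamma) = e^{\gamma}}.
#'
#' @param gamma numeric vector of scaled selection coefficients.
#' @return numeric vector, \eqn{H(\gamma)}.
#' @export
#' @examples
#' prf_H(0)        # 1
#' prf_H(2)        # 2 / (1 - exp(-2)) = 2.313...
prf_H <- function(gamma) {
  stopifnot(is.numeric(gamma), all(is.finite(gamma)))
  out <- numeric(length(gamma))
  small <- abs(gamma) < 1e-8
  # -expm1(-g) = 1 - e^-g, stable for both signs
  out[!small] <- gamma[!small] / (-expm1(-gamma[!small]))
  out[small] <- 1 + gamma[small] / 2 # first-order expansion at 0
  out
}

#' Poisson random field expected polymorphism factor
#'
#' Expected number of segregating sites (relative units) contributed by
#' mutations with scaled selection coefficient gamma, observable in a
#' sample of n haploid sequences:
#' \deqn{Q(\gamma, n) = \int_0^1
#'   \frac{1 - e^{-\gamma (1 - x)}}{1 - e^{-\gamma}} \cdot
#'   \frac{1 - x^n - (1 - x)^n}{x (1 - x)} \, dx}
#' The first factor is the standing frequency density under selection
#' (continuously extended to \eqn{1 - x} at \eqn{\gamma = 0}); the second
#' is the probability that a site at population frequency x is
#' polymorphic in the sample. Q is increasing in gamma: advantageous
#' mutations transit higher frequencies where sampled polymorphism is
#' more visible, deleterious ones are pinned near frequency 0.
#'
#' @param gamma scalar scaled selection coefficient (finite).
#' @param n haploid sample size, >= 2.
#' @param rel.tol relative tolerance passed to [stats::integrate()].
#' @return scalar Q(gamma, n).
#' @export
prf_Q <- function(gamma, n, rel.tol = 1e-10) {
  stopifnot(is.numeric(gamma), length(gamma) == 1, is.finite(gamma),
            is.numeric(n), length(n) == 1, n >= 2)
  freq_density <- if (abs(gamma) < 1e-8) {
    function(x) 1 - x
  } else {
    function(x) (-expm1(-gamma * (1 - x))) / (-expm1(-gamma))
  }
  integrand <- function(x) {
    freq_density(x) * (1 - x^n - (1 - x)^n) / (x * (1 - x))
  }
  stats::integrate(integrand, 0, 1, rel.tol = rel.tol,
                   subdivisions = 400L)$value
}

#' Polymorphism factor relative to neutrality
#'
#' \eqn{Qratio(\gamma, n) = Q(\gamma, n) / Q(0, n)}; equals 1 at
#' \eqn{\gamma = 0}.
#'
#' @inheritParams prf_Q
#' @return scalar Q(gamma, n) / Q(0, n).
#' @export
prf_Qratio <- function(gamma, n) {
  prf_Q(gamma, n) / prf_Q(0, n)
}

# log of the divergence/polymorphism PRF link: log(H(g) / Qratio(g, n)).
# Strictly increasing in g, so it is invertible; used by both directions
# of the effect <-> gamma mapping.
prf_log_link <- function(gamma, n, q0 = NULL) {
  if (is.null(q0)) q0 <- prf_Q(0, n)
  log(prf_H(gamma)) - log(prf_Q(gamma, n) / q0)
}

#' Selection effect implied by a scaled selection coefficient
#'
#' The hierarchical MK model's gene-level selection effect S is the log
#' excess of non-synonymous divergence over non-synonymous polymorphism
#' relative to neutral expectation; under the PRF model
#' \eqn{e^{S} = H(\gamma) / Qratio(\gamma, n)}.
#'
#' @param gamma scalar scaled selection coefficient.
#' @param n haploid sample size used for the polymorphism integral.
#' @return scalar S.
#' @seealso [gamma_from_effect()] for the inverse.
#' @export
effect_from_gamma <- function(gamma, n) {
  prf_log_link(gamma, n)
}

#' Invert the PRF link: scaled selection coefficient from an effect
#'
#' Solves \eqn{e^{S} = H(\gamma)/Qratio(\gamma, n)} for gamma by
#' bisection on \eqn{\gamma \in [-100, 100]}. The link is strictly
#' increasing so the root is unique; S = 0 maps to gamma = 0 exactly.
#'
#' @param S numeric vector of selection effects (log scale).
#' @param n haploid sample size, >= 2.
#' @param tol absolute tolerance on the link residual.
#' @return numeric vector of gamma values.
#' @export
#' @examples
#' gamma_from_effect(0, 20)                            # 0
#' gamma_from_effect(effect_from_gamma(1.7, 20), 20)   # 1.7
gamma_from_effect <- function(S, n, tol = 1e-12) {
  stopifnot(is.numeric(S), all(is.finite(S)), n >= 2)
  q0 <- prf_Q(0, n)
  vapply(S, function(s) {
    if (s == 0) return(0)
    f <- function(g) prf_log_link(g, n, q0) - s
    lo <- -100; hi <- 100
    flo <- f(lo); fhi <- f(hi)
    if (is.na(flo) || is.na(fhi) || flo > 0 || fhi < 0) {
      stop("gamma_from_effect: S = ", format(s),
           " out of invertible range for n = ", n)
    }
    stats::uniroot(f, c(lo, hi), tol = tol)$root
  }, numeric(1))
}

# Clamped variant used inside model fitting: extreme posterior draws
# (e.g. interval endpoints of nearly-empty genes) map to the bracket
# boundary instead of erroring; returns attribute "clamped" count.
gamma_from_effect_safe <- function(S, n) {
  q0 <- prf_Q(0, n)
  lo_val <- prf_log_link(-100, n, q0)
  hi_val <- prf_log_link(100, n, q0)
  s_clamped <- pmin(pmax(S, lo_val), hi_val)
  out <- gamma_from_effect(s_clamped, n)
  attr(out, "clamped") <- sum(S < lo_val | S > hi_val)
  out
}
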