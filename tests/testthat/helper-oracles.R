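# independent oracles, kept free of the closed forms the package uses

# quadrature oracle for the posterior of the relative reporting rate under
# the two-gamma mixture prior: marginals, posterior mean of log2(lambda)
# and posterior 5th percentile all by numerical integration of the
# explicit Poisson-gamma densities
quad_posterior <- function(a, E, th) {
  comp_marg <- function(alpha, beta) {
    stats::integrate(function(l) stats::dpois(a, E * l) *
                       stats::dgamma(l, alpha, rate = beta),
                     0, Inf, rel.tol = 1e-12, abs.tol = 0)$value
  }
  f1 <- comp_marg(th$alpha1, th$beta1)
  f2 <- comp_marg(th$alpha2, th$beta2)
  q1 <- th$w * f1 / (th$w * f1 + (1 - th$w) * f2)
  dens <- function(l)
    (th$w * stats::dpois(a, E * l) * stats::dgamma(l, th$alpha1,
                                                   rate = th$beta1) +
     (1 - th$w) * stats::dpois(a, E * l) * stats::dgamma(l, th$alpha2,
                                                         rate = th$beta2)) /
      (th$w * f1 + (1 - th$w) * f2)
  elog2 <- stats::integrate(function(l) log2(l) * dens(l), 0, Inf,
                            rel.tol = 1e-12, abs.tol = 0)$value
  cdf <- function(x) stats::integrate(dens, 0, x, rel.tol = 1e-12,
                                      abs.tol = 0)$value
  hi <- max(stats::qgamma(0.999, th$alpha1 + a, rate = th$beta1 + E),
            stats::qgamma(0.999, th$alpha2 + a, rate = th$beta2 + E))
  q05 <- stats::uniroot(function(x) cdf(x) - 0.05, c(1e-12, hi),
                        tol = 1e-9)$root
  list(ebgm = 2^elog2, ebgm05 = q05, q1 = q1)
}

# end-to-end run on an in-memory synthetic dataset: returns the signal
# table for one target drug at PT level
synthetic_signal_table <- function(sim, target) {
  cases <- deduplicate_cases(link_cases(sim$tables))
  coh <- select_target_cohort(cases, target)
  tab <- build_contingency_tables(cases, coh, "PT")
  compute_signal_stats(tab)
}
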