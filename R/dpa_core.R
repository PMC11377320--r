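# Disproportionality statistics for 2x2 drug-event tables.
#
# Cells: a = target drug & event, b = target drug & other events,
#        c = other drugs & event, d = neither; N = a+b+c+d.
# Expected count under independence: E = (a+b)(a+c)/N.
#
# Locked formulas (standard published forms):
#   ROR  = ad/bc;  95% CI = exp(ln ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))
#   PRR  = [a/(a+b)] / [c/(c+d)]
#          95% CI = exp(ln PRR +/- 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))
#   chi2 = N(|ad-bc| - yates*N/2)^2 / [(a+b)(c+d)(a+c)(b+d)]
#   BCPNN closed-form posterior approximation (information component), with
#   Dirichlet/Beta priors expectation-matched to independence:
#     gamma11 = 1, alpha1 = beta1 = 1, alpha = beta = 2,
#     gamma = gamma11 (N+alpha)(N+beta) / [(a+b+alpha1)(a+c+beta1)]
#     IC   = log2[ (a+gamma11)(N+alpha)(N+beta) /
#                  ((N+gamma)(a+b+alpha1)(a+c+beta1)) ]
#     V(IC)= (1/ln 2)^2 [ (N-a+gamma-gamma11) / ((a+gamma11)(1+N+gamma))
#                       + (N-a-b+alpha-alpha1) / ((a+b+alpha1)(1+N+alpha))
#                       + (N-a-c+beta-beta1) / ((a+c+beta1)(1+N+beta)) ]
#     IC025 = IC - 2 sqrt(V(IC))
#   MGPS: relative reporting rate lambda has the DuMouchel two-gamma prior
#     w Gamma(alpha1, beta1) + (1-w) Gamma(alpha2, beta2) (shape, RATE);
#     marginally a ~ mixture of negative binomials
#     NB(size = alpha_i, prob = beta_i/(beta_i + E)); posterior is again a
#     two-gamma mixture Gamma(alpha_i + a, beta_i + E) with weights
#     Q_i proportional to w_i NB(a; alpha_i, beta_i/(beta_i+E));
#     EBGM = 2^{E[log2 lambda | a]}
#          = 2^{ sum_i Q_i (digamma(alpha_i+a) - ln(beta_i+E)) / ln 2 },
#     EBGM05 = posterior 5th percentile of lambda.

#' Reporting odds ratio with Wald 95\% confidence interval
#'
#' `ROR = ad/bc`, CI `exp(ln ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))`. With a
#' zero cell the statistic is undefined (`NA`) under the default policy, or
#' all four cells receive the Haldane-Anscombe 0.5 continuity correction
#' with `zero_cell = "haldane"`.
#'
#' @param a,b,c,d vectors of 2x2 cell counts.
#' @param zero_cell `"undefined"` (default) or `"haldane"`.
#' @return data.frame with columns `ror`, `ror_lo`, `ror_hi`.
#' @export
ror_stats <- function(a, b, c, d, zero_cell = c("undefined", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  if (zero_cell == "haldane") {
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    c <- c + 0.5 * zero; d <- d + 0.5 * zero
    zero <- rep(FALSE, length(a))
  }
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  out <- data.frame(ror = ror,
                    ror_lo = exp(log(ror) - 1.96 * se),
                    ror_hi = exp(log(ror) + 1.96 * se))
  out[zero, ] <- NA_real_
  out
}

#' Proportional reporting ratio with Wald 95\% confidence interval
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`, CI
#' `exp(ln PRR +/- 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`.
#'
#' @inheritParams ror_stats
#' @return data.frame with columns `prr`, `prr_lo`, `prr_hi`.
#' @export
prr_stats <- function(a, b, c, d, zero_cell = c("undefined", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  if (zero_cell == "haldane") {
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    c <- c + 0.5 * zero; d <- d + 0.5 * zero
    zero <- rep(FALSE, length(a))
  }
  prr <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  out <- data.frame(prr = prr,
                    prr_lo = exp(log(prr) - 1.96 * se),
                    prr_hi = exp(log(prr) + 1.96 * se))
  out[zero, ] <- NA_real_
  out
}

#' Pearson chi-square statistic for a 2x2 table
#'
#' `chi2 = N(ad-bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`; with the Yates continuity
#' correction (default) `|ad-bc|` is replaced by `max(0, |ad-bc| - N/2)`
#' before squaring. Degenerate margins give `NA`.
#'
#' @inheritParams ror_stats
#' @param yates logical, apply the Yates continuity correction.
#' @return numeric vector of chi-square values.
#' @export
chi2_stat <- function(a, b, c, d, yates = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  num <- abs(a * d - b * c)
  if (yates) num <- pmax(0, num - N / 2)
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  out <- N * num^2 / den
  out[den == 0] <- NA_real_
  out
}

#' BCPNN information component with posterior lower bound
#'
#' Closed-form posterior approximation of the information component
#' `IC = E[log2 p(drug,event) / (p(drug) p(event))]` under the original
#' BCPNN Dirichlet/Beta priors with expectation-matched parameters
#' (see the formula block at the top of this file, locked by tests):
#' `IC025 = IC - 2 sqrt(V[IC])`. Defined for zero cells.
#'
#' @inheritParams ror_stats
#' @return data.frame with columns `ic`, `ic025`.
#' @export
bcpnn_ic <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  n1 <- a + b # drug margin
  m1 <- a + c # event margin
  g11 <- 1; a1 <- 1; b1 <- 1; al <- 2; be <- 2
  gamma <- g11 * (N + al) * (N + be) / ((n1 + a1) * (m1 + b1))
  ic <- log2((a + g11) * (N + al) * (N + be) /
               ((N + gamma) * (n1 + a1) * (m1 + b1)))
  v <- (1 / log(2)^2) * (
    (N - a + gamma - g11) / ((a + g11) * (1 + N + gamma)) +
    (N - n1 + al - a1) / ((n1 + a1) * (1 + N + al)) +
    (N - m1 + be - b1) / ((m1 + b1) * (1 + N + be)))
  data.frame(ic = ic, ic025 = ic - 2 * sqrt(v))
}

# mixture negative-binomial log marginal of observed counts given E
.mgps_marginal_ll <- function(a, E, alpha1, beta1, alpha2, beta2, w) {
  l1 <- stats::dnbinom(a, size = alpha1, prob = beta1 / (beta1 + E),
                       log = TRUE) + log(w)
  l2 <- stats::dnbinom(a, size = alpha2, prob = beta2 / (beta2 + E),
                       log = TRUE) + log1p(-w)
  m <- pmax(l1, l2)
  sum(m + log(exp(l1 - m) + exp(l2 - m)))
}

#' Fit the DuMouchel two-gamma (MGPS) prior by empirical Bayes
#'
#' Maximizes the negative-binomial mixture marginal likelihood of the
#' observed counts over the five hyperparameters (two gamma shape/rate
#' pairs and the mixture weight), by Nelder-Mead on log/logit-transformed
#' parameters from DuMouchel's conventional start
#' `(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4, w = 1/3)`, with
#' restarts until the log-likelihood improves by less than `tol`. The
#' search is boxed to shapes and rates in `[1e-6, 1e6]` (a component can
#' approach, but not become, a point mass).
#'
#' @param a integer vector of observed counts, one per drug-event table.
#' @param E numeric vector of expected counts `(a+b)(a+c)/N`.
#' @param init numeric(5) starting values `(alpha1, beta1, alpha2, beta2, w)`.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_restarts maximum Nelder-Mead restarts.
#' @return object of class `mgps_fit`: list with the five hyperparameters,
#'   `loglik`, `init_loglik`, `convergence` (0 = converged) and `n_tables`.
#'   Non-convergence raises an error of class `mgps_convergence_error`
#'   carrying the best-found parameters in its `params` field.
#' @export
fit_mgps <- function(a, E, init = c(0.2, 0.1, 2, 4, 1 / 3), tol = 1e-8,
                     max_restarts = 10) {
  stopifnot(length(a) == length(E), length(a) >= 2, all(E > 0))
  # box the search: shapes/rates in [1e-6, 1e6], w in plogis([-15, 15]).
  # The marginal likelihood can ridge toward a point-mass prior (alpha,
  # beta -> Inf at fixed alpha/beta); the box makes the optimum proper
  # without affecting interior solutions.
  lb <- c(rep(log(1e-6), 4), -15)
  ub <- c(rep(log(1e6), 4), 15)
  nll <- function(th) {
    thc <- pmin(pmax(th, lb), ub)
    p <- exp(thc[1:4])
    w <- stats::plogis(thc[5])
    v <- -.mgps_marginal_ll(a, E, p[1], p[2], p[3], p[4], w)
    if (!is.finite(v)) return(1e12)
    v + 1e3 * sum((th - thc)^2)
  }
  th <- c(log(init[1:4]), stats::qlogis(init[5]))
  init_ll <- -nll(th)
  best <- list(par = th, value = nll(th), convergence = 1L)
  # converged when a whole restart no longer improves the log-likelihood
  # by tol (the optimizer's own simplex code can stay 1 on flat ridges)
  for (i in seq_len(max_restarts)) {
    fit <- stats::optim(best$par, nll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    improved <- best$value - fit$value
    if (fit$value < best$value) best <- fit
    if (i > 1 && improved < tol) {
      best$convergence <- 0L
      break
    }
  }
  par <- pmin(pmax(best$par, lb), ub)
  p <- exp(par[1:4])
  w <- stats::plogis(par[5])
  res <- structure(list(alpha1 = p[1], beta1 = p[2], alpha2 = p[3],
                        beta2 = p[4], w = w, loglik = -best$value,
                        init_loglik = init_ll,
                        convergence = best$convergence,
                        n_tables = length(a)),
                   class = "mgps_fit")
  if (best$convergence != 0)
    stop(errorCondition(
      "MGPS hyperparameter optimization did not converge",
      class = "mgps_convergence_error", params = res))
  res
}

#' @export
print.mgps_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<mgps_fit> alpha1=%.4f beta1=%.4f alpha2=%.4f beta2=%.4f w=%.4f\n",
    "  logLik %.3f over %d tables (start %.3f)\n"),
    x$alpha1, x$beta1, x$alpha2, x$beta2, x$w, x$loglik, x$n_tables,
    x$init_loglik))
  invisible(x)
}

#' Empirical-Bayes geometric mean and posterior 5th percentile
#'
#' Given fitted (or fixed) MGPS hyperparameters, the posterior of the
#' relative reporting rate lambda is a two-component gamma mixture
#' `Gamma(alpha_i + a, beta_i + E)` (shape, rate) with weights proportional
#' to `w_i NB(a; alpha_i, beta_i/(beta_i+E))`.
#' `EBGM = 2^{E[log2 lambda | a]}` via the digamma closed form, and
#' `EBGM05` is the posterior 5th percentile, solved numerically to an
#' absolute tolerance of 1e-6 on the lambda scale.
#'
#' @param a integer vector of observed counts.
#' @param E numeric vector of expected counts (> 0).
#' @param theta an `mgps_fit` or list with `alpha1, beta1, alpha2, beta2, w`.
#' @return data.frame with columns `ebgm`, `ebgm05`.
#' @export
ebgm_scores <- function(a, E, theta) {
  stopifnot(length(a) == length(E))
  ok <- is.finite(E) & E > 0 & is.finite(a)
  ebgm <- ebgm05 <- rep(NA_real_, length(a))
  if (!any(ok)) return(data.frame(ebgm = ebgm, ebgm05 = ebgm05))
  aa <- a[ok]; EE <- E[ok]
  l1 <- stats::dnbinom(aa, size = theta$alpha1,
                       prob = theta$beta1 / (theta$beta1 + EE), log = TRUE) +
    log(theta$w)
  l2 <- stats::dnbinom(aa, size = theta$alpha2,
                       prob = theta$beta2 / (theta$beta2 + EE), log = TRUE) +
    log1p(-theta$w)
  q1 <- 1 / (1 + exp(l2 - l1))
  q1[!is.finite(q1)] <- theta$w # both marginals underflow: prior weights
  q2 <- 1 - q1
  s1 <- theta$alpha1 + aa; r1 <- theta$beta1 + EE
  s2 <- theta$alpha2 + aa; r2 <- theta$beta2 + EE
  eblog <- (q1 * (digamma(s1) - log(r1)) + q2 * (digamma(s2) - log(r2))) /
    log(2)
  ebgm[ok] <- 2^eblog

  q05 <- numeric(length(aa))
  for (i in seq_along(aa)) {
    cdf <- function(x) q1[i] * stats::pgamma(x, s1[i], rate = r1[i]) +
      q2[i] * stats::pgamma(x, s2[i], rate = r2[i]) - 0.05
    lo <- min(stats::qgamma(0.05, s1[i], rate = r1[i]),
              stats::qgamma(0.05, s2[i], rate = r2[i]))
    hi <- max(stats::qgamma(0.05, s1[i], rate = r1[i]),
              stats::qgamma(0.05, s2[i], rate = r2[i]))
    q05[i] <- if (hi - lo < 1e-12) lo else
      stats::uniroot(cdf, c(lo, hi), tol = 1e-8, extendInt = "yes")$root
  }
  ebgm05[ok] <- q05
  data.frame(ebgm = ebgm, ebgm05 = ebgm05)
}

#' Signal positivity criteria
#'
#' Defaults implement the classification rule used for the temozolomide
#' analysis: a signal is positive when the report count and all four
#' algorithms agree: `a >= 3`, `ROR >= 3`, `PRR >= 2`, `EBGM05 > 2`
#' (strict, per the stated rule) and `IC025 > 0` (the BCPNN criterion
#' completing the four-algorithm rule). Any threshold can be disabled by
#' setting it to `NA`.
#'
#' @param ror_min,prr_min,ebgm05_min,ic025_min,a_min numeric thresholds.
#' @param require_all if `TRUE` (default) all enabled criteria must hold;
#'   if `FALSE`, any one suffices.
#' @return object of class `signal_criteria`.
#' @export
signal_criteria <- function(ror_min = 3, prr_min = 2, ebgm05_min = 2,
                            ic025_min = 0, a_min = 3, require_all = TRUE) {
  for (f in c("ror_min", "prr_min", "ebgm05_min", "ic025_min", "a_min")) {
    v <- get(f)
    if (!is.na(v) && v < 0) stop_config(f, "must be non-negative")
  }
  structure(list(ror_min = ror_min, prr_min = prr_min,
                 ebgm05_min = ebgm05_min, ic025_min = ic025_min,
                 a_min = a_min, require_all = isTRUE(require_all)),
            class = "signal_criteria")
}

#' Classify signals against positivity criteria
#'
#' Boundary semantics follow the stated rule: `ROR >= ror_min`,
#' `PRR >= prr_min` are inclusive; `EBGM05 > ebgm05_min` and
#' `IC025 > ic025_min` are strict. Rows with any enabled statistic
#' undefined (`NA`) are negative with reason `"not evaluable"`.
#'
#' @param stats data.frame with columns `a`, `ror`, `prr`, `ebgm05`, `ic025`
#'   (e.g. from [compute_signal_stats()]).
#' @param criteria a [signal_criteria()].
#' @return data.frame with columns `signal` (`"positive"`/`"negative"`) and
#'   `reason` (`NA`, `"below threshold"`, or `"not evaluable"`).
#' @export
classify_signals <- function(stats, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  tests <- list(
    if (!is.na(criteria$a_min)) stats$a >= criteria$a_min,
    if (!is.na(criteria$ror_min)) stats$ror >= criteria$ror_min,
    if (!is.na(criteria$prr_min)) stats$prr >= criteria$prr_min,
    if (!is.na(criteria$ebgm05_min)) stats$ebgm05 > criteria$ebgm05_min,
    if (!is.na(criteria$ic025_min)) stats$ic025 > criteria$ic025_min)
  tests <- Filter(Negate(is.null), tests)
  m <- do.call(cbind, tests)
  not_eval <- apply(m, 1, anyNA)
  pos <- if (criteria$require_all) apply(m, 1, all) else apply(m, 1, any)
  pos[not_eval] <- FALSE
  data.frame(
    signal = ifelse(pos, "positive", "negative"),
    reason = ifelse(pos, NA_character_,
                    ifelse(not_eval, "not evaluable", "below threshold")),
    stringsAsFactors = FALSE)
}

#' Compute all four disproportionality statistics for a set of 2x2 tables
#'
#' Convenience wrapper: ROR, PRR, chi-square, BCPNN IC and MGPS EBGM for
#' every table, plus classification. The MGPS prior is fitted across all
#' supplied tables unless `theta` is given (the empirical-Bayes step needs
#' the whole database of tables at one level, unstratified).
#'
#' @param tables data.frame from [build_contingency_tables()] (columns
#'   `label`, `a`, `b`, `c`, `d`).
#' @param theta optional `mgps_fit` (or compatible list); fitted if `NULL`.
#' @param criteria a [signal_criteria()].
#' @param yates logical, Yates-corrected chi-square (default TRUE).
#' @param zero_cell zero-cell policy for ROR/PRR, see [ror_stats()].
#' @return data.frame: `label`, `a`, `E`, the statistic columns of
#'   `SignalStatistics`, `signal`, `reason`; attribute `mgps` holds the
#'   hyperparameter fit.
#' @export
compute_signal_stats <- function(tables, theta = NULL,
                                 criteria = signal_criteria(),
                                 yates = TRUE,
                                 zero_cell = c("undefined", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  a <- as.numeric(tables$a); b <- as.numeric(tables$b)
  c <- as.numeric(tables$c); d <- as.numeric(tables$d)
  N <- a + b + c + d
  E <- (a + b) * (a + c) / N
  if (is.null(theta)) theta <- fit_mgps(a, E)
  out <- cbind(
    data.frame(label = tables$label, a = a, E = E, stringsAsFactors = FALSE),
    ror_stats(a, b, c, d, zero_cell),
    prr_stats(a, b, c, d, zero_cell),
    chi2 = chi2_stat(a, b, c, d, yates = yates),
    bcpnn_ic(a, b, c, d),
    ebgm_scores(a, E, theta))
  out <- cbind(out, classify_signals(out, criteria))
  attr(out, "mgps") <- theta
  out
}
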