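#' Observed/expected cells for shrinkage-prior fitting
#'
#' Builds the (a, E) pairs over every normalized primary-suspect drug x PT
#' combination in a database, with `E` the usual independence expectation
#' from the report-level margins, `E = n_drug * n_pt / N`. By default only
#' cells with at least one co-occurrence are kept (no covariate
#' stratification is applied).
#'
#' @param x An `srs_reports` object.
#' @param min_count Keep cells with `a >=` this (default 1; 0 adds the full
#'   zero-cell grid).
#' @return Tibble with columns `drug_id`, `pt_code`, `a`, `E`.
#' @export
mgps_cells <- function(x, min_count = 1) {
  counts <- pair_counts(x)
  counts <- counts[counts$a >= min_count, ]
  tibble(drug_id = counts$drug_id, pt_code = counts$pt_code,
         a = counts$a, E = counts$n_drug * counts$n_pt / counts$n)
}

# Mixture negative-binomial marginal density of an observed count given E
# under the two-gamma prior. Returns the two component densities.
nb_components <- function(a, E, theta) {
  f1 <- dnbinom(a, size = theta$alpha1, prob = theta$beta1 / (theta$beta1 + E))
  f2 <- dnbinom(a, size = theta$alpha2, prob = theta$beta2 / (theta$beta2 + E))
  list(f1 = f1, f2 = f2)
}

mgps_loglik <- function(a, E, theta, wt = 1) {
  f <- nb_components(a, E, theta)
  sum(wt * log(pmax(theta$w * f$f1 + (1 - theta$w) * f$f2, 1e-300)))
}

# Cell squashing (the standard large-database device for gamma-Poisson
# shrinker fits): cells sharing the same observed count and a similar E are
# merged into one weighted point at the mean E. Counts above `keep_above`
# are left exact — high-count cells are rare and individually influential.
squash_cells <- function(a, E, bins = 50, keep_above = 50) {
  keep <- a > keep_above
  out <- list(a = a[keep], E = E[keep], wt = rep(1, sum(keep)))
  for (av in unique(a[!keep])) {
    Ei <- E[!keep & a == av]
    if (length(Ei) <= bins) {
      out$a <- c(out$a, rep(av, length(Ei)))
      out$E <- c(out$E, Ei)
      out$wt <- c(out$wt, rep(1, length(Ei)))
    } else {
      grp <- cut(rank(Ei, ties.method = "first"), bins, labels = FALSE)
      out$a <- c(out$a, rep(av, max(grp)))
      out$E <- c(out$E, as.numeric(tapply(Ei, grp, mean)))
      out$wt <- c(out$wt, as.numeric(tapply(Ei, grp, length)))
    }
  }
  out
}

# Weighted single-component NB fit used as the EM M-step: improves
# sum z_i log NB(a_i; alpha, beta/(beta+E_i)) over (alpha, beta) > 0 from a
# warm start, with analytic gradients on the log scale. The inner iteration
# count is capped (generalized EM): each M-step only needs to improve the
# weighted likelihood, not maximize it exactly.
fit_nb_component <- function(a, E, z, alpha0, beta0, maxit = 10) {
  negll <- function(par) {
    alpha <- exp(par[1]); beta <- exp(par[2])
    -sum(z * dnbinom(a, size = alpha, prob = beta / (beta + E), log = TRUE))
  }
  grad <- function(par) {
    alpha <- exp(par[1]); beta <- exp(par[2])
    d_alpha <- sum(z * (digamma(a + alpha) - digamma(alpha) +
                          log(beta) - log(beta + E)))
    d_beta <- sum(z * (alpha / beta - (alpha + a) / (beta + E))) * beta
    -c(d_alpha * alpha, d_beta)
  }
  fit <- optim(c(log(alpha0), log(beta0)), negll, gr = grad,
               method = "L-BFGS-B", lower = log(1e-6), upper = log(1e6),
               control = list(maxit = maxit))
  c(alpha = exp(fit$par[1]), beta = exp(fit$par[2]))
}

#' Fit the two-component gamma mixture prior (MGPS)
#'
#' Empirical-Bayes fit of the DuMouchel prior: the reporting-rate ratio of a
#' cell is modelled as `lambda ~ w Gamma(alpha1, beta1) + (1-w) Gamma(alpha2,
#' beta2)` (shape/rate), so the observed count is marginally a mixture of
#' negative binomials given `E`. The marginal likelihood is maximized by EM:
#' posterior component responsibilities in the E-step, weighted
#' negative-binomial fits per component in the M-step. Steps are accepted
#' only if the marginal log-likelihood does not decrease, so the accepted
#' trace is non-decreasing by construction.
#'
#' Because the mixture likelihood is multi-modal (a dominant near-null bulk
#' can absorb both components, hiding a rare high-ratio component), the fit
#' is run from several deterministic starting points and the best marginal
#' likelihood is kept; `start` prepends a user start to that list.
#'
#' @param cells Tibble/data.frame with columns `a` (observed count) and `E`
#'   (expected count, all positive), e.g. from [mgps_cells()].
#' @param start Primary starting hyperparameters
#'   `c(alpha1, beta1, alpha2, beta2, w)`; default `c(0.2, 0.1, 2, 4, 1/3)`.
#' @param max_iter Maximum EM iterations per start (default 500).
#' @param tol Convergence: log-likelihood improvement below `tol` for 3
#'   consecutive iterations (default 1e-8).
#' @param extra_starts List of additional start vectors (defaults cover a
#'   wide-signal component and a heavily null-weighted mixture).
#' @param squash Merge cells with equal count and similar E into weighted
#'   points before fitting (default when more than 5000 cells); the
#'   device DuMouchel's large-database fits use.
#' @return An `mgps_prior` object: `alpha1`, `beta1`, `alpha2`, `beta2`, `w`,
#'   `loglik`, `loglik_trace`, `converged`, `n_cells`, `n_iter`.
#' @export
fit_mgps_prior <- function(cells, start = c(0.2, 0.1, 2.0, 4.0, 1 / 3),
                           max_iter = 500, tol = 1e-8,
                           extra_starts = list(c(1, 1, 0.5, 0.1, 0.7),
                                               c(2, 2, 0.2, 0.04, 0.9),
                                               c(0.5, 0.5, 5, 1, 0.5),
                                               c(1, 1, 10, 1.2, 0.99),
                                               c(1, 1, 4, 0.5, 0.999)),
                           squash = NULL) {
  a <- as.numeric(cells$a); E <- as.numeric(cells$E)
  stopifnot(length(a) == length(E), all(E > 0), all(a >= 0))
  if (length(a) < 100)
    warning("fewer than 100 cells: the mixture prior may be poorly identified")
  n_cells <- length(a)
  squash <- squash %||% (n_cells > 5000)
  if (squash) {
    sq <- squash_cells(a, E)
    a <- sq$a; E <- sq$E; wt <- sq$wt
  } else wt <- rep(1, n_cells)
  fits <- lapply(c(list(start), extra_starts), function(s)
    mgps_em(a, E, wt, s, max_iter = max_iter, tol = tol))
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  best <- mgps_polish(a, E, wt, best)
  best$n_cells <- n_cells
  if (!best$converged)
    warning("MGPS EM did not converge within ", max_iter,
            " iterations; returning best fit so far")
  best
}

mgps_em <- function(a, E, wt, start, max_iter = 500, tol = 1e-8) {
  theta <- list(alpha1 = start[1], beta1 = start[2], alpha2 = start[3],
                beta2 = start[4], w = start[5])
  ll <- mgps_loglik(a, E, theta, wt)
  trace <- ll
  below <- 0L
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    f <- nb_components(a, E, theta)
    denom <- pmax(theta$w * f$f1 + (1 - theta$w) * f$f2, 1e-300)
    z <- theta$w * f$f1 / denom
    w_new <- min(max(sum(wt * z) / sum(wt), 1e-6), 1 - 1e-6)
    c1 <- fit_nb_component(a, E, wt * z, theta$alpha1, theta$beta1)
    c2 <- fit_nb_component(a, E, wt * (1 - z), theta$alpha2, theta$beta2)
    cand <- list(alpha1 = c1[["alpha"]], beta1 = c1[["beta"]],
                 alpha2 = c2[["alpha"]], beta2 = c2[["beta"]], w = w_new)
    ll_new <- mgps_loglik(a, E, cand, wt)
    if (ll_new >= ll - 1e-10) {   # accept; EM guarantees non-decrease up to numerics
      improve <- ll_new - ll
      theta <- cand
      ll <- max(ll_new, ll)
      trace <- c(trace, ll)
      below <- if (improve < tol) below + 1L else 0L
      if (below >= 3L) { converged <- TRUE; break }
    } else {
      converged <- TRUE  # no improving step available: local maximum reached
      break
    }
  }
  structure(list(alpha1 = theta$alpha1, beta1 = theta$beta1,
                 alpha2 = theta$alpha2, beta2 = theta$beta2, w = theta$w,
                 loglik = ll, loglik_trace = trace, converged = converged,
                 n_cells = length(a), n_iter = iter),
            class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat(sprintf(paste0("<mgps_prior> w=%.3f  G1(shape=%.3f, rate=%.3f)  ",
                     "G2(shape=%.3f, rate=%.3f)\n  loglik=%.2f on %d cells (%d iter%s)\n"),
              x$w, x$alpha1, x$beta1, x$alpha2, x$beta2, x$loglik, x$n_cells,
              x$n_iter, if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

# Joint quasi-Newton refinement of all five hyperparameters from the EM
# solution; accepted only when the marginal likelihood improves, so the
# reported trace stays non-decreasing.
mgps_polish <- function(a, E, wt, fit) {
  negll <- function(p) {
    th <- list(alpha1 = exp(p[1]), beta1 = exp(p[2]), alpha2 = exp(p[3]),
               beta2 = exp(p[4]), w = stats::plogis(p[5]))
    -mgps_loglik(a, E, th, wt)
  }
  p0 <- c(log(fit$alpha1), log(fit$beta1), log(fit$alpha2), log(fit$beta2),
          stats::qlogis(min(max(fit$w, 1e-6), 1 - 1e-6)))
  o <- tryCatch(optim(p0, negll, method = "BFGS", control = list(maxit = 200)),
                error = function(e) NULL)
  if (!is.null(o) && -o$value > fit$loglik) {
    fit$alpha1 <- exp(o$par[1]); fit$beta1 <- exp(o$par[2])
    fit$alpha2 <- exp(o$par[3]); fit$beta2 <- exp(o$par[4])
    fit$w <- stats::plogis(o$par[5])
    fit$loglik <- -o$value
    fit$loglik_trace <- c(fit$loglik_trace, fit$loglik)
  }
  # first-order convergence is judged at the refined solution: a clean
  # quasi-Newton stop means a local optimum was reached even if the EM
  # warm-up used all its iterations
  if (!is.null(o) && o$convergence == 0) fit$converged <- TRUE
  fit
}

#' Construct an MGPS prior from known hyperparameters
#'
#' @param alpha1,beta1,alpha2,beta2 Positive shape/rate parameters.
#' @param w Mixture weight in (0,1) on the first component.
#' @return An `mgps_prior` object (no fit metadata).
#' @export
mgps_prior <- function(alpha1, beta1, alpha2, beta2, w) {
  stopifnot(alpha1 > 0, beta1 > 0, alpha2 > 0, beta2 > 0, w > 0, w < 1)
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, w = w, loglik = NA_real_,
                 loglik_trace = numeric(), converged = NA, n_cells = NA_integer_,
                 n_iter = 0L), class = "mgps_prior")
}

#' Simulate observed counts from an MGPS prior
#'
#' Draws each cell's rate ratio from the two-gamma mixture and the count from
#' Poisson(lambda * E) — the generative model under which the marginal of the
#' count is the negative-binomial mixture the fitter maximizes. Used for
#' parameter-recovery checks.
#'
#' @param E Vector of expected counts (one cell each).
#' @param prior An `mgps_prior`.
#' @return Tibble with columns `a`, `E`, `lambda`, `component`.
#' @export
simulate_mgps_cells <- function(E, prior) {
  n <- length(E)
  comp <- 1L + (runif(n) >= prior$w)
  lambda <- ifelse(comp == 1L,
                   rgamma(n, shape = prior$alpha1, rate = prior$beta1),
                   rgamma(n, shape = prior$alpha2, rate = prior$beta2))
  a <- rpois(n, lambda * E)
  tibble(a = a, E = E, lambda = lambda, component = comp)
}

#' Posterior geometric mean and lower percentile (EBGM / EB05)
#'
#' Given a fitted prior, the posterior of a cell's rate ratio is a mixture of
#' `Gamma(alpha_k + a, beta_k + E)` with weights proportional to the prior
#' weight times the component's negative-binomial marginal. `EBGM =
#' 2^(E[log2 lambda | a])` via the digamma function; the lower bound is the
#' requested posterior percentile (default the 5th, the MGPS convention),
#' found by monotone root finding on the mixture CDF to 1e-8. Vectorised
#' over cells.
#'
#' @param a Observed count(s).
#' @param E Expected count(s).
#' @param prior An `mgps_prior`.
#' @param quantile Lower posterior percentile (default 0.05).
#' @return Tibble with columns `ebgm`, `ebgm05`, `q1` (posterior weight of
#'   the first component).
#' @export
ebgm_with_eb05 <- function(a, E, prior, quantile = 0.05) {
  stopifnot(inherits(prior, "mgps_prior"), length(a) == length(E), all(E > 0))
  f <- nb_components(a, E, prior)
  q1 <- prior$w * f$f1 / pmax(prior$w * f$f1 + (1 - prior$w) * f$f2, 1e-300)
  s1 <- prior$alpha1 + a; r1 <- prior$beta1 + E
  s2 <- prior$alpha2 + a; r2 <- prior$beta2 + E
  mean_log <- q1 * (digamma(s1) - log(r1)) + (1 - q1) * (digamma(s2) - log(r2))
  ebgm <- exp(mean_log)
  eb05 <- vapply(seq_along(a), function(i) {
    cdf <- function(x) q1[i] * pgamma(x, s1[i], rate = r1[i]) +
      (1 - q1[i]) * pgamma(x, s2[i], rate = r2[i]) - quantile
    lo <- min(qgamma(quantile, s1[i], rate = r1[i]),
              qgamma(quantile, s2[i], rate = r2[i]))
    hi <- max(qgamma(quantile, s1[i], rate = r1[i]),
              qgamma(quantile, s2[i], rate = r2[i]))
    if (hi - lo < 1e-12) return(lo)
    uniroot(cdf, lower = lo, upper = hi, tol = 1e-8, extendInt = "upX")$root
  }, numeric(1))
  tibble(ebgm = ebgm, ebgm05 = eb05, q1 = q1)
}
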