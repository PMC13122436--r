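#' Fit a two-component normal mixture by EM
#'
#' Maximum-likelihood fit of \eqn{w_1 N(\mu_1,\sigma_1^2) + w_2 N(\mu_2,\sigma_2^2)}
#' by expectation-maximisation with multiple starts: one deterministic start
#' from the lower/upper sample halves split at the median, one from the
#' 0.25/0.75 quantiles, and three seeded random starts (means drawn from the
#' sample, pooled SD). The best log-likelihood wins. A start is abandoned as
#' degenerate when a component SD collapses below `1e-6 * sd(x)`.
#'
#' @param x Numeric sample, n >= 10, non-constant.
#' @param seed Integer seed for the random starts.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum EM iterations per start.
#' @param n_starts Total number of starts (2 deterministic + the rest random).
#' @return An object of class `mixture_fit`: `lambda` (weights, sum 1), `mu`
#'   (ascending), `sigma`, `loglik`, `n_iter`, `converged`.
#' @export
fit_mixture <- function(x, seed = 1L, tol = 1e-8, max_iter = 1000L,
                        n_starts = 5L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) stop("mixture fit needs n >= 10", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant sample", call. = FALSE)
  sd_floor <- 1e-6 * stats::sd(x)

  em_one <- function(mu, sigma, lambda) {
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      d1 <- lambda[1] * stats::dnorm(x, mu[1], sigma[1])
      d2 <- lambda[2] * stats::dnorm(x, mu[2], sigma[2])
      tot <- d1 + d2
      if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
      ll <- sum(log(tot))
      g1 <- d1 / tot
      w1 <- sum(g1); w2 <- n - w1
      if (w1 < 1e-8 || w2 < 1e-8) return(NULL)
      mu <- c(sum(g1 * x) / w1, sum((1 - g1) * x) / w2)
      sigma <- c(sqrt(sum(g1 * (x - mu[1])^2) / w1),
                 sqrt(sum((1 - g1) * (x - mu[2])^2) / w2))
      if (any(sigma < sd_floor)) return(NULL)
      lambda <- c(w1, w2) / n
      if (abs(ll - ll_old) < tol) {
        return(list(lambda = lambda, mu = mu, sigma = sigma, loglik = ll,
                    n_iter = it, converged = TRUE))
      }
      ll_old <- ll
    }
    list(lambda = lambda, mu = mu, sigma = sigma, loglik = ll_old,
         n_iter = max_iter, converged = FALSE)
  }

  xs <- sort(x)
  half <- list(xs[seq_len(floor(n / 2))], xs[seq.int(floor(n / 2) + 1, n)])
  starts <- list(
    list(mu = vapply(half, mean, 0),
         sigma = pmax(vapply(half, stats::sd, 0), sd_floor * 10,
                      na.rm = TRUE),
         lambda = c(0.5, 0.5)),
    list(mu = stats::quantile(x, c(0.25, 0.75), names = FALSE),
         sigma = rep(stats::sd(x) / 2, 2), lambda = c(0.5, 0.5))
  )
  rand <- with_local_seed(seed, {
    lapply(seq_len(max(0L, n_starts - 2L)), function(i) {
      list(mu = sort(sample(x, 2)), sigma = rep(stats::sd(x), 2),
           lambda = c(0.5, 0.5))
    })
  })
  fits <- lapply(c(starts, rand), function(s) {
    if (s$mu[1] == s$mu[2]) s$mu <- s$mu + c(-0.5, 0.5) * stats::sd(x)
    em_one(s$mu, s$sigma, s$lambda)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    stop("all EM starts collapsed to a degenerate component", call. = FALSE)
  }
  best <- fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]
  ord <- order(best$mu)
  best$mu <- best$mu[ord]; best$sigma <- best$sigma[ord]
  best$lambda <- best$lambda[ord]
  structure(best, class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> w = %.3f/%.3f, mu = %.2f/%.2f, sigma = %.2f/%.2f, logLik %.2f (%s, %d it)\n",
    x$lambda[1], x$lambda[2], x$mu[1], x$mu[2], x$sigma[1], x$sigma[2],
    x$loglik, if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Density-crossing cutoff between the two mixture components
#'
#' Root of \eqn{w_1 \phi_1(x) - w_2 \phi_2(x) = 0} between the two component
#' means, found by bracketed root finding to 1e-6 mm. This is the point where
#' the weighted component densities exchange dominance; below it component 1
#' (the smaller mode) dominates, above it component 2. Errors if the
#' difference does not change sign between the means (components too
#' overlapping for a meaningful cutoff).
#'
#' @param fit A [fit_mixture()] result (or any list with `lambda`, `mu`,
#'   `sigma`, means distinct).
#' @param tol Root-finding tolerance.
#' @return The cutoff (same units as the data).
#' @export
density_crossing <- function(fit, tol = 1e-6) {
  if (fit$mu[1] >= fit$mu[2]) stop("component means must be distinct and ordered",
                                   call. = FALSE)
  f <- function(z) fit$lambda[1] * stats::dnorm(z, fit$mu[1], fit$sigma[1]) -
    fit$lambda[2] * stats::dnorm(z, fit$mu[2], fit$sigma[2])
  flo <- f(fit$mu[1]); fhi <- f(fit$mu[2])
  if (!(flo > 0 && fhi < 0)) {
    stop("no dominance exchange between the component means: ",
         "components overlap too severely", call. = FALSE)
  }
  stats::uniroot(f, c(fit$mu[1], fit$mu[2]), tol = tol)$root
}

#' Classify migratory phenotype from natal-exit size
#'
#' Early iff natal-exit fork length is at or below the cutoff (boundary
#' inclusive: a fish exactly at the cutoff left "at or below" it).
#'
#' @param natal_exit_fl Natal-exit fork length (mm), vectorised.
#' @param cutoff_fl Cutoff (mm).
#' @return Character vector `"early"` / `"late"`.
#' @export
classify_phenotype <- function(natal_exit_fl, cutoff_fl) {
  ifelse(natal_exit_fl <= cutoff_fl, "early", "late")
}

#' Estimate the early/late phenotype cutoff from pooled natal-exit sizes
#'
#' Full phenotype-model pipeline on a pooled sample of natal-exit fork
#' lengths: Hartigan's dip test for multimodality, two-component mixture fit,
#' density-crossing cutoff, and the cutoff expressed as an otolith radius.
#'
#' @param natal_exit_fl Pooled natal-exit fork lengths (mm).
#' @param seed Seed for the dip bootstrap and EM random starts.
#' @param n_boot Dip-test bootstrap resamples.
#' @param p [backcalc_params()] for the radius conversion.
#' @return A list of class `phenotype_cutoff`: `cutoff_fl`, `cutoff_radius`,
#'   `dip_statistic`, `dip_pvalue`, `fit`.
#' @export
phenotype_cutoff <- function(natal_exit_fl, seed = 1L, n_boot = 500L,
                             p = backcalc_params()) {
  dt <- dip_test(natal_exit_fl, n_boot = n_boot, seed = seed)
  fit <- fit_mixture(natal_exit_fl, seed = seed)
  cut <- density_crossing(fit)
  structure(list(cutoff_fl = cut,
                 cutoff_radius = radius_from_fl(cut, p),
                 dip_statistic = dt$statistic,
                 dip_pvalue = dt$p_value,
                 fit = fit),
            class = "phenotype_cutoff")
}

#' @export
print.phenotype_cutoff <- function(x, ...) {
  cat(sprintf(
    "<phenotype_cutoff> %.1f mm (%.0f um); dip D = %.4f, p = %.4g\n",
    x$cutoff_fl, x$cutoff_radius, x$dip_statistic, x$dip_pvalue))
  invisible(x)
}
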