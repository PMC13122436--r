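#' Hartigan's dip statistic
#'
#' Maximum distance between the empirical CDF and the closest unimodal CDF,
#' computed with the classical iterative greatest-convex-minorant /
#' least-concave-majorant (GCM/LCM) construction: the candidate modal
#' interval is shrunk repeatedly to the largest-discrepancy bracket between
#' the GCM and LCM of the ECDF, accumulating the one-sided deviations of the
#' ECDF from the GCM (left of the modal interval) and the LCM (right of it);
#' the dip is half the largest accumulated deviation. The statistic is
#' bounded below by 1/(2n) and is invariant to the ordering of the input.
#'
#' @param x Numeric sample (need not be sorted).
#' @return The dip statistic D (dimensionless, in `[1/(2n), 1/4]`).
#' @export
#' @examples
#' dip_stat(c(0, 1))       # 0.25, the two-point maximum
dip_stat <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 1) stop("empty sample", call. = FALSE)
  if (n == 1 || x[1] == x[n]) return(0)
  low <- 1L; high <- n
  dip <- 1 / n  # working value is 2*D; halved on return

  # Greatest convex minorant "predecessor" pointers over the whole sample:
  # mn[j] is the previous touch point when the GCM is extended to j.
  mn <- integer(n); mn[1] <- 1L
  for (j in 2:n) {
    mn[j] <- j - 1L
    repeat {
      mnj <- mn[j]
      if (mnj == 1L) break
      mnmnj <- mn[mnj]
      if ((x[j] - x[mnj]) * (mnj - mnmnj) <
          (x[mnj] - x[mnmnj]) * (j - mnj)) break
      mn[j] <- mnmnj
    }
  }
  # Least concave majorant "successor" pointers.
  mj <- integer(n); mj[n] <- n
  for (k in (n - 1L):1L) {
    mj[k] <- k + 1L
    repeat {
      mjk <- mj[k]
      if (mjk == n) break
      mjmjk <- mj[mjk]
      if ((x[k] - x[mjk]) * (mjk - mjmjk) <
          (x[mjk] - x[mjmjk]) * (k - mjk)) break
      mj[k] <- mjmjk
    }
  }

  repeat {
    # GCM touch points from high down to low; LCM touch points low to high.
    gcm <- high
    while (gcm[length(gcm)] > low) gcm <- c(gcm, mn[gcm[length(gcm)]])
    lcm <- low
    while (lcm[length(lcm)] < high) lcm <- c(lcm, mj[lcm[length(lcm)]])
    l_gcm <- length(gcm); l_lcm <- length(lcm)

    ig <- l_gcm; ih <- l_lcm
    if (l_gcm > 2L || l_lcm > 2L) {
      # Walk both curves from the low end, recording the largest
      # ECDF-gap between the GCM and the LCM inside [low, high].
      ix <- l_gcm - 1L; iv <- 2L; d <- 0
      repeat {
        gcmix <- gcm[ix]; lcmiv <- lcm[iv]
        if (gcmix > lcmiv) {
          gcmi1 <- gcm[ix + 1L]
          dx <- (lcmiv - gcmi1 + 1L) / n -
            (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1) /
            (n * (x[gcmix] - x[gcmi1]))
          iv <- iv + 1L
          if (dx >= d) { d <- dx; ig <- ix + 1L; ih <- iv - 1L }
        } else {
          lcmiv1 <- lcm[iv - 1L]
          dx <- (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1) /
            (n * (x[lcmiv] - x[lcmiv1])) -
            (gcmix - lcmiv1 - 1L) / n
          ix <- ix - 1L
          if (dx > d) { d <- dx; ig <- ix + 1L; ih <- iv }
        }
        if (ix < 1L) ix <- 1L
        if (iv > l_lcm) iv <- l_lcm
        if (gcm[ix] == lcm[iv]) break
      }
    } else {
      d <- 1 / n
    }
    if (d < dip) break

    # One-sided dip of the ECDF over the GCM segments outside the new modal
    # interval (indices gcm[ig] down to low) ...
    dip_l <- 0
    if (ig <= l_gcm - 1L) for (j in ig:(l_gcm - 1L)) {
      max_t <- 1 / n
      jb <- gcm[j + 1L]; je <- gcm[j]
      if (je - jb > 1L && x[je] != x[jb]) {
        C <- (je - jb) / (n * (x[je] - x[jb]))
        jj <- jb:je
        t <- (jj - jb + 1L) / n - (x[jj] - x[jb]) * C
        max_t <- max(max_t, t)
      }
      dip_l <- max(dip_l, max_t)
    }
    # ... and over the LCM segments (indices low up to lcm[ih]).
    dip_u <- 0
    if (ih <= l_lcm - 1L) for (j in ih:(l_lcm - 1L)) {
      max_t <- 1 / n
      jb <- lcm[j]; je <- lcm[j + 1L]
      if (je - jb > 1L && x[je] != x[jb]) {
        C <- (je - jb) / (n * (x[je] - x[jb]))
        jj <- jb:je
        t <- -((jj - jb - 1L) / n - (x[jj] - x[jb]) * C)
        max_t <- max(max_t, t)
      }
      dip_u <- max(dip_u, max_t)
    }

    dip <- max(dip, dip_l, dip_u)
    if (low == gcm[ig] && high == lcm[ih]) break
    low <- gcm[ig]
    high <- lcm[ih]
  }
  dip / 2
}

#' Dip test of unimodality with a uniform bootstrap null
#'
#' Tests whether a sample is consistent with a unimodal distribution.
#' The p-value is obtained by Monte Carlo: the dip of the observed sample is
#' compared against the dips of `n_boot` uniform(0,1) samples of the same
#' size (the uniform is the least-favourable unimodal null, so the test is
#' exact against it and conservative against peaked unimodal distributions
#' such as the normal). The Monte Carlo p-value uses the add-one rank
#' correction, `(1 + #\{D_b >= D\}) / (n_boot + 1)`.
#'
#' @param x Numeric sample, n >= 4.
#' @param n_boot Number of null resamples (values below 100 trigger a
#'   warning).
#' @param seed Integer seed for the null resamples.
#' @return A list with `statistic` (D), `p_value`, `n`, `n_boot`.
#' @export
dip_test <- function(x, n_boot = 500L, seed = 1L) {
  n <- length(x)
  if (n < 4) stop("dip test needs at least 4 observations", call. = FALSE)
  if (n_boot < 100) warning("n_boot < 100: p-value will be coarse")
  D <- dip_stat(x)
  boot <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) dip_stat(stats::runif(n)), 0)
  })
  list(statistic = D,
       p_value = (1 + sum(boot >= D)) / (n_boot + 1),
       n = n, n_boot = n_boot)
}

# evaluate an expression under a local RNG seed without disturbing the
# caller's RNG state
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
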