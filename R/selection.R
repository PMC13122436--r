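#' Standardized selection differential between an initial sample and its
#' survivors
#'
#' \deqn{i = (\bar z^*_t - \bar z_t) / v_t}
#'
#' where \eqn{\bar z_t} and \eqn{v_t} are the mean and variance (n-1
#' denominator) of the trait in the initial population at time t and
#' \eqn{\bar z^*_t} the mean of the survivors, measured on the same trait
#' recorded at the same earlier life stage (here: natal-exit fork length).
#' Positive values mean survivors were larger - relatively lower survival
#' of smaller outmigrants. The classical standardized differential divides
#' by the SD instead; `standardize_by = "sd"` switches to that convention.
#'
#' @param init_sizes Trait values (mm) in the initial sample.
#' @param surv_sizes Trait values (mm) in the surviving sample.
#' @param standardize_by `"variance"` (default) or `"sd"`.
#' @return A one-row data.frame: `i`, `z_bar_init`, `z_bar_surv`, `v_init`,
#'   `n_init`, `n_surv`.
#' @export
selection_differential <- function(init_sizes, surv_sizes,
                                   standardize_by = c("variance", "sd")) {
  standardize_by <- match.arg(standardize_by)
  if (length(init_sizes) < 2) stop("n_init < 2", call. = FALSE)
  if (length(surv_sizes) < 1) stop("empty survivor sample", call. = FALSE)
  v <- stats::var(init_sizes)
  if (v == 0) stop("zero variance in the initial sample", call. = FALSE)
  denom <- if (standardize_by == "variance") v else sqrt(v)
  data.frame(i = (mean(surv_sizes) - mean(init_sizes)) / denom,
             z_bar_init = mean(init_sizes),
             z_bar_surv = mean(surv_sizes),
             v_init = v,
             n_init = length(init_sizes),
             n_surv = length(surv_sizes))
}

#' Selection differentials for the Delta, Ocean and All segments by year
#'
#' Computes per-year differentials on natal-exit fork length between
#' sequential sampling points:
#'
#' * `Delta`: juveniles entering vs. leaving the Delta,
#' * `Ocean`: juveniles leaving the Delta vs. cohort-matched adults,
#' * `All`: juveniles entering the Delta vs. adults.
#'
#' Adults are matched to outmigration year as
#' `escapement_year - age + 1` (returns at age a outmigrated a-1 springs
#' before the fall they return). A segment-year whose endpoint sample is
#' missing (or smaller than `min_n`) is skipped with a log attribute.
#'
#' @param records Data.frame with columns `point` (one of `"delta-entry"`,
#'   `"delta-exit"`, `"adult"`; other labels ignored), `year` (outmigration
#'   year; for adults, already converted), and `natal_exit_fl`.
#' @param standardize_by Passed to [selection_differential()].
#' @param min_n Minimum sample size per endpoint.
#' @return Data.frame of per-segment-year results with a `skipped` attribute
#'   listing segment-years that could not be computed.
#' @export
segment_differentials <- function(records,
                                  standardize_by = c("variance", "sd"),
                                  min_n = 2L) {
  standardize_by <- match.arg(standardize_by)
  segs <- list(Delta = c("delta-entry", "delta-exit"),
               Ocean = c("delta-exit", "adult"),
               All = c("delta-entry", "adult"))
  years <- sort(unique(records$year))
  out <- list(); skipped <- character()
  grab <- function(point, yr) {
    v <- records$natal_exit_fl[records$point == point & records$year == yr]
    v[!is.na(v)]
  }
  for (seg in names(segs)) {
    for (yr in years) {
      a <- grab(segs[[seg]][1], yr); b <- grab(segs[[seg]][2], yr)
      if (length(a) < min_n || length(b) < max(1L, min_n - 1L)) {
        skipped <- c(skipped, paste0(seg, ":", yr))
        next
      }
      row <- selection_differential(a, b, standardize_by)
      out[[length(out) + 1]] <- cbind(
        data.frame(segment = seg, year = yr), row)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(segment = character(), year = integer(), i = numeric(),
               z_bar_init = numeric(), z_bar_surv = numeric(),
               v_init = numeric(), n_init = integer(), n_surv = integer())
  attr(res, "skipped") <- skipped
  res
}

#' Convert adult escapement years to outmigration years
#'
#' @param escapement_year Fall return (carcass survey) year.
#' @param age Return age (2-4).
#' @return Outmigration year, `escapement_year - age + 1`.
#' @export
outmigration_year <- function(escapement_year, age) {
  escapement_year - age + 1
}

#' Regress selection differentials (or any annual response) on a covariate
#'
#' Ordinary least squares with a linear or quadratic form
#' (`y ~ x` or `y ~ x + I(x^2)`), reported the way the annual-covariate
#' analyses are: coefficients, overall F, p, and adjusted R-squared.
#'
#' @param y Response (one value per year).
#' @param x Covariate (e.g., mean Jan-June natal-river flow in CFS,
#'   mean Delta-entry size in mm, or log escapement the previous fall).
#' @param form `"linear"` or `"quadratic"`.
#' @return A list: `coefficients`, `fstatistic`, `p_value`, `adj_r_squared`,
#'   `model` (the `lm` fit).
#' @export
regress_i <- function(y, x, form = c("linear", "quadratic")) {
  form <- match.arg(form)
  n_par <- if (form == "linear") 2L else 3L
  keep <- stats::complete.cases(y, x)
  if (sum(keep) < n_par + 2L) {
    stop("need at least p + 2 observations for ", form, " regression",
         call. = FALSE)
  }
  d <- data.frame(y = y[keep], x = x[keep])
  fit <- if (form == "linear") stats::lm(y ~ x, data = d)
         else stats::lm(y ~ x + I(x^2), data = d)
  if (fit$rank < n_par) stop("rank-deficient design", call. = FALSE)
  s <- summary(fit)
  fs <- s$fstatistic
  pval <- if (is.null(fs)) NA_real_ else
    stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  list(coefficients = stats::coef(fit),
       fstatistic = unname(if (is.null(fs)) NA_real_ else fs[1]),
       p_value = unname(pval),
       adj_r_squared = s$adj.r.squared,
       model = fit)
}

#' Expand otolith samples to match observed catch distributions
#'
#' Sensitivity tool for unbalanced trawl sampling: within each time bin the
#' otolith-sampled fish are resampled with replacement in proportion to the
#' observed catch, so the expanded sample mimics the catch's temporal
#' distribution. A bin with catch but no otolith samples is merged into the
#' subsequent bin before resampling; it is an error if the final bin cannot
#' be resolved this way.
#'
#' @param otolith_bins Integer/character bin label per otolith-sampled fish.
#' @param values Value carried per fish (e.g., natal-exit FL).
#' @param catch_counts Named numeric vector: catch per bin, names matching
#'   the bin labels, in temporal order.
#' @param total Expanded sample size; defaults to the total catch (capped at
#'   `max_total`).
#' @param max_total Cap on the expanded sample size; bin catches are used as
#'   proportions.
#' @param seed Integer seed.
#' @return Numeric vector of resampled `values` of length `total`.
#' @export
expand_to_catch <- function(otolith_bins, values, catch_counts,
                            total = NULL, max_total = 10000L, seed = 1L) {
  stopifnot(length(otolith_bins) == length(values))
  bins <- names(catch_counts)
  if (is.null(bins)) stop("catch_counts must be named by bin", call. = FALSE)
  # merge forward: a bin with catch but no samples joins the next bin
  catch <- as.numeric(catch_counts)
  names(catch) <- bins
  have <- vapply(bins, function(b) sum(otolith_bins == b) > 0, TRUE)
  i <- 1L
  while (i <= length(catch)) {
    if (catch[i] > 0 && !have[i]) {
      if (i == length(catch)) {
        stop("bin '", names(catch)[i],
             "' has catch but no otolith samples even after merging",
             call. = FALSE)
      }
      catch[i + 1L] <- catch[i + 1L] + catch[i]
      catch[i] <- 0
    }
    i <- i + 1L
  }
  if (is.null(total)) total <- min(sum(catch), max_total)
  shares <- catch / sum(catch)
  with_local_seed(seed, {
    n_per <- stats::rmultinom(1, total, shares)[, 1]
    out <- unlist(lapply(seq_along(bins), function(j) {
      if (n_per[j] == 0) return(numeric())
      pool <- values[otolith_bins == bins[j]]
      pool[sample.int(length(pool), n_per[j], replace = TRUE)]
    }))
    out
  })
}
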