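#' Hatchery fraction of escapement, expanded for unsampled marked fish
#'
#' Carcass surveys skip adipose-fin-clipped (marked) hatchery fish, which
#' represent `marking_rate` of hatchery production, so the hatchery-assigned
#' sample is expanded by `1 / (1 - marking_rate)` before computing the
#' hatchery fraction. The exact reciprocal is used internally (1/0.75 =
#' 1.333...), displayed as 1.33 at two decimals.
#'
#' @param n_hatchery_assigned,n_wild_assigned Otolith/lens-assigned counts
#'   among the sampled (unmarked) carcasses.
#' @param marking_rate Fraction of hatchery fish that are marked.
#' @return Estimated hatchery fraction of the total escapement.
#' @export
#' @examples
#' hatchery_fraction(30, 70, 0.25) # expanded 40 / (40 + 70)
hatchery_fraction <- function(n_hatchery_assigned, n_wild_assigned,
                              marking_rate = 0.25) {
  if (any(n_hatchery_assigned < 0) || any(n_wild_assigned < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(marking_rate < 0 | marking_rate >= 1)) {
    stop("marking_rate must lie in [0, 1)", call. = FALSE)
  }
  if (any(n_hatchery_assigned + n_wild_assigned == 0)) {
    stop("no assigned fish", call. = FALSE)
  }
  expanded <- n_hatchery_assigned / (1 - marking_rate)
  expanded / (expanded + n_wild_assigned)
}

#' Natural-origin escapement
#'
#' @param total_escapement Total spawner count.
#' @param fraction_hatchery Hatchery fraction (e.g. [hatchery_fraction()]).
#' @return Estimated natural-origin spawner count.
#' @export
natural_escapement <- function(total_escapement, fraction_hatchery) {
  total_escapement * (1 - fraction_hatchery)
}

#' Cohort replacement rate of natural-origin fish
#'
#' Returns per spawner for a brood year: the natural-origin returns
#' attributed to brood year B are the age-a fractions of natural escapement
#' in years B+2, B+3, B+4, and the rate divides their sum by the natural
#' escapement in B. Years missing age fractions are imputed with the
#' unweighted mean age fractions across years that have them. An
#' `age3_only` variant attributes every return to age 3.
#'
#' @param cohort_table Data.frame with columns `year`, `natural_escapement`,
#'   and (unless `age3_only`) `age2`, `age3`, `age4` (fractions summing to 1,
#'   `NA` allowed for whole years).
#' @param brood_year Brood (spawning) year B.
#' @param age3_only Attribute all returns to age 3.
#' @return A one-row data.frame: `label` ("B/B+1", brood year / offspring
#'   outmigration year), `spawners`, `returns`, `crr`.
#' @export
cohort_replacement <- function(cohort_table, brood_year, age3_only = FALSE) {
  ct <- cohort_table
  row_of <- function(y) ct[ct$year == y, , drop = FALSE]
  b <- row_of(brood_year)
  if (nrow(b) != 1) stop("brood year ", brood_year, " not in table",
                         call. = FALSE)
  if (is.na(b$natural_escapement) || b$natural_escapement <= 0) {
    stop("no natural spawners recorded for brood year ", brood_year,
         call. = FALSE)
  }
  ages <- 2:4
  if (age3_only) {
    r <- row_of(brood_year + 3)
    returns <- if (nrow(r)) r$natural_escapement else NA_real_
  } else {
    frac_cols <- c("age2", "age3", "age4")
    if (!all(frac_cols %in% names(ct))) {
      stop("cohort table lacks age-fraction columns", call. = FALSE)
    }
    mean_frac <- colMeans(ct[stats::complete.cases(ct[frac_cols]),
                             frac_cols, drop = FALSE])
    mean_frac <- mean_frac / sum(mean_frac)
    returns <- 0
    for (a in ages) {
      r <- row_of(brood_year + a)
      if (nrow(r) != 1 || is.na(r$natural_escapement)) {
        stop("natural escapement missing for return year ", brood_year + a,
             call. = FALSE)
      }
      f <- r[[paste0("age", a)]]
      if (is.na(f)) f <- mean_frac[[paste0("age", a)]]
      returns <- returns + r$natural_escapement * f
    }
  }
  data.frame(label = paste0(brood_year, "/", brood_year + 1),
             spawners = b$natural_escapement,
             returns = returns,
             crr = returns / b$natural_escapement)
}

#' Cohort replacement rates for all computable brood years
#'
#' @inheritParams cohort_replacement
#' @return Data.frame of [cohort_replacement()] rows for every brood year
#'   whose return years are covered by the table.
#' @export
cohort_replacement_series <- function(cohort_table, age3_only = FALSE) {
  yrs <- sort(cohort_table$year)
  need <- if (age3_only) 3 else 4
  ok <- yrs[yrs + need <= max(yrs)]
  ok <- ok[!is.na(cohort_table$natural_escapement[match(ok, cohort_table$year)])]
  do.call(rbind, lapply(ok, function(b)
    cohort_replacement(cohort_table, b, age3_only)))
}

#' Quadratic flow regression of cohort replacement rates
#'
#' OLS of the replacement rate on mean Jan-June natal-river flow and its
#' square; a thin wrapper over [regress_i()] kept separate because it is the
#' demography-level analysis (rates vs. hydrology) rather than the
#' selection-level one.
#'
#' @param rates Replacement rates (one per brood year).
#' @param flows Mean Jan-June flow (CFS) in the offspring outmigration year.
#' @param form `"quadratic"` (default) or `"linear"`.
#' @return See [regress_i()].
#' @export
crr_flow_regression <- function(rates, flows, form = "quadratic") {
  regress_i(rates, flows, form = form)
}
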