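#' Synthetic otolith profile from a true life history
#'
#' Inverse of the threshold reconstruction: builds the piecewise-linear
#' \eqn{^{87}Sr/^{86}Sr} and SrV transects implied by a fish's true natal and
#' freshwater exit sizes. The ratio profile sits on the natal-river plateau
#' (above the natal threshold), descends through the natal threshold exactly
#' at the radius equivalent to the true natal-exit fork length, plateaus at
#' the Delta water value, then rises through the Delta-exit threshold exactly
#' at the radius of the true freshwater exit, ending on the ocean plateau.
#' Rapid migrants (natal exit equal to freshwater exit) skip the Delta dip
#' entirely: their profile rises directly from the natal plateau to the ocean
#' value and never crosses either ratio threshold, so only the SrV rise
#' (centred so its normalized value passes the SrV exit fraction exactly at
#' the freshwater-exit radius) records their departure.
#'
#' With zero measurement noise, linear interpolation between 10-um spots
#' recovers both exit radii exactly (the crossing always falls inside a
#' linear piece of the curve), which is the generator-side half of the
#' round-trip identity the reconstruction tests rely on.
#'
#' @param fish_id Identifier.
#' @param natal_fl,fw_fl True natal-exit and freshwater-exit fork lengths
#'   (mm), `natal_fl <= fw_fl`.
#' @param iso An [isoscape_config()]; `measurement_sd` sets the ratio noise.
#' @param total_radius Transect end (um); adults are truncated around
#'   1000 um once the ocean plateau is reached.
#' @param step_um Spot spacing (um).
#' @param plateau_shift Additive offset on the natal plateau (used to give
#'   hatchery fish a slightly different natal signature).
#' @param srv_noise_sd SrV noise SD (plateau units; freshwater sits at 1,
#'   ocean at 3).
#' @param noise_seed Integer seed for this fish's measurement noise.
#' @param p [backcalc_params()] used for the fork-length-to-radius inverse.
#' @return A [chem_profile()].
#' @export
profile_from_history <- function(fish_id, natal_fl, fw_fl, iso,
                                 total_radius = 1000, step_um = 10,
                                 plateau_shift = 0, srv_noise_sd = 0.03,
                                 noise_seed = 1L, p = backcalc_params()) {
  if (natal_fl > fw_fl) stop("natal_fl > fw_fl", call. = FALSE)
  if (natal_fl < fl_from_radius(p$emergence_radius + step_um, p)) {
    stop("natal exit below emergence size: no otolith room to record it",
         call. = FALSE)
  }
  r_n <- radius_from_fl(natal_fl, p)
  r_f <- radius_from_fl(fw_fl, p)
  plat <- iso$ame_plateau_ratio + plateau_shift
  a <- iso$ame_min_ratio; d <- iso$delta_water_ratio
  c_ <- iso$chipps_mean_ratio; o <- iso$ocean_ratio
  rapid <- (r_f - r_n) < 1e-9

  sr_curve <- function(r) {
    if (rapid) {
      # straight natal -> ocean rise starting at the exit radius
      lo <- 60
      v <- ifelse(r <= r_f, plat,
           ifelse(r >= r_f + lo, o, plat + (o - plat) * (r - r_f) / lo))
      return(v)
    }
    gap <- r_f - r_n
    ld <- min(60, gap / 1.2); lo <- min(60, gap / 1.2)
    f_down <- (plat - a) / (plat - d)    # descent fraction at the threshold
    f_up <- (c_ - d) / (o - d)           # rise fraction at the threshold
    s1 <- r_n - f_down * ld              # descent start: crosses a at r_n
    s2 <- r_f - f_up * lo                # rise start: crosses c_ at r_f
    ifelse(r <= s1, plat,
    ifelse(r <= s1 + ld, plat + (d - plat) * (r - s1) / ld,
    ifelse(r <= s2, d,
    ifelse(r <= s2 + lo, d + (o - d) * (r - s2) / lo, o))))
  }
  srv_curve <- function(r) {
    ls <- 80
    s0 <- r_f - iso$srv_exit_fraction * ls  # normalized 0.52 exactly at r_f
    ifelse(r <= s0, 1,
    ifelse(r >= s0 + ls, 3, 1 + 2 * (r - s0) / ls))
  }

  radius <- seq(100, total_radius, by = step_um)
  if (length(radius) < 2) stop("profile too short", call. = FALSE)
  with_local_seed(noise_seed, {
    sr <- sr_curve(radius) + stats::rnorm(length(radius), 0,
                                          iso$measurement_sd)
    srv <- srv_curve(radius) + stats::rnorm(length(radius), 0, srv_noise_sd)
    chem_profile(fish_id, radius, sr,
                 sr8786_2se = rep(2e-5, length(radius)),
                 srv = srv, total_radius = total_radius)
  })
}

# truncated-normal draw via inverse CDF (lower truncation only)
rtnorm_lower <- function(n, mean, sd, lower) {
  u <- stats::runif(n, stats::pnorm(lower, mean, sd), 1)
  stats::qnorm(pmin(u, 1 - 1e-12), mean, sd)
}

#' Simulate one cohort-year: true histories, observed profiles, catches
#'
#' Generates a cohort with the statistical structure the downstream analysis
#' assumes: natal-exit fork lengths from a bimodal two-component normal
#' mixture (early fry vs. late parr/smolt migrants), unimodal ocean-entry
#' sizes, logistic size-selective survival on natal-exit size through the
#' Delta (entry to exit) and Ocean (exit to adult return) segments, a
#' hatchery component among adult returns with elevated eye-lens
#' \eqn{\delta^{34}S} and partial fin-clip marking, and sampling-point
#' catches (Delta entry, within-Delta seine, Delta exit, spawning-ground
#' carcasses) drawn from the survivors alive at each point. Observed otolith
#' profiles are built for every sampled fish with [profile_from_history()],
#' truncated at a capture-dependent total radius for juveniles.
#'
#' All randomness is governed by `cfg$seed`: identical config and seed give
#' identical output.
#'
#' @param cfg A [sim_config()].
#' @param iso An [isoscape_config()].
#' @param year Cohort (outmigration) year label.
#' @return A list with `histories` (one row per wild cohort fish plus
#'   hatchery adults; true values), `records` (one row per sampled fish:
#'   sampling point, measured FL, month, lens value, scale age, clip status,
#'   plus the true values for validation), and `profiles` (named list of
#'   [chem_profile()] for every record).
#' @export
simulate_cohort <- function(cfg = sim_config(), iso = isoscape_config(),
                            year = 2016L) {
  with_local_seed(cfg$seed, {
    n <- cfg$n_fish
    early <- stats::runif(n) < cfg$p_early
    natal <- ifelse(early,
                    rtnorm_lower(n, cfg$early_mean, cfg$early_sd,
                                 cfg$min_natal_fl),
                    rtnorm_lower(n, cfg$late_mean, cfg$late_sd,
                                 cfg$min_natal_fl))
    ocean <- stats::rnorm(n, cfg$ocean_mean, cfg$ocean_sd)
    fw <- pmax(natal, ocean)
    rapid <- (fw - natal) < cfg$rapid_gap_mm &
      stats::runif(n) < cfg$p_rapid
    fw[rapid] <- natal[rapid]

    p_delta <- stats::plogis(stats::qlogis(cfg$surv_delta) +
                               cfg$sel_delta * (natal - cfg$sel_center))
    surv_delta <- stats::runif(n) < p_delta
    p_ocean <- stats::plogis(stats::qlogis(cfg$surv_ocean) +
                               cfg$sel_ocean * (natal - cfg$sel_center))
    surv_ocean <- surv_delta & (stats::runif(n) < p_ocean)
    survived_to <- ifelse(surv_ocean, "adult",
                          ifelse(surv_delta, "delta-exit", "delta-entry"))

    wild <- data.frame(
      fish_id = sprintf("%d-W%04d", year, seq_len(n)),
      origin = "natal-river-wild",
      phenotype_true = ifelse(early, "early", "late"),
      natal_exit_fl_true = natal,
      freshwater_exit_fl_true = fw,
      survived_to = survived_to,
      age_at_return = ifelse(
        surv_ocean,
        as.integer(sample(names(cfg$age_probs), n, TRUE,
                          cfg$age_probs)), NA_integer_),
      lens_d34s_true = stats::rnorm(n, cfg$lens_wild_mean, cfg$lens_sd),
      stringsAsFactors = FALSE)

    # hatchery adults joining the return (trucked smolts: rapid histories)
    n_wild_ad <- sum(surv_ocean)
    h <- cfg$hatchery_fraction
    n_hat <- round(h / (1 - h) * max(1L, n_wild_ad))
    hatchery <- if (n_hat > 0) {
      hfl <- rtnorm_lower(n_hat, 85, 6, 60)
      data.frame(
        fish_id = sprintf("%d-H%04d", year, seq_len(n_hat)),
        origin = "natal-hatchery",
        phenotype_true = "late",
        natal_exit_fl_true = hfl,
        freshwater_exit_fl_true = hfl,
        survived_to = "adult",
        age_at_return = as.integer(sample(names(cfg$age_probs), n_hat, TRUE,
                                          cfg$age_probs)),
        lens_d34s_true = stats::rnorm(n_hat, cfg$lens_hatchery_mean,
                                      cfg$lens_sd),
        stringsAsFactors = FALSE)
    } else wild[0, ]
    histories <- rbind(wild, hatchery)

    # sampling-point catches -------------------------------------------------
    # juvenile catches are lethal and mutually exclusive; the adult carcass
    # survey samples the whole unmarked return (juvenile subsampling removes
    # a negligible fraction of a real population, so it does not deplete the
    # simulated adult pool either - a fish observed as a juvenile simply
    # contributes an independent adult record)
    take <- function(ids, k) if (length(ids) <= k) ids else sample(ids, k)
    id_entry <- take(wild$fish_id, cfg$catch_entry)
    id_seine <- take(setdiff(wild$fish_id, id_entry), cfg$catch_seine)
    id_exit <- take(setdiff(wild$fish_id[surv_delta],
                            c(id_entry, id_seine)), cfg$catch_exit)
    adults <- histories[histories$survived_to == "adult", ]
    clipped <- stats::runif(nrow(adults)) < cfg$marking_rate &
      adults$origin == "natal-hatchery"
    id_adult <- take(adults$fish_id[!clipped], cfg$catch_adult)

    mk_rec <- function(ids, point) {
      if (length(ids) == 0) return(NULL)
      hh <- histories[match(ids, histories$fish_id), ]
      is_early <- hh$phenotype_true == "early"
      month <- ifelse(is_early, sample(1:3, length(ids), TRUE),
                      sample(3:6, length(ids), TRUE))
      is_adult <- point == "adult"
      measured <- switch(point,
        "delta-entry" = hh$natal_exit_fl_true + stats::runif(length(ids), 0, 3),
        "delta-seine" = hh$natal_exit_fl_true + stats::runif(length(ids), 1, 15),
        "delta-exit" = hh$freshwater_exit_fl_true,
        "adult" = NA_real_)
      fl_cm <- if (is_adult) {
        mu <- c(`2` = 53, `3` = 80, `4` = 103)[as.character(hh$age_at_return)]
        stats::rnorm(length(ids), mu, 3)
      } else NA_real_
      data.frame(
        fish_id = ids,
        record_id = paste0(ids, "@", point),
        point = point,
        context = if (is_adult) "adult" else point,
        year = year, month = month,
        measured_fl = measured, fl_cm = fl_cm,
        scale_age = if (is_adult) ifelse(stats::runif(length(ids)) < 0.6,
                                         hh$age_at_return, NA_integer_)
                    else NA_integer_,
        lens_d34s = if (is_adult) hh$lens_d34s_true else NA_real_,
        fin_clipped = FALSE,
        origin_true = hh$origin,
        phenotype_true = hh$phenotype_true,
        natal_exit_fl_true = hh$natal_exit_fl_true,
        fw_exit_fl_true = hh$freshwater_exit_fl_true,
        stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, Filter(Negate(is.null), list(
      mk_rec(id_entry, "delta-entry"),
      mk_rec(id_seine, "delta-seine"),
      mk_rec(id_exit, "delta-exit"),
      mk_rec(id_adult, "adult"))))
    if (is.null(records)) records <- mk_rec(wild$fish_id[1], "delta-entry")[0, ]

    # observed profiles for sampled fish ------------------------------------
    p <- backcalc_params()
    profiles <- vector("list", nrow(records))
    names(profiles) <- records$record_id
    r_n_all <- radius_from_fl(records$natal_exit_fl_true, p)
    r_f_all <- radius_from_fl(records$fw_exit_fl_true, p)
    total <- ifelse(records$point == "delta-entry",
                    r_n_all + stats::runif(nrow(records), 0, 30),
             ifelse(records$point == "delta-seine",
                    r_n_all + stats::runif(nrow(records), 10, 60),
             ifelse(records$point == "delta-exit",
                    r_f_all + stats::runif(nrow(records), 0, 10), 1000)))
    total <- pmax(total, 100 + 2 * cfg$step_um)
    shift <- ifelse(records$origin_true == "natal-hatchery", -1.5e-4, 0) +
      stats::rnorm(nrow(records), 0, 5e-5)
    noise_seeds <- sample.int(.Machine$integer.max - 1L, nrow(records))
    for (i in seq_len(nrow(records))) {
      profiles[[i]] <- profile_from_history(
        records$fish_id[i], records$natal_exit_fl_true[i],
        records$fw_exit_fl_true[i], iso,
        total_radius = total[i], step_um = cfg$step_um,
        plateau_shift = shift[i], noise_seed = noise_seeds[i], p = p)
    }
    list(histories = histories, records = records, profiles = profiles)
  })
}

#' Stand-in natal assignment probabilities for synthetic fish
#'
#' The production assignment model (a random forest over the early otolith
#' ratio series) is consumed as an input by the provenance rules; for
#' synthetic data this stand-in supplies class probabilities from the mean
#' natal-region ratio: softmax of the negative absolute distance to each
#' source's reference plateau, with temperature `temp`. Natal-region spots
#' are those within `early_max_radius` of the core that still sit above the
#' natal-exit threshold (i.e., pre-departure plateau spots).
#'
#' @param profile A [chem_profile()].
#' @param iso An [isoscape_config()].
#' @param refs Named reference plateau ratios per source.
#' @param early_max_radius Outer radius (um) of the natal region.
#' @param temp Softmax temperature (ratio units).
#' @return Named probability vector over the sources.
#' @export
standin_assignment <- function(profile, iso,
                               refs = c(AME = 0.7090, NIH = 0.70885),
                               early_max_radius = 320, temp = 5e-5) {
  sel <- profile$radius_um <= early_max_radius &
    profile$sr8786 > iso$ame_min_ratio
  if (!any(sel)) sel <- profile$radius_um <= early_max_radius
  m <- mean(profile$sr8786[sel])
  w <- exp(-abs(m - refs) / temp)
  w / sum(w)
}

#' True early/late density crossing of the generator's natal-exit mixture
#'
#' The generator draws natal-exit sizes from a two-component normal mixture
#' with both components truncated below at `min_natal_fl` (the smallest size
#' the otolith back-calculation can represent above the emergence radius);
#' the generator's true phenotype cutoff is the density crossing of the
#' truncated component densities, located by bracketed root finding between
#' the component means.
#'
#' @param cfg A [sim_config()].
#' @return The true cutoff (mm).
#' @export
true_phenotype_cutoff <- function(cfg = sim_config()) {
  lo <- cfg$min_natal_fl
  f1 <- function(x) stats::dnorm(x, cfg$early_mean, cfg$early_sd) /
    (1 - stats::pnorm(lo, cfg$early_mean, cfg$early_sd))
  f2 <- function(x) stats::dnorm(x, cfg$late_mean, cfg$late_sd) /
    (1 - stats::pnorm(lo, cfg$late_mean, cfg$late_sd))
  g <- function(x) cfg$p_early * f1(x) - (1 - cfg$p_early) * f2(x)
  stats::uniroot(g, c(cfg$early_mean, cfg$late_mean), tol = 1e-8)$root
}

#' Simulate a multi-year escapement series for demography checks
#'
#' Deterministic natural-origin production with per-generation growth rate
#' `lambda_per_gen` (natural escapement in year y is
#' `base_natural * lambda_per_gen^(y/3)`; a three-year generation), constant
#' hatchery fraction and age composition, and binomial carcass sampling that
#' honours the marking convention: marked hatchery fish (a `marking_rate`
#' fraction of hatchery spawners) are never sampled, so the hatchery share
#' among sampled carcasses is `(1-marking_rate)*h / (1 - marking_rate*h)`.
#'
#' @param n_years Number of escapement years.
#' @param start_year First year label.
#' @param base_natural Natural-origin escapement in the first year.
#' @param lambda_per_gen Per-generation growth of natural production
#'   (1 = stationary).
#' @param hatchery_fraction True hatchery fraction of total escapement.
#' @param age_fractions Length-3 vector (ages 2, 3, 4) summing to 1.
#' @param n_sampled Carcasses sampled (and assigned) per year.
#' @param marking_rate Marked fraction of hatchery fish.
#' @param flow_mean_log,flow_sd_log Log-normal mean/sd of the annual mean
#'   Jan-June flow covariate (CFS).
#' @param seed Integer seed.
#' @return A data.frame, one row per year: `year`, `total_escapement`,
#'   `n_sampled`, `n_hatchery_assigned`, `n_wild_assigned`, `marking_rate`,
#'   `age2`, `age3`, `age4`, `mean_flow`, plus the true values
#'   `natural_true`, `hatchery_fraction_true`.
#' @export
simulate_escapement_series <- function(n_years = 10, start_year = 2010L,
                                       base_natural = 8000,
                                       lambda_per_gen = 1,
                                       hatchery_fraction = 0.6,
                                       age_fractions = c(0.10, 0.72, 0.18),
                                       n_sampled = 400L,
                                       marking_rate = 0.25,
                                       flow_mean_log = log(4000),
                                       flow_sd_log = 0.8,
                                       seed = 1L) {
  stopifnot(abs(sum(age_fractions) - 1) < 1e-6)
  with_local_seed(seed, {
    yrs <- start_year + seq_len(n_years) - 1L
    nat <- base_natural * lambda_per_gen^((seq_len(n_years) - 1) / 3)
    h <- hatchery_fraction
    total <- nat / (1 - h)
    q_unmarked <- (1 - marking_rate) * h / (1 - marking_rate * h)
    n_h <- stats::rbinom(n_years, n_sampled, q_unmarked)
    data.frame(year = yrs,
               total_escapement = total,
               n_sampled = n_sampled,
               n_hatchery_assigned = n_h,
               n_wild_assigned = n_sampled - n_h,
               marking_rate = marking_rate,
               age2 = age_fractions[1], age3 = age_fractions[2],
               age4 = age_fractions[3],
               mean_flow = stats::rlnorm(n_years, flow_mean_log, flow_sd_log),
               natural_true = nat,
               hatchery_fraction_true = h)
  })
}
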