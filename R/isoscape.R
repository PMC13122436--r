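#' Isoscape reference configuration
#'
#' Reference strontium isotope values and thresholds for the natal river /
#' Delta / ocean system, used both by the profile reconstruction (thresholds)
#' and by the synthetic profile generator (water end-members).
#'
#' The natal river (American River type) carries the highest \eqn{^{87}Sr/^{86}Sr}
#' values in the system, so its observed minimum acts as the natal-exit
#' threshold: the first downward departure below `ame_min_ratio` marks exit
#' from the natal river. The upward crossing of `chipps_mean_ratio` (the mean
#' value at the freshwater/brackish boundary) marks freshwater exit. Fish that
#' move too fast for the otolith to record the Delta's isotopic decrease cross
#' neither threshold; for those, the normalized strontium concentration (SrV)
#' rise through `srv_exit_fraction` of its within-fish range is used instead.
#'
#' @param ame_min_ratio Minimum water ratio observed in the natal river
#'   (natal-exit threshold). Dimensionless isotope ratio.
#' @param chipps_mean_ratio Mean ratio at the Delta exit boundary
#'   (freshwater-exit threshold).
#' @param ocean_ratio Global marine ratio reached after ocean entry.
#' @param delta_water_ratio Freshwater Delta end-member (generator only; must
#'   sit below `chipps_mean_ratio` so both crossings exist).
#' @param ame_plateau_ratio Natal-river otolith plateau level (generator only;
#'   must sit above `ame_min_ratio` so profiles start above the threshold).
#' @param srv_exit_fraction Fraction of the normalized within-fish SrV range
#'   whose upward crossing marks freshwater exit when the isotope threshold
#'   is never crossed.
#' @param measurement_sd Gaussian measurement noise SD applied by the
#'   generator to simulated isotope ratios.
#'
#' @return An object of class `isoscape_config` (a validated list).
#' @export
#' @examples
#' iso <- isoscape_config()
#' iso$ame_min_ratio
isoscape_config <- function(ame_min_ratio = 0.7085,
                            chipps_mean_ratio = 0.70785,
                            ocean_ratio = 0.70918,
                            delta_water_ratio = 0.7070,
                            ame_plateau_ratio = 0.7090,
                            srv_exit_fraction = 0.52,
                            measurement_sd = 5e-5) {
  iso <- list(
    ame_min_ratio = ame_min_ratio,
    chipps_mean_ratio = chipps_mean_ratio,
    ocean_ratio = ocean_ratio,
    delta_water_ratio = delta_water_ratio,
    ame_plateau_ratio = ame_plateau_ratio,
    srv_exit_fraction = srv_exit_fraction,
    measurement_sd = measurement_sd
  )
  if (!(delta_water_ratio < chipps_mean_ratio &&
        chipps_mean_ratio < ame_min_ratio &&
        ame_min_ratio < ocean_ratio)) {
    stop("isoscape ratios must satisfy delta < chipps < ame_min < ocean",
         call. = FALSE)
  }
  if (!(ame_plateau_ratio > ame_min_ratio)) {
    stop("ame_plateau_ratio must exceed ame_min_ratio", call. = FALSE)
  }
  if (!(srv_exit_fraction > 0 && srv_exit_fraction < 1)) {
    stop("srv_exit_fraction must lie strictly in (0, 1)", call. = FALSE)
  }
  if (measurement_sd < 0) stop("measurement_sd must be >= 0", call. = FALSE)
  structure(iso, class = "isoscape_config")
}

#' Synthetic cohort simulation configuration
#'
#' Parameters of the synthetic cohort generator: the phenotype mixture of
#' natal-exit sizes, the unimodal ocean-entry size distribution, logistic
#' size-selective survival per migration segment, hatchery composition, and
#' sampling-point catch sizes. Defaults emulate the study system: roughly
#' three quarters of outmigrants leave the natal river as fry (~30-45 mm),
#' the rest as larger parr/smolts, and ocean entry is centred on
#' 80.1 +/- 9.38 mm regardless of phenotype.
#'
#' @param n_fish Number of fish in the cohort reaching Delta entry.
#' @param p_early Mixture weight of the early (fry) component of natal-exit
#'   fork length.
#' @param early_mean,early_sd,late_mean,late_sd Component parameters (mm) of
#'   the bimodal natal-exit size mixture. Component draws are truncated below
#'   at `min_natal_fl` so every natal-exit size maps onto the otolith
#'   back-calculation domain.
#' @param min_natal_fl Lower truncation (mm) for natal-exit fork length.
#' @param ocean_mean,ocean_sd Ocean-entry (freshwater-exit) fork length
#'   distribution (mm); each fish's freshwater exit is the larger of its natal
#'   exit and its ocean-entry draw.
#' @param p_rapid Probability that a fish whose ocean-entry draw is within
#'   `rapid_gap_mm` of its natal exit is treated as a rapid migrant whose
#'   freshwater exit equals its natal exit (no Delta growth recorded).
#' @param rapid_gap_mm Minimum natal-to-freshwater exit gap (mm) below which
#'   a fish is collapsed to a rapid migrant.
#' @param sel_delta,sel_ocean Logistic survival slopes (per mm of natal-exit
#'   fork length) for the Delta (entry to exit) and Ocean (exit to return)
#'   segments. Zero disables selection in that segment.
#' @param surv_delta,surv_ocean Baseline survival probability of a fish of
#'   natal-exit size `sel_center` through each segment.
#' @param sel_center Centering fork length (mm) of the logistic survival.
#' @param hatchery_fraction Fraction of the adult return that is hatchery
#'   origin.
#' @param marking_rate Fraction of hatchery fish that carry an adipose fin
#'   clip (marked fish are excluded from carcass sampling).
#' @param age_probs Probabilities of return at ages 2, 3 and 4.
#' @param lens_wild_mean,lens_hatchery_mean,lens_sd Eye-lens natal
#'   \eqn{\delta^{34}S} (permil) distributions for wild and hatchery fish.
#' @param catch_entry,catch_seine,catch_exit,catch_adult Sampling-point catch
#'   sizes (fish lethally sampled at Delta entry, by beach seine within the
#'   Delta/Bay, at Delta exit, and on the spawning grounds).
#' @param step_um Measurement spacing along the otolith radius (micrometres).
#' @param seed Integer seed governing all randomness of a simulation run.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_fish = 600,
                       p_early = 0.75,
                       early_mean = 39, early_sd = 3.5,
                       late_mean = 68, late_sd = 8,
                       min_natal_fl = 36,
                       ocean_mean = 80.1, ocean_sd = 9.38,
                       p_rapid = 1.0, rapid_gap_mm = 4,
                       sel_delta = 0.08, sel_ocean = 0.04,
                       surv_delta = 0.4, surv_ocean = 0.05,
                       sel_center = 47,
                       hatchery_fraction = 0.6,
                       marking_rate = 0.25,
                       age_probs = c(`2` = 0.10, `3` = 0.72, `4` = 0.18),
                       lens_wild_mean = 7, lens_hatchery_mean = 14,
                       lens_sd = 1.5,
                       catch_entry = 100, catch_seine = 60,
                       catch_exit = 50, catch_adult = 150,
                       step_um = 10,
                       seed = 1L) {
  if (n_fish <= 0) stop("n_fish must be positive", call. = FALSE)
  if (early_sd <= 0 || late_sd <= 0 || ocean_sd <= 0) {
    stop("degenerate (zero-variance) size components are not allowed",
         call. = FALSE)
  }
  if (!(p_early > 0 && p_early < 1)) {
    stop("p_early must lie strictly in (0, 1)", call. = FALSE)
  }
  if (marking_rate < 0 || marking_rate > 1) {
    stop("marking_rate must lie in [0, 1]", call. = FALSE)
  }
  age_probs <- age_probs / sum(age_probs)
  names(age_probs) <- c("2", "3", "4")
  structure(
    list(n_fish = as.integer(n_fish), p_early = p_early,
         early_mean = early_mean, early_sd = early_sd,
         late_mean = late_mean, late_sd = late_sd,
         min_natal_fl = min_natal_fl,
         ocean_mean = ocean_mean, ocean_sd = ocean_sd,
         p_rapid = p_rapid, rapid_gap_mm = rapid_gap_mm,
         sel_delta = sel_delta, sel_ocean = sel_ocean,
         surv_delta = surv_delta, surv_ocean = surv_ocean,
         sel_center = sel_center,
         hatchery_fraction = hatchery_fraction,
         marking_rate = marking_rate, age_probs = age_probs,
         lens_wild_mean = lens_wild_mean,
         lens_hatchery_mean = lens_hatchery_mean, lens_sd = lens_sd,
         catch_entry = as.integer(catch_entry),
         catch_seine = as.integer(catch_seine),
         catch_exit = as.integer(catch_exit),
         catch_adult = as.integer(catch_adult),
         step_um = step_um, seed = as.integer(seed)),
    class = "sim_config")
}

#' Write / read a configuration as YAML
#'
#' @param cfg An `isoscape_config` or `sim_config` object.
#' @param path File path.
#' @export
write_config <- function(cfg, path) {
  cls <- class(cfg)[1]
  yaml::write_yaml(c(list(.class = cls), unclass(cfg)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  cls <- lst$.class
  lst$.class <- NULL
  if (identical(cls, "sim_config") && !is.null(lst$age_probs)) {
    lst$age_probs <- unlist(lst$age_probs)
  }
  do.call(switch(cls,
                 isoscape_config = isoscape_config,
                 sim_config = sim_config,
                 stop("unknown config class: ", cls)),
          lst)
}
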