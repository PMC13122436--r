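#' Natal-exit detection from an otolith profile
#'
#' The natal-exit radius is the first downward crossing of the natal-river
#' minimum ratio (`iso$ame_min_ratio`), linearly interpolated between
#' neighbouring measurements. Profiles that never drop below the threshold
#' (fish that had barely left the natal river, or moved to sea too fast for
#' the otolith to record the Delta's isotopic decrease) fall back by context:
#'
#' * `"juvenile-above-chipps"` - the fish was still upstream of the Delta
#'   exit when caught, so its total otolith radius is its natal-exit size;
#' * `"adult-or-bay"` - natal exit is matched to the freshwater exit
#'   (zero Delta growth assumed), which must already be resolved and supplied
#'   via `fw_exit`;
#' * `"rst-measured"` - the fish was measured in the natal river itself, so
#'   the supplied `measured_fl` is used directly and no profile inference is
#'   performed.
#'
#' @param profile A [chem_profile()].
#' @param iso An [isoscape_config()].
#' @param context One of `"adult-or-bay"`, `"juvenile-above-chipps"`,
#'   `"rst-measured"`.
#' @param fw_exit The freshwater-exit estimate (a row as returned by
#'   [freshwater_exit()]), required for the `"adult-or-bay"` fallback.
#' @param measured_fl Measured fork length (mm), required for
#'   `"rst-measured"`.
#' @param p A [backcalc_params()] used to express the estimate in mm.
#' @param min_run Minimum-run filter passed to [find_crossing()].
#' @return A one-row data.frame: `natal_exit_radius` (um),
#'   `natal_exit_method`, `natal_exit_fl` (mm), `natal_never_crossed`.
#' @export
natal_exit <- function(profile, iso,
                       context = c("adult-or-bay", "juvenile-above-chipps",
                                   "rst-measured"),
                       fw_exit = NULL, measured_fl = NULL,
                       p = backcalc_params(), min_run = 1L) {
  context <- match.arg(context)
  if (context == "rst-measured") {
    if (is.null(measured_fl)) {
      stop("rst-measured context needs measured_fl", call. = FALSE)
    }
    return(data.frame(natal_exit_radius = radius_from_fl(measured_fl, p),
                      natal_exit_method = "measured-FL",
                      natal_exit_fl = measured_fl,
                      natal_never_crossed = NA))
  }
  r <- find_crossing(profile$radius_um, profile$sr8786, iso$ame_min_ratio,
                     "downward", min_run = min_run)
  if (!is.na(r)) {
    return(data.frame(natal_exit_radius = r,
                      natal_exit_method = "ratio-crossing",
                      natal_exit_fl = fl_from_radius(r, p),
                      natal_never_crossed = FALSE))
  }
  if (context == "juvenile-above-chipps") {
    return(data.frame(natal_exit_radius = profile$total_radius,
                      natal_exit_method = "total-radius",
                      natal_exit_fl = fl_from_radius(profile$total_radius, p),
                      natal_never_crossed = TRUE))
  }
  # adult-or-bay: match to the resolved freshwater exit
  if (is.null(fw_exit) || is.na(fw_exit$fw_exit_radius)) {
    stop("adult-or-bay natal fallback requested before freshwater exit ",
         "was resolved", call. = FALSE)
  }
  data.frame(natal_exit_radius = fw_exit$fw_exit_radius,
             natal_exit_method = "matched-to-freshwater-exit",
             natal_exit_fl = fw_exit$fw_exit_fl,
             natal_never_crossed = TRUE)
}

#' Freshwater-exit detection from an otolith profile
#'
#' The freshwater-exit radius is the first upward crossing of the Delta-exit
#' mean ratio (`iso$chipps_mean_ratio`) after the natal exit. When the
#' profile never crosses it (rapid migrants), the within-fish normalized SrV
#' series is used instead: freshwater exit is where it rises through
#' `iso$srv_exit_fraction` of its range. Juveniles physically sampled at the
#' Delta exit skip profile inference: their measured fork length is their
#' freshwater-exit size (pass `measured_fl`).
#'
#' @inheritParams natal_exit
#' @param natal_radius Resolved natal-exit radius (um), or `NA` for fish
#'   whose natal exit is itself unresolved; crossings are searched at or
#'   after it.
#' @param srv_scope Passed to [normalize_srv()].
#' @return A one-row data.frame: `fw_exit_radius` (um), `fw_exit_method`,
#'   `fw_exit_fl` (mm), `fw_never_crossed`.
#' @export
freshwater_exit <- function(profile, iso, natal_radius = NA_real_,
                            measured_fl = NULL, p = backcalc_params(),
                            srv_scope = "full", min_run = 1L) {
  if (!is.null(measured_fl)) {
    return(data.frame(fw_exit_radius = radius_from_fl(measured_fl, p),
                      fw_exit_method = "measured-FL",
                      fw_exit_fl = measured_fl,
                      fw_never_crossed = NA))
  }
  start <- if (is.na(natal_radius)) -Inf else natal_radius
  r <- find_crossing(profile$radius_um, profile$sr8786,
                     iso$chipps_mean_ratio, "upward",
                     start_radius = start, min_run = min_run)
  if (!is.na(r)) {
    return(data.frame(fw_exit_radius = r,
                      fw_exit_method = "ratio-crossing",
                      fw_exit_fl = fl_from_radius(r, p),
                      fw_never_crossed = FALSE))
  }
  if (is.null(profile$srv)) {
    stop("SrV series absent but needed for the freshwater-exit fallback",
         call. = FALSE)
  }
  nsrv <- normalize_srv(profile$srv, scope = srv_scope,
                        fw_n = if (srv_scope == "freshwater")
                          max(2L, sum(profile$radius_um <= start)) else NULL)
  r <- find_crossing(profile$radius_um, nsrv, iso$srv_exit_fraction,
                     "upward", min_run = min_run)
  if (is.na(r)) {
    return(data.frame(fw_exit_radius = NA_real_,
                      fw_exit_method = "srv-crossing",
                      fw_exit_fl = NA_real_, fw_never_crossed = TRUE))
  }
  data.frame(fw_exit_radius = r, fw_exit_method = "srv-crossing",
             fw_exit_fl = fl_from_radius(r, p), fw_never_crossed = TRUE)
}

#' Reconstruct natal and freshwater exit for one fish
#'
#' Applies the full decision tree for a fish's sampling context:
#'
#' * `"rst"` - rotary screw trap in the natal river: measured FL is the
#'   natal-exit size; no freshwater exit yet.
#' * `"delta-entry"`, `"delta-seine"` - juveniles upstream of the Delta exit:
#'   natal exit by threshold with total-radius fallback; no freshwater exit.
#' * `"delta-exit"` - juveniles leaving freshwater: measured FL is the
#'   freshwater-exit size; natal exit by threshold, matched to the measured
#'   freshwater exit if the profile never crossed.
#' * `"adult"`, `"bay"` - complete freshwater history in the otolith: both
#'   thresholds, SrV fallback for freshwater exit, natal matched to
#'   freshwater exit if the natal threshold was never crossed.
#'
#' @param profile A [chem_profile()] (may be `NULL` for `"rst"`).
#' @param iso An [isoscape_config()].
#' @param context Sampling context (see Details).
#' @param measured_fl Fork length measured at capture (mm); required for
#'   `"rst"` and `"delta-exit"`.
#' @param p A [backcalc_params()].
#' @param srv_scope,min_run Passed through to the detectors.
#' @return A one-row data.frame combining the [natal_exit()] and
#'   [freshwater_exit()] fields.
#' @export
reconstruct_exits <- function(profile, iso,
                              context = c("adult", "bay", "delta-entry",
                                          "delta-seine", "delta-exit", "rst"),
                              measured_fl = NULL, p = backcalc_params(),
                              srv_scope = "full", min_run = 1L) {
  context <- match.arg(context)
  na_fw <- data.frame(fw_exit_radius = NA_real_,
                      fw_exit_method = NA_character_,
                      fw_exit_fl = NA_real_, fw_never_crossed = NA)
  out <- switch(
    context,
    "rst" = cbind(natal_exit(profile, iso, "rst-measured",
                             measured_fl = measured_fl, p = p), na_fw),
    "delta-entry" = ,
    "delta-seine" = cbind(natal_exit(profile, iso, "juvenile-above-chipps",
                                     p = p, min_run = min_run), na_fw),
    "delta-exit" = {
      fw <- freshwater_exit(profile, iso, measured_fl = measured_fl, p = p)
      nat <- natal_exit(profile, iso, "adult-or-bay", fw_exit = fw, p = p,
                        min_run = min_run)
      cbind(nat, fw)
    },
    "adult" = ,
    "bay" = {
      # natal threshold first; the freshwater search starts at the natal
      # radius when it resolved, else from the profile start
      r_nat <- find_crossing(profile$radius_um, profile$sr8786,
                             iso$ame_min_ratio, "downward",
                             min_run = min_run)
      fw <- freshwater_exit(profile, iso, natal_radius = r_nat, p = p,
                            srv_scope = srv_scope, min_run = min_run)
      nat <- natal_exit(profile, iso, "adult-or-bay", fw_exit = fw, p = p,
                        min_run = min_run)
      cbind(nat, fw)
    })
  ok <- !is.na(out$natal_exit_radius) & !is.na(out$fw_exit_radius)
  if (any(ok & out$natal_exit_radius > out$fw_exit_radius + 1e-9)) {
    stop("inconsistent reconstruction: natal exit after freshwater exit",
         call. = FALSE)
  }
  out
}

#' Reconstruct exits for a set of fish records
#'
#' Vectorised driver: joins per-fish profiles to a record table, applies
#' [reconstruct_exits()] per fish using each record's `context` and
#' `measured_fl`, and appends the result columns to the records.
#'
#' @param records Data.frame with at least `fish_id`, `context`, and
#'   `measured_fl` (mm, `NA` where not applicable); a `record_id` column, if
#'   present, keys the profile list instead of `fish_id`.
#' @param profiles Named list of [chem_profile()] objects keyed by record or
#'   fish id.
#' @param iso,p,srv_scope,min_run See [reconstruct_exits()].
#' @return `records` with the exit-estimate columns appended.
#' @export
reconstruct_cohort <- function(records, profiles, iso,
                               p = backcalc_params(), srv_scope = "full",
                               min_run = 1L) {
  key <- if ("record_id" %in% names(records)) "record_id" else "fish_id"
  est <- lapply(seq_len(nrow(records)), function(i) {
    id <- as.character(records[[key]][i])
    ml <- records$measured_fl[i]
    reconstruct_exits(profiles[[id]], iso, context = records$context[i],
                      measured_fl = if (is.na(ml)) NULL else ml,
                      p = p, srv_scope = srv_scope, min_run = min_run)
  })
  cbind(records, do.call(rbind, est))
}
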