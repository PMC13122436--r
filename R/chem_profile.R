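#' Otolith chemical profile
#'
#' One fish's ordered otolith transect: radius from the core along the dorsal
#' axis (um) with the \eqn{^{87}Sr/^{86}Sr} ratio, its 2SE, and the SrV
#' strontium-concentration signal at each spot.
#'
#' @param fish_id Fish identifier.
#' @param radius_um Strictly increasing measurement radii (um).
#' @param sr8786 Isotope ratios, same length as `radius_um`.
#' @param sr8786_2se Per-spot 2SE of the ratio (carried through, not used in
#'   crossing detection). Optional.
#' @param srv SrV signal (arbitrary instrument units). Optional, required
#'   only for the SrV freshwater-exit fallback.
#' @param total_radius Total otolith radius (um); defaults to the last
#'   measurement radius, must not be smaller.
#' @return An object of class `chem_profile`.
#' @export
chem_profile <- function(fish_id, radius_um, sr8786,
                         sr8786_2se = NULL, srv = NULL,
                         total_radius = NULL) {
  n <- length(radius_um)
  if (n < 2) stop("a profile needs at least 2 measurements", call. = FALSE)
  if (length(sr8786) != n) stop("sr8786 length mismatch", call. = FALSE)
  if (any(diff(radius_um) <= 0)) {
    stop("radii must be strictly increasing", call. = FALSE)
  }
  if (is.null(total_radius)) total_radius <- radius_um[n]
  if (total_radius < radius_um[n]) {
    stop("total_radius smaller than the last measurement radius",
         call. = FALSE)
  }
  structure(list(fish_id = fish_id,
                 radius_um = as.numeric(radius_um),
                 sr8786 = as.numeric(sr8786),
                 sr8786_2se = if (is.null(sr8786_2se)) rep(NA_real_, n)
                              else as.numeric(sr8786_2se),
                 srv = if (is.null(srv)) NULL else as.numeric(srv),
                 total_radius = as.numeric(total_radius)),
            class = "chem_profile")
}

#' @export
print.chem_profile <- function(x, ...) {
  cat("<chem_profile> fish", x$fish_id, "-", length(x$radius_um),
      "spots,", min(x$radius_um), "-", max(x$radius_um), "um (total",
      x$total_radius, "um)\n")
  invisible(x)
}

#' First threshold crossing of a profile series, with linear interpolation
#'
#' Scans an ordered series for the first crossing of `threshold` in the
#' stated direction at or after `start_radius` and returns the linearly
#' interpolated radius of the crossing. A measurement lying exactly on the
#' threshold counts as a crossing at that measurement's radius, which keeps
#' the crossing radius continuous in the data. Only the first qualifying
#' crossing is reported; an optional minimum-run filter requires `min_run`
#' consecutive measurements on the far side of the threshold (starting at the
#' crossing's right endpoint) before a crossing is accepted, which suppresses
#' transient noise spikes. The default `min_run = 1` applies no filtering.
#'
#' @param radius Ordered measurement radii (um).
#' @param values Series measured at `radius` (isotope ratio or normalized SrV).
#' @param threshold Threshold value.
#' @param direction `"downward"` (series falls through the threshold) or
#'   `"upward"`.
#' @param start_radius Radius at or after which the crossing must occur.
#' @param min_run Minimum number of consecutive far-side measurements.
#' @return Interpolated crossing radius (um), or `NA_real_` if the series
#'   never crosses.
#' @export
#' @examples
#' # hand-checked interpolation: (0.7090-0.7085)/(0.7090-0.7080)*20 + 300
#' find_crossing(c(300, 320), c(0.7090, 0.7080), 0.7085, "downward") # 310
find_crossing <- function(radius, values, threshold,
                          direction = c("downward", "upward"),
                          start_radius = -Inf, min_run = 1L) {
  direction <- match.arg(direction)
  n <- length(radius)
  if (n == 0) stop("empty profile", call. = FALSE)
  if (length(values) != n) stop("radius/values length mismatch", call. = FALSE)
  if (any(diff(radius) <= 0)) stop("unordered radii", call. = FALSE)
  if (is.finite(start_radius) &&
      (start_radius > radius[n])) {
    stop("start_radius outside the profile span", call. = FALSE)
  }
  # work on the sign-adjusted series so a crossing is always "downward"
  v <- if (direction == "downward") values - threshold else threshold - values
  far_side <- v <= 0          # at or beyond threshold (boundary inclusive)
  run_ok <- function(j) {     # >= min_run consecutive far-side points from j
    if (min_run <= 1L) return(TRUE)
    k <- j + seq_len(min(min_run, n - j + 1L)) - 1L
    length(k) >= min_run && all(far_side[k])
  }
  for (i in seq_len(n)) {
    # exact hit (or already beyond) at a measurement: crossing at that radius,
    # provided the series was on the near side before it (a true crossing)
    if (far_side[i] && radius[i] >= start_radius && run_ok(i)) {
      if (i == 1L) {
        if (v[i] == 0) return(radius[i])  # starts exactly on the threshold
        next                              # starts beyond: scan for a later
                                          # genuine crossing
      }
      if (v[i - 1L] > 0) {
        if (v[i] == 0) return(radius[i])
        r <- radius[i - 1L] + (radius[i] - radius[i - 1L]) *
          v[i - 1L] / (v[i - 1L] - v[i])
        if (r >= start_radius) return(r)
        # interpolated crossing falls before start_radius: keep scanning
      }
    }
  }
  NA_real_
}

#' Min-max normalize a SrV series over the measured profile
#'
#' Rescales the within-fish SrV series to `[0, 1]` by
#' `(srv - min) / (max - min)` over the whole measured profile, so the
#' relative rise toward the marine plateau can be thresholded. Order
#' preserving and invariant to gain/offset changes of the instrument signal.
#'
#' @param srv Numeric SrV series.
#' @param scope `"full"` (default) normalizes over the entire profile;
#'   `"freshwater"` normalizes over the first `fw_n` measurements only (the
#'   freshwater portion) while still returning the full rescaled series.
#' @param fw_n Number of leading measurements treated as freshwater when
#'   `scope = "freshwater"`.
#' @return Numeric series; values in `[0, 1]` under `scope = "full"`.
#' @export
normalize_srv <- function(srv, scope = c("full", "freshwater"), fw_n = NULL) {
  scope <- match.arg(scope)
  if (length(srv) < 2) stop("need >= 2 SrV measurements", call. = FALSE)
  ref <- if (scope == "full") srv else {
    if (is.null(fw_n)) stop("fw_n required for freshwater scope", call. = FALSE)
    srv[seq_len(fw_n)]
  }
  rng <- range(ref)
  if (diff(rng) == 0) {
    stop("constant SrV series: normalization undefined", call. = FALSE)
  }
  (srv - rng[1]) / (rng[2] - rng[1])
}

#' Read / write otolith profiles as tidy CSV
#'
#' One row per measurement with columns `fish_id`, `radius_um`, `sr8786`,
#' `sr8786_2se`, `srv` (and optionally `total_radius`, repeated per fish).
#'
#' @param profiles A list of [chem_profile()] objects.
#' @param path CSV file path.
#' @return `read_profiles()` returns a named list of `chem_profile` objects.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(fish_id = p$fish_id, radius_um = p$radius_um,
               sr8786 = p$sr8786, sr8786_2se = p$sr8786_2se,
               srv = if (is.null(p$srv)) NA_real_ else p$srv,
               total_radius = p$total_radius)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path)
  out <- lapply(split(df, df$fish_id), function(d) {
    d <- d[order(d$radius_um), ]
    chem_profile(d$fish_id[1], d$radius_um, d$sr8786,
                 sr8786_2se = d$sr8786_2se,
                 srv = if (all(is.na(d$srv))) NULL else d$srv,
                 total_radius = if ("total_radius" %in% names(d))
                   d$total_radius[1] else NULL)
  })
  out[order(names(out))]
}
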