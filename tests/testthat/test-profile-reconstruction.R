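test_that("find_crossing interpolates linearly and honours conventions", {
  # hand-checked: (0.7090-0.7085)/(0.7090-0.7080)*20 + 300 = 310
  expect_equal(find_crossing(c(300, 320), c(0.7090, 0.7080), 0.7085,
                             "downward"), 310)
  # profile entirely above threshold: no crossing
  expect_true(is.na(find_crossing(c(1, 2, 3), c(0.71, 0.71, 0.7095),
                                  0.7085, "downward")))
  # measurement exactly at threshold counts as a crossing at that radius
  expect_equal(find_crossing(c(100, 200, 300), c(0.7090, 0.7085, 0.7080),
                             0.7085, "downward"), 200)
  # upward direction and start_radius
  expect_equal(find_crossing(c(600, 625), c(0.7070, 0.70800), 0.70785,
                             "upward"), 621.25)
  expect_equal(find_crossing(c(1, 2, 3, 4), c(1, 0, 1, 0), 0.5, "downward",
                             start_radius = 2.5), 3.5)
  expect_error(find_crossing(c(2, 1), c(1, 0), 0.5, "downward"), "unordered")
  expect_error(find_crossing(numeric(), numeric(), 0.5, "downward"), "empty")
})

test_that("minimum-run filter skips transient spikes but is off by default", {
  r <- c(1, 2, 3, 4, 5)
  v <- c(1.0, 0.4, 1.0, 0.4, 0.3)  # transient dip at 2, real crossing at 4
  expect_equal(find_crossing(r, v, 0.5, "downward"), 1 + 0.5 / 0.6)
  expect_equal(find_crossing(r, v, 0.5, "downward", min_run = 2),
               3 + 0.5 / 0.6)
})

test_that("find_crossing agrees with a brute-force scan on random profiles", {
  set.seed(99)
  for (rep in 1:1000) {
    n <- sample(3:12, 1)
    r <- sort(runif(n, 0, 100))
    while (any(diff(r) <= 0)) r <- sort(runif(n, 0, 100))
    v <- runif(n)
    thr <- runif(1)
    dir <- sample(c("downward", "upward"), 1)
    expect_equal(find_crossing(r, v, thr, dir),
                 brute_crossing(r, v, thr, dir))
  }
})

test_that("SrV normalization is min-max over the profile and affine
          invariant", {
  expect_equal(normalize_srv(c(10, 20, 30)), c(0, 0.5, 1))
  s <- c(3, 9, 4, 12, 7)
  expect_equal(normalize_srv(2.5 * s + 40), normalize_srv(s))
  expect_error(normalize_srv(rep(2, 5)), "constant")
  expect_error(normalize_srv(3), ">= 2")
  # monotone series: unique 0.52 crossing, equal to brute-force scan
  s <- c(1, 1.5, 2.2, 2.9, 3.4)
  ns <- normalize_srv(s)
  r <- c(10, 20, 30, 40, 50)
  expect_equal(find_crossing(r, ns, 0.52, "upward"),
               brute_crossing(r, ns, 0.52, "upward"))
})

test_that("natal exit falls back by sampling context", {
  iso <- iso_clean()
  # juvenile upstream of the Delta exit, never crossed: total radius
  pr <- chem_profile("j1", c(100, 150, 200), rep(0.7090, 3),
                     total_radius = 230)
  est <- natal_exit(pr, iso, "juvenile-above-chipps")
  expect_equal(est$natal_exit_radius, 230)
  expect_equal(est$natal_exit_method, "total-radius")
  expect_true(est$natal_never_crossed)
  # adult never crossed: matched to the freshwater exit, which must exist
  expect_error(natal_exit(pr, iso, "adult-or-bay"), "freshwater exit")
  fw <- data.frame(fw_exit_radius = 458, fw_exit_method = "srv-crossing",
                   fw_exit_fl = 70, fw_never_crossed = TRUE)
  est <- natal_exit(pr, iso, "adult-or-bay", fw_exit = fw)
  expect_equal(est$natal_exit_radius, 458)
  expect_equal(est$natal_exit_method, "matched-to-freshwater-exit")
  # rotary-screw-trap fish: measured FL, no profile inference
  est <- natal_exit(NULL, iso, "rst-measured", measured_fl = 42)
  expect_equal(est$natal_exit_fl, 42)
  expect_equal(est$natal_exit_method, "measured-FL")
})

test_that("freshwater exit uses measured FL at the Delta exit and the SrV
          fallback when the ratio never crosses", {
  iso <- iso_clean()
  est <- freshwater_exit(toy_profile(), iso, measured_fl = 78)
  expect_equal(est$fw_exit_fl, 78)
  expect_equal(est$fw_exit_method, "measured-FL")
  # ratio crossing (interpolated on the toy profile): hand value 621.25
  est <- freshwater_exit(toy_profile(), iso, natal_radius = 330)
  expect_equal(est$fw_exit_radius, 621.25)
  expect_equal(est$fw_exit_method, "ratio-crossing")
  # never-crossing profile without SrV errors
  pr <- chem_profile("x", c(100, 200), c(0.7090, 0.7091))
  expect_error(freshwater_exit(pr, iso), "SrV")
})

test_that("round-trip: noiseless profiles recover both exits within one
          measurement step, on every fallback path", {
  iso <- iso_clean()
  p <- backcalc_params()
  set.seed(21)
  cases <- data.frame(natal = c(40, 38, 55, 70, 83, 36.5),
                      fw = c(80, 38, 85, 70, 83, 90))
  for (k in seq_len(nrow(cases))) {
    pr <- profile_from_history("f", cases$natal[k], cases$fw[k], iso,
                               srv_noise_sd = 0, noise_seed = k)
    est <- reconstruct_exits(pr, iso, "adult")
    expect_lt(abs(est$natal_exit_radius - radius_from_fl(cases$natal[k], p)),
              10 + 1e-9)
    expect_lt(abs(est$fw_exit_radius - radius_from_fl(cases$fw[k], p)),
              10 + 1e-9)
  }
})

test_that("rapid migrants never cross either ratio threshold and resolve via
          SrV with zero Delta growth", {
  iso <- iso_clean()
  pr <- profile_from_history("r", 70, 70, iso, srv_noise_sd = 0,
                             noise_seed = 5)
  expect_true(all(pr$sr8786 > iso$ame_min_ratio - 1e-12))
  est <- reconstruct_exits(pr, iso, "adult")
  expect_equal(est$natal_exit_method, "matched-to-freshwater-exit")
  expect_equal(est$fw_exit_method, "srv-crossing")
  expect_equal(est$natal_exit_radius, est$fw_exit_radius)
  expect_equal(est$natal_exit_fl, 70, tolerance = 1e-6)
})

test_that("reconstruction is invariant to measurements beyond the ocean
          plateau", {
  iso <- iso_clean()
  a <- profile_from_history("a", 42, 78, iso, total_radius = 700,
                            srv_noise_sd = 0, noise_seed = 9)
  b <- profile_from_history("a", 42, 78, iso, total_radius = 1400,
                            srv_noise_sd = 0, noise_seed = 9)
  ea <- reconstruct_exits(a, iso, "adult")
  eb <- reconstruct_exits(b, iso, "adult")
  expect_equal(ea$natal_exit_radius, eb$natal_exit_radius, tolerance = 1e-9)
  expect_equal(ea$fw_exit_radius, eb$fw_exit_radius, tolerance = 1e-9)
})

test_that("natal exit never exceeds freshwater exit across a simulated
          cohort with noise", {
  iso <- isoscape_config()
  cfg <- sim_config(n_fish = 150, seed = 31L)
  out <- simulate_cohort(cfg, iso)
  rec <- reconstruct_cohort(out$records, out$profiles, iso)
  ok <- !is.na(rec$natal_exit_radius) & !is.na(rec$fw_exit_radius)
  expect_true(any(ok))
  expect_true(all(rec$natal_exit_radius[ok] <= rec$fw_exit_radius[ok] + 1e-9))
})

test_that("profile CSV writer and reader round-trip", {
  iso <- isoscape_config()
  prs <- list(a = profile_from_history("a", 40, 80, iso, noise_seed = 1),
              b = profile_from_history("b", 70, 70, iso, noise_seed = 2))
  path <- tempfile(fileext = ".csv")
  write_profiles(prs, path)
  back <- read_profiles(path)
  expect_equal(back$a$sr8786, prs$a$sr8786, tolerance = 1e-12)
  expect_equal(back$b$radius_um, prs$b$radius_um)
  expect_equal(back$a$total_radius, prs$a$total_radius)
})

test_that("chem_profile validates its invariants", {
  expect_error(chem_profile("x", c(1), c(0.7)), "at least 2")
  expect_error(chem_profile("x", c(2, 1), c(0.7, 0.7)), "increasing")
  expect_error(chem_profile("x", c(1, 2), c(0.7, 0.7), total_radius = 1.5),
               "total_radius")
})
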