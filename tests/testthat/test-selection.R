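test_that("selection differential follows the defining arithmetic", {
  x <- c(40, 50, 60)             # mean 50, sample variance 100
  expect_equal(selection_differential(x, x)$i, 0)
  got <- selection_differential(x, 60)
  expect_equal(got$i, 0.1)
  expect_equal(got$z_bar_init, 50)
  expect_equal(got$v_init, 100)
  expect_error(selection_differential(rep(5, 4), c(5, 5)), "variance")
  expect_error(selection_differential(5, c(5, 5)), "n_init")
})

test_that("truncation selection matches brute-force computation from the
          retained subset", {
  set.seed(41)
  for (rep in 1:100) {
    init <- rnorm(sample(20:200, 1), 50, 12)
    surv <- init[init >= median(init)]   # drop everything below the median
    got <- selection_differential(init, surv)
    expect_equal(got$i, (mean(surv) - mean(init)) / var(init))
    expect_gt(got$i, 0)
  }
})

test_that("i is shift invariant and scales as 1/c under the variance
          convention, scale-free under the SD convention", {
  set.seed(6)
  init <- rnorm(300, 50, 10); surv <- init[init > 45]
  i0 <- selection_differential(init, surv)$i
  expect_equal(selection_differential(init + 7, surv + 7)$i, i0)
  expect_equal(selection_differential(3 * init, 3 * surv)$i, i0 / 3,
               tolerance = 1e-12)
  s0 <- selection_differential(init, surv, "sd")$i
  expect_equal(selection_differential(3 * init, 3 * surv, "sd")$i, s0,
               tolerance = 1e-12)
})

test_that("segment differentials equal pairwise selection differentials and
          skip missing endpoints", {
  set.seed(17)
  rec <- rbind(
    data.frame(point = "delta-entry", year = 2015,
               natal_exit_fl = rnorm(80, 45, 10)),
    data.frame(point = "delta-exit", year = 2015,
               natal_exit_fl = rnorm(40, 55, 10)),
    data.frame(point = "adult", year = 2015,
               natal_exit_fl = rnorm(30, 65, 10)),
    data.frame(point = "delta-entry", year = 2016,
               natal_exit_fl = rnorm(50, 45, 10)))
  got <- segment_differentials(rec)
  expect_equal(nrow(got), 3)  # three segments for 2015, none for 2016
  for (k in seq_len(nrow(got))) {
    seg <- got$segment[k]
    pts <- switch(seg, Delta = c("delta-entry", "delta-exit"),
                  Ocean = c("delta-exit", "adult"),
                  All = c("delta-entry", "adult"))
    a <- rec$natal_exit_fl[rec$point == pts[1] & rec$year == got$year[k]]
    b <- rec$natal_exit_fl[rec$point == pts[2] & rec$year == got$year[k]]
    expect_equal(got$i[k], selection_differential(a, b)$i)
  }
  expect_setequal(attr(got, "skipped"),
                  c("Delta:2016", "Ocean:2016", "All:2016"))
})

test_that("adult cohort matching converts escapement year by age", {
  expect_equal(outmigration_year(2019, c(2, 3, 4)), c(2018, 2017, 2016))
})

test_that("regressions recover known structure", {
  set.seed(30)
  x <- seq(1, 15, length.out = 40)
  y <- 2 + 0.8 * x - 0.05 * x^2 + rnorm(40, 0, 0.1)
  fit <- regress_i(y, x, "quadratic")
  ci <- confint(fit$model)
  expect_gt(0.8, ci["x", 1]); expect_lt(0.8, ci["x", 2])
  expect_gt(-0.05, ci["I(x^2)", 1]); expect_lt(-0.05, ci["I(x^2)", 2])
  # constant response: slope terms indistinguishable from zero
  fit <- regress_i(rep(3, 10) + rnorm(10, 0, 1e-8), seq_len(10), "linear")
  expect_lt(abs(fit$coefficients[["x"]]), 1e-6)
  # linear data under the quadratic form: curvature term near zero
  y <- 1 + 2 * x
  fit <- suppressWarnings(regress_i(y, x, "quadratic"))
  expect_lt(abs(fit$coefficients[["I(x^2)"]]), 1e-8)
  expect_error(regress_i(1:3, 1:3, "quadratic"), "observations")
})

test_that("catch expansion reproduces bin shares and honours the merge
          rule", {
  # two bins, 3:1 catch: expected shares 0.75/0.25 across many seeds
  bins <- rep(c("jan", "feb"), each = 50)
  vals <- c(rep(1, 50), rep(2, 50))
  share1 <- vapply(1:300, function(s) {
    mean(expand_to_catch(bins, vals, c(jan = 300, feb = 100), seed = s) == 1)
  }, 0)
  expect_equal(mean(share1), 0.75, tolerance = 0.01)
  # all catch in one bin: only that bin's fish appear
  got <- expand_to_catch(bins, vals, c(jan = 0, feb = 200), seed = 2)
  expect_true(all(got == 2))
  expect_equal(length(got), 200)
  # catch proportional to the sample: distribution preserved up to noise
  got <- expand_to_catch(bins, vals, c(jan = 5000, feb = 5000), seed = 3)
  expect_equal(mean(got == 1), 0.5, tolerance = 0.05)
  # a bin with catch but no samples merges into the next one
  got <- expand_to_catch(rep("feb", 40), rnorm(40),
                         c(jan = 100, feb = 100), seed = 4)
  expect_equal(length(got), 200)
  expect_error(expand_to_catch(rep("jan", 40), rnorm(40),
                               c(jan = 10, feb = 100), seed = 5),
               "no otolith samples")
})

test_that("estimated i rises monotonically with the configured survival
          slope", {
  slopes <- c(0, 0.05, 0.12)
  mean_i <- vapply(slopes, function(b) {
    mean(vapply(1:20, function(s) {
      cfg <- sim_config(n_fish = 400, sel_delta = b, sel_ocean = 0,
                        catch_adult = 0, seed = 100L + s)
      out <- simulate_cohort(cfg)
      h <- out$histories
      init <- h$natal_exit_fl_true[h$origin == "natal-river-wild"]
      surv <- h$natal_exit_fl_true[h$origin == "natal-river-wild" &
                                     h$survived_to != "delta-entry"]
      selection_differential(init, surv)$i
    }, 0))
  }, 0)
  expect_lt(abs(mean_i[1]), 0.01)        # no selection: i ~ 0
  expect_true(all(diff(mean_i) > 0))     # stronger selection, larger i
})
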