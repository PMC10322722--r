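make_series <- function(times, sulfide, replicate = "a", dilution = NULL) {
  tibble::tibble(
    time_d = times, replicate = replicate, sulfide_mM = sulfide,
    dilution = if (is.null(dilution)) rep(0L, length(times)) else dilution
  )
}

test_that("segmentation splits at dilution flags and preserves the records", {
  ts <- make_series(0:8, c(1, 4, 12, 4, 8, 14, 5, 9, 13),
                    dilution = c(0, 0, 0, 1, 0, 0, 1, 0, 0))
  seg <- segment_series(ts)
  expect_identical(unique(seg$segment), 1:3)
  expect_identical(seg[names(ts)], ts)

  no_flags <- make_series(0:3, c(1, 2, 4, 8))
  seg1 <- segment_series(no_flags)
  expect_true(all(seg1$segment == 1L))
  expect_identical(seg1[names(no_flags)], no_flags)

  leading <- make_series(0:3, c(1, 2, 4, 8), dilution = c(1, 0, 0, 0))
  expect_warning(seg2 <- segment_series(leading), "leading empty segment")
  expect_true(all(seg2$segment == 1L))

  empty <- segment_series(make_series(numeric(0), numeric(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("exponential fits recover noise-free rates exactly", {
  t <- seq(0, 30, 3)
  fit <- fit_exponential(make_series(t, 0.5 * exp(0.1 * t)), min_sulfide = 0)
  expect_equal(fit$m, 0.1, tolerance = 1e-9)
  expect_equal(fit$doubling_time, log(2) / 0.1, tolerance = 1e-9)
  expect_equal(fit$n0, 0.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  fit20 <- fit_exponential(make_series(t, 0.5 * exp(log(2) / 20 * t)), min_sulfide = 0)
  expect_equal(fit20$doubling_time, 20, tolerance = 1e-9)

  # irregular sampling grid changes nothing on noise-free data
  t2 <- c(0, 1, 2.5, 7, 11, 13, 19, 23)
  fit2 <- fit_exponential(make_series(t2, 2 * exp(0.07 * t2)), min_sulfide = 0)
  expect_lt(abs(fit2$m - 0.07) / 0.07, 1e-9)

  # doubling time halves when the rate doubles
  fit_fast <- fit_exponential(make_series(t, 0.5 * exp(0.2 * t)), min_sulfide = 0)
  expect_equal(fit_fast$doubling_time, fit$doubling_time / 2, tolerance = 1e-9)

  expect_error(
    fit_exponential(make_series(0:1, c(2, 4))),
    "insufficient points"
  )
  expect_warning(
    decay <- fit_exponential(make_series(t, 10 * exp(-0.05 * t)), min_sulfide = 0),
    "non-positive"
  )
  expect_true(is.na(decay$doubling_time))
})

test_that("usable-point filter removes background and plateau values", {
  t <- seq(0, 60, 4)
  y <- pmin(0.5 * exp(0.15 * t), 12)           # plateau at 12 mM
  y[1] <- 0.4                                  # below assay background
  fit <- fit_exponential(make_series(t, y), min_sulfide = 1, plateau_fraction = 0.9)
  used <- fit$fit$model
  expect_true(all(exp(used[[1]]) > 1))
  expect_true(all(exp(used[[1]]) < 0.9 * 12))
  expect_equal(fit$m, 0.15, tolerance = 1e-9)  # plateau points would bias m low
})

test_that("doubling-time summaries average the first two segments", {
  t <- 0:10
  seg1 <- 1.2 * exp(log(2) / 10 * t)
  seg2 <- 1.2 * exp(log(2) / 20 * t)
  ts <- tibble::tibble(
    time_d = c(t, t + 11), replicate = "a",
    sulfide_mM = c(seg1, seg2),
    dilution = c(rep(0L, 11), 1L, rep(0L, 10))
  )
  s <- doubling_time_summary(ts, min_sulfide = 0)
  expect_identical(nrow(s), 2L)
  expect_equal(sort(s$doubling_time), c(10, 20), tolerance = 1e-9)
  expect_equal(attr(s, "mean_doubling_time"), 15, tolerance = 1e-9)

  single <- doubling_time_summary(make_series(t, seg1), min_sulfide = 0)
  expect_equal(attr(single, "mean_doubling_time"), 10, tolerance = 1e-9)

  flat <- make_series(0:3, c(2, 2, 2, 2))
  expect_error(
    suppressWarnings(doubling_time_summary(flat, min_sulfide = 3)),
    "no segment could be fitted"
  )
})

test_that("segmenting a flag-free series then fitting equals fitting it whole", {
  t <- seq(0, 40, 5)
  ts <- make_series(t, 0.8 * exp(0.09 * t))
  whole <- fit_exponential(ts, min_sulfide = 0)
  via_segments <- fit_exponential(
    dplyr::filter(segment_series(ts), segment == 1),
    min_sulfide = 0
  )
  expect_equal(via_segments$m, whole$m, tolerance = 1e-12)
  expect_equal(via_segments$doubling_time, whole$doubling_time, tolerance = 1e-12)
})

test_that("noisy doubling-time estimates stay within 10% in at least 95% of runs", {
  t <- seq(0, 44, 4)  # 12 points
  true_td <- 15
  m <- log(2) / true_td
  hits <- vapply(1:500, function(s) {
    withr::with_seed(s, {
      y <- 1.5 * exp(m * t) * exp(rnorm(length(t), 0, 0.05))
      fit <- fit_exponential(make_series(t, y), min_sulfide = 0, plateau_fraction = 1.1)
      abs(fit$doubling_time - true_td) / true_td < 0.1
    })
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("sustained activity requires consecutive passing segments", {
  two_good <- tibble::tibble(
    time_d = 0:5, replicate = "a",
    sulfide_mM = c(2, 8, 12, 4, 9, 11),
    dilution = c(0, 0, 0, 1, 0, 0)
  )
  expect_true(classify_sustained_activity(two_good)$success)

  negative_control <- make_series(0:5, rep(0.5, 6))
  expect_false(classify_sustained_activity(negative_control)$success)

  stalls <- tibble::tibble(
    time_d = 0:5, replicate = "a",
    sulfide_mM = c(2, 8, 12, 1, 2, 3),
    dilution = c(0, 0, 0, 1, 0, 0)
  )
  expect_false(classify_sustained_activity(stalls)$success)

  # monotone in threshold: success at t implies success at any t' < t
  for (thr in c(2, 5, 8)) {
    expect_true(classify_sustained_activity(two_good, threshold = thr)$success)
  }
  expect_false(classify_sustained_activity(two_good, threshold = 12)$success)

  # non-consecutive passing segments do not count
  gap <- tibble::tibble(
    time_d = 0:8, replicate = "a",
    sulfide_mM = c(2, 8, 12, 1, 2, 3, 5, 9, 13),
    dilution = c(0, 0, 0, 1, 0, 0, 1, 0, 0)
  )
  expect_false(classify_sustained_activity(gap)$success)
})
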