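# A well-conditioned synthetic series: near-complete description so the
# pool size is identifiable, per-bin counts in the hundreds.
recovery_series <- function(seed, S_T = 2000L, poisson_draw = TRUE) {
  set.seed(seed)
  series_from_model(S_T, a = 0.0125, b = 0, T_ = rep(20L, 12L),
                    poisson_draw = poisson_draw)
}

test_that("the returned optimum never degrades the starting likelihood", {
  for (s in 1:3) {
    ser <- recovery_series(s)
    for (fam in c("poisson", "gaussian")) {
      spec <- model_spec(fam)
      f <- suppressWarnings(fit(ser, spec))
      start <- spec$start
      start$S_T <- max(start$S_T, described_total(ser) * 1.02)
      nll0 <- nll_for(spec)(start, ser)
      expect_lte(f$nll, nll0)
      ci <- f$wald_intervals
      ok <- !is.na(ci$lower)
      expect_true(all(ci$lower[ok] <= ci$estimate[ok] + 1e-8))
      expect_true(all(ci$estimate[ok] <= ci$upper[ok] + 1e-8))
      expect_gte(f$estimates[["S_T"]], described_total(ser))
    }
  }
})

test_that("one further restart moves no estimate by 9e-6 or more", {
  ser <- recovery_series(7)
  f <- suppressWarnings(fit(ser, model_spec("poisson")))
  expect_true(f$converged)
  obj <- function(theta) {
    v <- nll_poisson(list(a = exp(theta[1]), b = exp(theta[2]),
                          S_T = theta[3]), ser)
    if (!is.finite(v)) .Machine$double.xmax else v
  }
  again <- stats::optim(f$theta, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000L, reltol = 1e-12))
  est2 <- c(exp(again$par[1:2]), again$par[3])
  est1 <- c(f$estimates[["a"]], f$estimates[["b"]], f$estimates[["S_T"]])
  expect_lt(max(abs(est2 - est1)), 9e-6)
})

test_that("the pool size is recovered from model-generated data", {
  medians <- vapply(1:20, function(s) {
    f <- suppressWarnings(fit(recovery_series(s), model_spec("poisson")))
    f$estimates[["S_T"]]
  }, numeric(1L))
  expect_lt(abs(stats::median(medians) - 2000) / 2000, 0.01)
  # every replicate lands in a sane neighbourhood
  expect_true(all(abs(medians - 2000) / 2000 < 0.05))
})

test_that("Wald interval width agrees with a parametric-bootstrap oracle", {
  ser <- recovery_series(11)
  f <- suppressWarnings(fit(ser, model_spec("poisson")))
  ci <- f$wald_intervals
  st <- ci[ci$parameter == "S_T", ]
  wald_width <- st$upper - st$lower

  est <- f$estimates
  set.seed(99)
  boot <- vapply(1:300, function(i) {
    bs <- series_from_model(round(est[["S_T"]]), est[["a"]], est[["b"]],
                            ser$T, poisson_draw = TRUE)
    bf <- suppressWarnings(fit(bs, model_spec("poisson")))
    bf$estimates[["S_T"]]
  }, numeric(1L))
  boot_width <- 2 * stats::qnorm(0.975) * stats::sd(boot)
  expect_lt(abs(wald_width - boot_width), 0.2 * boot_width)
})

test_that("fitted curves reproduce their own generating series", {
  ser <- recovery_series(3, poisson_draw = FALSE)  # noiseless, rounded
  f <- suppressWarnings(fit(ser, model_spec("poisson")))
  expect_gt(f$fit_correlation, 0.999)
  pred <- f$predicted
  expect_true(all(pred$fitted >= 0))
  expect_true(all(pred$lower <= pred$upper))
  # zero-intensity bins get a degenerate (0, 0) interval
  zed <- binned_series(c(1900L, 1905L, 1910L, 1915L),
                       c(4L, 2L, 0L, 0L), c(2L, 2L, 0L, 0L), d0 = 0L)
  fz <- suppressWarnings(fit(zed, model_spec("poisson")))
  pz <- fz$predicted
  expect_equal(pz$fitted[3:4], c(0, 0))
  expect_equal(pz$lower[3:4], c(0, 0))
  expect_equal(pz$upper[3:4], c(0, 0))
})

test_that("undescribed summary applies the reporting conventions", {
  mock <- structure(list(
    estimates = c(a = 1e-3, b = 1e-3, S_T = 5860),
    wald_intervals = data.frame(parameter = c("a", "b", "S_T"),
                                estimate = c(1e-3, 1e-3, 5860),
                                lower = c(NA, NA, 5792),
                                upper = c(NA, NA, 5928)),
    spec = model_spec("poisson")), class = "desc_fit")
  ser <- binned_series(c(2000L, 2005L), c(7L, 0L), c(1L, 1L), d0 = 5550L)
  u <- undescribed_summary(mock, ser)
  expect_equal(u$known, 5557L)
  expect_equal(u$unknown, 303)
  expect_equal(u$percent_unknown, 5.2)
  expect_equal(u$lower, 5792 - 5557)
  expect_equal(u$upper, 5928 - 5557)

  # estimate exactly at the described total: nothing left
  mock$estimates[["S_T"]] <- 5557
  mock$wald_intervals$lower[3] <- 5500
  mock$wald_intervals$upper[3] <- 5600
  u2 <- undescribed_summary(mock, ser)
  expect_equal(u2$unknown, 0)
  expect_equal(u2$percent_unknown, 0)
  expect_equal(u2$lower, 0)   # floored at zero
})

test_that("fit rejects unusable series", {
  expect_error(fit(binned_series(c(1900L, 1905L, 1910L),
                                 c(0L, 0L, 0L), c(1L, 1L, 1L))),
               "at least 4 bins")
  zero <- binned_series(1900L + 5L * (0:5), rep(0L, 6L), rep(2L, 6L))
  expect_error(fit(zero), "all-zero")
  mism <- binned_series(1900L + 5L * (0:5), c(3L, 0L, 0L, 0L, 0L, 0L),
                        c(0L, 2L, 2L, 2L, 2L, 2L))
  expect_error(fit(mism), "no bin with both")
})

test_that("fit serialises to JSON and CSV", {
  f <- suppressWarnings(fit(recovery_series(2), model_spec("poisson")))
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_fit(f, jp, cp)
  obj <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(obj$estimates$S_T, f$estimates[["S_T"]])
  expect_named(obj$undescribed,
               c("known", "S_T", "unknown", "percent_unknown", "lower",
                 "upper"))
  pred <- utils::read.csv(cp)
  expect_equal(nrow(pred), n_bins(recovery_series(2)))
})
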