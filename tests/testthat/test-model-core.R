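test_that("efficiency forms evaluate as specified", {
  em <- efficiency_model("exponential", a = 7e-4, b = 0.1)
  expect_equal(efficiency_at(em, 0), 7e-4)

  flat <- efficiency_model("exponential", a = 7e-4, b = 0)
  expect_equal(efficiency_at(flat, c(0, 50, 250)), rep(7e-4, 3))

  # frozen against an independent high-precision evaluation of 0.001*e^1.25
  em2 <- efficiency_model("exponential", a = 0.001, b = 0.005)
  expect_equal(efficiency_at(em2, 250), 0.0034903429574597416,
               tolerance = 1e-12)

  lin <- efficiency_model("linear", a = 0.01, b = 2e-4)
  expect_equal(efficiency_at(lin, 100), 0.03)

  expect_error(efficiency_model("exponential", a = 0), "a must be > 0")
  expect_error(efficiency_model("exponential", a = 1e-3, b = -1),
               "b must be >= 0")
})

test_that("intensity is the effort x pool x efficiency product", {
  ser <- binned_series(c(1755L, 1760L), c(0L, 0L), c(10L, 0L), d0 = 0L)
  em <- efficiency_model("exponential", a = 0.001, b = 0)
  lam <- intensity(ser, S_T = 100, em)
  expect_equal(lam, c(10 * 100 * 0.001, 0))   # T=0 bin gives 0

  # an exactly exhausted pool gives zero intensity
  ser2 <- binned_series(c(1755L, 1760L), c(5L, 0L), c(3L, 3L), d0 = 0L)
  expect_equal(intensity(ser2, S_T = 5, em)[2L], 0)

  expect_error(intensity(ser2, S_T = 3, em), "pool exhausted")
})

test_that("intensity is monotone in effort, pool, efficiency and depletion", {
  set.seed(21)
  ser <- random_series(10L)
  em <- efficiency_model("exponential", a = 2e-3, b = 1e-3)
  base <- intensity(ser, 500, em)
  expect_true(all(intensity(ser, 600, em) >= base))
  em_up <- efficiency_model("exponential", a = 3e-3, b = 1e-3)
  expect_true(all(intensity(ser, 500, em_up) >= base))
  more_T <- binned_series(ser$year_start, ser$S, ser$T + 1L, D = ser$D)
  expect_true(all(intensity(more_T, 500, em) >= base))
  deeper <- binned_series(ser$year_start, ser$S, ser$T, d0 = ser$D[1L] + 50L)
  expect_true(all(intensity(deeper, 500, em) <= base))
})

test_that("exponential and linear efficiency coincide at b = 0", {
  ser <- random_series(12L, seed = 4)
  expect_equal(intensity(ser, 400, efficiency_model("exponential", 1e-3, 0)),
               intensity(ser, 400, efficiency_model("linear", 1e-3, 0)))
})

test_that("calculated efficiency is the species/pool/effort ratio", {
  ser <- binned_series(c(1755L, 1760L, 1765L), c(5L, 0L, 2L),
                       c(10L, 4L, 0L), d0 = 0L)
  ce <- calculated_efficiency(ser, S_T = 1000)
  expect_equal(ce[1L], 5 / (1000 * 10))
  expect_equal(ce[2L], 0)          # S = 0 with taxonomists active
  expect_true(is.na(ce[3L]))       # T = 0: undefined
})

test_that("Poisson NLL matches the independent log-density oracle", {
  one <- nll_poisson(list(a = 0.1, b = 0, S_T = 10),
                     binned_series(c(1900L, 1905L), c(1L, 0L),
                                   c(1L, 0L), d0 = 0L))
  expect_equal(one, 1.0, tolerance = 1e-12)  # lambda = 10*0.1 = 1, S = 1

  for (s in 1:20) {
    ser <- random_series(B = sample(4:12, 1L), seed = s)
    a <- stats::runif(1, 1e-4, 5e-2)
    b <- stats::runif(1, 0, 0.02)
    S_T <- described_total(ser) + sample(10:500, 1L)
    lam <- intensity(ser, S_T, efficiency_model("exponential", a, b))
    oracle <- -sum(stats::dpois(ser$S, lam, log = TRUE))
    expect_equal(nll_poisson(list(a = a, b = b, S_T = S_T), ser), oracle,
                 tolerance = 1e-10)
  }
})

test_that("Poisson NLL honours the zero-intensity conventions and penalties", {
  empty_bin <- binned_series(c(1900L, 1905L), c(0L, 0L), c(0L, 0L),
                             d0 = 3L)
  expect_equal(nll_poisson(list(a = 1e-3, b = 0, S_T = 3), empty_bin), 0)

  impossible <- binned_series(c(1900L, 1905L), c(2L, 0L), c(0L, 1L),
                              d0 = 0L)
  expect_equal(nll_poisson(list(a = 1e-3, b = 0, S_T = 10), impossible),
               Inf)

  ser <- random_series(6L, seed = 1)
  expect_equal(nll_poisson(list(a = -1, b = 0, S_T = 1e4), ser), Inf)
  expect_equal(nll_poisson(list(a = 1e-3, b = 0,
                                S_T = described_total(ser) - 1), ser),
               Inf)
})

test_that("Gaussian NLL matches the independent normal log-density oracle", {
  for (s in 1:20) {
    ser <- random_series(B = sample(4:12, 1L), seed = 100 + s)
    a <- stats::runif(1, 1e-4, 5e-2)
    b <- stats::runif(1, 0, 1e-4)
    z <- stats::runif(1, 0.5, 10)
    S_T <- described_total(ser) + sample(10:500, 1L)
    mu <- intensity(ser, S_T, efficiency_model("linear", a, b))
    oracle <- -sum(stats::dnorm(ser$S, mu, z, log = TRUE))
    expect_equal(nll_gaussian(list(a = a, b = b, S_T = S_T, z = z), ser),
                 oracle, tolerance = 1e-10)
  }
})

test_that("Gaussian NLL has the exact zero-residual floor and quadratic residuals", {
  z <- 3
  ser <- series_from_model(200, 0.002, 0, rep(10L, 5L))
  mu <- intensity(ser, 200, efficiency_model("linear", 0.002, 0))
  floor_term <- n_bins(ser) * 0.5 * log(2 * pi * z^2)

  # residual terms are exactly quadratic: doubling residuals at fixed z
  # quadruples the residual part of the NLL
  ser2 <- binned_series(ser$year_start,
                        pmax(as.integer(round(mu + 2 * (ser$S - mu))), 0L),
                        ser$T, d0 = 0L)
  n1 <- nll_gaussian(list(a = 0.002, b = 0, S_T = 200, z = z), ser)
  n2 <- nll_gaussian(list(a = 0.002, b = 0, S_T = 200, z = z), ser2)
  r1 <- sum((ser$S - mu)^2 / (2 * z^2))
  r2 <- sum((ser2$S - mu)^2 / (2 * z^2))
  expect_equal(n1 - floor_term, r1, tolerance = 1e-10)
  expect_equal(n2 - floor_term, r2, tolerance = 1e-10)

  # an exact-mean series sits on the floor B * 0.5 * log(2 pi z^2)
  exact <- binned_series(c(1900L, 1905L), c(6L, 0L), c(3L, 0L), d0 = 0L)
  mu_exact <- intensity(exact, 102, efficiency_model("linear",
                                                     6 / (3 * 102), 0))
  expect_equal(mu_exact[1L], 6)
  expect_equal(nll_gaussian(list(a = 6 / (3 * 102), b = 0, S_T = 102,
                                 z = z), exact),
               2 * 0.5 * log(2 * pi * z^2), tolerance = 1e-10)

  expect_equal(nll_gaussian(list(a = 0.002, b = 0, S_T = 200, z = -1),
                            ser),
               Inf)
})

test_that("bin-wise Poisson NLL is minimised where intensity equals the count", {
  # two-bin series with one active bin: lambda_1 = (S1 + 1) * a, so the
  # profile over a must bottom out where lambda_1 equals the count S1
  for (S1 in c(1L, 4L, 17L)) {
    ser <- binned_series(c(1900L, 1905L), c(S1, 0L), c(1L, 0L), d0 = 0L)
    g <- function(a) nll_poisson(list(a = a, b = 0, S_T = S1 + 1L), ser)
    opt <- stats::optimize(g, c(1e-8, 5))
    expect_equal((S1 + 1L) * opt$minimum, S1, tolerance = 1e-4)
  }
})
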