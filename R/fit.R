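# Fitting scale: (ln a, ln b, S_T[, ln z]). Logging a and b constrains
# them positive; S_T stays natural with an +Inf penalty below the
# described total. b = 0 is unreachable on the log scale; b < 1e-8 is
# reported as numerically zero behaviour in practice.

theta_names <- function(spec)
  c("a", "b", "S_T", if (spec$family == "gaussian") "z")

to_fitting_scale <- function(est) {
  th <- c(log(est[["a"]]), log(est[["b"]]), est[["S_T"]])
  if ("z" %in% names(est)) th <- c(th, log(est[["z"]]))
  th
}

from_fitting_scale <- function(theta, spec) {
  est <- c(a = exp(theta[1L]), b = exp(theta[2L]), S_T = theta[3L])
  if (spec$family == "gaussian") est["z"] <- exp(theta[4L])
  est
}

# Data-driven starting values: a small pool margin above the described
# total, efficiency coefficients from a least-squares line through the
# calculated efficiencies, and z from the residual spread. Used as a
# second optimisation start so series far from the default start's scale
# do not strand Nelder-Mead in a poor local optimum.
auto_start <- function(series, spec) {
  S_T0 <- described_total(series) * 1.05
  ce <- calculated_efficiency(series, S_T0)
  ok <- !is.na(ce) & ce > 0
  Y <- series$Y[ok]
  if (sum(ok) >= 3L && length(unique(Y)) >= 2L) {
    if (spec$efficiency == "exponential") {
      co <- stats::coef(stats::lm(log(ce[ok]) ~ Y))
      a0 <- exp(co[[1L]])
      b0 <- max(co[[2L]], 1e-6)
    } else {
      co <- stats::coef(stats::lm(ce[ok] ~ Y))
      a0 <- max(co[[1L]], min(ce[ok]))
      b0 <- max(co[[2L]], 1e-8)
    }
  } else {
    # too few active bins for a regression (burst-like series): flat
    # efficiency matched to the aggregate count near the pool boundary
    denom <- sum(series$T * (S_T0 - series$D))
    if (denom <= 0) return(NULL)
    a0 <- sum(series$S) / denom
    b0 <- 1e-6
  }
  if (!is.finite(a0) || a0 <= 0 || !is.finite(b0)) return(NULL)
  start <- list(S_T = S_T0, a = a0, b = min(b0, 0.5))
  if (spec$family == "gaussian") {
    mu <- lambda_raw(series, S_T0, a0, b0, "linear")
    start$z <- max(stats::sd(series$S - mu), 1)
  }
  start
}

# Boundary-profile starting values: fix the pool just above the
# described total and optimise the remaining parameters there before
# releasing everything. On sparse or burst-dominated series the
# likelihood is nearly flat in S_T, and a full search started far from
# the boundary can stall above the boundary-region optimum.
profile_start <- function(series, spec, nll) {
  S_T0 <- described_total(series) * 1.02
  denom <- sum(series$T * (S_T0 - series$D))
  if (denom <= 0 || sum(series$S) == 0) return(NULL)
  a0 <- sum(series$S) / denom
  p0 <- c(log(a0), log(1e-6))
  if (spec$family == "gaussian") {
    mu0 <- lambda_raw(series, S_T0, a0, 1e-6, "linear")
    p0 <- c(p0, log(max(stats::sd(series$S - mu0), 1)))
  }
  pr <- function(p) {
    par <- list(a = exp(p[1L]), b = exp(p[2L]), S_T = S_T0)
    if (spec$family == "gaussian") par$z <- exp(p[3L])
    v <- nll(par, series)
    if (!is.finite(v)) .Machine$double.xmax else v
  }
  opt <- stats::optim(p0, pr, method = "Nelder-Mead",
                      control = list(maxit = 1000L, reltol = 1e-10))
  start <- list(S_T = S_T0, a = exp(opt$par[1L]), b = exp(opt$par[2L]))
  if (spec$family == "gaussian") start$z <- exp(opt$par[3L])
  start
}

#' Fit a pool-depletion description model by maximum likelihood
#'
#' Minimises the family's negative log-likelihood over
#' \eqn{(\ln a, \ln b, S_T)} (plus \eqn{\ln z} for the Gaussian
#' comparator) with Nelder-Mead, restarting the optimiser from its own
#' optimum until the maximum absolute change across the natural-scale
#' estimates falls below `9e-6` (capped at `max_restarts`, after which
#' `converged` is `FALSE`). The optimisation is multi-start: from the
#' [model_spec()] starting values (with the starting pool never below
#' 1.02 times the series' described total), from a data-driven start
#' derived from the calculated efficiencies, and from a boundary-profile
#' start with the pool anchored just above the described total. The
#' lowest optimum is returned; among optima whose likelihoods tie to
#' within `1e-6`, the smallest pool estimate is preferred.
#'
#' @param series A [binned_series()] with at least 4 bins and at least one
#'   bin with positive `S` and `T`.
#' @param spec A [model_spec()].
#' @param level Confidence level for Wald intervals.
#' @param max_restarts Cap on restart cycles.
#' @return An object of class `desc_fit`: estimates, `nll`,
#'   `wald_intervals` (see [wald_ci()]), per-bin `predicted` (see
#'   [predict_series()]), `undescribed` summary (see
#'   [undescribed_summary()]), `fit_correlation`, `converged` and
#'   `n_restarts`.
#' @export
#' @examples
#' sc <- scenario(2, true_S_T = 800,
#'                taxonomist_trajectory = rep(50L, 40), seed = 1)
#' sim <- simulate_history(sc)
#' fit(sim$binned, model_spec("poisson"))
fit <- function(series, spec = model_spec("poisson"), level = 0.95,
                max_restarts = 100L) {
  stopifnot(inherits(series, "binned_series"), inherits(spec, "model_spec"))
  if (n_bins(series) < 4L)
    stop("need at least 4 bins to fit, got ", n_bins(series))
  if (all(series$S == 0L))
    stop("all-zero species counts: nothing to fit")
  if (!any(series$S > 0L & series$T > 0L))
    stop("no bin with both species and taxonomists")

  nll <- nll_for(spec)
  obj <- function(theta) {
    est <- from_fitting_scale(theta, spec)
    v <- nll(as.list(est), series)
    if (!is.finite(v)) .Machine$double.xmax else v
  }

  start <- spec$start
  start$S_T <- max(start$S_T, described_total(series) * 1.02)
  starts <- list(start)
  st2 <- auto_start(series, spec)
  if (!is.null(st2)) starts <- c(starts, list(st2))
  st3 <- profile_start(series, spec, nll)
  if (!is.null(st3)) starts <- c(starts, list(st3))
  starts <- Filter(function(s) {
    th <- to_fitting_scale(unlist(s))
    all(is.finite(th)) && obj(th) < .Machine$double.xmax
  }, starts)
  if (!length(starts))
    stop("non-finite likelihood at starting values ",
         paste(names(start), unlist(start), sep = "=", collapse = ", "))

  run_restarts <- function(theta) {
    est_prev <- from_fitting_scale(theta, spec)
    n_restarts <- 0L
    converged <- FALSE
    opt <- NULL
    repeat {
      opt <- stats::optim(theta, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000L, reltol = 1e-12))
      theta <- opt$par
      est_now <- from_fitting_scale(theta, spec)
      if (max(abs(est_now - est_prev)) < 9e-6) {
        converged <- TRUE
        break
      }
      est_prev <- est_now
      n_restarts <- n_restarts + 1L
      if (n_restarts >= max_restarts) break
    }
    list(theta = theta, value = opt$value, converged = converged,
         n_restarts = n_restarts)
  }
  runs <- lapply(starts, function(s)
    run_restarts(to_fitting_scale(unlist(s))))
  # Tie-break on likelihood plateaus: when a burst-dominated series
  # leaves S_T unidentified, the NLL is flat in (S_T up, a down) and
  # different starts stop at arbitrary points along the ridge. Among
  # optima within tolerance of the best NLL, prefer the smallest pool.
  vals <- vapply(runs, `[[`, numeric(1L), "value")
  near <- which(vals <= min(vals) + 1e-6)
  best <- runs[[near[which.min(vapply(runs, function(r) r$theta[3L],
                                      numeric(1L))[near])]]]
  theta <- best$theta
  opt <- best
  converged <- best$converged
  n_restarts <- best$n_restarts
  estimates <- from_fitting_scale(theta, spec)

  out <- structure(
    list(spec = spec, estimates = estimates, nll = opt$value,
         theta = theta, converged = converged, n_restarts = n_restarts,
         level = level, series_label = series$label,
         described = described_total(series)),
    class = "desc_fit")
  out$wald_intervals <- wald_ci(out, series, level)
  pred <- predict_series(out, series, level)
  out$predicted <- pred
  out$fit_correlation <- attr(pred, "correlation")
  out$undescribed <- undescribed_summary(out, series)
  out
}

#' Wald confidence intervals for a fitted model
#'
#' Standard errors from the inverse of the finite-difference Hessian of
#' the negative log-likelihood at the optimum, computed on the fitting
#' scale (log for `a`, `b`, `z`; natural for `S_T`). Intervals are
#' estimate plus/minus the normal quantile times the standard error,
#' back-transformed for logged parameters, which makes the `a`, `b`, `z`
#' intervals asymmetric about their estimates. A singular or indefinite
#' Hessian yields `NA` bounds with a warning.
#'
#' @param fit A `desc_fit`.
#' @param series The [binned_series()] the model was fitted to.
#' @param level Confidence level.
#' @return Data frame with one row per parameter: `estimate`, `lower`,
#'   `upper`.
#' @export
wald_ci <- function(fit, series, level = 0.95) {
  spec <- fit$spec
  nll <- nll_for(spec)
  obj <- function(theta) {
    v <- nll(as.list(from_fitting_scale(theta, spec)), series)
    if (!is.finite(v)) .Machine$double.xmax else v
  }
  nm <- theta_names(spec)
  q <- stats::qnorm((1 + level) / 2)
  se <- rep(NA_real_, length(nm))
  H <- try(stats::optimHess(fit$theta, obj), silent = TRUE)
  if (!inherits(H, "try-error")) {
    # Invert over the informative directions only: a parameter at the
    # edge of its domain (e.g. b -> 0 on the log scale) leaves a flat,
    # possibly indefinite direction that would otherwise void every
    # interval. Flat/negative-curvature parameters get NA bounds.
    keep <- which(is.finite(diag(H)) & diag(H) > 0)
    while (length(keep)) {
      cov <- try(solve(H[keep, keep, drop = FALSE]), silent = TRUE)
      if (!inherits(cov, "try-error") && all(is.finite(diag(cov))) &&
          all(diag(cov) >= 0)) {
        se[keep] <- sqrt(diag(cov))
        break
      }
      keep <- keep[-which.min(diag(H)[keep])]
    }
    if (anyNA(se))
      warning("flat or indefinite Hessian direction: Wald intervals ",
              "unavailable for ", paste(nm[is.na(se)], collapse = ", "))
  } else warning("Hessian evaluation failed: Wald intervals unavailable")
  lo_t <- fit$theta - q * se
  hi_t <- fit$theta + q * se
  logscale <- nm != "S_T"
  lower <- ifelse(logscale, exp(lo_t), lo_t)
  upper <- ifelse(logscale, exp(hi_t), hi_t)
  data.frame(parameter = nm, estimate = unname(fit$estimates[nm]),
             lower = lower, upper = upper, row.names = NULL)
}

#' Fitted per-bin description counts with intervals
#'
#' Evaluates the fitted intensity \eqn{\hat S_i} in every bin and attaches
#' a central interval: Poisson quantiles at \eqn{\hat\lambda_i} for the
#' Poisson family, \eqn{\hat\mu_i \pm q \hat z} for the Gaussian
#' comparator. Parameter uncertainty is not propagated into these per-bin
#' intervals. The Pearson correlation between fitted and observed counts
#' is attached as attribute `"correlation"`.
#'
#' @param fit A `desc_fit`.
#' @param series The fitted [binned_series()].
#' @param level Interval level.
#' @return Data frame `year_start`, `Y`, `S`, `fitted`, `lower`, `upper`
#'   with attribute `correlation`.
#' @export
predict_series <- function(fit, series, level = 0.95) {
  est <- fit$estimates
  form <- fit$spec$efficiency
  lam <- pmax(lambda_raw(series, est[["S_T"]], est[["a"]], est[["b"]],
                         form), 0)
  alpha <- (1 - level) / 2
  if (fit$spec$family == "poisson") {
    lower <- stats::qpois(alpha, lam)
    upper <- stats::qpois(1 - alpha, lam)
  } else {
    q <- stats::qnorm(1 - alpha)
    lower <- pmax(lam - q * est[["z"]], 0)
    upper <- lam + q * est[["z"]]
  }
  out <- data.frame(year_start = series$year_start, Y = series$Y,
                    S = series$S, fitted = lam, lower = lower,
                    upper = upper)
  attr(out, "correlation") <-
    if (stats::sd(lam) > 0 && stats::sd(series$S) > 0)
      stats::cor(lam, series$S) else NA_real_
  out
}

#' Undescribed-species summary
#'
#' Reports the described total (`known`), the estimated pool `S_T`, the
#' remaining undescribed count `unknown = S_T - known` (rounded to an
#' integer), the percentage unknown (one decimal), and the `S_T` Wald
#' interval shifted by `-known` and floored at zero.
#'
#' @param fit A `desc_fit`.
#' @param series The fitted [binned_series()].
#' @return List `known`, `S_T`, `unknown`, `percent_unknown`, `lower`,
#'   `upper`.
#' @export
undescribed_summary <- function(fit, series) {
  known <- described_total(series)
  S_T <- fit$estimates[["S_T"]]
  ci <- fit$wald_intervals
  st_row <- ci[ci$parameter == "S_T", ]
  unknown <- round(S_T - known)
  list(known = known, S_T = S_T, unknown = unknown,
       percent_unknown = round(100 * (S_T - known) / S_T, 1),
       lower = max(st_row$lower - known, 0),
       upper = max(st_row$upper - known, 0))
}

#' @export
print.desc_fit <- function(x, ...) {
  cat(sprintf("%s-%s fit to '%s'%s\n", x$spec$family, x$spec$efficiency,
              x$series_label,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  NLL %.4f after %d restart(s)\n", x$nll, x$n_restarts))
  ci <- x$wald_intervals
  for (i in seq_len(nrow(ci)))
    cat(sprintf("  %-4s %12.6g  [%.6g, %.6g]\n", ci$parameter[i],
                ci$estimate[i], ci$lower[i], ci$upper[i]))
  u <- x$undescribed
  cat(sprintf("  described %d; estimated pool %.0f; undescribed %d (%.1f%%), interval [%.0f, %.0f]\n",
              u$known, u$S_T, u$unknown, u$percent_unknown, u$lower,
              u$upper))
  cat(sprintf("  fitted/observed Pearson correlation %.3f\n",
              x$fit_correlation))
  invisible(x)
}

#' Serialise a fit to JSON and per-bin CSV
#'
#' @param fit A `desc_fit`.
#' @param json_path,csv_path Output paths; either may be `NULL` to skip.
#' @return `fit`, invisibly.
#' @export
write_fit <- function(fit, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    obj <- list(
      family = fit$spec$family, efficiency = fit$spec$efficiency,
      series = fit$series_label,
      estimates = as.list(fit$estimates), nll = fit$nll,
      converged = fit$converged, n_restarts = fit$n_restarts,
      level = fit$level,
      intervals = fit$wald_intervals,
      undescribed = fit$undescribed,
      fit_correlation = fit$fit_correlation)
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path))
    utils::write.csv(fit$predicted, csv_path, row.names = FALSE)
  invisible(fit)
}
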