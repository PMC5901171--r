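#' Taxonomic efficiency models
#'
#' Taxonomic efficiency is the number of species described per taxonomist,
#' per remaining undescribed species, per interval. Two parametric forms
#' are supported: the exponential \eqn{E(Y) = a e^{bY}}, which is
#' everywhere nonnegative and strictly increasing (or constant at
#' \eqn{b = 0}) as technique and accumulated knowledge improve, and the
#' linear comparator \eqn{E(Y) = a + bY} used by earlier effort-based
#' accumulation models.
#'
#' @param form `"exponential"` or `"linear"`.
#' @param a Efficiency intercept, \eqn{a > 0}.
#' @param b Rate of efficiency change per year of bin offset,
#'   \eqn{b \ge 0}.
#' @return An object of class `efficiency_model`.
#' @export
#' @examples
#' em <- efficiency_model("exponential", a = 7e-4, b = 5.4e-3)
#' efficiency_at(em, c(0, 125, 250))
efficiency_model <- function(form = c("exponential", "linear"),
                             a, b = 0) {
  form <- match.arg(form)
  if (!is.finite(a) || a <= 0) stop("efficiency intercept a must be > 0")
  if (!is.finite(b) || b < 0) stop("efficiency slope b must be >= 0")
  structure(list(form = form, a = a, b = b), class = "efficiency_model")
}

#' Evaluate a taxonomic-efficiency model
#'
#' @param model An [efficiency_model()].
#' @param Y Nonnegative year offsets.
#' @return Efficiency values \eqn{E(Y)}.
#' @rdname efficiency_model
#' @export
efficiency_at <- function(model, Y) {
  if (model$a <= 0) stop("efficiency intercept a must be > 0")
  switch(model$form,
         exponential = model$a * exp(model$b * Y),
         linear = model$a + model$b * Y)
}

#' Model specification for fitting
#'
#' Pairs a distribution family for the per-bin counts with an efficiency
#' form, plus starting values for the optimiser. The Poisson family takes
#' the per-bin intensity as its mean and variance; the Gaussian comparator
#' models counts as Normal with mean \eqn{\mu_i} and a single free
#' dispersion scale `z` estimated jointly with the other parameters.
#'
#' Default starting values are `S_T = 5970`, `a = 8e-4`, `b = 2e-3` (and
#' `z = 5` for the Gaussian family); `fit()` raises the starting `S_T` to
#' 1.02 times the series total when the series has described more species
#' than that.
#'
#' @param family `"poisson"` or `"gaussian"`.
#' @param efficiency `"exponential"` or `"linear"`; defaults to
#'   exponential for the Poisson family and linear for the Gaussian
#'   comparator.
#' @param start Named list overriding starting values `S_T`, `a`, `b`, `z`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("poisson", "gaussian"),
                       efficiency = NULL, start = list()) {
  family <- match.arg(family)
  if (is.null(efficiency))
    efficiency <- if (family == "poisson") "exponential" else "linear"
  efficiency <- match.arg(efficiency, c("exponential", "linear"))
  sv <- list(S_T = 5970, a = 8e-4, b = 2e-3)
  if (family == "gaussian") sv$z <- 5
  bad <- setdiff(names(start), names(sv))
  if (length(bad))
    stop("unknown starting value(s): ", paste(bad, collapse = ", "))
  sv[names(start)] <- start
  structure(list(family = family, efficiency = efficiency, start = sv),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model spec: %s family, %s efficiency\n", x$family,
              x$efficiency))
  cat("  start:", paste(names(x$start), unlist(x$start), sep = "=",
                        collapse = ", "), "\n")
  invisible(x)
}

# Per-bin intensity without domain errors; invalid regions give NaN/neg
# values which the likelihoods turn into +Inf penalties.
lambda_raw <- function(series, S_T, a, b, form) {
  E <- if (form == "exponential") a * exp(b * series$Y) else
    a + b * series$Y
  series$T * (S_T - series$D) * E
}

#' Per-bin expected description counts
#'
#' The model's intensity: \eqn{\lambda_i = T_i (S_T - D_i) E(Y_i)} where
#' \eqn{E} is the efficiency model. \eqn{D_i} counts species described
#' strictly before bin \eqn{i}, so a bin's own descriptions do not deplete
#' its own pool.
#'
#' @param series A [binned_series()].
#' @param S_T Total species pool; must be at least every \eqn{D_i}.
#' @param efficiency An [efficiency_model()].
#' @return Numeric vector of nonnegative per-bin intensities.
#' @export
intensity <- function(series, S_T, efficiency) {
  if (any(S_T < series$D))
    stop("pool exhausted before data end: S_T = ", S_T,
         " < max D_i = ", max(series$D))
  lam <- lambda_raw(series, S_T, efficiency$a, efficiency$b,
                    efficiency$form)
  pmax(lam, 0)
}

#' Calculated efficiency
#'
#' The empirical per-bin efficiency implied by the data at a given pool
#' size: \eqn{CE_i = S_i / ((S_T - D_i) T_i)}. Plotted against the fitted
#' parametric efficiency it diagnoses the efficiency submodel. Bins with
#' no taxonomists or an exhausted pool are undefined and return `NA`.
#'
#' @param series A [binned_series()].
#' @param S_T Total species pool.
#' @return Numeric vector of per-bin calculated efficiencies, `NA` where
#'   undefined.
#' @export
calculated_efficiency <- function(series, S_T) {
  denom <- (S_T - series$D) * series$T
  ifelse(denom > 0, series$S / denom, NA_real_)
}

#' Negative log-likelihoods of the per-bin count models
#'
#' `nll_poisson()` evaluates \eqn{-\sum_i \log(e^{-\lambda_i}
#' \lambda_i^{S_i} / S_i!)} with \eqn{\lambda_i} the model intensity,
#' computed through `lgamma` for numerical stability. A bin with
#' \eqn{\lambda_i = 0} contributes 0 when \eqn{S_i = 0} and \eqn{+\infty}
#' otherwise. `nll_gaussian()` evaluates the comparator
#' \eqn{S_i \sim N(\mu_i, z)} with \eqn{\mu_i = T_i (S_T - D_i)(a + b
#' Y_i)}. Both return `+Inf` outside the valid parameter domain
#' (\eqn{a \le 0}, \eqn{b < 0}, a pool smaller than the described total,
#' \eqn{z \le 0}, or negative \eqn{\mu_i}) so derivative-free optimisers
#' can probe freely.
#'
#' @param params Named list or vector with `a`, `b`, `S_T` and, for the
#'   Gaussian family, `z`.
#' @param series A [binned_series()].
#' @return Scalar negative log-likelihood.
#' @export
nll_poisson <- function(params, series) {
  params <- as.list(params)
  a <- params$a; b <- params$b; S_T <- params$S_T
  if (!is.finite(a) || !is.finite(b) || !is.finite(S_T) ||
      a <= 0 || b < 0 || S_T < described_total(series))
    return(Inf)
  lam <- lambda_raw(series, S_T, a, b, "exponential")
  if (any(!is.finite(lam))) return(Inf)
  S <- series$S
  ll <- numeric(length(lam))
  pos <- lam > 0
  ll[pos] <- S[pos] * log(lam[pos]) - lam[pos] - lgamma(S[pos] + 1)
  if (any(!pos & S > 0)) return(Inf)
  -sum(ll)
}

#' @rdname nll_poisson
#' @export
nll_gaussian <- function(params, series) {
  params <- as.list(params)
  a <- params$a; b <- params$b; S_T <- params$S_T; z <- params$z
  if (!is.finite(a) || !is.finite(b) || !is.finite(S_T) ||
      !is.finite(z) || a <= 0 || b < 0 || z <= 0 ||
      S_T < described_total(series))
    return(Inf)
  mu <- lambda_raw(series, S_T, a, b, "linear")
  if (any(!is.finite(mu)) || any(mu < 0)) return(Inf)
  sum(0.5 * log(2 * pi * z^2) + (series$S - mu)^2 / (2 * z^2))
}

nll_for <- function(spec) {
  if (spec$family == "poisson") nll_poisson else nll_gaussian
}
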