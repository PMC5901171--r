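# Shared generators and independent oracles for the test suite.

# Small random series for property-style tests.
random_series <- function(B = 8L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- stats::rpois(B, sample(1:8, B, replace = TRUE))
  if (all(S == 0L)) S[1L] <- 1L
  binned_series(1900L + 5L * (0:(B - 1L)), S,
                sample(0:12, B, replace = TRUE),
                d0 = sample(0:5, 1L))
}

# Series generated from the model's own per-bin intensity with sequential
# pool depletion; deterministic (rounded intensity) or Poisson-sampled.
series_from_model <- function(S_T, a, b, T_, width = 5L, d0 = 0L,
                              poisson_draw = FALSE) {
  B <- length(T_)
  Y <- (0:(B - 1L)) * width
  S <- integer(B)
  D <- integer(B)
  Dcur <- d0
  for (i in seq_len(B)) {
    D[i] <- Dcur
    lam <- T_[i] * (S_T - Dcur) * a * exp(b * Y[i])
    S[i] <- if (poisson_draw) stats::rpois(1L, lam) else round(lam)
    S[i] <- min(S[i], S_T - Dcur)
    Dcur <- Dcur + S[i]
  }
  binned_series(1755L + Y, S, T_, D = D, label = "model series")
}

# Independent oracle for the Gillespie simulator: in a pure-death process
# with piecewise-constant per-capita hazard r_i = T_i * E_i, species are
# iid with per-species cumulative hazard cumsum(r_i * width); a unit
# exponential inverted through it gives each species' description bin.
# No event loop is involved.
oracle_bin_counts <- function(S_T, T_, E, width = 5) {
  cum <- cumsum(T_ * E * width)
  u <- stats::rexp(S_T)
  bin <- findInterval(u, cum) + 1L   # > length(T_) means never described
  tabulate(bin[bin <= length(T_)], nbins = length(T_))
}

# Description years with a depleting-pool flavour: early-heavy sampling
# so the description curve declines and the pool size is identifiable.
depleting_years <- function(n, from = 1761L, to = 2005L, rate = 80) {
  yrs <- from:to
  sample(yrs, n, replace = TRUE, prob = exp(-(yrs - from) / rate))
}

# Records table builder for binning/realm tests.
make_records <- function(years, authorship = NULL, realm = NULL,
                         prefix = "Genus sp") {
  n <- length(years)
  df <- data.frame(
    binomial = paste0(prefix, seq_len(n)),
    year = as.integer(years),
    authorship = if (is.null(authorship))
      paste0("Author", (seq_len(n) %% 7L) + 1L) else authorship)
  if (!is.null(realm)) df$realm <- realm
  df
}
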