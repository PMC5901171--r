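# Replicate r of a study uses seed (root_seed + 179 * r) mod 2^31 - 1,
# so studies are reproducible and replicates independently re-runnable.
replicate_seed <- function(root_seed, r) {
  as.integer((as.numeric(root_seed) + 179 * r) %% (2^31 - 1))
}

#' Run a bias/coverage simulation study
#'
#' For each replicate, simulates a description history from the scenario
#' and fits each candidate model to the binned outcome, then summarises
#' per model: the replicate pool estimates \eqn{\hat S_T}, their mean,
#' bias (mean minus truth), mean absolute deviation from truth, and the
#' coverage of the nominal-level Wald interval (fraction of replicates
#' whose \eqn{S_T} interval contains the true pool). Replicates whose fit
#' fails outright (error or non-convergence) are excluded and counted in
#' `n_failed`. A converged fit whose \eqn{S_T} interval is unavailable —
#' typically an estimate on the boundary \eqn{S_T = D_{end}}, common
#' under gamma-noise scenarios where a burst describes the whole pool —
#' still contributes its estimate to the mean/bias/MAD summaries but not
#' to coverage; such replicates are counted in `n_no_interval`.
#'
#' @param sc A [scenario()]; its seed drives every replicate.
#' @param n_reps Number of replicates, at least 1.
#' @param models List of [model_spec()]s to compare.
#' @param level Wald interval level used for coverage.
#' @return An object of class `study_summary`: the scenario, `n_reps`,
#'   and per-model summaries (`estimates`, `mean_estimate`, `bias`,
#'   `mad`, `coverage`, `n_failed`).
#' @export
run_study <- function(sc, n_reps,
                      models = list(poisson = model_spec("poisson"),
                                    gaussian = model_spec("gaussian")),
                      level = 0.95) {
  stopifnot(inherits(sc, "scenario"))
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (is.null(names(models)) || any(!nzchar(names(models))))
    names(models) <- vapply(models, function(m)
      paste(m$family, m$efficiency, sep = "_"), character(1L))
  res <- lapply(models, function(m)
    list(estimates = numeric(0L), covered = logical(0L),
         n_failed = 0L, n_no_interval = 0L))
  for (r in seq_len(n_reps)) {
    set.seed(replicate_seed(sc$seed, r))
    sim <- simulate_history_impl(sc)
    for (mname in names(models)) {
      f <- try(suppressWarnings(fit(sim$binned, models[[mname]],
                                    level = level)), silent = TRUE)
      if (inherits(f, "try-error") || !f$converged) {
        res[[mname]]$n_failed <- res[[mname]]$n_failed + 1L
        next
      }
      res[[mname]]$estimates <- c(res[[mname]]$estimates,
                                  f$estimates[["S_T"]])
      ci <- f$wald_intervals
      st <- ci[ci$parameter == "S_T", ]
      if (is.finite(st$lower) && is.finite(st$upper))
        res[[mname]]$covered <- c(res[[mname]]$covered,
                                  st$lower <= sc$true_S_T &&
                                    sc$true_S_T <= st$upper)
      else
        res[[mname]]$n_no_interval <- res[[mname]]$n_no_interval + 1L
    }
  }
  if (all(vapply(res, function(x) length(x$estimates) == 0L, logical(1L))))
    stop("all fits failed in every model")
  summaries <- lapply(res, function(x) {
    n_ok <- length(x$estimates)
    list(estimates = x$estimates,
         n_ok = n_ok,
         mean_estimate = if (n_ok) mean(x$estimates) else NA_real_,
         median_estimate = if (n_ok) stats::median(x$estimates) else
           NA_real_,
         bias = if (n_ok) mean(x$estimates) - sc$true_S_T else NA_real_,
         mad = if (n_ok) mean(abs(x$estimates - sc$true_S_T)) else
           NA_real_,
         coverage = if (length(x$covered)) mean(x$covered) else NA_real_,
         n_covered_basis = length(x$covered),
         n_failed = x$n_failed,
         n_no_interval = x$n_no_interval)
  })
  structure(list(scenario = sc, n_reps = as.integer(n_reps),
                 level = level, models = summaries),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("Simulation study: scenario %s, true S_T = %d, %d replicates\n",
              x$scenario$id, x$scenario$true_S_T, x$n_reps))
  for (m in names(x$models)) {
    s <- x$models[[m]]
    cat(sprintf(
      "  %-20s mean %.1f  bias %+.1f  MAD %.1f  coverage %.3f (of %d)  failed %d  no-interval %d\n",
      m, s$mean_estimate, s$bias, s$mad, s$coverage, s$n_covered_basis,
      s$n_failed, s$n_no_interval))
  }
  invisible(x)
}

#' Long-format replicate estimates for plotting
#'
#' Flattens a study into one row per (model, replicate) with the pool
#' estimate, the layout used for boxplot-style summaries of the study.
#' Failed replicates contribute no rows. Ordering is deterministic:
#' models in study order, replicates in fit order.
#'
#' @param summary A `study_summary`.
#' @return Data frame `scenario`, `model`, `replicate`, `estimate`.
#' @export
summarize_study_for_plot <- function(summary) {
  stopifnot(inherits(summary, "study_summary"))
  rows <- lapply(names(summary$models), function(m) {
    est <- summary$models[[m]]$estimates
    if (!length(est)) return(NULL)
    data.frame(scenario = as.character(summary$scenario$id), model = m,
               replicate = seq_along(est), estimate = est)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(scenario = character(0L), model = character(0L),
                      replicate = integer(0L), estimate = numeric(0L))
  out
}

#' Serialise a study summary
#'
#' Writes the per-model summary statistics as JSON and, optionally, the
#' long-format replicate estimates as CSV.
#'
#' @param summary A `study_summary`.
#' @param json_path,csv_path Output paths; either may be `NULL`.
#' @return `summary`, invisibly.
#' @export
write_study <- function(summary, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    obj <- list(
      scenario = summary$scenario[c("id", "true_S_T", "a", "b",
                                    "efficiency_noise", "n_bins",
                                    "bin_width", "seed")],
      n_reps = summary$n_reps, level = summary$level,
      models = lapply(summary$models, function(s)
        s[c("n_ok", "mean_estimate", "median_estimate", "bias", "mad",
            "coverage", "n_covered_basis", "n_failed",
            "n_no_interval")]))
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path))
    utils::write.csv(summarize_study_for_plot(summary), csv_path,
                     row.names = FALSE)
  invisible(summary)
}

#' Fit the model independently within each biogeographic realm
#'
#' Splits labelled description records by realm, bins each realm's
#' records into its own series (realm-specific S, T, D), fits the model
#' per realm, and assembles a table of known, estimated-pool and
#' percent-unknown values. Each species appears in exactly one realm, so
#' realm pools can be compared with (and summed against) a global fit
#' without double counting. Realms whose fit fails or whose series
#' cannot be built are flagged in the `note` column rather than dropped.
#'
#' @param records Data frame of description records; every row must carry
#'   a non-empty `realm`.
#' @param spec A [model_spec()].
#' @param window_start,window_end,width Binning window, as in
#'   [bin_records()].
#' @param level Wald interval level.
#' @return Data frame with one row per realm: `realm`, `known`, `S_T`,
#'   `lower`, `upper`, `unknown`, `percent_unknown`, `note` (empty when
#'   the fit succeeded).
#' @export
fit_by_realm <- function(records, spec = model_spec("poisson"),
                         window_start = 1755L, window_end = 2010L,
                         width = 5L, level = 0.95) {
  records <- validate_records(records)
  if (is.null(records$realm) || any(!nzchar(trimws(records$realm))))
    stop("every record needs a realm label for per-realm fitting")
  realms <- sort(unique(records$realm))
  rows <- lapply(realms, function(rl) {
    sub <- records[records$realm == rl, , drop = FALSE]
    row <- data.frame(realm = rl, known = NA_integer_, S_T = NA_real_,
                      lower = NA_real_, upper = NA_real_,
                      unknown = NA_real_, percent_unknown = NA_real_,
                      note = "")
    f <- try(suppressWarnings({
      ser <- bin_records(sub, window_start, window_end, width, label = rl)
      fit(ser, spec, level = level)
    }), silent = TRUE)
    if (inherits(f, "try-error")) {
      row$note <- paste("insufficient data:",
                        trimws(conditionMessage(attr(f, "condition"))))
      return(row)
    }
    u <- f$undescribed
    row$known <- u$known
    row$S_T <- round(u$S_T)
    ci <- f$wald_intervals
    st <- ci[ci$parameter == "S_T", ]
    row$lower <- round(st$lower)
    row$upper <- round(st$upper)
    row$unknown <- u$unknown
    row$percent_unknown <- u$percent_unknown
    row
  })
  do.call(rbind, rows)
}
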