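#' Binned species-description series
#'
#' A `binned_series` holds, for one taxon or region, the per-interval data
#' that the pool-depletion model consumes: for each fixed-width time bin
#' \eqn{i}, the bin offset \eqn{Y_i} (years since the window origin), the
#' number of species described \eqn{S_i}, the number of distinct taxonomists
#' publishing descriptions \eqn{T_i}, and the cumulative number of species
#' described strictly before the bin, \eqn{D_i} (including any descriptions
#' predating the window, which enter \eqn{D_0}).
#'
#' @param year_start Integer calendar year at which each bin starts.
#' @param S Nonnegative integer species counts per bin.
#' @param T_ Nonnegative integer taxonomist counts per bin.
#' @param D Cumulative species described strictly before each bin. If
#'   `NULL`, recomputed as `d0 + cumsum(S) - S`.
#' @param d0 Species described before the first bin (used when `D` is
#'   `NULL`).
#' @param label Name of the taxon/region the series describes.
#'
#' @return An object of class `binned_series`: a list with elements `Y`
#'   (bin offsets), `year_start`, `S`, `T`, `D`, `label` and `width`.
#' @seealso [bin_records()], [read_series_csv()]
#' @export
binned_series <- function(year_start, S, T_, D = NULL, d0 = 0L,
                          label = "series") {
  year_start <- as.integer(year_start)
  S <- as.integer(S)
  T_ <- as.integer(T_)
  B <- length(year_start)
  if (B < 2L)
    stop("a binned series needs at least 2 bins, got ", B)
  if (length(S) != B || length(T_) != B)
    stop("year_start, S and T must have equal length")
  widths <- diff(year_start)
  if (length(unique(widths)) != 1L)
    stop("non-uniform bin widths: ", paste(unique(widths), collapse = ", "))
  width <- widths[1L]
  if (width <= 0L) stop("bin width must be positive")
  if (any(S < 0L)) stop("negative species count S")
  if (any(T_ < 0L)) stop("negative taxonomist count T")
  if (is.null(D)) {
    D <- as.integer(d0) + cumsum(c(0L, S[-B]))
  } else {
    D <- as.integer(D)
    if (length(D) != B) stop("D must have one entry per bin")
    if (any(D < 0L)) stop("negative cumulative count D")
    if (any(diff(D) != S[-B]))
      stop("inconsistent cumulative counts: D[i+1] must equal D[i] + S[i]")
  }
  structure(
    list(Y = year_start - year_start[1L], year_start = year_start,
         S = S, T = T_, D = D, label = as.character(label),
         width = as.integer(width)),
    class = "binned_series")
}

#' @export
print.binned_series <- function(x, ...) {
  cat("Binned description series: ", x$label, "\n", sep = "")
  cat(sprintf("  %d bins of %d years, %d-%d\n", n_bins(x), x$width,
              x$year_start[1L], x$year_start[n_bins(x)] + x$width))
  cat(sprintf("  described before window: %d; described in window: %d\n",
              x$D[1L], sum(x$S)))
  cat(sprintf("  taxonomists per bin: %d-%d\n", min(x$T), max(x$T)))
  invisible(x)
}

#' @export
as.data.frame.binned_series <- function(x, ...) {
  data.frame(year_start = x$year_start, Y = x$Y, S = x$S, T = x$T, D = x$D)
}

#' Number of bins in a series
#' @param series A [binned_series()].
#' @return Integer bin count \eqn{B}.
#' @export
n_bins <- function(series) length(series$S)

#' Total species described by the end of a series
#'
#' Cumulative described species at the close of the last bin, i.e.
#' \eqn{D_B = D_0 + \sum_i S_i}.
#'
#' @param series A [binned_series()].
#' @return Integer total.
#' @export
described_total <- function(series) series$D[n_bins(series)] +
  series$S[n_bins(series)]

canonical_author <- function(x) {
  x <- trimws(x)
  x <- gsub("[[:space:]]+", " ", x)
  tolower(x)
}

validate_records <- function(records) {
  need <- c("binomial", "year", "authorship")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("record table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!nzchar(trimws(records$binomial))))
    stop("empty species binomial in record table")
  if (any(is.na(records$year)))
    stop("missing description year in record table")
  records$year <- as.integer(records$year)
  records
}

# Exact-duplicate binomials collapse to their first description year;
# synonymy beyond literal duplicates is out of scope.
dedupe_records <- function(records) {
  ord <- order(records$year)
  records <- records[ord, , drop = FALSE]
  records[!duplicated(records$binomial), , drop = FALSE]
}

#' Bin description records into a fixed-width series
#'
#' Assigns each description record to a half-open interval
#' `(start, start + width]` so that a description in year
#' `window_start + k * width` falls in bin `k - 1`; with the default
#' `window_start = 1755` and 5-year bins, a 1760 description lands in bin
#' \eqn{Y = 0} (1755-1760). Records dated at or before `window_start`
#' accumulate into the pre-window count \eqn{D_0} so the depletion term
#' remains correct when the window opens late; records after `window_end`
#' are an error. Duplicate binomials are collapsed to their earliest year
#' before binning. Taxonomist counts are computed with
#' [count_taxonomists()].
#'
#' @param records Data frame of description records with columns
#'   `binomial`, `year`, `authorship` and optionally `realm`.
#' @param window_start,window_end Calendar years delimiting the fitted
#'   window; their difference must be a positive multiple of `width`.
#' @param width Bin width in years.
#' @param label Series label.
#' @return A [binned_series()].
#' @export
#' @examples
#' recs <- data.frame(
#'   binomial = c("Aus bus", "Cus dus", "Eus fus"),
#'   year = c(1761, 1762, 1766),
#'   authorship = c("Smith", "Smith", "Jones"))
#' bin_records(recs, 1755, 1775)
bin_records <- function(records, window_start = 1755L, window_end = 2010L,
                        width = 5L, label = "series") {
  records <- validate_records(records)
  window_start <- as.integer(window_start)
  window_end <- as.integer(window_end)
  width <- as.integer(width)
  span <- window_end - window_start
  if (span <= 0L || span %% width != 0L)
    stop("window_end - window_start must be a positive multiple of width")
  records <- dedupe_records(records)
  late <- records$year > window_end
  if (any(late))
    stop("record(s) described after window_end ", window_end, ": ",
         paste(utils::head(records$binomial[late], 5L), collapse = ", "))
  pre <- records$year <= window_start
  d0 <- sum(pre)
  inwin <- records[!pre, , drop = FALSE]
  if (nrow(inwin) == 0L)
    stop("empty series: no records inside the window ",
         window_start, "-", window_end)
  B <- span %/% width
  # (start, start+width]: year start+1 .. start+width -> bin 0
  bin <- (inwin$year - window_start - 1L) %/% width
  year_start <- window_start + width * seq_len(B) - width
  S <- tabulate(bin + 1L, nbins = B)
  T_ <- count_taxonomists(inwin, bin, B)
  binned_series(year_start, S, T_, d0 = d0, label = label)
}

#' Count distinct taxonomists per bin
#'
#' Taxonomic effort \eqn{T_i} is the number of distinct authorship strings
#' among the descriptions in bin \eqn{i}. Canonicalisation is purely
#' lexical: trim, collapse internal whitespace, case-fold. Different author
#' orders remain distinct entries ("Mares & Braun" and "Mares, Braun,
#' Barquez & Diaz" count as two), and repeated identical strings count
#' once.
#'
#' @param records Data frame with an `authorship` column.
#' @param bin Zero-based bin index per record.
#' @param n_bins Total number of bins.
#' @return Integer vector of per-bin distinct-authorship counts (0 for
#'   empty bins).
#' @export
count_taxonomists <- function(records, bin, n_bins) {
  if (any(!nzchar(trimws(records$authorship))))
    stop("empty authorship string; needed for taxonomist counting")
  auth <- canonical_author(records$authorship)
  out <- integer(n_bins)
  tab <- tapply(auth, factor(bin, levels = 0:(n_bins - 1L)),
                function(a) length(unique(a)))
  out[] <- ifelse(is.na(tab), 0L, as.integer(tab))
  out
}

#' Read and write series CSV files
#'
#' The series CSV dialect has one row per bin with columns `year_start`,
#' `Y`, `S`, `T` and optionally `D`; when `D` is absent it is recomputed
#' from `S` with \eqn{D_0} taken from an optional `# d0: <n>` comment
#' header (default 0). A `# label: <name>` comment carries the series
#' label. [write_series_csv()] always writes both comments and all five
#' columns, so a write/read round trip is the identity.
#'
#' @param path File path.
#' @return [read_series_csv()] returns a [binned_series()];
#'   [write_series_csv()] returns `path` invisibly.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop("no such series file: ", path)
  hdr <- readLines(path, n = 5L)
  hdr <- hdr[startsWith(hdr, "#")]
  grab <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", hit[1L]))
  }
  label <- grab("label")
  d0 <- grab("d0")
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("year_start", "Y", "S", "T")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("series CSV ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  for (col in intersect(c(need, "D"), names(df))) {
    v <- df[[col]]
    if (any(is.na(v)) || any(v != round(v)))
      stop("non-integer values in column ", col, " of ", path)
  }
  binned_series(df$year_start, df$S, df$T,
                D = if ("D" %in% names(df)) df$D else NULL,
                d0 = if (is.na(d0)) 0L else as.integer(d0),
                label = if (is.na(label)) "series" else label)
}

#' @rdname read_series_csv
#' @param series A [binned_series()].
#' @export
write_series_csv <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# label: ", series$label),
               paste0("# d0: ", series$D[1L])), con)
  utils::write.csv(as.data.frame(series), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read description records from CSV
#'
#' Expects a UTF-8 CSV with header and columns `binomial`, `year`,
#' `authorship` and optionally `realm`.
#'
#' @param path File path.
#' @return Data frame of records.
#' @export
read_records_csv <- function(path) {
  if (!file.exists(path)) stop("no such records file: ", path)
  df <- utils::read.csv(path, encoding = "UTF-8")
  validate_records(df)
}
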