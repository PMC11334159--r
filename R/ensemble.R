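#' Ensemble of per-configuration objective values
#'
#' A container for the objective values of many packings — either local
#' optima from random restarts ("optimized") or geometry-matched random
#' packings ("random") — together with the settings and seeds that produced
#' them, so percentile and z-score comparisons are reproducible.
#'
#' @param values Numeric vector of objective values (mm^2 or mm).
#' @param kind `"optimized"` or `"random"`.
#' @param settings List snapshot of the generating configuration.
#' @param seeds Integer vector (or scalar) of seeds used.
#' @param extra Optional list of additional fields (e.g. per-restart
#'   convergence flags, acceptance bookkeeping).
#' @return An object of class `ensemble_result`.
#' @export
ensemble_result <- function(values, kind = c("optimized", "random"),
                            settings = list(), seeds = integer(),
                            extra = list()) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) >= 1L && any(!is.finite(values))) {
    stop("ensemble values must be finite", call. = FALSE)
  }
  structure(c(list(values = values, kind = kind, settings = settings,
                   seeds = seeds), extra),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("%s ensemble of %d configurations", x$kind, length(x$values)))
  if (length(x$values) > 0L) {
    cat(sprintf(": mean %.6g, sd %.4g, range [%.6g, %.6g]",
                mean(x$values), stats::sd(x$values), min(x$values),
                max(x$values)))
  }
  cat("\n")
  invisible(x)
}

#' Percentile of an observed value on an ensemble
#'
#' With the default strict convention the percentile is 100 times the
#' fraction of ensemble values strictly less than the observed value (ties
#' count above); `ties = "midrank"` gives ties half weight.
#'
#' @param observed Observed objective value.
#' @param values Numeric vector of ensemble values (n >= 1).
#' @param ties `"strict"` or `"midrank"`.
#' @return The unrounded percentile in \[0, 100\].
#' @export
percentile_of <- function(observed, values, ties = c("strict", "midrank")) {
  ties <- match.arg(ties)
  if (length(values) == 0L) stop("empty ensemble", call. = FALSE)
  below <- sum(values < observed)
  if (ties == "midrank") below <- below + 0.5 * sum(values == observed)
  100 * below / length(values)
}

#' Z-score of an observed value on an ensemble
#'
#' @inheritParams percentile_of
#' @return `(observed - mean(values)) / sd(values)` with the sample (n-1)
#'   standard deviation.
#' @export
zscore_of <- function(observed, values) {
  if (length(values) < 2L) stop("need at least 2 ensemble values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("degenerate ensemble: zero standard deviation", call. = FALSE)
  (observed - mean(values)) / s
}

# Internal: Freedman-Diaconis bin edges over the union of ensembles so
# overlaid histograms share bins; falls back to Sturges when IQR is 0.
shared_bin_edges <- function(all_values) {
  rng <- range(all_values)
  if (rng[1L] == rng[2L]) return(c(rng[1L] - 0.5, rng[1L] + 0.5))
  iqr <- stats::IQR(all_values)
  h <- 2 * iqr * length(all_values)^(-1 / 3)
  if (h <= 0) h <- diff(rng) / (ceiling(log2(length(all_values))) + 1)
  k <- max(1L, ceiling(diff(rng) / h))
  seq(rng[1L], rng[2L], length.out = k + 1L)
}

#' Locate an observed efficiency on optimized and random ensembles
#'
#' Produces the summary used to judge spatial efficiency: the observed
#' value's percentile and z-score on each ensemble, its distance from the
#' optimized-ensemble median in optimized-sd units, and shared-bin
#' histogram tables for overlay plotting.
#'
#' @param observed Observed objective value (e.g. the true configuration's
#'   neural efficiency, mm^2).
#' @param optimized An [ensemble_result()] of kind `"optimized"`.
#' @param random An [ensemble_result()] of kind `"random"`.
#' @param ties Percentile tie convention, see [percentile_of()].
#' @return An object of class `comparison_report`: a list with `observed`,
#'   per-ensemble blocks (`percentile`, `zscore`, `mean`, `sd`, `median`,
#'   `n`), `median_abs_dev_in_sd` (optimized ensemble), `degenerate` flags,
#'   and a `histogram` list with shared `breaks` and per-ensemble `counts`.
#' @export
compare_ensembles <- function(observed, optimized, random,
                              ties = c("strict", "midrank")) {
  ties <- match.arg(ties)
  stopifnot(inherits(optimized, "ensemble_result"),
            inherits(random, "ensemble_result"))
  if (length(optimized$values) == 0L || length(random$values) == 0L) {
    stop("both ensembles must be nonempty", call. = FALSE)
  }
  block <- function(values) {
    s <- if (length(values) >= 2L) stats::sd(values) else 0
    list(
      n = length(values),
      mean = mean(values),
      sd = s,
      median = stats::median(values),
      percentile = percentile_of(observed, values, ties = ties),
      zscore = if (s > 0) (observed - mean(values)) / s else NA_real_,
      degenerate = s == 0
    )
  }
  opt <- block(optimized$values)
  rnd <- block(random$values)
  med_dist <- if (opt$sd > 0) abs(observed - opt$median) / opt$sd else {
    if (observed == opt$median) 0 else NA_real_
  }
  breaks <- shared_bin_edges(c(optimized$values, random$values, observed))
  counts <- function(v) {
    graphics_free_hist(v, breaks)
  }
  structure(list(
    observed = observed,
    ties = ties,
    optimized = opt,
    random = rnd,
    median_abs_dev_in_sd = med_dist,
    histogram = list(breaks = breaks,
                     optimized_counts = counts(optimized$values),
                     random_counts = counts(random$values)),
    provenance = list(optimized_settings = optimized$settings,
                      optimized_seeds = optimized$seeds,
                      random_settings = random$settings,
                      random_seeds = random$seeds)
  ), class = "comparison_report")
}

# Internal: histogram counts on fixed edges without plotting machinery.
# Values on interior edges go to the lower bin (right-closed), matching
# hist(right = TRUE); values outside the range are clamped into end bins
# (only `observed` can sit on an edge by construction).
graphics_free_hist <- function(values, breaks) {
  k <- length(breaks) - 1L
  idx <- findInterval(values, breaks, rightmost.closed = TRUE,
                      left.open = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > k] <- k
  tabulate(idx, nbins = k)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Observed objective: %.6g\n", x$observed))
  cat(sprintf("  vs random ensemble (n=%d): percentile %.1f, z = %.3g\n",
              x$random$n, x$random$percentile, x$random$zscore))
  cat(sprintf("  vs optimized ensemble (n=%d): percentile %.1f, z = %.3g\n",
              x$optimized$n, x$optimized$percentile, x$optimized$zscore))
  cat(sprintf("  |observed - median(optimized)| = %.3g optimized-sd\n",
              x$median_abs_dev_in_sd))
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' @param report A [compare_ensembles()] report.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  payload <- unclass(report)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Read a comparison report back from JSON
#'
#' @param path Path written by [report_to_json()].
#' @return A `comparison_report`.
#' @export
report_from_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  payload$histogram$breaks <- as.numeric(payload$histogram$breaks)
  payload$histogram$optimized_counts <- as.integer(payload$histogram$optimized_counts)
  payload$histogram$random_counts <- as.integer(payload$histogram$random_counts)
  structure(payload, class = "comparison_report")
}
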