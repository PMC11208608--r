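#' Paired ATP / microglia-reporter traces over an event ROI
#'
#' Container for the two traces used to quantify microglial process
#' recruitment to a focal ATP event: the ATP-sensor dF/F trace and the
#' microglia-reporter MFI trace measured over the ATP event footprint at
#' maximum intensity.
#'
#' @param atp_trace ATP-sensor dF/F trace.
#' @param mg_trace Microglia-reporter MFI trace (same length).
#' @param dt Sample interval in seconds.
#' @param atp_peak_time ATP event peak time in seconds; when `NULL`, taken
#'   as the time of the maximum of `atp_trace`.
#' @return An object of class `recruitment_pair`.
#' @export
recruitment_pair <- function(atp_trace, mg_trace, dt, atp_peak_time = NULL) {
  check_positive(dt, "dt")
  check_that(length(atp_trace) == length(mg_trace), "mg_trace",
             "must have the same length as atp_trace")
  span <- (length(atp_trace) - 1) * dt
  if (is.null(atp_peak_time)) {
    atp_peak_time <- (which.max(atp_trace) - 1L) * dt
  }
  check_that(atp_peak_time >= 0 && atp_peak_time <= span, "atp_peak_time",
             "must lie within the trace span")
  structure(list(atp_trace = as.numeric(atp_trace),
                 mg_trace = as.numeric(mg_trace),
                 dt = dt, atp_peak_time = atp_peak_time),
            class = "recruitment_pair")
}

#' @export
print.recruitment_pair <- function(x, ...) {
  cat(sprintf("<recruitment_pair> %d samples, dt = %g s, ATP peak at %g s\n",
              length(x$atp_trace), x$dt, x$atp_peak_time))
  invisible(x)
}

#' Microglial process recruitment as percent MFI change
#'
#' Quantifies recruitment as the percent change of the microglia-reporter
#' signal relative to its pre-event baseline: the baseline is the average
#' of the reporter signal over the `baseline_window` (100 s) preceding the
#' ATP event peak; the response is the value of the reporter peak closest
#' to the ATP peak when a definitive peak exists within `search_window`
#' (300 s) after it, and otherwise the average over `post_window` (100 s)
#' after the ATP peak. A "definitive" reporter peak is a local maximum with
#' topographic prominence of at least `prominence_sd` baseline-window
#' standard deviations.
#'
#' @param pair A [recruitment_pair()].
#' @param search_window Peak search window after the ATP peak, seconds
#'   (default 300).
#' @param baseline_window Baseline averaging window before the ATP peak,
#'   seconds (default 100).
#' @param post_window Fallback averaging window after the ATP peak, seconds
#'   (default 100).
#' @param prominence_sd Minimum peak prominence in baseline-SD units
#'   (default 3).
#' @param smooth_samples Width (samples) of the moving-average applied to
#'   the reporter trace before peak detection (default 3; 1 = no
#'   smoothing). Noise-only local maxima near the ATP peak would otherwise
#'   occasionally qualify as "definitive" peaks and, being closest to the
#'   ATP peak, displace the true response peak.
#' @return A one-row tibble: `baseline`, `response`, `dmfi_percent`
#'   (`100 * (response - baseline) / baseline`), `rule_used`
#'   (`"peak"` or `"post-window-average"`), `baseline_sd`.
#' @export
recruitment_dmfi <- function(pair, search_window = 300,
                             baseline_window = 100, post_window = 100,
                             prominence_sd = 3, smooth_samples = 3) {
  stopifnot(inherits(pair, "recruitment_pair"))
  t <- (seq_along(pair$mg_trace) - 1L) * pair$dt
  tp <- pair$atp_peak_time
  pre <- which(t >= tp - baseline_window & t < tp)
  check_that(length(pre) >= 2L, "pair",
             "insufficient samples before the ATP peak for the baseline")
  baseline <- mean(pair$mg_trace[pre])
  check_that(baseline > 0, "pair", "baseline must be positive")
  base_sd <- stats::sd(pair$mg_trace[pre])

  mg_s <- if (smooth_samples > 1L) {
    as.numeric(stats::filter(pair$mg_trace,
                             rep(1 / smooth_samples, smooth_samples),
                             sides = 2))
  } else {
    pair$mg_trace
  }
  # moving average leaves NA at the ends; fall back to the raw samples there
  mg_s[is.na(mg_s)] <- pair$mg_trace[is.na(mg_s)]

  search <- which(t > tp & t <= tp + search_window)
  response <- NA_real_
  rule <- "post-window-average"
  if (length(search) >= 3L) {
    seg <- mg_s[search]
    pk <- local_maxima(seg)
    if (length(pk)) {
      prom <- peak_prominence(seg, pk)
      pk <- pk[prom >= prominence_sd * max(base_sd, .Machine$double.eps)]
    }
    if (length(pk)) {
      best <- pk[which.min(abs(t[search][pk] - tp))]
      response <- seg[best]
      rule <- "peak"
    }
  }
  if (rule == "post-window-average") {
    post <- which(t > tp & t <= tp + post_window)
    check_that(length(post) >= 1L, "pair",
               "no samples after the ATP peak for the fallback average")
    response <- mean(pair$mg_trace[post])
  }

  tibble(baseline = baseline, response = response,
         dmfi_percent = 100 * (response - baseline) / baseline,
         rule_used = rule, baseline_sd = base_sd)
}

#' Directed-movement classification
#'
#' A recruitment result is classified as directed movement when its percent
#' MFI change reaches `dmfi_min` (and, optionally, when the response was an
#' actual reporter peak rather than the fallback window average).
#'
#' @param result A tibble from [recruitment_dmfi()] (any number of rows).
#' @param dmfi_min Minimum percent MFI change (default 10).
#' @param require_peak Require `rule_used == "peak"` (default `FALSE`).
#' @return `result` with a logical `directed` column added.
#' @export
classify_directed <- function(result, dmfi_min = 10, require_peak = FALSE) {
  check_that(nrow(result) >= 1L, "result", "must contain at least one row")
  dplyr::mutate(result,
    directed = .data$dmfi_percent >= dmfi_min &
      (!require_peak | .data$rule_used == "peak"))
}

#' Prevalence of directed movement
#'
#' Fraction of events followed by directed microglial process movement,
#' with an exact binomial confidence interval.
#'
#' @param results Tibble with a logical `directed` column.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `n`, `n_directed`, `prevalence`, `conf_low`,
#'   `conf_high`.
#' @export
directed_prevalence <- function(results, conf_level = 0.95) {
  check_that(nrow(results) >= 1L, "results",
             "prevalence is undefined for an empty result set")
  n <- nrow(results)
  k <- sum(results$directed)
  ci <- binom.test(k, n, conf.level = conf_level)$conf.int
  tibble(n = n, n_directed = k, prevalence = k / n,
         conf_low = ci[1], conf_high = ci[2])
}

#' Latency of microglial process movement
#'
#' The latency is the first time after the ATP peak at which the reporter
#' trace exceeds `baseline + k_sd * SD(baseline window)` and stays above it
#' for at least two consecutive samples; undefined (`NA`) when the trace
#' never does.
#'
#' @param pair A [recruitment_pair()].
#' @param k_sd Threshold in baseline-SD units (default 2).
#' @param baseline_window Baseline window before the ATP peak, seconds
#'   (default 100).
#' @return Latency in seconds after the ATP peak, or `NA_real_`.
#' @export
movement_latency <- function(pair, k_sd = 2, baseline_window = 100) {
  stopifnot(inherits(pair, "recruitment_pair"))
  t <- (seq_along(pair$mg_trace) - 1L) * pair$dt
  tp <- pair$atp_peak_time
  pre <- which(t >= tp - baseline_window & t < tp)
  check_that(length(pre) >= 2L, "pair",
             "insufficient samples before the ATP peak for the baseline")
  baseline <- mean(pair$mg_trace[pre])
  thr <- baseline + k_sd * stats::sd(pair$mg_trace[pre])

  post <- which(t > tp)
  above <- pair$mg_trace[post] > thr
  sustained <- which(above & c(above[-1], FALSE))
  if (!length(sustained)) return(NA_real_)
  t[post[sustained[1]]] - tp
}
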