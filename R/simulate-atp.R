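#' Time-lapse stack container
#'
#' A T x H x W intensity movie with its frame interval and physical pixel
#' size, as acquired in two-photon ATP-sensor imaging.
#'
#' @param frames Numeric array with dim `c(T, H, W)`.
#' @param dt Frame interval in seconds.
#' @param pixel_size Pixel size in um/px.
#' @return An object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(frames, dt, pixel_size) {
  check_that(is.array(frames) && length(dim(frames)) == 3L &&
               dim(frames)[1] >= 2L, "frames",
             "must be a T x H x W array with T >= 2")
  check_positive(dt, "dt")
  check_positive(pixel_size, "pixel_size")
  structure(list(frames = frames, dt = dt, pixel_size = pixel_size),
            class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<timelapse_stack> %d frames of %d x %d px, dt = %g s, %g um/px\n",
              d[1], d[2], d[3], x$dt, x$pixel_size))
  invisible(x)
}

# Per-class kinetic parameter set: log-normal log-means / log-sds of
# peak dF/F, footprint area (um^2, at half maximum), rise tau and decay tau
# (seconds). Event duration (FWHM) follows from the taus:
# FWHM = ln(2) * (tau_rise + tau_decay).
default_flash_params <- function() {
  list(peak_log_mean = log(0.25), peak_log_sd = 0.4,
       area_log_mean = log(25),   area_log_sd = 0.4,
       rise_log_mean = log(4),    rise_log_sd = 0.3,
       decay_log_mean = log(8),   decay_log_sd = 0.3)
}

default_surge_params <- function() {
  list(peak_log_mean = log(1.0), peak_log_sd = 0.4,
       area_log_mean = log(150), area_log_sd = 0.4,
       rise_log_mean = log(15),  rise_log_sd = 0.3,
       decay_log_mean = log(40), decay_log_sd = 0.3)
}

#' Simulate a two-photon ATP-sensor movie with focal events
#'
#' Builds a movie of an exponentially decaying background (emulating the
#' slow run-down of ambient sensor fluorescence after slice preparation)
#' with focal ATP transients superimposed. Each event has a 2-D Gaussian
#' spatial footprint and a two-sided exponential temporal profile
#' (exponential rise with time constant `tau_rise` to the peak, exponential
#' decay with `tau_decay` after it), so the 10-90% rise time is
#' `tau_rise * ln 9` and the full width at half maximum is
#' `ln 2 * (tau_rise + tau_decay)`. Event features are drawn log-normally
#' per class from `flash_params` / `surge_params`; event counts per class
#' are Poisson with the given per-movie rates. Shot-like noise
#' (Gaussian with SD proportional to the square root of the signal) is added.
#'
#' Ground-truth footprint area is defined at half maximum of the spatial
#' Gaussian; ground-truth peak dF/F is the footprint-centre peak relative to
#' the local background.
#'
#' @param n_frames Number of frames (default 300: 10 min at 0.5 frame/s).
#' @param dt Frame interval in seconds (default 2).
#' @param height,width Frame size in px (default 128 x 256, a
#'   256 x 128 um field at 1 um/px).
#' @param pixel_size Pixel size in um/px (default 1).
#' @param background_f0 Initial background intensity (default 100).
#' @param background_decay_tau Background decay time constant in seconds
#'   (default 1200).
#' @param flash_rate,surge_rate Expected events per movie for each class
#'   (defaults 10 and 5).
#' @param flash_params,surge_params Log-normal feature parameters per class;
#'   see [default_flash_params()].
#' @param noise_scale Shot-noise scale: per-pixel SD is
#'   `noise_scale * sqrt(signal)` (default 0.3).
#' @param seed Integer seed.
#' @return A list with `stack` (a [timelapse_stack()]) and `truth` (a tibble
#'   with one row per event: `class`, `peak_time`, `row`, `col`, `peak_dff`,
#'   `area_um2`, `rise_tau`, `decay_tau`, `duration_fwhm`).
#' @export
simulate_atp_movie <- function(n_frames = 300, dt = 2, height = 128,
                               width = 256, pixel_size = 1,
                               background_f0 = 100,
                               background_decay_tau = 1200,
                               flash_rate = 10, surge_rate = 5,
                               flash_params = default_flash_params(),
                               surge_params = default_surge_params(),
                               noise_scale = 0.3, seed = NULL) {
  check_count(n_frames, "n_frames", min = 2L)
  check_positive(dt, "dt")
  check_count(height, "height", min = 8L)
  check_count(width, "width", min = 8L)
  check_positive(pixel_size, "pixel_size")
  check_positive(background_f0, "background_f0")
  check_positive(background_decay_tau, "background_decay_tau")
  check_nonneg(flash_rate, "flash_rate")
  check_nonneg(surge_rate, "surge_rate")
  for (p in list(flash_params, surge_params)) {
    check_that(all(vapply(p[c("rise_log_mean", "decay_log_mean")],
                          is.numeric, logical(1))),
               "flash_params/surge_params", "missing kinetic parameters")
  }

  with_seed(seed, {
    tvec <- (seq_len(n_frames) - 1L) * dt
    bg <- background_f0 * exp(-tvec / background_decay_tau)
    frames <- array(rep(bg, height * width), dim = c(n_frames, height, width))

    draw_events <- function(rate, params, class) {
      n <- if (rate > 0) rpois(1L, rate) else 0L
      if (!n) return(NULL)
      tibble(
        class = class,
        peak_time = runif(n, 0.1 * n_frames * dt, 0.9 * n_frames * dt),
        row = runif(n, 8, height - 8),
        col = runif(n, 8, width - 8),
        peak_dff = exp(rnorm(n, params$peak_log_mean, params$peak_log_sd)),
        area_um2 = exp(rnorm(n, params$area_log_mean, params$area_log_sd)),
        rise_tau = exp(rnorm(n, params$rise_log_mean, params$rise_log_sd)),
        decay_tau = exp(rnorm(n, params$decay_log_mean, params$decay_log_sd))
      )
    }
    truth <- dplyr::bind_rows(
      draw_events(flash_rate, flash_params, "flash"),
      draw_events(surge_rate, surge_params, "surge")
    )
    if (is.null(truth) || !nrow(truth)) {
      truth <- tibble(class = character(0), peak_time = numeric(0),
                      row = numeric(0), col = numeric(0),
                      peak_dff = numeric(0), area_um2 = numeric(0),
                      rise_tau = numeric(0), decay_tau = numeric(0))
    }
    truth <- dplyr::mutate(truth,
      duration_fwhm = log(2) * (.data$rise_tau + .data$decay_tau))

    rows <- matrix(seq_len(height), height, width)
    cols <- matrix(seq_len(width), height, width, byrow = TRUE)
    for (i in seq_len(nrow(truth))) {
      e <- truth[i, ]
      # footprint sd from half-max area: A = 2*pi*ln(2)*sigma^2 (um^2)
      sigma_px <- sqrt(e$area_um2 / (2 * pi * log(2))) / pixel_size
      spatial <- exp(-((rows - e$row)^2 + (cols - e$col)^2) / (2 * sigma_px^2))
      dtime <- tvec - e$peak_time
      temporal <- ifelse(dtime <= 0, exp(dtime / e$rise_tau),
                         exp(-dtime / e$decay_tau))
      # dF/F is relative to the local background at event time
      amp <- e$peak_dff * background_f0 *
        exp(-e$peak_time / background_decay_tau)
      for (k in seq_len(n_frames)) {
        if (temporal[k] > 1e-3) {
          frames[k, , ] <- frames[k, , ] + amp * temporal[k] * spatial
        }
      }
    }

    if (noise_scale > 0) {
      frames <- frames + noise_scale * sqrt(pmax(frames, 0)) *
        array(rnorm(length(frames)), dim = dim(frames))
    }

    list(stack = timelapse_stack(frames, dt, pixel_size), truth = truth)
  })
}

#' Simulate a paired ATP / microglia-reporter trace
#'
#' Produces one focal ATP transient (two-sided exponential dF/F profile) and
#' a microglia-reporter MFI trace over the same ROI. If `directed`, the
#' reporter trace rises by `dmfi_true` percent of its baseline along a
#' saturating-exponential time course that starts `latency_true` seconds
#' after the ATP peak; otherwise it stays flat (plus noise).
#'
#' @param directed Logical: does the microglia trace respond?
#' @param dmfi_true True plateau response in percent of baseline.
#' @param latency_true True response latency after the ATP peak, seconds.
#' @param dt Sample interval in seconds (default 2).
#' @param duration Total trace length in seconds (default 900).
#' @param atp_peak_time ATP peak time in seconds (default 300).
#' @param baseline Microglia-reporter baseline MFI (default 100).
#' @param rise_tau Response rise time constant in seconds (default 30).
#' @param atp_peak_dff,atp_rise_tau,atp_decay_tau ATP transient shape.
#' @param noise_sd Gaussian noise SD added to both traces (default 0).
#' @param seed Integer seed.
#' @return A list with `pair` (a [recruitment_pair()]) and `truth` (a
#'   one-row tibble: `directed`, `dmfi_true`, `latency_true`).
#' @export
simulate_recruitment_pair <- function(directed, dmfi_true = 30,
                                      latency_true = 60, dt = 2,
                                      duration = 900, atp_peak_time = 300,
                                      baseline = 100, rise_tau = 30,
                                      atp_peak_dff = 1, atp_rise_tau = 10,
                                      atp_decay_tau = 30, noise_sd = 0,
                                      seed = NULL) {
  check_positive(dt, "dt")
  check_nonneg(dmfi_true, "dmfi_true")
  check_nonneg(latency_true, "latency_true")
  check_positive(duration, "duration")
  check_positive(baseline, "baseline")
  check_that(atp_peak_time > 0 && atp_peak_time < duration, "atp_peak_time",
             "must lie inside the trace")

  with_seed(seed, {
    tvec <- seq(0, duration, by = dt)
    dtime <- tvec - atp_peak_time
    atp <- atp_peak_dff * ifelse(dtime <= 0, exp(dtime / atp_rise_tau),
                                 exp(-dtime / atp_decay_tau))
    mg <- rep(baseline, length(tvec))
    if (isTRUE(directed) && dmfi_true > 0) {
      t0 <- atp_peak_time + latency_true
      ramp <- ifelse(tvec <= t0, 0, 1 - exp(-(tvec - t0) / rise_tau))
      mg <- baseline * (1 + dmfi_true / 100 * ramp)
    }
    if (noise_sd > 0) {
      atp <- atp + rnorm(length(tvec), 0, noise_sd * atp_peak_dff / 10)
      mg <- mg + rnorm(length(tvec), 0, noise_sd)
    }
    list(
      pair = recruitment_pair(atp, mg, dt, atp_peak_time),
      truth = tibble(directed = isTRUE(directed), dmfi_true = dmfi_true,
                     latency_true = latency_true)
    )
  })
}
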