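#' LFP recording container
#'
#' A uniformly sampled single-channel voltage trace with its sampling rate,
#' the carrier of the sharp wave-ripple pipeline.
#'
#' @param samples Numeric vector of voltages (uV).
#' @param fs Sampling rate in Hz.
#' @param channel_id Optional channel label.
#' @return An object of class `lfp_recording` (a list with elements
#'   `samples`, `fs`, `channel_id`).
#' @export
lfp_recording <- function(samples, fs, channel_id = "ch1") {
  check_positive(fs, "fs")
  check_that(is.numeric(samples) && length(samples) >= 2L &&
               !anyNA(samples), "samples",
             "must be a numeric vector of length >= 2 with no missing values")
  structure(list(samples = as.numeric(samples), fs = fs,
                 channel_id = as.character(channel_id)),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %s: %d samples @ %g Hz (%.1f s)\n",
              x$channel_id, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Time axis of a recording (seconds, first sample at t = 0).
#' @param x An [lfp_recording()].
#' @return Numeric vector of sample times in seconds.
#' @export
lfp_time <- function(x) {
  (seq_along(x$samples) - 1L) / x$fs
}

#' Simulate an LFP recording with embedded sharp wave-ripples
#'
#' Generates a 1/f-coloured ("pink") noise trace and embeds sharp-wave
#' deflections at Poisson-process times. Each sharp wave is a Gaussian
#' envelope of peak amplitude `swr_amplitude` carrying a ripple oscillation
#' at `ripple_freq` under the same envelope. By convention (CA3 stratum
#' pyramidale recordings) the sharp-wave deflection is negative; pass
#' `polarity = "positive"` for the opposite sign.
#'
#' The pink noise is produced by spectral shaping of white Gaussian noise
#' (amplitude proportional to \eqn{1/\sqrt{f}}) and rescaled to the requested
#' standard deviation, so the band filters downstream are stressed by a
#' realistic LFP-like spectrum.
#'
#' @param duration Recording length in seconds.
#' @param fs Sampling rate in Hz (default 10000, matching the acquisition
#'   rate the pipeline was designed for).
#' @param noise_sd Background noise standard deviation in uV.
#' @param event_rate Sharp-wave rate in events/s (Poisson).
#' @param swr_amplitude Peak sharp-wave amplitude in uV (unsigned magnitude).
#' @param swr_width Sharp-wave Gaussian envelope SD in seconds.
#' @param ripple_freq Ripple oscillation frequency in Hz.
#' @param ripple_amplitude Peak ripple amplitude in uV.
#' @param polarity `"negative"` (default) or `"positive"` sharp-wave sign.
#' @param noise_color `"pink"` (default, 1/f amplitude shaping) or
#'   `"white"`. Pink noise stresses the band filters with a realistic
#'   LFP-like spectrum; white noise emulates recordings whose power is
#'   spread across the band (most of it outside the 30 Hz sharp-wave band).
#' @param event_times Optional vector of event peak times in seconds; when
#'   given it overrides the Poisson process (useful for constructing
#'   recordings with an exact, known event count).
#' @param seed Integer seed; identical seed and parameters give identical
#'   output. `NULL` uses (and advances) the current RNG state.
#' @return A list with elements `recording` (an [lfp_recording()]) and
#'   `truth` (a tibble with one row per embedded event: `peak_time`,
#'   `amplitude`, `ripple_freq`, `ripple_amplitude`).
#' @examples
#' sim <- simulate_lfp(duration = 10, fs = 2000, event_rate = 0.5, seed = 1)
#' nrow(sim$truth)
#' @export
simulate_lfp <- function(duration, fs = 10000, noise_sd = 20,
                         event_rate = 0.5, swr_amplitude = 120,
                         swr_width = 0.02, ripple_freq = 200,
                         ripple_amplitude = 40,
                         polarity = c("negative", "positive"),
                         noise_color = c("pink", "white"),
                         event_times = NULL, seed = NULL) {
  polarity <- match.arg(polarity)
  noise_color <- match.arg(noise_color)
  check_positive(duration, "duration")
  check_positive(fs, "fs")
  check_nonneg(noise_sd, "noise_sd")
  check_nonneg(event_rate, "event_rate")
  check_nonneg(swr_amplitude, "swr_amplitude")
  check_positive(swr_width, "swr_width")
  check_positive(ripple_freq, "ripple_freq")
  check_nonneg(ripple_amplitude, "ripple_amplitude")
  check_that(fs > 2 * ripple_freq, "fs",
             "must exceed twice ripple_freq (Nyquist)")

  n <- round(duration * fs)
  with_seed(seed, {
    x <- if (noise_color == "pink") {
      pink_noise(n, noise_sd)
    } else if (noise_sd > 0) {
      rnorm(n, 0, noise_sd)
    } else {
      numeric(n)
    }

    # Poisson event times, kept clear of the edges so full envelopes fit
    margin <- 4 * swr_width
    if (is.null(event_times)) {
      n_events <- if (event_rate > 0 && duration > 2 * margin) {
        rpois(1L, duration * event_rate)
      } else {
        0L
      }
      if (swr_amplitude == 0 && ripple_amplitude == 0) n_events <- 0L
      times <- sort(runif(n_events, margin, duration - margin))
    } else {
      check_that(all(event_times >= margin & event_times <= duration - margin),
                 "event_times", "must lie inside the recording (with margin)")
      times <- sort(event_times)
      if (swr_amplitude == 0 && ripple_amplitude == 0) times <- numeric(0)
    }

    sign_sw <- if (polarity == "negative") -1 else 1
    t <- (seq_len(n) - 1L) / fs
    for (t0 in times) {
      idx <- which(abs(t - t0) <= margin)
      env <- exp(-(t[idx] - t0)^2 / (2 * swr_width^2))
      x[idx] <- x[idx] + sign_sw * swr_amplitude * env +
        ripple_amplitude * env * sin(2 * pi * ripple_freq * (t[idx] - t0))
    }

    list(
      recording = lfp_recording(x, fs),
      truth = tibble(
        peak_time = times,
        amplitude = rep(swr_amplitude, length(times)),
        ripple_freq = rep(ripple_freq, length(times)),
        ripple_amplitude = rep(ripple_amplitude, length(times))
      )
    )
  })
}

# 1/f-amplitude-shaped Gaussian noise with standard deviation `sd`.
pink_noise <- function(n, sd) {
  if (sd == 0) return(numeric(n))
  w <- rnorm(n)
  W <- fft(w)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)                       # symmetric frequency index
  shape <- ifelse(f == 0, 0, 1 / sqrt(f))
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}
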