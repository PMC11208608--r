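# Shared fixture builders (everything is generated in code at test time).

# Recording with an exact number of embedded sharp wave-ripples.
fixture_lfp <- function(n_events = 20, duration = 60, fs = 2000,
                        noise_sd = 20, swr_amplitude = 8 * noise_sd,
                        ripple_amplitude = 3 * noise_sd, seed = 42, ...) {
  times <- seq(2, duration - 2, length.out = n_events)
  simulate_lfp(duration = duration, fs = fs, noise_sd = noise_sd,
               swr_amplitude = swr_amplitude,
               ripple_amplitude = ripple_amplitude,
               event_times = times, seed = seed, ...)
}

# Two-sided exponential transient sampled at dt, peak at t_peak.
fixture_transient <- function(t, t_peak, peak, rise_tau, decay_tau) {
  dtime <- t - t_peak
  peak * ifelse(dtime <= 0, exp(dtime / rise_tau), exp(-dtime / decay_tau))
}

# Well-separated flash/surge feature table with known labels.
fixture_separated_features <- function(n_flash = 30, n_surge = 20,
                                       sep_log_sd = 4, log_sd = 0.25,
                                       seed = 1) {
  set.seed(seed)
  flash_mu <- log(0.25)
  surge_mu <- flash_mu + sep_log_sd * log_sd
  tibble::tibble(
    peak = exp(c(rnorm(n_flash, flash_mu, log_sd),
                 rnorm(n_surge, surge_mu, log_sd))),
    duration = exp(c(rnorm(n_flash, log(8), log_sd),
                     rnorm(n_surge, log(8) + sep_log_sd * log_sd, log_sd))),
    area = exp(c(rnorm(n_flash, log(25), log_sd),
                 rnorm(n_surge, log(25) + sep_log_sd * log_sd, log_sd))),
    true_label = rep(c("flash", "surge"), c(n_flash, n_surge))
  )
}

# All permutations of 1:n as a matrix (rows are permutations), for
# brute-force assignment oracles at small n.
build_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- build_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

# Blocky scene helpers for histology tests (1-based row/col rectangles).
blank_image <- function(h = 64, w = 64) matrix(0, h, w)

add_rect <- function(img, r0, r1, c0, c1, value = 1) {
  img[r0:r1, c0:c1] <- value
  img
}
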