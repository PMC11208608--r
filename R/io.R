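#' Read and write LFP recordings as delimited text
#'
#' Two-column tab-separated text with a header (`time_s`, `uv`); the
#' sampling rate is recovered from the time column on read.
#'
#' @param x An [lfp_recording()].
#' @param path File path.
#' @return `write_lfp` returns `path` invisibly; `read_lfp` returns an
#'   [lfp_recording()].
#' @export
write_lfp <- function(x, path) {
  stopifnot(inherits(x, "lfp_recording"))
  readr::write_tsv(tibble(time_s = lfp_time(x), uv = x$samples), path)
  invisible(path)
}

#' @rdname write_lfp
#' @export
read_lfp <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  check_that(all(c("time_s", "uv") %in% names(d)), "path",
             "file must have columns time_s and uv")
  fs <- 1 / median(diff(d$time_s))
  lfp_recording(d$uv, fs)
}

#' Read and write time-lapse stacks as multi-page TIFF with a JSON sidecar
#'
#' The movie is written as a multi-page 32-bit float TIFF (one page per
#' frame) and the acquisition metadata (`dt_s`, `pixel_size_um`) as a JSON
#' sidecar next to it.
#'
#' @param x A [timelapse_stack()].
#' @param path TIFF path; the sidecar is `paste0(path, ".json")`.
#' @param scale Intensities are divided by `scale` on write and multiplied
#'   back on read (TIFF float storage is unscaled by default).
#' @return `write_stack` returns `path` invisibly; `read_stack` a
#'   [timelapse_stack()].
#' @export
write_stack <- function(x, path, scale = 1) {
  stopifnot(inherits(x, "timelapse_stack"))
  pages <- purrr::map(seq_len(dim(x$frames)[1]),
                      function(k) x$frames[k, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(dt_s = x$dt, pixel_size_um = x$pixel_size, scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- array(0, dim = c(length(pages), dim(pages[[1]])[1],
                             dim(pages[[1]])[2]))
  for (k in seq_along(pages)) {
    frames[k, , ] <- pages[[k]] * (meta$scale %||% 1)
  }
  timelapse_stack(frames, meta$dt_s, meta$pixel_size_um)
}

#' Write detected events or any result table as CSV
#'
#' Thin wrapper kept for a uniform interface with the other writers.
#'
#' @param x A data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
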