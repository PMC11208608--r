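#' Depth-zone profile of cell positions across a slice cross-section
#'
#' Places a measuring grid over the entire slice thickness, dividing it into
#' `n_zones` equal zones (default seven), and counts cell bodies per zone.
#' Depths are measured from the top surface, increasing downward; zone 1 is
#' the top zone. Zone intervals are half-open `[lo, hi)` except the last,
#' which is closed, so boundary cells count exactly once. If a per-cell
#' `density` weight column is supplied (e.g. integrated process density),
#' its per-zone sum is reported as well.
#'
#' @param cells A data frame with a `depth_um` column (and optionally
#'   `density`).
#' @param slice_thickness Slice thickness in um.
#' @param n_zones Number of equal-width zones (default 7).
#' @return A tibble with one row per zone: `zone`, `lower_um`, `upper_um`,
#'   `count`, `percent` (summing to 100 when any cells exist), and
#'   `density` when weights were supplied.
#' @examples
#' cells <- tibble::tibble(depth_um = runif(700, 0, 300))
#' zone_profile(cells, slice_thickness = 300)
#' @export
zone_profile <- function(cells, slice_thickness, n_zones = 7) {
  check_positive(slice_thickness, "slice_thickness")
  check_count(n_zones, "n_zones", min = 1L)
  check_that(is.data.frame(cells) && "depth_um" %in% names(cells), "cells",
             "must be a data frame with a depth_um column")
  depths <- cells$depth_um
  bad <- which(depths < 0 | depths > slice_thickness)
  if (length(bad)) {
    abort(sprintf("cell %d lies outside [0, %g] um (depth %g)",
                  bad[1], slice_thickness, depths[bad[1]]),
          class = "sliceglia_validation_error")
  }

  edges <- seq(0, slice_thickness, length.out = n_zones + 1L)
  zone <- pmin(findInterval(depths, edges, rightmost.closed = TRUE), n_zones)
  counts <- tabulate(zone, nbins = n_zones)
  total <- length(depths)
  out <- tibble(
    zone = seq_len(n_zones),
    lower_um = edges[-length(edges)],
    upper_um = edges[-1],
    count = counts,
    percent = if (total) 100 * counts / total else rep(NA_real_, n_zones)
  )
  if ("density" %in% names(cells)) {
    dens <- vapply(seq_len(n_zones), function(z) {
      sum(cells$density[zone == z])
    }, numeric(1))
    out$density <- dens
  }
  out
}

#' Minimal-displacement transport between two depth distributions
#'
#' Given the depths of the same number of cells at two timepoints, sorts
#' both sets ascending and subtracts elementwise (t1 minus t0). This
#' monotone (sorted) matching is the assignment that minimises the total
#' absolute one-dimensional movement, so the resulting per-cell values are
#' the minimal distances cells had to travel to turn the first distribution
#' into the second. Negative values are displacement toward the top surface
#' (smaller depth).
#'
#' @param depths_t0,depths_t1 Numeric depth vectors (um, from the top
#'   surface), equal lengths.
#' @return A list with `per_cell` (tibble: `rank`, `depth_t0`, `depth_t1`,
#'   `displacement_um`), `total_abs_um`, `mean_abs_um`,
#'   `mean_signed_um` (negative = net movement toward the top).
#' @examples
#' minimal_displacement(c(1, 2, 3), c(2, 3, 4))
#' @export
minimal_displacement <- function(depths_t0, depths_t1) {
  check_that(length(depths_t0) == length(depths_t1), "depths_t1",
             "cell counts must be identical at the two timepoints")
  check_that(length(depths_t0) >= 1L, "depths_t0",
             "need at least one cell")
  s0 <- sort(depths_t0)
  s1 <- sort(depths_t1)
  d <- s1 - s0
  list(
    per_cell = tibble(rank = seq_along(d), depth_t0 = s0, depth_t1 = s1,
                      displacement_um = d),
    total_abs_um = sum(abs(d)),
    mean_abs_um = mean(abs(d)),
    mean_signed_um = mean(d)
  )
}

#' Percent area covered by a binary process mask
#'
#' @param mask A two-valued (logical or 0/1) matrix.
#' @return Percent of on-pixels, in `[0, 100]`.
#' @export
area_coverage <- function(mask) {
  check_that(length(mask) >= 1L, "mask", "must be non-empty")
  vals <- unique(as.vector(mask))
  check_that(all(vals %in% c(0, 1, TRUE, FALSE)), "mask",
             "must be binary (0/1 or logical)")
  100 * sum(mask != 0) / length(mask)
}

#' Simulate a depth-drifting cell population
#'
#' Cell depths at t0 are uniform across the slab; at t1 each cell has
#' drifted toward the top surface by `drift_to_top` um plus Gaussian noise,
#' clipped to the slab. Counts are conserved.
#'
#' @param n_cells Number of cells.
#' @param thickness Slice thickness in um (default 300).
#' @param drift_to_top Mean drift toward the top surface in um.
#' @param noise_sd Per-cell drift noise SD in um (default 5; 0 = pure
#'   shift).
#' @param seed Integer seed.
#' @return A list with `t0`, `t1` (tibbles with `cell_id`, `depth_um`) and
#'   `truth` (one-row tibble: `n_cells`, `drift_to_top`).
#' @export
simulate_cell_map <- function(n_cells, thickness = 300, drift_to_top = 30,
                              noise_sd = 5, seed = NULL) {
  check_count(n_cells, "n_cells", min = 1L)
  check_positive(thickness, "thickness")
  check_nonneg(drift_to_top, "drift_to_top")
  check_that(drift_to_top < thickness, "drift_to_top",
             "must be smaller than the slice thickness")
  check_nonneg(noise_sd, "noise_sd")
  with_seed(seed, {
    d0 <- runif(n_cells, 0, thickness)
    shift <- drift_to_top + if (noise_sd > 0) rnorm(n_cells, 0, noise_sd) else 0
    d1 <- pmin(pmax(d0 - shift, 0), thickness)
    list(
      t0 = tibble(cell_id = seq_len(n_cells), depth_um = d0),
      t1 = tibble(cell_id = seq_len(n_cells), depth_um = d1),
      truth = tibble(n_cells = n_cells, drift_to_top = drift_to_top)
    )
  })
}
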