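#' Registered multi-channel puncta scene
#'
#' Container for the registered presynaptic, postsynaptic and microglia
#' channels of a confocal plane, with the physical pixel size.
#'
#' @param pre_channel,post_channel,microglia_channel Numeric matrices (or
#'   binary masks) sharing dimensions; `microglia_channel` may be `NULL`.
#' @param pixel_size_nm Pixel size in nm/px (default 50).
#' @return An object of class `puncta_scene`.
#' @export
puncta_scene <- function(pre_channel, post_channel, microglia_channel = NULL,
                         pixel_size_nm = 50) {
  check_positive(pixel_size_nm, "pixel_size_nm")
  check_that(identical(dim(pre_channel), dim(post_channel)), "post_channel",
             "channels must share dimensions")
  if (!is.null(microglia_channel)) {
    check_that(identical(dim(pre_channel), dim(microglia_channel)),
               "microglia_channel", "channels must share dimensions")
  }
  structure(list(pre_channel = pre_channel, post_channel = post_channel,
                 microglia_channel = microglia_channel,
                 pixel_size_nm = pixel_size_nm),
            class = "puncta_scene")
}

#' @export
print.puncta_scene <- function(x, ...) {
  d <- dim(x$pre_channel)
  cat(sprintf("<puncta_scene> %d x %d px @ %g nm/px, microglia channel: %s\n",
              d[1], d[2], x$pixel_size_nm,
              if (is.null(x$microglia_channel)) "absent" else "present"))
  invisible(x)
}

#' Detect puncta in a single channel
#'
#' Reproduces the standard binary pipeline: automatic global (Otsu)
#' threshold, hole filling, one binary erosion step, connected-component
#' labelling, and a minimum-size filter. A blank (constant) image yields an
#' empty result rather than an error.
#'
#' @param channel Numeric matrix (intensities) or an already-binary mask.
#' @param min_size_px Minimum punctum size after erosion, px (default 4).
#' @param erode Apply the erosion step (default `TRUE`).
#' @return A list with `puncta` (tibble: `id`, `centroid_row`,
#'   `centroid_col`, `area_px`) and `labels` (integer matrix of punctum
#'   labels, 0 = background).
#' @export
detect_puncta <- function(channel, min_size_px = 4, erode = TRUE) {
  check_that(is.matrix(channel), "channel", "must be a single-channel matrix")
  rng <- range(channel)
  if (rng[1] == rng[2]) {
    return(list(puncta = tibble(id = integer(0), centroid_row = numeric(0),
                                centroid_col = numeric(0),
                                area_px = integer(0)),
                labels = matrix(0L, nrow(channel), ncol(channel))))
  }
  if (all(channel %in% c(0, 1))) {
    bin <- channel
  } else {
    norm <- (channel - rng[1]) / (rng[2] - rng[1])
    thr <- EBImage::otsu(EBImage::Image(norm))
    bin <- matrix(as.numeric(norm > thr), nrow(channel))
  }
  bin <- EBImage::fillHull(bin)
  if (erode) {
    bin <- EBImage::erode(bin, EBImage::makeBrush(3, shape = "box"))
  }
  labels <- EBImage::bwlabel(bin)
  labels <- matrix(as.integer(labels), nrow(channel))
  if (max(labels) == 0L) {
    return(list(puncta = tibble(id = integer(0), centroid_row = numeric(0),
                                centroid_col = numeric(0),
                                area_px = integer(0)),
                labels = labels))
  }
  sizes <- tabulate(labels[labels > 0], nbins = max(labels))
  keep <- which(sizes >= min_size_px)
  relabel <- integer(max(labels))
  relabel[keep] <- seq_along(keep)
  labels <- matrix(ifelse(labels > 0, relabel[pmax(labels, 1L)], 0L),
                   nrow(channel))
  if (!length(keep)) {
    return(list(puncta = tibble(id = integer(0), centroid_row = numeric(0),
                                centroid_col = numeric(0),
                                area_px = integer(0)),
                labels = labels))
  }
  pts <- which(labels > 0, arr.ind = TRUE)
  ids <- labels[pts]
  puncta <- tibble(id = ids, row = pts[, 1], col = pts[, 2]) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(centroid_row = mean(.data$row),
                     centroid_col = mean(.data$col),
                     area_px = dplyr::n(), .groups = "drop")
  list(puncta = puncta, labels = labels)
}

#' Identify synapses as touching pre/post punctum pairs
#'
#' A synapse is scored wherever a presynaptic punctum touches a
#' postsynaptic one: their masks overlap or are 8-adjacent. The synapse
#' footprint is the union of the two punctum masks.
#'
#' @param pre,post Results of [detect_puncta()] for the two channels.
#' @return A list with `synapses` (tibble: `synapse_id`, `pre_id`,
#'   `post_id`, `row`, `col` joint centroid) and `footprints` (list of
#'   logical masks).
#' @export
identify_synapses <- function(pre, post) {
  pre_lab <- pre$labels
  post_lab <- post$labels
  check_that(identical(dim(pre_lab), dim(post_lab)), "post",
             "channels must be registered (same dimensions)")
  if (!nrow(pre$puncta) || !nrow(post$puncta)) {
    return(list(synapses = tibble(synapse_id = integer(0),
                                  pre_id = integer(0), post_id = integer(0),
                                  row = numeric(0), col = numeric(0)),
                footprints = list()))
  }
  # 8-adjacency: dilate pre labels by a 3x3 box and look for overlap
  pre_dil <- EBImage::dilate(matrix(as.numeric(pre_lab > 0), nrow(pre_lab)),
                             EBImage::makeBrush(3, shape = "box"))
  touch <- pre_dil > 0 & post_lab > 0
  if (!any(touch)) {
    return(list(synapses = tibble(synapse_id = integer(0),
                                  pre_id = integer(0), post_id = integer(0),
                                  row = numeric(0), col = numeric(0)),
                footprints = list()))
  }
  # pair each touching post pixel with the nearest pre punctum label:
  # dilate the pre label image itself (grayscale dilation keeps max label)
  pre_lab_dil <- EBImage::dilate(pre_lab, EBImage::makeBrush(3, shape = "box"))
  pairs <- unique(cbind(pre_id = pre_lab_dil[touch],
                        post_id = post_lab[touch]))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0, , drop = FALSE]
  pairs <- unique(pairs)

  footprints <- vector("list", nrow(pairs))
  rows <- numeric(nrow(pairs))
  cols <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    fp <- pre_lab == pairs[i, 1] | post_lab == pairs[i, 2]
    footprints[[i]] <- fp
    pts <- which(fp, arr.ind = TRUE)
    rows[i] <- mean(pts[, 1])
    cols[i] <- mean(pts[, 2])
  }
  list(
    synapses = tibble(synapse_id = seq_len(nrow(pairs)),
                      pre_id = as.integer(pairs[, 1]),
                      post_id = as.integer(pairs[, 2]),
                      row = rows, col = cols),
    footprints = footprints
  )
}

#' Score microglial contact on identified synapses
#'
#' A synapse is considered contacted by microglia when a microglial process
#' lies closer than `max_dist_nm` (default 200 nm, i.e. 4 px at 50 nm/px)
#' to the synapse footprint. Distance is the Euclidean gap between mask
#' boundaries, computed by distance transform: the centre-to-centre distance
#' from the nearest footprint pixel to the nearest microglia pixel minus one
#' pixel (adjacent pixels have zero gap), clamped at zero for overlap. The
#' comparison is strictly less-than at the bound.
#'
#' @param synapses Result of [identify_synapses()].
#' @param microglia_mask Logical/0-1 matrix of the microglia channel (or an
#'   intensity image, thresholded via [detect_puncta()] machinery upstream).
#' @param pixel_size_nm Pixel size in nm/px.
#' @param max_dist_nm Contact distance bound in nm (default 200).
#' @return The `synapses` tibble with `min_dist_px`, `min_dist_nm` and
#'   logical `contacted` columns added.
#' @export
microglia_contact <- function(synapses, microglia_mask, pixel_size_nm = 50,
                              max_dist_nm = 200) {
  check_positive(pixel_size_nm, "pixel_size_nm")
  check_positive(max_dist_nm, "max_dist_nm")
  syn <- synapses$synapses
  if (!nrow(syn)) {
    syn$min_dist_px <- numeric(0)
    syn$min_dist_nm <- numeric(0)
    syn$contacted <- logical(0)
    return(syn)
  }
  mg <- microglia_mask != 0
  if (!any(mg)) {
    syn$min_dist_px <- Inf
    syn$min_dist_nm <- Inf
    syn$contacted <- FALSE
    return(syn)
  }
  # distance of every pixel centre to the nearest microglia pixel centre
  dt <- EBImage::distmap(matrix(as.numeric(!mg), nrow(microglia_mask)))
  gap <- vapply(synapses$footprints, function(fp) {
    max(min(dt[fp]) - 1, 0)
  }, numeric(1))
  syn$min_dist_px <- gap
  syn$min_dist_nm <- gap * pixel_size_nm
  syn$contacted <- syn$min_dist_nm < max_dist_nm
  syn
}

#' Systematic random subsample
#'
#' Deterministically ordered items are sampled by taking every k-th item
#' (`k = floor(count / n)`) from a seeded random start, the standard
#' systematic random sampling scheme for selecting an unbiased subset of
#' identified synapses.
#'
#' @param items A vector or data frame (rows are items).
#' @param n Subset size; must not exceed the item count.
#' @param seed Integer seed for the random start.
#' @return The selected items (same type as `items`), in order.
#' @export
systematic_random_subset <- function(items, n, seed = NULL) {
  count <- if (is.data.frame(items)) nrow(items) else length(items)
  check_count(n, "n", min = 1L)
  check_that(n <= count, "n", "cannot exceed the number of items")
  if (n == count) return(items)
  k <- floor(count / n)
  start <- with_seed(seed, sample.int(k, 1L))
  idx <- start + (seq_len(n) - 1L) * k
  if (is.data.frame(items)) items[idx, , drop = FALSE] else items[idx]
}

#' Integrated fluorescent density per ROI
#'
#' Sums pixel intensities within each rectangular ROI and reports the sum,
#' the ROI area and the mean.
#'
#' @param image Numeric matrix.
#' @param rois Data frame with columns `row`, `col` (top-left, 1-based),
#'   `height`, `width` in px.
#' @return A tibble with one row per ROI: `roi`, `integrated_density`,
#'   `area_px`, `mean_intensity`.
#' @export
synaptic_density <- function(image, rois) {
  check_that(is.matrix(image), "image", "must be a matrix")
  check_that(all(c("row", "col", "height", "width") %in% names(rois)),
             "rois", "must have columns row, col, height, width")
  ok <- rois$row >= 1 & rois$col >= 1 &
    rois$row + rois$height - 1 <= nrow(image) &
    rois$col + rois$width - 1 <= ncol(image)
  if (!all(ok)) {
    abort(sprintf("ROI %d lies outside the image", which(!ok)[1]),
          class = "sliceglia_validation_error")
  }
  purrr::map(seq_len(nrow(rois)), function(i) {
    sel <- image[rois$row[i]:(rois$row[i] + rois$height[i] - 1),
                 rois$col[i]:(rois$col[i] + rois$width[i] - 1)]
    tibble(roi = i, integrated_density = sum(sel),
           area_px = length(sel), mean_intensity = mean(sel))
  }) |> purrr::list_rbind()
}

#' Somatic contact prevalence and coverage
#'
#' For one neuronal soma reconstructed across serial sections: the surface
#' is the sum over sections of circumference times section thickness, the
#' microglia-covered surface is the sum of contact arc length times section
#' thickness, and the soma counts as contacted when any single contact arc
#' is at least `min_contact_um` long. A boundary point is in contact when a
#' microglial pixel lies at zero gap (overlap or 8-adjacency) from it.
#'
#' @param outlines List of per-section closed outlines, each a 2-column
#'   matrix of (row, col) pixel coordinates in order.
#' @param microglia_masks List of per-section logical microglia masks (same
#'   length as `outlines`), or `NULL` for no microglia.
#' @param pixel_size_um Pixel size in um/px.
#' @param section_thickness Section thickness in um.
#' @param min_contact_um Minimum contact arc length in um (default 0.5).
#' @param step_um Arc-length sampling step along the outline (default one
#'   pixel).
#' @return A one-row tibble: `surface_um2`, `covered_um2`,
#'   `coverage_percent`, `contacted`, `n_sections`,
#'   `max_contact_arc_um`.
#' @export
soma_metrics <- function(outlines, microglia_masks = NULL, pixel_size_um,
                         section_thickness, min_contact_um = 0.5,
                         step_um = NULL) {
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(section_thickness, "section_thickness")
  check_that(is.list(outlines) && length(outlines) >= 1L, "outlines",
             "must be a non-empty list of outline matrices")
  if (!is.null(microglia_masks)) {
    check_that(length(microglia_masks) == length(outlines),
               "microglia_masks", "must match outlines in length")
  }
  if (is.null(step_um)) step_um <- pixel_size_um

  surface <- 0
  covered <- 0
  max_arc <- 0
  for (s in seq_along(outlines)) {
    poly <- outlines[[s]]
    check_that(is.matrix(poly) && ncol(poly) == 2 && nrow(poly) >= 3,
               "outlines", "each outline needs >= 3 (row, col) points")
    check_that(all(poly[1, ] == poly[nrow(poly), ]) ||
                 sqrt(sum((poly[1, ] - poly[nrow(poly), ])^2)) <= 2,
               "outlines", "outline must be closed (ends meet)")
    # close explicitly
    if (!all(poly[1, ] == poly[nrow(poly), ])) {
      poly <- rbind(poly, poly[1, ])
    }
    seg <- diff(poly)
    seg_len <- sqrt(rowSums(seg^2)) * pixel_size_um
    circumference <- sum(seg_len)
    surface <- surface + circumference * section_thickness

    if (is.null(microglia_masks)) next
    mg <- microglia_masks[[s]] != 0
    if (!any(mg)) next
    dtm <- EBImage::distmap(matrix(as.numeric(!mg), nrow(mg)))

    # sample the outline at uniform arc length
    cum <- c(0, cumsum(seg_len))
    svals <- seq(0, circumference, by = step_um)
    pr <- stats::approx(cum, poly[, 1], xout = svals)$y
    pc <- stats::approx(cum, poly[, 2], xout = svals)$y
    ri <- pmin(pmax(round(pr), 1), nrow(dtm))
    ci <- pmin(pmax(round(pc), 1), ncol(dtm))
    # zero-gap adjacency: nearest microglia pixel centre within sqrt(2)
    in_contact <- dtm[cbind(ri, ci)] <= sqrt(2)

    # contiguous contact runs -> arc lengths (circular trace)
    r <- rle(in_contact)
    if (r$values[1] && r$values[length(r$values)] && length(r$values) > 1) {
      # merge the wrap-around run
      r$lengths[1] <- r$lengths[1] + r$lengths[length(r$values)]
      r$lengths <- r$lengths[-length(r$values)]
      r$values <- r$values[-length(r$values)]
    }
    arcs <- r$lengths[r$values] * step_um
    arcs <- pmin(arcs, circumference)
    covered <- covered + sum(arcs) * section_thickness
    if (length(arcs)) max_arc <- max(max_arc, max(arcs))
  }

  tibble(
    surface_um2 = surface,
    covered_um2 = covered,
    coverage_percent = 100 * covered / surface,
    contacted = max_arc >= min_contact_um,
    n_sections = length(outlines),
    max_contact_arc_um = max_arc
  )
}

#' Receptor labelling intensity per membrane length
#'
#' The delineated membrane outline is extended by `width_nm / 2` to each
#' side (default 250 + 250 nm, a 500 nm wide ribbon-shaped ROI), the
#' receptor-channel intensities are integrated within the ribbon, and the
#' integral is divided by the membrane length. A pixel belongs to the
#' ribbon when its centre lies within `width_nm / 2` perpendicular distance
#' of some polyline segment (no end caps beyond the polyline ends).
#'
#' @param polyline 2-column matrix of (row, col) pixel coordinates (>= 2
#'   points).
#' @param image Receptor-channel intensity matrix.
#' @param pixel_size_nm Pixel size in nm/px (default 50).
#' @param width_nm Full ribbon width in nm (default 500).
#' @return A one-row tibble: `integrated_density`, `length_um`,
#'   `ribbon_px`, `intensity_per_um` (integrated density / length in um)
#'   and `intensity_per_px_length` (integrated density / length in px).
#' @export
membrane_intensity <- function(polyline, image, pixel_size_nm = 50,
                               width_nm = 500) {
  check_that(is.matrix(polyline) && ncol(polyline) == 2 &&
               nrow(polyline) >= 2, "polyline",
             "must be a 2-column matrix with >= 2 points")
  check_positive(width_nm, "width_nm")
  check_positive(pixel_size_nm, "pixel_size_nm")
  half_px <- (width_nm / 2) / pixel_size_nm
  check_that(all(polyline[, 1] >= 1 - half_px &
                   polyline[, 1] <= nrow(image) + half_px &
                   polyline[, 2] >= 1 - half_px &
                   polyline[, 2] <= ncol(image) + half_px),
             "polyline", "ribbon lies outside the image")

  # candidate pixels: bounding box of the polyline padded by the half-width
  r0 <- max(1L, floor(min(polyline[, 1]) - half_px))
  r1 <- min(nrow(image), ceiling(max(polyline[, 1]) + half_px))
  c0 <- max(1L, floor(min(polyline[, 2]) - half_px))
  c1 <- min(ncol(image), ceiling(max(polyline[, 2]) + half_px))
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)

  in_ribbon <- rep(FALSE, length(rr))
  seg_len_px <- numeric(nrow(polyline) - 1L)
  for (i in seq_len(nrow(polyline) - 1L)) {
    a <- polyline[i, ]
    b <- polyline[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    seg_len_px[i] <- sqrt(len2)
    if (len2 == 0) next
    tproj <- ((rr - a[1]) * ab[1] + (cc - a[2]) * ab[2]) / len2
    inside <- tproj >= 0 & tproj <= 1
    perp2 <- (rr - a[1] - tproj * ab[1])^2 + (cc - a[2] - tproj * ab[2])^2
    in_ribbon <- in_ribbon | (inside & perp2 <= half_px^2)
  }

  total <- sum(image[cbind(rr[in_ribbon], cc[in_ribbon])])
  length_px <- sum(seg_len_px)
  length_um <- length_px * pixel_size_nm / 1000
  tibble(
    integrated_density = total,
    length_um = length_um,
    ribbon_px = sum(in_ribbon),
    intensity_per_um = total / length_um,
    intensity_per_px_length = total / length_px
  )
}
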