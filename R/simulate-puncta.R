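#' Simulate a pre/post/microglia puncta scene with known synapses
#'
#' Places `n_synapses` true synapses (a presynaptic and a postsynaptic
#' punctum drawn as bright disks whose masks overlap by a couple of pixels,
#' so they "touch") plus isolated orphan puncta in each channel at least
#' `orphan_gap_px` pixels away from any opposite-channel punctum. The
#' microglia channel contains `n_processes` thick line segments ("processes")
#' unless empty. Ground truth records each synapse's position and whether a
#' microglial process lies within the contact distance of its footprint
#' (computed from the generated geometry by distance transform).
#'
#' @param n_synapses Number of true synapses.
#' @param n_orphan_pre,n_orphan_post Numbers of isolated single-channel
#'   puncta.
#' @param n_processes Number of microglial process segments (0 = empty
#'   channel).
#' @param height,width Scene size in px (default 512 x 512, a 25.6 um field
#'   at 50 nm/px).
#' @param pixel_size_nm Pixel size in nm/px (default 50).
#' @param punctum_radius_px Punctum disk radius in px (default 4).
#' @param process_width_px Microglial process width in px (default 6).
#' @param orphan_gap_px Minimum separation of orphans from opposite-channel
#'   puncta, px (default 6).
#' @param contact_dist_nm Ground-truth contact distance in nm (default 200).
#' @param intensity Foreground intensity (default 200; background is
#'   Gaussian noise of SD ~5 around 10).
#' @param seed Integer seed.
#' @return A list with `scene` (a [puncta_scene()]) and `truth` (tibble:
#'   `synapse_id`, `row`, `col`, `contacted`).
#' @export
simulate_puncta_scene <- function(n_synapses, n_orphan_pre = 0,
                                  n_orphan_post = 0, n_processes = 3,
                                  height = 512, width = 512,
                                  pixel_size_nm = 50, punctum_radius_px = 4,
                                  process_width_px = 6, orphan_gap_px = 6,
                                  contact_dist_nm = 200, intensity = 200,
                                  seed = NULL) {
  check_count(n_synapses, "n_synapses")
  check_count(n_orphan_pre, "n_orphan_pre")
  check_count(n_orphan_post, "n_orphan_post")
  check_count(n_processes, "n_processes")
  check_positive(pixel_size_nm, "pixel_size_nm")

  r <- punctum_radius_px
  margin <- 4 * r + orphan_gap_px
  check_that(height > 2 * margin && width > 2 * margin, "height",
             "scene too small for the requested objects")

  with_seed(seed, {
    pre <- matrix(0, height, width)
    post <- matrix(0, height, width)
    mg <- matrix(0, height, width)

    draw_disk <- function(img, row, col, radius) {
      rr <- max(1, floor(row - radius)):min(height, ceiling(row + radius))
      cc <- max(1, floor(col - radius)):min(width, ceiling(col + radius))
      for (i in rr) {
        sel <- cc[(i - row)^2 + (cc - col)^2 <= radius^2]
        img[i, sel] <- 1
      }
      img
    }

    # rejection-sample well-separated centres
    centres <- matrix(numeric(0), 0, 2)
    place <- function(min_gap, tries = 2000) {
      for (k in seq_len(tries)) {
        p <- c(runif(1, margin, height - margin),
               runif(1, margin, width - margin))
        if (!nrow(centres) ||
            min(sqrt(rowSums(sweep(centres, 2, p)^2))) >= min_gap) {
          centres <<- rbind(centres, p)
          return(p)
        }
      }
      abort("scene too small to place requested objects without violating separation",
            class = "sliceglia_placement_error")
    }

    sep <- 4 * r + orphan_gap_px + 2
    syn <- matrix(numeric(0), 0, 2)
    for (i in seq_len(n_synapses)) {
      p <- place(sep)
      ang <- runif(1, 0, 2 * pi)
      # post centre offset so masks overlap by ~3 px (robust to erosion)
      off <- 2 * r - 3
      q <- p + off * c(cos(ang), sin(ang))
      pre <- draw_disk(pre, p[1], p[2], r)
      post <- draw_disk(post, q[1], q[2], r)
      syn <- rbind(syn, (p + q) / 2)
    }
    for (i in seq_len(n_orphan_pre)) {
      p <- place(sep)
      pre <- draw_disk(pre, p[1], p[2], r)
    }
    for (i in seq_len(n_orphan_post)) {
      p <- place(sep)
      post <- draw_disk(post, p[1], p[2], r)
    }

    if (n_processes > 0) {
      for (i in seq_len(n_processes)) {
        a <- c(runif(1, 1, height), runif(1, 1, width))
        ang <- runif(1, 0, 2 * pi)
        len <- runif(1, 0.3, 0.8) * min(height, width)
        b <- pmin(pmax(a + len * c(cos(ang), sin(ang)), 1),
                  c(height, width))
        # rasterize the thick segment
        npts <- ceiling(2 * sqrt(sum((b - a)^2)))
        ts <- seq(0, 1, length.out = max(npts, 2))
        for (tt in ts) {
          p <- a + tt * (b - a)
          mg <- draw_disk(mg, p[1], p[2], process_width_px / 2)
        }
      }
    }

    truth_contact <- rep(FALSE, n_synapses)
    if (n_synapses > 0 && any(mg > 0)) {
      dtm <- EBImage::distmap(matrix(as.numeric(mg == 0), height, width))
      both <- pre > 0 | post > 0
      lab <- EBImage::bwlabel(both)
      for (i in seq_len(n_synapses)) {
        l <- lab[round(syn[i, 1]), round(syn[i, 2])]
        if (l == 0) {
          # centre between the two disks may be off-mask; use nearest on-pixel
          pts <- which(both, arr.ind = TRUE)
          d2 <- (pts[, 1] - syn[i, 1])^2 + (pts[, 2] - syn[i, 2])^2
          l <- lab[pts[which.min(d2), , drop = FALSE]]
        }
        gap <- max(min(dtm[lab == l]) - 1, 0)
        truth_contact[i] <- gap * pixel_size_nm < contact_dist_nm
      }
    }

    noisify <- function(img) {
      intensity * img + 10 + matrix(rnorm(height * width, 0, 5),
                                    height, width)
    }
    list(
      scene = puncta_scene(noisify(pre), noisify(post),
                           if (n_processes > 0) noisify(mg) else
                             matrix(0, height, width),
                           pixel_size_nm),
      truth = tibble(
        synapse_id = seq_len(n_synapses),
        row = if (n_synapses) syn[, 1] else numeric(0),
        col = if (n_synapses) syn[, 2] else numeric(0),
        contacted = truth_contact
      )
    )
  })
}
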