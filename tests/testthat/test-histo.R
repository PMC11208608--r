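test_that("puncta detection handles blank, holey and synthetic inputs", {
  expect_identical(nrow(detect_puncta(blank_image())$puncta), 0L)

  # punctum with an interior hole becomes one filled component
  img <- add_rect(blank_image(), 10, 20, 10, 20, 200)
  img[14:16, 14:16] <- 0
  det <- detect_puncta(img + matrix(rnorm(64 * 64, 10, 2), 64))
  expect_identical(nrow(det$puncta), 1L)
  expect_gt(det$puncta$area_px, 80)       # hole was filled

  # synthetic scene: all 30 presynaptic puncta recovered
  sc <- simulate_puncta_scene(n_synapses = 15, n_orphan_pre = 15,
                              n_orphan_post = 0, n_processes = 0,
                              seed = 14)
  det_pre <- detect_puncta(sc$scene$pre_channel)
  expect_identical(nrow(det_pre$puncta), 30L)
})

test_that("synapses are scored where pre and post puncta touch", {
  # overlap by one pixel: a synapse
  pre <- detect_puncta(add_rect(blank_image(), 10, 14, 10, 14),
                       erode = FALSE)
  post <- detect_puncta(add_rect(blank_image(), 10, 14, 14, 18),
                        erode = FALSE)
  expect_identical(nrow(identify_synapses(pre, post)$synapses), 1L)

  # 8-adjacency (diagonal) counts as touching
  pre2 <- detect_puncta(add_rect(blank_image(), 10, 14, 10, 14),
                        erode = FALSE)
  post2 <- detect_puncta(add_rect(blank_image(), 15, 19, 15, 19),
                         erode = FALSE)
  expect_identical(nrow(identify_synapses(pre2, post2)$synapses), 1L)

  # separated by 3 px: not a synapse
  post3 <- detect_puncta(add_rect(blank_image(), 10, 14, 18, 22),
                         erode = FALSE)
  expect_identical(nrow(identify_synapses(pre, post3)$synapses), 0L)
})

test_that("the 200 nm microglial contact rule is exact on constructed gaps", {
  scene_with_gap <- function(gap_px) {
    pre <- detect_puncta(add_rect(blank_image(), 20, 24, 10, 14),
                         erode = FALSE)
    post <- detect_puncta(add_rect(blank_image(), 20, 24, 15, 19),
                          erode = FALSE)
    syn <- identify_synapses(pre, post)
    mg <- add_rect(blank_image(), 10, 40, 20 + gap_px, 30 + gap_px)
    microglia_contact(syn, mg, pixel_size_nm = 50, max_dist_nm = 200)
  }
  expect_true(scene_with_gap(3)$contacted)        # 150 nm away
  expect_false(scene_with_gap(4)$contacted)       # exactly 200 nm: not <
  expect_false(scene_with_gap(5)$contacted)       # 250 nm away
  expect_equal(scene_with_gap(3)$min_dist_nm, 150)
  expect_equal(scene_with_gap(5)$min_dist_nm, 250)

  # no microglia at all: infinite distance, never contacted
  pre <- detect_puncta(add_rect(blank_image(), 20, 24, 10, 14),
                       erode = FALSE)
  post <- detect_puncta(add_rect(blank_image(), 20, 24, 15, 19),
                        erode = FALSE)
  syn <- identify_synapses(pre, post)
  out <- microglia_contact(syn, blank_image())
  expect_false(out$contacted)
  expect_identical(out$min_dist_nm, Inf)
})

test_that("synapse/contact pipeline reaches 0.9 precision and recall on simulated scenes", {
  sc <- simulate_puncta_scene(n_synapses = 25, n_orphan_pre = 10,
                              n_orphan_post = 10, n_processes = 3,
                              seed = 77)
  pre <- detect_puncta(sc$scene$pre_channel)
  post <- detect_puncta(sc$scene$post_channel)
  syn <- identify_synapses(pre, post)
  mg_mask <- sc$scene$microglia_channel > 100
  rec <- microglia_contact(syn, mg_mask)

  match_dist <- 2 * 4 + 2                        # within a punctum diameter
  matched_truth <- vapply(seq_len(nrow(sc$truth)), function(i) {
    any(sqrt((rec$row - sc$truth$row[i])^2 +
               (rec$col - sc$truth$col[i])^2) <= match_dist)
  }, logical(1))
  matched_det <- vapply(seq_len(nrow(rec)), function(j) {
    any(sqrt((rec$row[j] - sc$truth$row)^2 +
               (rec$col[j] - sc$truth$col)^2) <= match_dist)
  }, logical(1))
  recall <- mean(matched_truth)
  precision <- mean(matched_det)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("systematic random subsets are strided and deterministic", {
  items <- seq_len(100)
  sub <- systematic_random_subset(items, 10, seed = 3)
  expect_identical(length(sub), 10L)
  expect_true(all(diff(sub) == 10))              # constant stride k = 10
  expect_identical(sub, systematic_random_subset(items, 10, seed = 3))
  expect_identical(systematic_random_subset(items, 100, seed = 1), items)
  expect_error(systematic_random_subset(items, 101, seed = 1), "exceed")

  df <- tibble::tibble(x = 1:30)
  expect_identical(nrow(systematic_random_subset(df, 6, seed = 2)), 6L)
})

test_that("integrated density sums intensities per ROI and is additive", {
  img <- matrix(0, 40, 40)
  expect_equal(
    synaptic_density(img, tibble::tibble(row = 1, col = 1, height = 10,
                                         width = 10))$integrated_density, 0)

  img2 <- matrix(3, 40, 40)
  d1 <- synaptic_density(img2, tibble::tibble(row = 5, col = 5,
                                              height = 10, width = 10))
  expect_equal(d1$integrated_density, 3 * 100)

  d2 <- synaptic_density(img2, tibble::tibble(row = 5, col = 5,
                                              height = 10, width = 20))
  expect_equal(d2$integrated_density, 2 * d1$integrated_density)

  expect_error(
    synaptic_density(img2, tibble::tibble(row = 35, col = 35, height = 10,
                                          width = 10)), "outside")
})

test_that("soma surface, coverage and the 0.5 um contact rule", {
  expect_identical(formals(soma_metrics)$min_contact_um, 0.5)

  square <- rbind(c(20, 20), c(20, 120), c(120, 120), c(120, 20),
                  c(20, 20))
  outlines <- list(square, square, square)
  # one of three equal sections fully wrapped: coverage 33.3%
  full <- matrix(TRUE, 140, 140)
  none <- matrix(FALSE, 140, 140)
  m <- soma_metrics(outlines, list(full, none, none), pixel_size_um = 0.1,
                    section_thickness = 0.3)
  expect_equal(m$coverage_percent, 100 / 3, tolerance = 0.02)
  expect_true(m$contacted)

  # no microglia: zero coverage, not contacted
  m0 <- soma_metrics(outlines, NULL, pixel_size_um = 0.1,
                     section_thickness = 0.3)
  expect_equal(m0$coverage_percent, 0)
  expect_false(m0$contacted)

  # a contact arc shorter than 0.5 um does not flag the soma
  tiny <- matrix(FALSE, 140, 140)
  tiny[19:21, 60:61] <- TRUE                    # ~0.3 um along the top edge
  m1 <- soma_metrics(list(square), list(tiny), pixel_size_um = 0.1,
                     section_thickness = 0.3)
  expect_false(m1$contacted)
  expect_gt(m1$covered_um2, 0)

  # coverage is monotone under microglia dilation
  grown <- matrix(FALSE, 140, 140)
  grown[17:23, 50:72] <- TRUE
  m2 <- soma_metrics(list(square), list(grown), pixel_size_um = 0.1,
                     section_thickness = 0.3)
  expect_gte(m2$covered_um2, m1$covered_um2)
  expect_true(m2$coverage_percent >= 0 && m2$coverage_percent <= 100)

  expect_error(
    soma_metrics(list(rbind(c(1, 1), c(50, 80), c(90, 5))),
                 NULL, 0.1, 0.3), "closed")
})

test_that("membrane ribbon intensity per unit length", {
  expect_identical(formals(membrane_intensity)$width_nm, 500)

  img <- matrix(7, 80, 80)
  # horizontal membrane at a half-integer row: exact 10 px ribbon width
  line <- rbind(c(30.5, 10), c(30.5, 70))
  r <- membrane_intensity(line, img, pixel_size_nm = 50, width_nm = 500)
  # per length (px) = intensity * width(px); width = 500/50 = 10 px
  expect_equal(r$intensity_per_px_length, 7 * 10, tolerance = 0.05)

  # doubling the polyline length leaves the per-length value unchanged
  line2 <- rbind(c(30.5, 10), c(30.5, 40), c(30.5, 70))
  r2 <- membrane_intensity(line2, img, 50, 500)
  expect_equal(r2$intensity_per_um, r$intensity_per_um, tolerance = 0.05)

  # oblique membrane (incommensurate slope): within the 5% rasterisation
  # tolerance; at exactly 45 degrees perpendicular pixel distances
  # quantise at 1/sqrt(2) and the band systematically overcounts
  diag_line <- rbind(c(10, 10), c(32, 74))
  r3 <- membrane_intensity(diag_line, img, 50, 500)
  expect_equal(r3$intensity_per_px_length, 7 * 10, tolerance = 0.05)

  expect_error(membrane_intensity(rbind(c(200, 5), c(220, 9)), img, 50,
                                  500), "outside")
})
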