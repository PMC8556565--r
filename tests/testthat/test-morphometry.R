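test_that("axial scale corrects the air pitch by the refractive index", {
  expect_equal(round(axial_scale(3.42, 1.35), 2), 2.53)
  expect_equal(axial_scale(7, 1), 7)
  expect_equal(axial_scale(3.42, 1.38), 3.42 / 1.38, tolerance = 1e-12)
  expect_equal(round(axial_scale(3.42, 1.38), 3), 2.478)
  expect_error(axial_scale(-1, 1.35), "positive")
  expect_error(axial_scale(3.42, 0), "positive")
})

fake_seg <- function(depths, scale = 2) {
  b <- lapply(names(depths), function(nm)
    boundary_surface(depths[[nm]], nm))
  names(b) <- names(depths)
  structure(list(boundaries = b, axial_scale_um = scale,
                 onh = list(center = NULL, width_px = 0,
                            mask = matrix(FALSE, nrow(depths[[1]]),
                                          ncol(depths[[1]])))),
            class = "segmentation_result")
}

test_that("thickness maps subtract consecutive boundaries", {
  m <- matrix(10, 3, 4)
  seg <- fake_seg(list(vitreous_NFL = m, NFL_IPL = m, IPL_INL = m + 5,
                       OPL = m + 8, OS_anterior = m + 12,
                       RPE_posterior = m + 20), scale = 2)
  expect_equal(thickness_map(seg, "vitreous_NFL", "NFL_IPL"),
               matrix(0, 3, 4))
  expect_equal(thickness_map(seg, "NFL_IPL", "IPL_INL"), matrix(10, 3, 4))
  expect_error(thickness_map(seg, "OPL", "NFL_IPL"), "anterior")
  # NaN propagates
  seg$boundaries$OPL$depth[1, 1] <- NaN
  expect_true(is.nan(thickness_map(seg, "IPL_INL", "OPL")[1, 1]))
})

test_that("layer maps partition the total retina exactly", {
  ph <- noisefree_phantom()
  seg <- segment_retina(average_frames(ph$volume),
                        axial_scale_um = ph$volume$axial_scale_um)
  maps <- layer_thickness_maps(seg)
  stack <- maps$NFL + maps$IPL + maps$INL + maps$ORL
  expect_equal(stack, maps$total, tolerance = 1e-12)
  # noise-free NFL map equals the configured thickness (each bounding
  # surface is sub-pixel accurate, so the map stays within 2 px worst
  # case and 1 px on average)
  expect_lt(max(abs(maps$NFL - 15)), 2 * ph$volume$axial_scale_um)
  expect_lt(mean(abs(maps$NFL - 15)), 1 * ph$volume$axial_scale_um)
  # scaling linearity
  maps2 <- layer_thickness_maps(seg, scale_um = 2 * seg$axial_scale_um)
  expect_equal(maps2$total, 2 * maps$total, tolerance = 1e-12)
})

test_that("ROI placement maximizes clearance deterministically", {
  none <- matrix(FALSE, 41, 41)
  roi <- select_roi(none, NULL, radius_um = 5, lateral_scale_um = 1)
  expect_equal(roi$center_xy, c(21, 21))
  # masks covering everything except one disk
  excl <- matrix(TRUE, 41, 41)
  excl[disk_mask <- (row(excl) - 10)^2 + (col(excl) - 30)^2 <= 64] <- FALSE
  roi2 <- select_roi(excl, NULL, radius_um = 3, lateral_scale_um = 1)
  expect_equal(roi2$center_xy, c(10, 30))
  expect_error(select_roi(none, NULL, radius_um = 100,
                          lateral_scale_um = 1),
               "feasible")
})

test_that("ROI averaging counts only valid pixels", {
  m <- matrix(10, 40, 40)
  roi <- roi_spec(c(20, 20), radius_um = 6, lateral_scale_um = 1)
  r <- roi_thickness(m, roi)
  expect_equal(r$mean_um, 10)
  m2 <- m
  m2[, 20:40] <- 20  # half/half split through the centre
  r2 <- roi_thickness(m2, roi)
  # pixel-count oracle: enumerate the disk explicitly
  px <- expand.grid(r = 1:40, c = 1:40)
  px <- px[(px$r - 20)^2 + (px$c - 20)^2 <= 6^2, ]
  expected <- mean(ifelse(px$c >= 20, 20, 10))
  expect_equal(r2$mean_um, expected)
  expect_lt(abs(r2$mean_um - 15), 1)
  m3 <- m
  m3[18:22, 18:22] <- NaN
  r3 <- roi_thickness(m3, roi)
  expect_equal(r3$mean_um, 10)
  expect_equal(r3$n, r$n - 25)
  expect_error(roi_thickness(matrix(NaN, 40, 40), roi), "valid")
})

test_that("ONH band annuli are disjoint and error on overlap", {
  onh <- list(center = c(51, 51), width_px = 20)
  br <- band_rois(onh, band_um = 11, lateral_scale_um = 1,
                  fov_radius_px = 50, dim_bscan = 101, dim_aline = 101)
  expect_false(any(br$adjacent & br$distal))
  expect_true(any(br$adjacent) && any(br$distal))
  # radii: adjacent [10, 21], distal [39, 50]
  expect_equal(unname(br$radii_px),
               c(10, 21, 39, 50))
  expect_error(
    band_rois(list(center = c(51, 51), width_px = 60), band_um = 11,
              lateral_scale_um = 1, fov_radius_px = 50,
              dim_bscan = 101, dim_aline = 101),
    "overlap")
  expect_error(band_rois(list(center = NULL, width_px = 0),
                         dim_bscan = 10, dim_aline = 10),
               "ONH")
})

test_that("band difference tracks a radial thickness gradient", {
  # flat map: zero difference
  onh <- list(center = c(51, 51), width_px = 20)
  br <- band_rois(onh, band_um = 11, lateral_scale_um = 1,
                  fov_radius_px = 50, dim_bscan = 101, dim_aline = 101)
  flat <- matrix(200, 101, 101)
  bd <- band_difference(flat, br$adjacent, br$distal)
  expect_equal(bd$difference_um, 0)
  # radially increasing thickness: distal exceeds adjacent
  cfg <- phantom_config(n_alines = 96, n_bscans = 96, n_repeats = 2,
                        n_depth = 400, speckle_shape = Inf, noise_floor = 0,
                        radial_thickness_gain = 0.15, onh_radius_px = 8,
                        vessel_specs = NULL, seed = 6)
  ph <- make_phantom(cfg)
  tr <- ph$truth
  total <- (tr$boundaries$RPE_posterior - tr$boundaries$vitreous_NFL) *
    ph$volume$axial_scale_um
  br2 <- band_rois(list(center = tr$onh_center, width_px = tr$onh_width_px),
                   band_um = 55, lateral_scale_um =
                     ph$volume$lateral_scale_um,
                   dim_bscan = 96, dim_aline = 96)
  bd2 <- band_difference(total, br2$adjacent, br2$distal)
  expect_gt(bd2$difference_um, 0)
  nan <- matrix(NaN, 101, 101)
  expect_error(band_difference(nan, br$adjacent, br$distal), "adjacent")
})

test_that("thickness tables hold five layer rows per ROI", {
  ph <- noisefree_phantom()
  seg <- segment_retina(average_frames(ph$volume),
                        axial_scale_um = ph$volume$axial_scale_um)
  roi <- roi_spec(c(4, 32), radius_um = 30,
                  lateral_scale_um = ph$volume$lateral_scale_um)
  tab <- thickness_table(seg, list(central = roi), sample_id = "s1",
                         age_label = "P12")
  expect_equal(nrow(tab), 5L)
  expect_setequal(tab$layer, c("NFL", "IPL", "INL", "ORL", "total"))
  expect_true(all(tab$thickness_um > 0))
  parts <- tab$thickness_um[tab$layer != "total"]
  expect_equal(sum(parts), tab$thickness_um[tab$layer == "total"],
               tolerance = 1e-9)
})
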