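test_that("rectangular denoising behaves like a normalized box filter", {
  arr <- array(runif(1 * 20 * 15), c(1, 20, 15))
  expect_identical(denoise(arr, c(1, 1)), arr)
  cst <- array(3, c(2, 10, 8))
  expect_equal(denoise(cst, c(3, 3)), cst)
  imp <- array(0, c(1, 11, 11))
  imp[1, 6, 6] <- 1
  sm <- denoise(imp, c(3, 3))
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  expect_equal(sm[1, 5:7, 5:7], matrix(1 / 9, 3, 3), tolerance = 1e-12)
  expect_true(all(sm[1, -(5:7), ] == 0))
  expect_error(denoise(arr, c(2, 3)), "odd")
})

test_that("axial derivative matches finite-difference arithmetic", {
  ramp <- array(rep(2 * (1:30), times = 4), c(1, 30, 4))
  D <- axial_derivative(ramp)
  expect_equal(D[1, 2:29, ], matrix(2, 28, 4), tolerance = 1e-12)
  expect_true(all(axial_derivative(array(5, c(2, 10, 3))) == 0))
  # dual-window gradient preserves a ramp's slope too
  D4 <- axial_derivative(ramp, scale_px = 4)
  expect_equal(D4[1, 6:25, ], matrix(2, 20, 4), tolerance = 1e-12)
  step <- array(0, c(1, 40, 2))
  step[1, 21:40, ] <- 10
  for (w in c(1, 4)) {
    Ds <- axial_derivative(step, w)
    expect_equal(apply(matrix(Ds[1, , ], 40, 2), 2, which.max),
                 c(20L, 20L))
  }
  expect_error(axial_derivative(array(1, c(2, 1, 2))), "depth")
})

test_that("RPE detection takes the anterior argmax of intensity", {
  ph <- noisefree_phantom()
  st <- denoise(average_frames(ph$volume), c(3, 3))
  rpe <- detect_rpe(st)
  expect_true(all(abs(rpe$depth - truth_rpe_center(ph$truth)) <= 1))
  # explicit tie: two equal maxima, anterior one wins
  prof <- array(0, c(1, 30, 1))
  prof[1, c(10, 20), 1] <- 5
  expect_equal(detect_rpe(prof)$depth[1, 1], 10)
  # all-NaN A-line yields NaN
  prof[1, , 1] <- NaN
  expect_true(is.nan(detect_rpe(prof)$depth[1, 1]))
})

test_that("ONH geometry is recovered from the RPE-band disruption", {
  ph <- noisefree_phantom()  # no ONH
  st <- denoise(average_frames(ph$volume), c(3, 3))
  onh0 <- detect_onh(st, detect_rpe(st))
  expect_equal(onh0$width_px, 0)
  expect_false(any(onh0$mask))

  cfg <- phantom_config(n_alines = 128, n_bscans = 64, n_repeats = 2,
                        n_depth = 400, speckle_shape = Inf,
                        noise_floor = 0, onh_radius_px = 10,
                        vessel_specs = NULL, seed = 2)
  ph2 <- make_phantom(cfg)
  st2 <- denoise(average_frames(ph2$volume), c(3, 3))
  onh <- detect_onh(st2, detect_rpe(st2))
  expect_lt(abs(onh$width_px - 20), 2)
  expect_lt(max(abs(onh$center - ph2$truth$onh_center)), 2)
})

test_that("vitreous/NFL interface detection follows the surface", {
  ph <- noisefree_phantom()
  st <- denoise(average_frames(ph$volume), c(3, 3))
  D <- axial_derivative(st, 4)
  rpe <- correct_boundary(detect_rpe(st))
  v <- detect_vitreous_nfl(st, D, rpe, axial_scale_um = 2.53333)
  err <- v$depth - ph$truth$boundaries$vitreous_NFL
  expect_lt(mean(abs(err)), 1)
  expect_true(all(abs(err) <= 1.5))
  # window entirely anterior of the raster -> NaN
  shallow <- boundary_surface(matrix(10, 1, 4), "RPE_center")
  arr <- array(1, c(1, 50, 4))
  vn <- detect_vitreous_nfl(arr, axial_derivative(arr), shallow,
                            axial_scale_um = 2.53)
  expect_true(all(is.nan(vn$depth)))
})

test_that("OPL detection finds the weighted intensity peak", {
  ph <- noisefree_phantom()
  st <- denoise(average_frames(ph$volume), c(3, 3))
  rpe <- correct_boundary(detect_rpe(st))
  vn <- boundary_surface(ph$truth$boundaries$vitreous_NFL, "vitreous_NFL")
  opl <- detect_opl(st, vn, rpe)
  expect_lt(mean(abs(opl$depth - ph$truth$boundaries$OPL)), 1)
  expect_false(any(attr(opl, "low_confidence")))
  # an effectively flat window (huge Hann support, no distinct peak)
  # reduces to the unweighted argmax of intensity
  p_wide <- segmentation_params(hann_length_px = 1e6)
  opl_w <- detect_opl(st, vn, rpe, p_wide)
  manual <- matrix(NaN, 8, 64)
  for (b in 1:8) for (a in 1:64) {
    span <- rpe$depth[b, a] - vn$depth[b, a]
    l <- ceiling(vn$depth[b, a] + 0.25 * span)
    h <- floor(rpe$depth[b, a] - 4 - 2)
    manual[b, a] <- l + which.max(st[b, l:h, a]) - 1
  }
  expect_equal(opl_w$depth, manual)
})

test_that("flat outer retina sends the OPL to its prior, flagged", {
  cfg <- phantom_config(n_alines = 48, n_bscans = 4, n_repeats = 2,
                        n_depth = 400, speckle_shape = Inf, noise_floor = 0,
                        onh_radius_px = 0, vessel_specs = NULL,
                        reflectances = c(vitreous = 0.02, NFL = 1, IPL = 0.8,
                                         INL = 0.2, OPL = 0.2, ONL = 0.2,
                                         ISOS = 0.2, RPE_Bruch = 2,
                                         choroid = 0.3),
                        seed = 3)
  ph <- make_phantom(cfg)
  st <- denoise(average_frames(ph$volume), c(3, 3))
  rpe <- correct_boundary(detect_rpe(st))
  vn <- boundary_surface(ph$truth$boundaries$vitreous_NFL, "vitreous_NFL")
  opl <- detect_opl(st, vn, rpe)
  lc <- attr(opl, "low_confidence")
  expect_true(mean(lc) > 0.9)
  expected <- vn$depth + 0.5 * (rpe$depth - vn$depth)
  expect_true(all(abs(opl$depth[lc] - expected[lc]) <= 1))
})

test_that("gated derivative extrema find the remaining interfaces", {
  ph <- noisefree_phantom()
  tr <- ph$truth$boundaries
  st <- denoise(average_frames(ph$volume), c(3, 3))
  D <- axial_derivative(st, 4)
  vn <- boundary_surface(tr$vitreous_NFL, "vitreous_NFL")
  opl <- boundary_surface(tr$OPL, "OPL")
  rpe <- correct_boundary(detect_rpe(st))
  ii <- detect_ipl_inl(st, D, vn, opl)
  expect_lt(mean(abs(ii$depth - tr$IPL_INL)), 1)
  ni <- detect_nfl_ipl(st, D, vn, ii, axial_scale_um = 2.53333)
  expect_lt(mean(abs(ni$depth - tr$NFL_IPL)), 1)
  os <- detect_os(st, D, opl, rpe)
  expect_lt(mean(abs(os$depth - tr$OS_anterior)), 1)
  # single-pixel window returns that depth
  one <- array(0, c(1, 30, 1))
  D1 <- axial_derivative(one)
  r <- detect_ipl_inl(one, D1, boundary_surface(matrix(5, 1, 1), "v"),
                      boundary_surface(matrix(8, 1, 1), "o"))
  expect_equal(r$depth[1, 1], 7)
})

test_that("a vanishing NFL collapses its boundary onto the vitreous", {
  cfg <- phantom_config(n_alines = 48, n_bscans = 4, n_repeats = 2,
                        n_depth = 400, speckle_shape = Inf, noise_floor = 0,
                        onh_radius_px = 0, vessel_specs = NULL,
                        rolloff_decay = 1,
                        layer_thicknesses_um = c(NFL = 0.5, IPL = 55,
                                                 INL = 30, ORL = 100,
                                                 RPE_Bruch = 20),
                        seed = 3)
  ph <- make_phantom(cfg)
  st <- denoise(average_frames(ph$volume), c(3, 3))
  D <- axial_derivative(st, 4)
  vn <- boundary_surface(ph$truth$boundaries$vitreous_NFL, "vitreous_NFL")
  ii <- boundary_surface(ph$truth$boundaries$IPL_INL, "IPL_INL")
  ni <- detect_nfl_ipl(st, D, vn, ii, axial_scale_um = 2.53333)
  expect_true(all(abs(ni$depth - vn$depth) <= 2.5))
})

test_that("polynomial artifact correction replaces only outliers", {
  # fixed point: an order-2 surface survives an order-4 fit untouched
  x <- seq_len(64)
  quad <- outer(rep(1, 4), 100 + 0.01 * (x - 32)^2)
  s <- boundary_surface(quad, "test")
  expect_equal(correct_boundary(s)$depth, quad, tolerance = 1e-9)
  # uniform displacement is absorbed by the fit
  expect_equal(correct_boundary(boundary_surface(quad + 5, "t"))$depth,
               quad + 5, tolerance = 1e-9)
  # flat surface with one 20-px spike: the spike lands on the curve,
  # everything else is untouched
  flat <- matrix(50, 3, 64)
  flat[2, 30] <- 70
  cb <- correct_boundary(boundary_surface(flat, "t"))$depth
  expect_equal(cb[2, 30], 50, tolerance = 1e-9)
  expect_equal(cb[, -30], matrix(50, 3, 63))
  # NaN gaps fill from the fit
  gap <- outer(rep(1, 2), 80 + 0.1 * x)
  gap[1, 10] <- NaN
  cg <- correct_boundary(boundary_surface(gap, "t"))$depth
  expect_equal(cg[1, 10], 80 + 0.1 * 10, tolerance = 1e-9)
  # a B-scan with too few valid points inherits its neighbour's fit
  sparse <- outer(rep(1, 2), 80 + 0.1 * x)
  sparse[2, ] <- NaN
  sparse[2, 1:3] <- 80
  cs <- correct_boundary(boundary_surface(sparse, "t"))
  expect_equal(cs$depth[2, ], 80 + 0.1 * x, tolerance = 1e-9)
  expect_equal(attr(cs, "replaced_bscans"), 2L)
})

test_that("noise-free segmentation recovers every boundary within 1 px", {
  ph <- noisefree_phantom()
  seg <- segment_retina(average_frames(ph$volume),
                        axial_scale_um = ph$volume$axial_scale_um)
  for (nm in names(seg$boundaries)) {
    err <- seg$boundaries[[nm]]$depth - ph$truth$boundaries[[nm]]
    expect_true(all(abs(err) <= 1),
                label = sprintf("%s within 1 px everywhere", nm))
  }
})

test_that("segmentation is deterministic and axially equivariant", {
  ph <- noisefree_phantom()
  st <- average_frames(ph$volume)
  s1 <- segment_retina(st, axial_scale_um = 2.53333)
  s2 <- segment_retina(st, axial_scale_um = 2.53333)
  for (nm in names(s1$boundaries))
    expect_identical(s1$boundaries[[nm]]$depth, s2$boundaries[[nm]]$depth)
  # shift the whole volume 5 px posterior: boundaries follow exactly
  k <- 5
  shifted <- st
  shifted[, (k + 1):dim(st)[2], ] <- st[, 1:(dim(st)[2] - k), ]
  shifted[, 1:k, ] <- st[, rep(1, k), ]
  s3 <- segment_retina(shifted, axial_scale_um = 2.53333)
  for (nm in names(s1$boundaries)) {
    d <- s3$boundaries[[nm]]$depth - s1$boundaries[[nm]]$depth
    expect_true(all(abs(d - k) <= 1e-6),
                label = sprintf("%s shifts by k", nm))
  }
})

test_that("boundary ordering holds on randomized speckled phantoms", {
  for (seed in c(21, 22)) {
    cfg <- phantom_config(n_alines = 64, n_bscans = 16, n_repeats = 3,
                          n_depth = 400, onh_radius_px = 6, seed = seed)
    ph <- make_phantom(cfg)
    seg <- suppressWarnings(
      segment_retina(average_frames(ph$volume),
                     axial_scale_um = ph$volume$axial_scale_um))
    nm <- names(seg$boundaries)
    for (j in 2:length(nm)) {
      a <- seg$boundaries[[nm[j - 1]]]$depth
      b <- seg$boundaries[[nm[j]]]$depth
      ok <- is.finite(a) & is.finite(b)
      expect_true(all(b[ok] >= a[ok]))
    }
  }
})

test_that("ONH A-lines carry no boundary values", {
  cfg <- default_small_config(seed = 12)
  ph <- make_phantom(cfg)
  bg <- make_background(cfg)
  v <- correct_rolloff(subtract_background(ph$volume, bg),
                       cfg$rolloff_decay)
  seg <- suppressWarnings(
    segment_retina(average_frames(v), axial_scale_um = v$axial_scale_um))
  expect_gt(seg$onh$width_px, 0)
  for (nm in names(seg$boundaries))
    expect_true(all(is.nan(seg$boundaries[[nm]]$depth[seg$onh$mask])))
  expect_false(any(seg$valid_mask & seg$onh$mask))
})

test_that("an undetectable RPE is a hard failure with a diagnostic", {
  arr <- array(NaN, c(2, 60, 10))
  expect_error(segment_retina(arr, axial_scale_um = 2.53),
               "RPE undetectable")
})
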