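test_that("zero dispersion coefficients reduce to the plain transform", {
  f <- make_fringes(c(30, 90), 256)
  ref <- Mod(fft(unclass(f)))^2
  expect_equal(compensate_dispersion(f), ref, ignore_attr = TRUE)
})

test_that("matched compensation restores the point-spread width", {
  clean <- compensate_dispersion(make_fringes(60, 512))
  w0 <- oracle_fwhm(clean)
  set.seed(7)
  for (i in 1:4) {
    a2 <- runif(1, 1e-4, 8e-4)
    a3 <- runif(1, 0, 2e-6)
    fr <- make_fringes(60, 512, a2 = a2, a3 = a3)
    comp <- compensate_dispersion(fr, dispersion_coefficients(a2, a3))
    expect_lt(oracle_fwhm(comp) / w0, 1.05)
    # compensating with negated coefficients doubles the phase error
    wrong <- compensate_dispersion(fr, dispersion_coefficients(-a2, -a3))
    expect_gt(oracle_fwhm(wrong), oracle_fwhm(compensate_dispersion(fr)))
  }
})

test_that("background subtraction removes the mean depth profile", {
  d <- c(3, 2, 40, 8)
  set.seed(1)
  arr <- array(runif(prod(d), 1, 2), d)
  vol <- oct_volume(arr, 2.53, 6.25)
  expect_true(all(subtract_background(vol, vol)$data >= 0))
  # bg = vol leaves only within-profile fluctuation; identical profiles
  # cancel exactly when the volume itself is depth-profiled
  prof <- array(rep(1:40, each = 1), c(40, 1))
  flat <- oct_volume(aperm(array(prof, c(40, 3, 2, 8)), c(2, 3, 1, 4)),
                     2.53, 6.25)
  expect_equal(subtract_background(flat, flat)$data,
               array(0, dim(flat$data)))
  zero <- oct_volume(array(0, d), 2.53, 6.25)
  expect_equal(subtract_background(vol, zero)$data, arr)
  const <- oct_volume(array(1.5, d), 2.53, 6.25)
  expect_equal(subtract_background(vol, const)$data, pmax(arr - 1.5, 0))
  expect_error(subtract_background(vol, oct_volume(array(0, c(3, 2, 10, 8)),
                                                   2.53, 6.25)),
               "depth")
})

test_that("roll-off correction flattens an exponentially attenuated layer", {
  expect_identical(correct_rolloff(array(1, c(2, 5, 3)), 1),
                   array(1, c(2, 5, 3)))
  expect_error(correct_rolloff(array(1, c(2, 5, 3)), 0), "decay")
  # uniform slab with decay: corrected depth profile has ~zero slope
  cfg <- phantom_config(n_alines = 64, n_bscans = 8, n_repeats = 2,
                        n_depth = 300, rolloff_decay = 0.999,
                        noise_floor = 0, speckle_shape = 25,
                        onh_radius_px = 0, vessel_specs = NULL,
                        surface_curvature = c(60, 0, 0), seed = 4)
  ph <- make_phantom(cfg)
  zr <- 150:200  # inside the ORL (ONL region), a homogeneous band
  raw_prof <- apply(ph$volume$data[, 1, zr, ], 2, mean)
  cor <- correct_rolloff(ph$volume, 0.999)
  cor_prof <- apply(cor$data[, 1, zr, ], 2, mean)
  sl <- function(y) unname(coef(lm(y ~ seq_along(y)))[2])
  expect_lt(abs(sl(cor_prof)), 0.1 * abs(sl(raw_prof)))
  # correcting then re-applying the decay restores the original
  back <- cor$data * aperm(array(0.999^(seq_len(300) - 1),
                                 c(300, 8, 2, 64)), c(2, 3, 1, 4))
  expect_equal(back, ph$volume$data, tolerance = 1e-12)
})

test_that("registration recovers injected integer shifts exactly", {
  cfg <- phantom_config(n_alines = 64, n_bscans = 2, n_repeats = 2,
                        n_depth = 200, surface_curvature = c(60, 0, 8),
                        onh_radius_px = 0, seed = 5)
  base <- make_phantom(cfg)$volume$data[1, 1, , ]
  inj <- cbind(dz = c(0, 3, -3, 2, 0, -1), dx = c(0, 1, -2, 0, 3, -3))
  arr <- array(0, c(6, 1, 200, 64))
  for (b in 1:6) arr[b, 1, , ] <- circshift(base, inj[b, 1], inj[b, 2])
  reg <- register_bscans(oct_volume(arr, 2.53, 6.25))
  expect_equal(unname(reg$shifts), unname(inj))
  # translation equivariance: shifting the whole series shifts recoveries
  arr2 <- array(0, c(6, 1, 200, 64))
  for (b in 1:6) arr2[b, 1, , ] <- circshift(arr[b, 1, , ], 2, -1)
  reg2 <- register_bscans(oct_volume(arr2, 2.53, 6.25))
  expect_equal(unname(reg2$shifts), unname(inj))
})

test_that("degenerate registration inputs give zero shifts", {
  const <- oct_volume(array(1, c(3, 1, 50, 40)), 2.53, 6.25)
  expect_true(all(register_bscans(const)$shifts == 0))
  single <- oct_volume(array(runif(400), c(1, 2, 50, 4)), 2.53, 6.25)
  reg <- register_bscans(single)
  expect_equal(dim(reg$shifts), c(1L, 2L))
  expect_true(all(reg$shifts == 0))
  expect_identical(reg$registered$data, single$data)
})

test_that("identical B-scans register with zero shifts", {
  m <- matrix(runif(200 * 32), 200, 32)
  arr <- array(0, c(4, 1, 200, 32))
  for (b in 1:4) arr[b, 1, , ] <- m
  reg <- register_bscans(oct_volume(arr, 2.53, 6.25))
  expect_true(all(reg$shifts == 0))
})

test_that("frame averaging reduces speckle contrast by ~1/sqrt(n)", {
  one <- array(runif(24), c(2, 1, 4, 3))
  expect_equal(average_frames(oct_volume(one, 1, 1)), one[, 1, , ])
  rep5 <- array(0, c(2, 5, 4, 3))
  for (r in 1:5) rep5[, r, , ] <- one[, 1, , ]
  expect_equal(average_frames(oct_volume(rep5, 1, 1)), one[, 1, , ])
  cfg <- phantom_config(n_alines = 64, n_bscans = 6, n_repeats = 5,
                        n_depth = 300, frozen_speckle = FALSE,
                        noise_floor = 0, rolloff_decay = 1,
                        onh_radius_px = 0, vessel_specs = NULL,
                        surface_curvature = c(60, 0, 0), seed = 3)
  ph <- make_phantom(cfg)
  sel <- array(FALSE, c(6, 300, 64))
  for (b in 1:6) for (a in 1:64) {
    z1 <- ceiling(ph$truth$boundaries$NFL_IPL[b, a] + 1)
    z2 <- floor(ph$truth$boundaries$IPL_INL[b, a] - 1)
    sel[b, z1:z2, a] <- TRUE
  }
  av <- average_frames(ph$volume)
  f1 <- ph$volume$data[, 1, , ]
  contrast <- function(x) sd(x) / mean(x)
  ratio <- contrast(av[sel]) / contrast(f1[sel])
  expect_lt(abs(ratio / (1 / sqrt(5)) - 1), 0.10)
})

test_that("preprocessing preserves raster shape and nonnegativity", {
  ph <- noisefree_phantom()
  cfg <- noisefree_config()
  v1 <- subtract_background(ph$volume, make_background(cfg))
  expect_equal(dim(v1$data), dim(ph$volume$data))
  expect_true(all(v1$data >= 0))
  v2 <- correct_rolloff(v1, 0.999)
  expect_equal(dim(v2$data), dim(v1$data))
  expect_true(all(v2$data >= 0))
  st <- average_frames(v2)
  expect_equal(dim(st), dim(v2$data)[c(1, 3, 4)])
})
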