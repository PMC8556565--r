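# Shared fixtures, generated in code and memoized per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# Noise-free phantom: no speckle, no noise floor, no ONH, no vessels.
noisefree_config <- function(...) {
  phantom_config(n_alines = 64, n_bscans = 8, n_repeats = 2,
                 n_depth = 400, speckle_shape = Inf, noise_floor = 0,
                 onh_radius_px = 0, vessel_specs = NULL, seed = 1, ...)
}

noisefree_phantom <- function() memo("noisefree", {
  make_phantom(noisefree_config())
})

# Default-noise phantom at the working raster used across modules.
default_small_config <- function(seed = 3, ...) {
  phantom_config(n_alines = 128, n_bscans = 64, n_repeats = 5,
                 n_depth = 400, seed = seed, ...)
}

default_small_phantom <- function() memo("default_small", {
  make_phantom(default_small_config())
})

# Preprocessed structural volume of the default phantom.
default_structural <- function() memo("default_structural", {
  ph <- default_small_phantom()
  cfg <- default_small_config()
  v <- subtract_background(ph$volume, make_background(cfg))
  v <- correct_rolloff(v, cfg$rolloff_decay)
  average_frames(v)
})

default_segmentation <- function() memo("default_seg", {
  ph <- default_small_phantom()
  segment_retina(default_structural(),
                 axial_scale_um = ph$volume$axial_scale_um)
})

# Independent FWHM oracle (linear interpolation of half-max crossings).
oracle_fwhm <- function(y) {
  i <- which.max(y)
  h <- y[i] / 2
  l <- i
  while (l > 1 && y[l - 1] > h) l <- l - 1
  r <- i
  while (r < length(y) && y[r + 1] > h) r <- r + 1
  stopifnot(l > 1, r < length(y))
  xl <- (l - 1) + (h - y[l - 1]) / (y[l] - y[l - 1])
  xr <- r + (y[r] - h) / (y[r] - y[r + 1])
  xr - xl
}

oracle_dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Circular 2-D shift (content moves +dz rows, +dx cols).
circshift <- function(m, dz, dx) {
  m[((seq_len(nrow(m)) - 1 - dz) %% nrow(m)) + 1,
    ((seq_len(ncol(m)) - 1 - dx) %% ncol(m)) + 1]
}

truth_rpe_center <- function(truth) {
  (truth$rpe_anterior + truth$boundaries$RPE_posterior) / 2
}

# Per-boundary error of a segmentation against phantom truth, restricted
# to a logical keep-mask.
boundary_errors <- function(seg, truth, keep) {
  sapply(names(seg$boundaries), function(nm) {
    err <- (seg$boundaries[[nm]]$depth - truth$boundaries[[nm]])[keep]
    mean(abs(err))
  })
}

# Full-chain recovery study over several seeded phantoms at the working
# raster; memoized because several acceptance checks consume it.
recovery_study <- function(seeds = 101:105) {
  memo(paste0("study_", paste(seeds, collapse = "_")), {
    lapply(seeds, function(seed) run_recovery_seed(seed))
  })
}

run_recovery_seed <- function(seed) {
  cfg <- default_small_config(seed = seed)
  ph <- make_phantom(cfg)
  bg <- make_background(cfg)
  vol <- correct_rolloff(subtract_background(ph$volume, bg),
                         cfg$rolloff_decay)
  seg <- suppressWarnings(
    segment_retina(average_frames(vol),
                   axial_scale_um = vol$axial_scale_um))
  tr <- ph$truth
  sv <- speckle_variance(vol)
  mr <- motion_robust_variance(vol)
  loo_le_full <- all(vapply(seq_len(dim(sv$variance)[1]), function(b)
    mean(mr$variance[b, , ]) <= mean(sv$variance[b, , ]) + 1e-12,
    logical(1)))
  v0 <- median(seg$boundaries$vitreous_NFL$depth, na.rm = TRUE)
  ef <- enface_projection(mr$variance, c(floor(v0), ceiling(v0 + 8)))
  vm <- vessel_mask(ef)
  keep <- !tr$onh_mask & !tr$vessel_mask & seg$valid_mask
  mae <- boundary_errors(seg, tr, keep)
  roi <- select_roi(vm, seg$onh$mask, radius_um = 51,
                    lateral_scale_um = vol$lateral_scale_um)
  maps <- layer_thickness_maps(seg)
  th <- cfg$layer_thicknesses_um
  target <- c(NFL = th[["NFL"]], IPL = th[["IPL"]], INL = th[["INL"]],
              ORL = th[["ORL"]] + th[["RPE_Bruch"]],
              total = sum(th))
  th_err <- vapply(names(target), function(l)
    roi_thickness(maps[[l]], roi)$mean_um - target[[l]], numeric(1))
  list(seed = seed, mae_px = mae, thickness_err_um = th_err,
       dice = oracle_dice(vm$mask, tr$vessel_mask),
       onh_width_err_px = seg$onh$width_px - tr$onh_width_px,
       onh_center_err_px = max(abs(seg$onh$center - tr$onh_center)),
       onh_mask_clean = all(vapply(seg$boundaries, function(bb)
         all(is.nan(bb$depth[seg$onh$mask])), logical(1))),
       loo_le_full = loo_le_full,
       axial_scale_um = vol$axial_scale_um)
}
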