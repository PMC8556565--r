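#' Configuration for the synthetic retinal OCT phantom
#'
#' Describes a layered, curved retinal slab imaged as repeated B-scans
#' (BM-scans), with multiplicative gamma speckle, depth sensitivity
#' roll-off, an additive noise floor, superficial vessels with dynamic
#' speckle and shadowing, and an optic nerve head (ONH) modelled as a
#' quasi-cylindrical disruption of the RPE-Bruch band.
#'
#' The default raster matches the acquisition geometry of a developing-mouse
#' retinal protocol: 512 BM-scan positions, 5 repeated B-scans of 512
#' A-lines each, with a native axial pitch of 3.42 um/px in air corrected by
#' a tissue refractive index of 1.35. Layer thicknesses default to values
#' typical of the maturing mouse retina (NFL 15, IPL 55, INL 30, ORL 100,
#' RPE-Bruch 20 um). Reflectances follow the canonical contrast ordering:
#' hyper-reflective NFL/IPL/OPL/IS-OS and brightest RPE-Bruch band,
#' hypo-reflective nuclear layers (INL, ONL).
#'
#' @param n_alines,n_bscans,n_repeats,n_depth raster dimensions.
#' @param axial_scale_air_um native axial pitch in air, um/pixel.
#' @param refractive_index tissue group refractive index; the in-tissue
#'   axial pitch is `axial_scale_air_um / refractive_index`.
#' @param fov_width_um lateral field-of-view width; the lateral pitch is
#'   `fov_width_um / n_alines`.
#' @param layer_thicknesses_um named vector with entries NFL, IPL, INL,
#'   ORL, RPE_Bruch (um). ORL is the composite OPL + ONL + IS/OS.
#' @param isos_um thickness of the IS/OS portion at the posterior end of
#'   the ORL (um); must be smaller than the ORL thickness.
#' @param opl_band_um width of the bright OPL band centred on the INL/ONL
#'   boundary (um).
#' @param surface_curvature polynomial coefficients (intercept first, in
#'   depth pixels) of the vitreous/NFL surface as a function of normalized
#'   en-face radius u in [0, 1] (u = 1 at half the larger lateral extent).
#' @param radial_thickness_gain fractional thickness increase per unit u;
#'   0 gives laterally uniform layers.
#' @param reflectances named vector of relative mean linear intensities:
#'   vitreous, NFL, IPL, INL, OPL, ONL, ISOS, RPE_Bruch, choroid.
#'   RPE_Bruch must be the strict maximum; INL and ONL must be below IPL.
#' @param speckle_shape gamma shape parameter of the multiplicative
#'   speckle (mean 1, contrast `1/sqrt(shape)`); `Inf` disables speckle.
#' @param frozen_speckle if `TRUE` (default) static tissue shares one
#'   speckle draw across repeats and only vessels decorrelate; if `FALSE`
#'   every frame redraws the speckle everywhere.
#' @param rolloff_decay per-pixel depth attenuation factor in (0, 1].
#' @param noise_floor mean of the additive exponential background noise.
#' @param onh_center_xy ONH centre as (bscan, aline) pixels, or `NULL` for
#'   the field centre; `onh_radius_px = 0` removes the ONH.
#' @param onh_radius_px ONH radius, lateral pixels.
#' @param onh_suppression multiplicative attenuation of the RPE-Bruch band
#'   inside the ONH (the disruption the detector looks for).
#' @param vessel_specs list of vessel descriptors, each a list with
#'   `center` (bscan, aline), `radius_px`, `depth_offset_px` (below the
#'   vitreous/NFL surface), `angle_deg` and `length_px` (a straight tube;
#'   `length_px = 0` gives a disk), and `gain` scaling the dynamic speckle
#'   excursion. `"auto"` places four radial vessels just outside the ONH.
#' @param shadow_atten attenuation applied beneath vessels (shadowing).
#' @param seed integer RNG seed; identical configs and seeds reproduce the
#'   phantom bit for bit.
#' @return a validated list of class `phantom_config`.
#' @seealso [make_phantom()], [make_background()], [make_fringes()]
#' @export
phantom_config <- function(n_alines = 512L, n_bscans = 512L,
                           n_repeats = 5L, n_depth = 400L,
                           axial_scale_air_um = 3.42,
                           refractive_index = 1.35,
                           fov_width_um = 800,
                           layer_thicknesses_um = c(
                             NFL = 15, IPL = 55, INL = 30,
                             ORL = 100, RPE_Bruch = 20),
                           isos_um = 40,
                           opl_band_um = 15,
                           surface_curvature = c(80, 0, 10),
                           radial_thickness_gain = 0,
                           reflectances = c(
                             vitreous = 0.02, NFL = 1.0, IPL = 0.8,
                             INL = 0.2, OPL = 0.7, ONL = 0.2,
                             ISOS = 0.55, RPE_Bruch = 2.0,
                             choroid = 0.3),
                           speckle_shape = 4,
                           frozen_speckle = TRUE,
                           rolloff_decay = 0.999,
                           noise_floor = 0.01,
                           onh_center_xy = NULL,
                           onh_radius_px = 10,
                           onh_suppression = 0.1,
                           vessel_specs = "auto",
                           shadow_atten = 0.7,
                           seed = 1L) {
  cfg <- list(n_alines = as.integer(n_alines),
              n_bscans = as.integer(n_bscans),
              n_repeats = as.integer(n_repeats),
              n_depth = as.integer(n_depth),
              axial_scale_air_um = axial_scale_air_um,
              refractive_index = refractive_index,
              fov_width_um = fov_width_um,
              layer_thicknesses_um = layer_thicknesses_um,
              isos_um = isos_um, opl_band_um = opl_band_um,
              surface_curvature = surface_curvature,
              radial_thickness_gain = radial_thickness_gain,
              reflectances = reflectances,
              speckle_shape = speckle_shape,
              frozen_speckle = isTRUE(frozen_speckle),
              rolloff_decay = rolloff_decay,
              noise_floor = noise_floor,
              onh_center_xy = onh_center_xy,
              onh_radius_px = onh_radius_px,
              onh_suppression = onh_suppression,
              vessel_specs = vessel_specs,
              shadow_atten = shadow_atten,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  th <- cfg$layer_thicknesses_um
  need <- c("NFL", "IPL", "INL", "ORL", "RPE_Bruch")
  if (!all(need %in% names(th)))
    stop("layer_thicknesses_um must name ", paste(need, collapse = ", "))
  if (any(th[need] <= 0)) stop("all layer thicknesses must be > 0")
  if (cfg$isos_um <= 0 || cfg$isos_um >= th[["ORL"]])
    stop("isos_um must lie strictly inside the ORL thickness")
  rf <- cfg$reflectances
  neede <- c("vitreous", "NFL", "IPL", "INL", "OPL", "ONL", "ISOS",
             "RPE_Bruch", "choroid")
  if (!all(neede %in% names(rf)))
    stop("reflectances must name ", paste(neede, collapse = ", "))
  others <- rf[setdiff(neede, "RPE_Bruch")]
  if (!all(rf[["RPE_Bruch"]] > others))
    stop("RPE_Bruch reflectance must be the strict maximum")
  if (rf[["INL"]] >= rf[["IPL"]] || rf[["ONL"]] >= rf[["IPL"]])
    stop("nuclear layers (INL, ONL) must be hypo-reflective relative to IPL")
  if (cfg$n_repeats < 2L)
    stop("n_repeats must be >= 2 (speckle variance needs repeated frames)")
  if (cfg$rolloff_decay <= 0 || cfg$rolloff_decay > 1)
    stop("rolloff_decay must be in (0, 1]")
  if (cfg$speckle_shape <= 0) stop("speckle_shape must be > 0")
  if (cfg$noise_floor < 0) stop("noise_floor must be >= 0")
  s <- cfg$axial_scale_air_um / cfg$refractive_index
  total_px <- sum(th[need]) * (1 + max(0, cfg$radial_thickness_gain)) / s
  apex <- polyval_u(cfg$surface_curvature, c(0, 0.5, 1, 1.2))
  if (max(apex) + total_px + 2 > cfg$n_depth)
    stop("configured layer thicknesses exceed the axial raster depth")
  if (min(apex) < 1) stop("surface curvature rises above the raster")
  invisible(cfg)
}

# Evaluate polynomial coefficients (intercept first) at u.
polyval_u <- function(coefs, u) {
  out <- 0
  for (i in rev(seq_along(coefs))) out <- out * u + coefs[i]
  out
}

# En-face normalized radius and boundary depth maps for a config.
phantom_geometry <- function(cfg) {
  nb <- cfg$n_bscans; na <- cfg$n_alines
  ctr <- c((nb + 1) / 2, (na + 1) / 2)
  b <- matrix(seq_len(nb), nb, na)
  a <- matrix(seq_len(na), nb, na, byrow = TRUE)
  u <- sqrt((b - ctr[1])^2 + (a - ctr[2])^2) / (max(nb, na) / 2)
  s <- cfg$axial_scale_air_um / cfg$refractive_index
  th <- cfg$layer_thicknesses_um
  mult <- 1 + cfg$radial_thickness_gain * u
  z0 <- polyval_u(cfg$surface_curvature, u)
  z1 <- z0 + th[["NFL"]] * mult / s
  z2 <- z1 + th[["IPL"]] * mult / s
  z3 <- z2 + th[["INL"]] * mult / s
  zos <- z3 + (th[["ORL"]] - cfg$isos_um) * mult / s
  z4 <- z3 + th[["ORL"]] * mult / s
  z5 <- z4 + th[["RPE_Bruch"]] * mult / s
  list(center = ctr, u = u, axial_scale_um = s,
       lateral_scale_um = cfg$fov_width_um / cfg$n_alines,
       boundaries = list(vitreous_NFL = z0, NFL_IPL = z1, IPL_INL = z2,
                         OPL = z3, OS_anterior = zos, RPE_posterior = z5),
       rpe_anterior = z4)
}

default_vessels <- function(cfg, ctr) {
  r0 <- max(cfg$onh_radius_px, 4) + 2
  rmax <- min(cfg$n_bscans, cfg$n_alines) / 2 - 2
  lapply(c(30, 120, 210, 300), function(ang) {
    rad <- ang * pi / 180
    mid <- (r0 + rmax) / 2
    list(center = c(ctr[1] + mid * cos(rad), ctr[2] + mid * sin(rad)),
         radius_px = 2.5, depth_offset_px = 4,
         angle_deg = ang, length_px = rmax - r0, gain = 1)
  })
}

# En-face footprint, centre depth offset and half-depth extent of vessels.
vessel_fields <- function(cfg, geom) {
  nb <- cfg$n_bscans; na <- cfg$n_alines
  foot <- matrix(FALSE, nb, na)
  half <- matrix(0, nb, na)       # axial half-extent of the tube
  doff <- matrix(0, nb, na)       # centreline depth below the surface
  gain <- matrix(1, nb, na)
  specs <- cfg$vessel_specs
  if (identical(specs, "auto")) specs <- default_vessels(cfg, geom$center)
  if (is.null(specs) || length(specs) == 0L)
    return(list(foot = foot, half = half, doff = doff, gain = gain,
                specs = list()))
  b <- matrix(seq_len(nb), nb, na)
  a <- matrix(seq_len(na), nb, na, byrow = TRUE)
  for (v in specs) {
    ang <- (if (is.null(v$angle_deg)) 0 else v$angle_deg) * pi / 180
    len <- if (is.null(v$length_px)) 0 else v$length_px
    # distance to the segment centred at v$center along direction ang
    db <- b - v$center[1]; da <- a - v$center[2]
    t <- db * cos(ang) + da * sin(ang)
    t <- pmin(pmax(t, -len / 2), len / 2)
    d2 <- (db - t * cos(ang))^2 + (da - t * sin(ang))^2
    inside <- d2 <= v$radius_px^2
    foot <- foot | inside
    h <- sqrt(pmax(v$radius_px^2 - d2, 0))
    sel <- inside & (h >= half)
    half[sel] <- h[sel]
    doff[sel] <- v$depth_offset_px
    g <- if (is.null(v$gain)) 1 else v$gain
    gain[sel] <- g
  }
  list(foot = foot, half = half, doff = doff, gain = gain, specs = specs)
}

#' Generate a synthetic OCT BM-scan volume with known ground truth
#'
#' Builds the noise-free layered reflectance structure described by the
#' configuration, applies depth roll-off, multiplicative gamma speckle
#' (frozen across repeats for static tissue, redrawn per frame inside
#' vessels), vessel shadowing, ONH suppression of the RPE-Bruch band, and
#' an additive exponential noise floor.
#'
#' @param config a [phantom_config()].
#' @return list with elements `volume` (an [oct_volume()]) and `truth`
#'   (class `phantom_truth`: named boundary depth maps in 1-based float
#'   pixels, en-face `vessel_mask` and `onh_mask`, `onh_width_px`, and the
#'   noise-free `signal` array).
#' @examples
#' cfg <- phantom_config(n_alines = 32, n_bscans = 8, n_repeats = 2,
#'                       n_depth = 160, onh_radius_px = 0,
#'                       vessel_specs = NULL, seed = 7)
#' ph <- make_phantom(cfg)
#' dim(ph$volume$data)
#' @export
make_phantom <- function(config) {
  cfg <- validate_phantom_config(config)
  geom <- phantom_geometry(cfg)
  nb <- cfg$n_bscans; na <- cfg$n_alines
  nz <- cfg$n_depth; nr <- cfg$n_repeats
  bnd <- geom$boundaries
  rf <- cfg$reflectances
  s <- geom$axial_scale_um

  onh_mask <- if (cfg$onh_radius_px > 0) {
    ctr <- if (is.null(cfg$onh_center_xy)) geom$center else cfg$onh_center_xy
    disk_mask(nb, na, ctr, cfg$onh_radius_px)
  } else matrix(FALSE, nb, na)
  ves <- vessel_fields(cfg, geom)

  wopl <- cfg$opl_band_um / s
  wrpe <- cfg$layer_thicknesses_um[["RPE_Bruch"]] / s
  z <- seq_len(nz)
  rolloff <- cfg$rolloff_decay^(z - 1)

  sig <- array(0, c(nb, nz, na))
  vmask <- array(FALSE, c(nb, nz, na))
  shade <- array(1, c(nb, nz, na))
  for (b in seq_len(nb)) {
    zm <- matrix(z, nz, na)
    up <- function(m) matrix(m[b, ], nz, na, byrow = TRUE)
    z0 <- up(bnd$vitreous_NFL); z1 <- up(bnd$NFL_IPL)
    z2 <- up(bnd$IPL_INL);      z3 <- up(bnd$OPL)
    zo <- up(bnd$OS_anterior);  z4 <- up(geom$rpe_anterior)
    z5 <- up(bnd$RPE_posterior)
    base <- matrix(rf[["vitreous"]], nz, na)
    base[zm >= z0 & zm < z1] <- rf[["NFL"]]
    base[zm >= z1 & zm < z2] <- rf[["IPL"]]
    base[zm >= z2 & zm < z3] <- rf[["INL"]]
    base[zm >= z3 & zm < zo] <- rf[["ONL"]]
    base[zm >= zo & zm < z4] <- rf[["ISOS"]]
    base[zm >= z4]           <- rf[["choroid"]]
    # bright OPL band: raised-cosine bump peaking on the INL/ONL boundary
    du <- (zm - z3) / wopl
    bump <- ifelse(abs(du) < 0.5, rf[["OPL"]] * cos(pi * du)^2, 0)
    base <- pmax(base, bump)
    # RPE-Bruch band, suppressed inside the ONH (quasi-cylindrical: the
    # same attenuation at every depth of the band)
    amp <- rf[["RPE_Bruch"]] *
      ifelse(matrix(onh_mask[b, ], nz, na, byrow = TRUE),
             cfg$onh_suppression, 1)
    du <- (zm - (z4 + z5) / 2) / wrpe
    bump <- ifelse(abs(du) < 0.5, amp * cos(pi * du)^2, 0)
    base <- pmax(base, bump)
    # vessels: tube voxels and the shadow column beneath them
    fb <- matrix(ves$foot[b, ], nz, na, byrow = TRUE)
    if (any(fb)) {
      vc <- z0 + matrix(ves$doff[b, ], nz, na, byrow = TRUE)
      vh <- matrix(ves$half[b, ], nz, na, byrow = TRUE)
      vmask[b, , ] <- fb & abs(zm - vc) <= vh
      shade[b, , ] <- ifelse(fb & zm > vc + vh, cfg$shadow_atten, 1)
    }
    sig[b, , ] <- base * rolloff
  }
  sig <- sig * shade

  set.seed(cfg$seed)
  vol <- array(0, c(nb, nr, nz, na))
  nvox <- length(sig)
  finite_shape <- is.finite(cfg$speckle_shape)
  static <- if (finite_shape && cfg$frozen_speckle)
    array(rgamma(nvox, cfg$speckle_shape, rate = cfg$speckle_shape),
          c(nb, nz, na)) else NULL
  vidx <- which(vmask)
  gvec <- array(0, c(nb, nz, na))
  for (b in seq_len(nb))
    gvec[b, , ] <- matrix(ves$gain[b, ], nz, na, byrow = TRUE)
  gvec <- gvec[vidx]
  for (r in seq_len(nr)) {
    if (!finite_shape) {
      frame <- sig
    } else if (cfg$frozen_speckle) {
      m <- static
      if (length(vidx)) {
        draw <- rgamma(length(vidx), cfg$speckle_shape,
                       rate = cfg$speckle_shape)
        m[vidx] <- 1 + gvec * (draw - 1)
      }
      frame <- sig * m
    } else {
      frame <- sig * array(rgamma(nvox, cfg$speckle_shape,
                                  rate = cfg$speckle_shape), c(nb, nz, na))
    }
    if (cfg$noise_floor > 0)
      frame <- frame + array(rexp(nvox, rate = 1 / cfg$noise_floor),
                             c(nb, nz, na))
    vol[, r, , ] <- frame
  }

  truth <- structure(
    list(boundaries = bnd,
         vessel_mask = ves$foot,
         onh_mask = onh_mask,
         onh_width_px = 2 * cfg$onh_radius_px * (cfg$onh_radius_px > 0),
         onh_center = if (cfg$onh_radius_px > 0) {
           if (is.null(cfg$onh_center_xy)) geom$center else cfg$onh_center_xy
         } else NULL,
         rpe_anterior = geom$rpe_anterior,
         signal = sig),
    class = "phantom_truth")
  volume <- oct_volume(vol, axial_scale_um = geom$axial_scale_um,
                       lateral_scale_um = geom$lateral_scale_um,
                       meta = list(seed = cfg$seed,
                                   rolloff_decay = cfg$rolloff_decay,
                                   config = cfg))
  list(volume = volume, truth = truth)
}

#' Background-noise volume matching a phantom raster
#'
#' Emulates the extra volume acquired outside the field of view to
#' characterise background noise: pure additive exponential noise with
#' mean `noise_floor` and no structure.
#'
#' @param config a [phantom_config()].
#' @return an [oct_volume()] of the configured raster shape.
#' @export
make_background <- function(config) {
  cfg <- validate_phantom_config(config)
  d <- c(cfg$n_bscans, cfg$n_repeats, cfg$n_depth, cfg$n_alines)
  set.seed(cfg$seed + 1L)
  data <- if (cfg$noise_floor > 0)
    array(rexp(prod(d), rate = 1 / cfg$noise_floor), d)
  else array(0, d)
  s <- cfg$axial_scale_air_um / cfg$refractive_index
  oct_volume(data, axial_scale_um = s,
             lateral_scale_um = cfg$fov_width_um / cfg$n_alines,
             meta = list(kind = "background", seed = cfg$seed + 1L))
}

#' Simulate a spectral interferogram of point reflectors
#'
#' Returns the complex spectral fringe of one A-line containing point
#' reflectors at the given depths, under a Gaussian source envelope, with
#' optional second/third-order dispersion phase
#' `exp(+i (a2 (k - k0)^2 + a3 (k - k0)^3))`. Transforming the undispersed
#' fringe (see [compensate_dispersion()]) yields peaks at the configured
#' depth indices; a nonzero `a2`/`a3` broadens them.
#'
#' @param depths_px reflector depths in 0-based pixels, each within the
#'   Nyquist range `[0, n_samples / 2)`.
#' @param n_samples number of spectral samples (wavenumber bins).
#' @param a2,a3 dispersion phase coefficients, rad per (sample index)^2
#'   and rad per (sample index)^3.
#' @param amplitudes reflector amplitudes, recycled to the number of depths.
#' @param envelope_sd standard deviation of the Gaussian spectral envelope
#'   in samples (`Inf` for a flat spectrum).
#' @return complex vector of length `n_samples` with attribute `k0_index`.
#' @export
make_fringes <- function(depths_px, n_samples, a2 = 0, a3 = 0,
                         amplitudes = 1, envelope_sd = n_samples / 6) {
  n_samples <- as.integer(n_samples)
  if (n_samples <= 0L) stop("n_samples must be positive")
  if (length(depths_px) == 0L) stop("at least one reflector depth required")
  if (any(depths_px < 0 | depths_px >= n_samples / 2))
    stop("reflector depths must lie within the Nyquist range [0, n/2)")
  amplitudes <- rep_len(amplitudes, length(depths_px))
  k <- seq_len(n_samples) - 1
  k0 <- n_samples / 2
  env <- if (is.finite(envelope_sd))
    exp(-(k - k0)^2 / (2 * envelope_sd^2)) else rep(1, n_samples)
  s <- complex(real = rep(0, n_samples), imaginary = rep(0, n_samples))
  for (j in seq_along(depths_px))
    s <- s + amplitudes[j] * exp(2i * pi * k * depths_px[j] / n_samples)
  s <- s * env * exp(1i * (a2 * (k - k0)^2 + a3 * (k - k0)^3))
  attr(s, "k0_index") <- k0
  s
}
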