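#' Segmentation parameters
#'
#' Tunables of the iterative intensity/derivative boundary detection.
#' Defaults are expressed in micrometres where anatomy is involved and in
#' pixels where the quantity is purely numerical.
#'
#' @param kernel_size odd (depth, lateral) dimensions of the rectangular
#'   averaging kernel applied before boundary detection.
#' @param derivative_scale_px half-window of the dual-window axial
#'   gradient used by the derivative-based detectors (see
#'   [axial_derivative()]); 1 is the plain central difference.
#' @param prior_retina_um a priori distance between the RPE-Bruch complex
#'   and the vitreous (about 200 um in the developing mouse).
#' @param prior_margin_um half-width of the axial search window placed
#'   around prior depths.
#' @param nfl_prior_um expected NFL thickness used to centre the NFL/IPL
#'   detector window.
#' @param opl_position_frac expected OPL depth as a fraction of the
#'   vitreous-to-RPE distance.
#' @param hann_length_px support length of the squared-Hann axial
#'   weighting used by the OPL and NFL/IPL detectors.
#' @param rpe_band_halfwidth_px half-width of the RPE-Bruch band: the
#'   posterior boundary is the detected band centre plus this offset, and
#'   the en-face ONH projection averages over the same band.
#' @param os_search_offset_px axial margin posterior to the OPL where the
#'   IS/OS search window starts.
#' @param poly_order order of the per-B-scan polynomial used to smooth
#'   boundaries during artifact correction.
#' @param sd_threshold residual threshold (in standard deviations) beyond
#'   which a boundary point is replaced by the fitted curve.
#' @param onh_drop_fraction fraction of the median en-face RPE-band
#'   intensity below which a pixel counts as a disruption core.
#' @param onh_min_area smallest disruption (pixels) accepted as an ONH.
#' @param min_valid_frac hard-failure threshold: smallest fraction of
#'   A-lines on which the RPE must be detectable.
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(kernel_size = c(3L, 3L),
                                derivative_scale_px = 4L,
                                prior_retina_um = 200,
                                prior_margin_um = 50,
                                nfl_prior_um = 15,
                                opl_position_frac = 0.5,
                                hann_length_px = 31L,
                                rpe_band_halfwidth_px = 4,
                                os_search_offset_px = 5,
                                poly_order = 4L,
                                sd_threshold = 2,
                                onh_drop_fraction = 0.45,
                                onh_min_area = 8L,
                                min_valid_frac = 0.5) {
  if (any(kernel_size %% 2L == 0L) || any(kernel_size < 1L))
    stop("kernel_size dimensions must be odd and >= 1")
  if (poly_order < 1L) stop("poly_order must be >= 1")
  if (sd_threshold <= 0) stop("sd_threshold must be > 0")
  structure(list(kernel_size = as.integer(kernel_size),
                 derivative_scale_px = as.integer(derivative_scale_px),
                 prior_retina_um = prior_retina_um,
                 prior_margin_um = prior_margin_um,
                 nfl_prior_um = nfl_prior_um,
                 opl_position_frac = opl_position_frac,
                 hann_length_px = as.integer(hann_length_px),
                 rpe_band_halfwidth_px = rpe_band_halfwidth_px,
                 os_search_offset_px = os_search_offset_px,
                 poly_order = as.integer(poly_order),
                 sd_threshold = sd_threshold,
                 onh_drop_fraction = onh_drop_fraction,
                 onh_min_area = as.integer(onh_min_area),
                 min_valid_frac = min_valid_frac),
            class = "segmentation_params")
}

#' Boundary surface
#'
#' Per-(bscan, aline) depth map of one anatomical interface, in 1-based
#' axial pixels; `NaN` marks undetected positions.
#'
#' @param depth numeric matrix (bscan x aline).
#' @param name interface name, e.g. `"vitreous_NFL"`.
#' @return list of class `boundary_surface`.
#' @export
boundary_surface <- function(depth, name) {
  stopifnot(is.matrix(depth))
  structure(list(depth = depth, name = name, units = "px"),
            class = "boundary_surface")
}

#' Rectangular-kernel denoising of a structural volume
#'
#' Normalized nearest-neighbour box averaging of every B-scan (reflect
#' padding), reducing static speckle before boundary detection.
#'
#' @param vol3d 3-D array (bscan, depth, aline).
#' @param kernel_size odd (depth, lateral) kernel dimensions.
#' @return array of the same shape.
#' @export
denoise <- function(vol3d, kernel_size = c(3L, 3L)) {
  stopifnot(length(dim(vol3d)) == 3L)
  if (any(kernel_size %% 2L == 0L))
    stop("kernel dimensions must be odd")
  if (all(kernel_size == 1L)) return(vol3d)
  out <- vol3d
  for (b in seq_len(dim(vol3d)[1]))
    out[b, , ] <- box_blur(matrix(vol3d[b, , ], dim(vol3d)[2]), kernel_size)
  out
}

#' Axial first derivative
#'
#' Signed axial gradient of the intensity (anterior-to-posterior
#' increasing index). With `scale_px = 1` this is the central finite
#' difference, one-sided at the edges. Larger scales compute the
#' dual-window gradient
#' `(mean(I[z+1 .. z+w]) - mean(I[z-w .. z-1])) / (w + 1)`
#' -- the derivative at scale w -- which averages speckle on both sides
#' of an edge while keeping its response apex on the edge itself (for a
#' sharp step the apex ties on the two pixels flanking the interface,
#' exactly as the central difference does). Windows are clipped at the
#' raster edges. Dark-to-bright transitions give positive values,
#' bright-to-dark transitions negative values.
#'
#' @param vol3d 3-D array (bscan, depth, aline).
#' @param scale_px half-window w in pixels (>= 1).
#' @return signed array of the same shape.
#' @export
axial_derivative <- function(vol3d, scale_px = 1L) {
  stopifnot(length(dim(vol3d)) == 3L)
  d <- dim(vol3d)
  nz <- d[2]
  if (nz < 2L) stop("need at least two depth pixels")
  w <- as.integer(scale_px)
  stopifnot(w >= 1L)
  # cumulative sums along depth give clipped-window means in O(1)
  x <- aperm(vol3d, c(2, 1, 3))
  dim(x) <- c(nz, d[1] * d[3])
  cs <- rbind(0, apply(x, 2L, cumsum))
  z <- seq_len(nz)
  post_hi <- pmin(z + w, nz); post_lo <- pmin(z + 1L, nz + 1L)
  ant_hi <- pmax(z - 1L, 0L); ant_lo <- pmax(z - w, 1L)
  post_n <- pmax(post_hi - post_lo + 1L, 1L)
  ant_n <- pmax(ant_hi - ant_lo + 1L, 1L)
  post <- (cs[post_hi + 1L, , drop = FALSE] -
           cs[post_lo, , drop = FALSE]) / post_n
  ant <- (cs[ant_hi + 1L, , drop = FALSE] -
          cs[ant_lo, , drop = FALSE]) / ant_n
  D <- (post - ant) / (w + 1L)
  # one-sided edges: reuse the nearest interior value's convention
  D[1, ] <- (post[1, ] - x[1, ]) * 2 / (w + 1L)
  D[nz, ] <- (x[nz, ] - ant[nz, ]) * 2 / (w + 1L)
  dim(D) <- c(nz, d[1], d[3])
  aperm(D, c(2, 1, 3))
}

# Per-A-line extremum search. `lo`/`hi` are matrices (bscan x aline) of
# float window bounds; the extremum of `arr` (optionally multiplied by a
# weight centred at `wcenter` with support `wlen`) is located within
# [ceiling(lo), floor(hi)]. Ties take the anterior-most depth.
window_extremum <- function(arr, lo, hi, mode = c("max", "min"),
                            wcenter = NULL, wlen = NULL,
                            fallback_unweighted = FALSE) {
  mode <- match.arg(mode)
  d <- dim(arr)
  nb <- d[1]; nz <- d[2]; na <- d[3]
  out <- matrix(NaN, nb, na)
  val <- matrix(NaN, nb, na)
  for (b in seq_len(nb)) {
    M <- matrix(arr[b, , ], nz, na)
    for (a in seq_len(na)) {
      l <- max(1, ceiling(lo[b, a])); h <- min(nz, floor(hi[b, a]))
      if (!is.finite(l) || !is.finite(h) || l > h) next
      prof <- M[l:h, a]
      weighted <- !is.null(wcenter) &&
        !(fallback_unweighted && (h - l + 1L) < wlen)
      if (weighted) {
        if (!is.finite(wcenter[b, a])) next
        prof <- prof * hann_sq_weight(l:h, wcenter[b, a], wlen)
      }
      i <- if (mode == "max") which.max(prof) else which.min(prof)
      if (length(i)) {
        out[b, a] <- l + i - 1
        val[b, a] <- prof[i]
      }
    }
  }
  list(depth = out, value = val)
}

#' Detect the RPE-Bruch band centre
#'
#' The RPE-Bruch complex carries the highest back-scattered intensity in
#' the retina; the band centre is located as the per-A-line argmax of the
#' denoised intensity (ties take the anterior depth). A-lines without
#' finite intensity return `NaN`.
#'
#' @param vol3d denoised structural array (bscan, depth, aline).
#' @return `boundary_surface` named `"RPE_center"`.
#' @export
detect_rpe <- function(vol3d) {
  stopifnot(length(dim(vol3d)) == 3L)
  d <- dim(vol3d)
  out <- matrix(NaN, d[1], d[3])
  for (b in seq_len(d[1])) {
    M <- matrix(vol3d[b, , ], d[2], d[3])
    idx <- apply(M, 2L, function(col) {
      if (!any(is.finite(col))) return(NaN)
      which.max(col)
    })
    out[b, ] <- idx
  }
  boundary_surface(out, "RPE_center")
}

#' Locate the optic nerve head from the RPE-band en-face projection
#'
#' Projects the mean intensity of the band around the (polynomial
#' smoothed) RPE centre, smooths the projection, and searches for a
#' disruption: the largest 8-connected region darker than
#' `onh_drop_fraction` times the median projection. The ONH width is the
#' diameter at which the radial median profile around the region
#' centroid crosses half way between the interior and intact-band
#' levels (the half-level crossing of a symmetrically blurred edge sits
#' on the true edge), and the exclusion mask is the circle of that
#' diameter at the centroid (the ONH is treated as quasi-cylindrical,
#' with no curvature along depth).
#'
#' @param vol3d denoised structural array.
#' @param rpe `boundary_surface` from [detect_rpe()].
#' @param params a [segmentation_params()].
#' @return list with `center` (bscan, aline) or `NULL`, `width_px`
#'   (equivalent diameter, 0 when absent), logical `mask`, and the
#'   `enface` projection used.
#' @export
detect_onh <- function(vol3d, rpe, params = segmentation_params()) {
  d <- dim(vol3d)
  smooth <- correct_boundary(rpe, params)$depth
  hw <- params$rpe_band_halfwidth_px
  ef <- matrix(NA_real_, d[1], d[3])
  for (b in seq_len(d[1])) {
    M <- matrix(vol3d[b, , ], d[2], d[3])
    for (a in seq_len(d[3])) {
      c0 <- smooth[b, a]
      if (!is.finite(c0)) next
      l <- max(1, min(d[2], round(c0 - hw)))
      h <- max(1, min(d[2], round(c0 + hw)))
      if (l > h) next
      ef[b, a] <- mean(M[l:h, a])
    }
  }
  # smooth the projection before thresholding: single-pixel speckle dips
  # and vessel shadows must not connect to (or masquerade as) the ONH
  efs <- ef
  if (all(is.finite(ef)) && nrow(ef) >= 3 && ncol(ef) >= 3)
    efs <- box_blur(ef, c(3L, 3L))
  med <- median(efs, na.rm = TRUE)
  empty <- list(center = NULL, width_px = 0,
                mask = matrix(FALSE, d[1], d[3]), enface = ef)
  # strict core threshold: vessel shadows (partial attenuation) must
  # not register as disruption
  core <- !is.na(efs) & efs < params$onh_drop_fraction * med
  if (!any(core)) return(empty)
  lab <- label_components(core)
  sizes <- tabulate(lab)
  big <- which.max(sizes)
  if (sizes[big] < params$onh_min_area) return(empty)
  core <- lab == big
  ctr <- c(mean(row(core)[core]), mean(col(core)[core]))
  # The disruption edge is blurred symmetrically by the smoothing
  # kernels, so its true radius sits at the half-level crossing of the
  # radial median profile between the interior and local intact-band
  # levels. Centre and width are refined jointly: a symmetric
  # half-level pixel set re-centres the profile, which sharpens the
  # crossing, which re-centres again (converges in a few passes).
  interior <- median(efs[core])
  half <- (interior + med) / 2
  width <- 2 * sqrt(sum(core) / pi)  # fallback: core-area equivalent
  rowm <- row(efs); colm <- col(efs)
  for (it in 1:4) {
    rr <- sqrt((rowm - ctr[1])^2 + (colm - ctr[2])^2)
    kmax <- floor(min(ctr[1] - 1, d[1] - ctr[1],
                      ctr[2] - 1, d[3] - ctr[2]))
    if (kmax < 2) break
    prof <- vapply(0:kmax, function(k)
      median(efs[rr >= k - 0.5 & rr < k + 0.5], na.rm = TRUE), numeric(1))
    cross <- which(prof >= half & seq_along(prof) > 1)[1]
    if (is.na(cross) || cross < 2) break
    p1 <- prof[cross - 1]; p2 <- prof[cross]
    r_edge <- (cross - 2) + (half - p1) / (p2 - p1)
    width <- 2 * r_edge
    ext <- efs[rr > r_edge + 2 & rr < r_edge + 7]
    if (length(ext)) half <- (interior + median(ext)) / 2
    sel2 <- efs < half & rr <= r_edge + 3
    if (!any(sel2)) break
    ctr <- c(mean(rowm[sel2]), mean(colm[sel2]))
  }
  list(center = ctr, width_px = width,
       mask = disk_mask(d[1], d[3], ctr, width / 2), enface = ef)
}

#' Detect the vitreous / NFL interface
#'
#' Within an axial window placed `prior_retina_um` anterior to the
#' RPE-band centre (half-width `prior_margin_um`), the boundary is the
#' per-A-line maximum of the axial derivative: the dark vitreous to
#' bright NFL transition. Windows falling outside the raster yield `NaN`.
#'
#' @param vol3d denoised structural array.
#' @param D axial derivative from [axial_derivative()].
#' @param rpe RPE band-centre surface (ideally artifact-corrected).
#' @param params a [segmentation_params()].
#' @param axial_scale_um axial pixel pitch, um (converts the priors).
#' @return `boundary_surface` named `"vitreous_NFL"`.
#' @export
detect_vitreous_nfl <- function(vol3d, D, rpe,
                                params = segmentation_params(),
                                axial_scale_um = 2.53) {
  prior <- params$prior_retina_um / axial_scale_um
  marg <- params$prior_margin_um / axial_scale_um
  ctr <- rpe$depth - prior
  res <- window_extremum(D, ctr - marg, ctr + marg, "max")
  boundary_surface(res$depth, "vitreous_NFL")
}

#' Detect the OPL by weighted intensity maximum
#'
#' The OPL is a local intensity maximum between the inner retina and the
#' RPE. The search profile is the intensity multiplied by a squared-Hann
#' window of length `hann_length_px` centred at the expected OPL depth
#' (`opl_position_frac` of the vitreous-to-RPE distance); the argmax of
#' the weighted profile is the boundary. When the window support carries
#' no distinct peak (flat profile), the expected depth itself is
#' returned and the position is flagged low-confidence.
#'
#' @param vol3d denoised structural array.
#' @param vitreous_nfl,rpe bracketing `boundary_surface` objects.
#' @param params a [segmentation_params()].
#' @return `boundary_surface` named `"OPL"` with attribute
#'   `low_confidence` (logical matrix).
#' @export
detect_opl <- function(vol3d, vitreous_nfl, rpe,
                       params = segmentation_params()) {
  v <- vitreous_nfl$depth; r <- rpe$depth
  span <- r - v
  ctr <- v + params$opl_position_frac * span
  lo <- v + 0.25 * span
  hi <- r - params$rpe_band_halfwidth_px - 2
  res <- window_extremum(vol3d, lo, hi, "max",
                         wcenter = ctr, wlen = params$hann_length_px,
                         fallback_unweighted = TRUE)
  out <- res$depth
  # flat-profile fallback: when the window carries no distinct intensity
  # peak (relative prominence below 10%), the detection is weight-driven;
  # report the expected depth and flag it
  d <- dim(vol3d)
  lowc <- matrix(FALSE, nrow(out), ncol(out))
  half <- params$hann_length_px / 2
  for (b in seq_len(d[1])) {
    M <- matrix(vol3d[b, , ], d[2], d[3])
    for (a in seq_len(d[3])) {
      z <- out[b, a]
      if (!is.finite(z)) next
      l <- max(1, ceiling(max(lo[b, a], ctr[b, a] - half)))
      h <- min(d[2], floor(min(hi[b, a], ctr[b, a] + half)))
      if (l > h) next
      ref <- median(M[l:h, a])
      if (ref <= 0 || (M[z, a] - ref) / ref < 0.1) {
        out[b, a] <- round(ctr[b, a])
        lowc[b, a] <- TRUE
      }
    }
  }
  bs <- boundary_surface(out, "OPL")
  attr(bs, "low_confidence") <- lowc
  bs
}

#' Detect the IPL / INL interface
#'
#' A hard axial gate on the derivative from just below the vitreous
#' boundary to the OPL; the boundary is the per-A-line minimum of D (the
#' bright IPL to dark INL transition; ties anterior).
#'
#' @param vol3d denoised structural array (unused beyond shape checks;
#'   kept for interface symmetry).
#' @param D axial derivative.
#' @param vitreous_nfl,opl bracketing surfaces.
#' @return `boundary_surface` named `"IPL_INL"`.
#' @export
detect_ipl_inl <- function(vol3d, D, vitreous_nfl, opl) {
  res <- window_extremum(D, vitreous_nfl$depth + 2, opl$depth - 1, "min")
  boundary_surface(res$depth, "IPL_INL")
}

#' Detect the NFL / IPL interface
#'
#' Within the gate (vitreous_NFL, IPL_INL), the derivative is weighted by
#' a squared-Hann window centred at the expected NFL posterior depth
#' (`nfl_prior_um` below the vitreous boundary); the minimum of the
#' weighted derivative (bright NFL to dimmer IPL transition) is the
#' boundary. If the gate is empty or carries no negative transition the
#' boundary collapses onto the vitreous/NFL interface.
#'
#' @param vol3d denoised structural array (interface symmetry).
#' @param D axial derivative.
#' @param vitreous_nfl,ipl_inl bracketing surfaces.
#' @param params a [segmentation_params()].
#' @param axial_scale_um axial pixel pitch, um.
#' @return `boundary_surface` named `"NFL_IPL"`.
#' @export
detect_nfl_ipl <- function(vol3d, D, vitreous_nfl, ipl_inl,
                           params = segmentation_params(),
                           axial_scale_um = 2.53) {
  v <- vitreous_nfl$depth
  ctr <- v + params$nfl_prior_um / axial_scale_um
  # posterior margin keeps the dual-window gradient (and the kernel
  # blur) from sensing the IPL/INL edge just beyond the gate
  hi <- ipl_inl$depth - 2 - params$derivative_scale_px
  res <- window_extremum(D, v + 2, hi, "min",
                         wcenter = ctr, wlen = params$hann_length_px)
  out <- res$depth
  # a candidate weaker than 1% of the strongest gradient in the volume
  # is smoothing residue, not an NFL/IPL transition (a genuine edge at
  # the default contrast is an order of magnitude above this)
  tol <- 0.01 * max(abs(D), na.rm = TRUE)
  collapse <- (!is.finite(out) | res$value >= -tol) & is.finite(v)
  out[collapse] <- v[collapse]
  boundary_surface(out, "NFL_IPL")
}

#' Detect the anterior boundary of the photoreceptor outer segments
#'
#' The maximum axial derivative strictly between the OPL and the anterior
#' edge of the RPE-Bruch band (the ONL to IS/OS rise). Detections landing
#' on the window's posterior edge (no IS/OS band present, so the RPE rise
#' is caught instead) are flagged low-confidence.
#'
#' @param vol3d denoised structural array (interface symmetry).
#' @param D axial derivative.
#' @param opl,rpe bracketing surfaces (`rpe` is the band centre).
#' @param params a [segmentation_params()].
#' @return `boundary_surface` named `"OS_anterior"` with attribute
#'   `low_confidence`.
#' @export
detect_os <- function(vol3d, D, opl, rpe,
                      params = segmentation_params()) {
  lo <- opl$depth + params$os_search_offset_px
  # stay clear of the RPE band rise by the gradient's reach
  hi <- rpe$depth - params$rpe_band_halfwidth_px - 2 -
    (params$derivative_scale_px - 1)
  res <- window_extremum(D, lo, hi, "max")
  lowc <- is.finite(res$depth) & res$depth >= hi - 2
  bs <- boundary_surface(res$depth, "OS_anterior")
  attr(bs, "low_confidence") <- lowc
  bs
}

#' Polynomial artifact correction of a boundary surface
#'
#' Per B-scan, a least-squares polynomial of order `poly_order` is fitted
#' to the boundary depths along the A-line axis. Points deviating from
#' the fitted curve by more than `sd_threshold` residual standard
#' deviations are moved onto the curve (shadow artifacts, punctual
#' variations); all other points are kept; `NaN` gaps are filled from the
#' fit. B-scans with fewer than `poly_order + 1` valid points inherit the
#' fit of the nearest valid B-scan and are flagged.
#'
#' @param surface a `boundary_surface`.
#' @param params a [segmentation_params()].
#' @return corrected `boundary_surface`; attribute `replaced_bscans`
#'   lists B-scans that had to be filled wholesale.
#' @export
correct_boundary <- function(surface, params = segmentation_params()) {
  stopifnot(inherits(surface, "boundary_surface"))
  depth <- surface$depth
  nb <- nrow(depth); na <- ncol(depth)
  x <- seq_len(na)
  ord <- params$poly_order
  fits <- matrix(NA_real_, nb, na)
  out <- depth
  bad_bscans <- integer(0)
  for (b in seq_len(nb)) {
    y <- depth[b, ]
    ok <- is.finite(y)
    if (sum(ok) < ord + 1L) {
      bad_bscans <- c(bad_bscans, b)
      next
    }
    # centred/scaled Vandermonde keeps the fit well-conditioned
    xs <- (x - mean(x)) / max(x[length(x)] - mean(x), 1)
    X <- outer(xs, 0:ord, `^`)
    polyfit <- function(use) {
      co <- lm.fit(X[use, , drop = FALSE], y[use])$coefficients
      co[is.na(co)] <- 0
      drop(X %*% co)
    }
    # trimmed refit: an initial fit ranks the points, the best 75% are
    # refitted, so clustered gross deviations (ONH, shadows) can drag
    # neither the curve nor the residual scale
    res1 <- abs(y - polyfit(ok))
    trim <- ok & res1 <= quantile(res1[ok], 0.75, names = FALSE)
    if (sum(trim) < ord + 1L) trim <- ok
    yhat <- polyfit(trim)
    res <- y - yhat
    # robust residual scale; SD fallback when the MAD degenerates, and
    # an exact-fit tolerance when both collapse (e.g. flat + one spike)
    s <- stats::mad(res[trim])
    if (s == 0) s <- sd(res[trim])
    repl <- if (s > 0)
      !ok | (is.finite(res) & abs(res) > params$sd_threshold * s)
    else
      !ok | (is.finite(res) &
               abs(res) > 1e-6 * max(1, abs(median(y[ok]))))
    fits[b, ] <- yhat
    out[b, repl] <- yhat[repl]
  }
  if (length(bad_bscans)) {
    good <- setdiff(seq_len(nb), bad_bscans)
    if (length(good) == 0L) stop("no B-scan has enough valid points to fit")
    for (b in bad_bscans)
      out[b, ] <- fits[good[which.min(abs(good - b))], ]
  }
  res <- boundary_surface(out, surface$name)
  attr(res, "replaced_bscans") <- bad_bscans
  res
}

#' Segment all retinal layer boundaries of a structural volume
#'
#' Full iterative workflow: rectangular-kernel denoising; RPE-Bruch band
#' detection (intensity argmax); ONH localisation and exclusion from the
#' RPE-band en-face projection; vitreous/NFL detection from the
#' derivative under the retina-thickness prior; OPL by squared-Hann
#' weighted intensity maximum; IPL/INL by gated derivative minimum;
#' NFL/IPL by Hann-weighted derivative minimum; IS/OS anterior boundary
#' by gated derivative maximum; polynomial artifact correction of every
#' surface. A-lines inside the ONH mask are set `NaN` in all surfaces,
#' and the anatomical ordering is enforced by clipping (with a warning
#' when clipping was needed).
#'
#' @param vol an [oct_volume()] (repeats are intensity-averaged) or a
#'   3-D structural array.
#' @param params a [segmentation_params()].
#' @param axial_scale_um axial pixel pitch, um; taken from `vol` when it
#'   is an [oct_volume()].
#' @return list of class `segmentation_result`: `boundaries` (named list
#'   of corrected `boundary_surface` objects in anatomical order),
#'   `onh`, `valid_mask`, `params`, `axial_scale_um`.
#' @export
segment_retina <- function(vol, params = segmentation_params(),
                           axial_scale_um = NULL) {
  if (inherits(vol, "oct_volume") && is.null(axial_scale_um))
    axial_scale_um <- vol$axial_scale_um
  if (is.null(axial_scale_um))
    stop("axial_scale_um required for a bare array input")
  I3 <- denoise(as_structural(vol), params$kernel_size)
  D <- axial_derivative(I3, params$derivative_scale_px)

  rpe_raw <- detect_rpe(I3)
  frac_ok <- mean(is.finite(rpe_raw$depth))
  if (frac_ok < params$min_valid_frac)
    stop(sprintf(
      "RPE undetectable on %.0f%% of A-lines (need at least %.0f%% valid)",
      100 * (1 - frac_ok), 100 * params$min_valid_frac))

  onh <- detect_onh(I3, rpe_raw, params)
  rpe <- rpe_raw
  rpe$depth[onh$mask] <- NaN
  rpe <- correct_boundary(rpe, params)

  vnfl <- correct_boundary(
    detect_vitreous_nfl(I3, D, rpe, params, axial_scale_um), params)
  opl <- correct_boundary(detect_opl(I3, vnfl, rpe, params), params)
  ipl_inl <- correct_boundary(detect_ipl_inl(I3, D, vnfl, opl), params)
  nfl_ipl <- correct_boundary(
    detect_nfl_ipl(I3, D, vnfl, ipl_inl, params, axial_scale_um), params)
  osb <- correct_boundary(detect_os(I3, D, opl, rpe, params), params)
  rpe_post <- boundary_surface(rpe$depth + params$rpe_band_halfwidth_px,
                               "RPE_posterior")

  b <- list(vitreous_NFL = vnfl,
            NFL_IPL = nfl_ipl,
            IPL_INL = ipl_inl,
            OPL = opl,
            OS_anterior = osb,
            RPE_posterior = rpe_post)
  for (nm in names(b)) {
    b[[nm]]$depth[onh$mask] <- NaN
    b[[nm]]$name <- nm
  }
  # ordering invariant: clip each surface below its anterior neighbour
  clipped <- 0L
  for (i in 2:length(b)) {
    lo <- b[[i - 1L]]$depth
    bad <- is.finite(b[[i]]$depth) & is.finite(lo) & b[[i]]$depth < lo
    clipped <- clipped + sum(bad)
    b[[i]]$depth[bad] <- lo[bad]
  }
  if (clipped > 0L)
    warning(sprintf("boundary ordering enforced by clipping %d points",
                    clipped))
  valid <- !onh$mask
  for (nm in names(b)) valid <- valid & is.finite(b[[nm]]$depth)
  structure(list(boundaries = b, onh = onh, valid_mask = valid,
                 params = params, axial_scale_um = axial_scale_um),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result>\n")
  cat("  boundaries:", paste(names(x$boundaries), collapse = ", "), "\n")
  cat(sprintf("  valid A-lines: %d / %d\n",
              sum(x$valid_mask), length(x$valid_mask)))
  cat(sprintf("  ONH width: %.1f px\n", x$onh$width_px))
  invisible(x)
}
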