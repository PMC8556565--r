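#' Dispersion coefficients for spectral-domain reconstruction
#'
#' Second and third order phase coefficients applied to the spectral
#' fringe pattern to compensate the chromatic dispersion mismatch
#' introduced by the sample (the coefficients themselves are inputs,
#' typically obtained from a system model or calibration).
#'
#' @param a2 second-order coefficient, rad per (sample index)^2.
#' @param a3 third-order coefficient, rad per (sample index)^3.
#' @param k0_index centre sample index of the phase expansion (`NULL`:
#'   half the number of spectral samples).
#' @return list of class `dispersion_coefficients`.
#' @export
dispersion_coefficients <- function(a2 = 0, a3 = 0, k0_index = NULL) {
  if (!is.finite(a2) || !is.finite(a3))
    stop("dispersion coefficients must be finite")
  structure(list(a2 = a2, a3 = a3, k0_index = k0_index),
            class = "dispersion_coefficients")
}

#' Numerically compensate dispersion and reconstruct A-line intensities
#'
#' Multiplies the complex spectral fringes by the phase correction
#' `exp(-i (a2 (k - k0)^2 + a3 (k - k0)^3))` and Fourier-transforms along
#' wavenumber to depth, returning linear intensity (squared transform
#' magnitude). With coefficients matching the ones that generated the
#' dispersion, the point-spread function recovers its undispersed width.
#'
#' @param fringes complex vector (one A-line) or matrix with one column
#'   per A-line, sampled uniformly in wavenumber.
#' @param coeffs a [dispersion_coefficients()] object.
#' @return numeric intensity vector/matrix of the same shape; depth index
#'   1 corresponds to zero path difference.
#' @export
compensate_dispersion <- function(fringes, coeffs = dispersion_coefficients()) {
  stopifnot(inherits(coeffs, "dispersion_coefficients"))
  one <- is.null(dim(fringes))
  m <- if (one) matrix(fringes, ncol = 1L) else fringes
  n <- nrow(m)
  if (n < 2L) stop("fringes must contain at least two spectral samples")
  k <- seq_len(n) - 1
  k0 <- if (is.null(coeffs$k0_index)) n / 2 else coeffs$k0_index
  phase <- exp(-1i * (coeffs$a2 * (k - k0)^2 + coeffs$a3 * (k - k0)^3))
  out <- Mod(stats::mvfft(m * phase))^2
  if (one) drop(out) else out
}

#' Subtract the mean background depth profile
#'
#' The background volume (acquired outside the field of view) is reduced
#' to its mean depth profile, which is subtracted from every A-line of the
#' signal volume; negative results are clipped at zero. Only the depth
#' statistics of the background generalize to the imaging field, hence
#' the profile (not voxelwise) model.
#'
#' @param vol an [oct_volume()].
#' @param bg an [oct_volume()] with the same depth extent.
#' @return the corrected [oct_volume()].
#' @export
subtract_background <- function(vol, bg) {
  stopifnot(inherits(vol, "oct_volume"), inherits(bg, "oct_volume"))
  if (n_depth(vol) != n_depth(bg))
    stop("signal and background volumes disagree in depth extent")
  profile <- apply(bg$data, 3L, mean)
  d <- dim(vol$data)
  prof4 <- aperm(array(profile, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
  out <- pmax(vol$data - prof4, 0)
  oct_volume(out, vol$axial_scale_um, vol$lateral_scale_um,
             meta = c(vol$meta, list(background_subtracted = TRUE)))
}

#' Correct depth sensitivity roll-off
#'
#' Undoes an exponential signal-to-noise roll-off by multiplying depth
#' pixel z (1-based) by `decay^-(z - 1)`. The decay factor is a known or
#' user-fitted system property.
#'
#' @param vol an [oct_volume()] or a 3-D structural array
#'   (bscan, depth, aline).
#' @param decay per-pixel attenuation factor in (0, 1].
#' @return object of the same type as `vol`.
#' @export
correct_rolloff <- function(vol, decay) {
  if (!is.numeric(decay) || decay <= 0 || decay > 1)
    stop("decay must lie in (0, 1]")
  if (decay == 1) return(vol)
  if (inherits(vol, "oct_volume")) {
    d <- dim(vol$data)
    gain <- decay^-(seq_len(d[3]) - 1)
    g4 <- aperm(array(gain, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
    return(oct_volume(vol$data * g4, vol$axial_scale_um,
                      vol$lateral_scale_um,
                      meta = c(vol$meta, list(rolloff_corrected = decay))))
  }
  d <- dim(vol)
  stopifnot(length(d) == 3L)
  gain <- decay^-(seq_len(d[2]) - 1)
  vol * aperm(array(gain, c(d[2], d[1], d[3])), c(2, 1, 3))
}

#' Rigid registration of consecutive B-scans
#'
#' Minimises eye-motion artefacts by aligning every B-scan to the previous
#' (already aligned) one with an integer-pixel translation maximising the
#' 2-D FFT cross-correlation of repeat-averaged B-scans; the first B-scan
#' is the reference. Ties in the correlation peak are broken toward the
#' zero shift, so constant images are left untouched.
#'
#' @param vol an [oct_volume()].
#' @param max_shift largest |shift| considered in each direction, pixels.
#' @return list of class `registration_result` with `shifts` (n_bscans x 2
#'   matrix of detected cumulative (dz, dx) displacements relative to the
#'   first B-scan) and `registered` (the aligned [oct_volume()], with the
#'   negated displacements applied; zero-filled at exposed edges).
#' @export
register_bscans <- function(vol, max_shift = 20L) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$data)
  nb <- d[1]
  shifts <- matrix(0L, nb, 2L,
                   dimnames = list(NULL, c("dz", "dx")))
  out <- vol$data
  repavg <- function(arr, b) {
    x <- arr[b, , , , drop = FALSE]
    dim(x) <- d[2:4]
    colMeans(x)
  }
  if (nb >= 2L) {
    ref <- repavg(out, 1L)
    for (b in 2:nb) {
      img <- repavg(out, b)
      sh <- xcorr_shift(ref, img, max_shift)
      # report the detected motion; apply its negation to correct it
      shifts[b, ] <- -sh
      if (any(sh != 0L))
        for (r in seq_len(d[2]))
          out[b, r, , ] <- shift_matrix(out[b, r, , ], sh[1], sh[2])
      ref <- repavg(out, b)
    }
  }
  structure(
    list(shifts = shifts,
         registered = oct_volume(out, vol$axial_scale_um,
                                 vol$lateral_scale_um,
                                 meta = c(vol$meta,
                                          list(registered = TRUE)))),
    class = "registration_result")
}

# Integer translation (dz, dx) that best aligns `img` onto `ref` by FFT
# cross-correlation; ties broken toward zero shift, then lexicographically.
xcorr_shift <- function(ref, img, max_shift = 20L) {
  cc <- Re(fft(fft(ref) * Conj(fft(img)), inverse = TRUE))
  nr <- nrow(cc); nc <- ncol(cc)
  wrap <- function(i, n) ifelse(i - 1 <= n / 2, i - 1, i - 1 - n)
  dz <- wrap(row(cc), nr)
  dx <- wrap(col(cc), nc)
  ok <- abs(dz) <= max_shift & abs(dx) <= max_shift
  vals <- cc[ok]
  top <- max(vals)
  cand <- which(ok & cc >= top - 1e-9 * max(abs(top), 1))
  o <- order(abs(dz[cand]) + abs(dx[cand]), dz[cand], dx[cand])
  best <- cand[o[1L]]
  c(dz[best], dx[best])
}

#' Average repeated frames into a structural volume
#'
#' Intensity averaging over the repeat axis; with independent speckle
#' realisations per frame this reduces speckle contrast by about
#' `1/sqrt(n_repeats)`.
#'
#' @param vol an [oct_volume()] or bare 4-D array.
#' @return 3-D array (bscan, depth, aline).
#' @export
average_frames <- function(vol) {
  a <- if (inherits(vol, "oct_volume")) vol$data else vol
  stopifnot(length(dim(a)) == 4L)
  d <- dim(a)
  if (d[2] == 1L) return(array(a, d[c(1, 3, 4)]))
  m <- colMeans(aperm(a, c(2, 1, 3, 4)))
  array(m, d[c(1, 3, 4)])
}
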