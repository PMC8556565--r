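#' Speckle-variance angiography
#'
#' Per-voxel temporal variance of the intensity across the repeated
#' frames of every BM-scan (population variance, divisor N). Moving
#' scatterers (blood) decorrelate the speckle between frames and light up,
#' while static tissue stays dark.
#'
#' @param vol an [oct_volume()] with at least two repeats.
#' @return list of class `angio_volume`: `variance` (3-D array, bscan x
#'   depth x aline), `n_frames_used` (per B-scan), `removed_frame`
#'   (all `NA`: no frame removal).
#' @seealso [motion_robust_variance()] for the frame-removal variant.
#' @export
speckle_variance <- function(vol) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$data)
  if (d[2] < 2L) stop("speckle variance requires n_repeats >= 2")
  x <- aperm(vol$data, c(2, 1, 3, 4))
  m1 <- colMeans(x)
  m2 <- colMeans(x^2)
  v <- pmax(m2 - m1^2, 0)
  structure(list(variance = array(v, d[c(1, 3, 4)]),
                 n_frames_used = rep(d[2], d[1]),
                 removed_frame = rep(NA_integer_, d[1])),
            class = "angio_volume")
}

#' Motion-robust speckle variance via worst-frame removal
#'
#' For every BM-scan, the temporal variance is evaluated on each
#' leave-one-out subset of frames and the subset with the lowest spatial
#' mean variance is kept -- equivalently, the frame whose exclusion lowers
#' the variance the most (typically the one displaced by bulk eye motion)
#' is removed. Ties drop the last frame.
#'
#' @param vol an [oct_volume()] with at least three repeats.
#' @return an `angio_volume` (see [speckle_variance()]) with
#'   `n_frames_used = n_repeats - 1` and the index of the removed frame
#'   per B-scan.
#' @export
motion_robust_variance <- function(vol) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$data)
  nrep <- d[2]
  if (nrep < 3L) stop("frame removal requires n_repeats >= 3")
  nb <- d[1]
  out <- array(0, d[c(1, 3, 4)])
  removed <- integer(nb)
  m <- nrep - 1L
  for (b in seq_len(nb)) {
    x <- vol$data[b, , , , drop = FALSE]
    dim(x) <- c(nrep, d[3] * d[4])
    s1 <- colSums(x)
    s2 <- colSums(x^2)
    sms <- vapply(seq_len(nrep), function(j) {
      mu <- (s1 - x[j, ]) / m
      mean(pmax((s2 - x[j, ]^2) / m - mu^2, 0))
    }, numeric(1))
    # lowest spatial-mean variance wins; ties drop the last frame
    eps <- 1e-12 * max(sms, 1e-300)
    j <- max(which(sms <= min(sms) + eps))
    removed[b] <- j
    mu <- (s1 - x[j, ]) / m
    out[b, , ] <- matrix(pmax((s2 - x[j, ]^2) / m - mu^2, 0), d[3], d[4])
  }
  structure(list(variance = out,
                 n_frames_used = rep(m, nb),
                 removed_frame = removed),
            class = "angio_volume")
}

#' En-face projection over a depth window
#'
#' Mean intensity across an axial window for every (bscan, aline)
#' position, producing a top-down 2-D map.
#'
#' @param vol3d 3-D array (bscan, depth, aline) -- a structural volume or
#'   an angiography `variance` array.
#' @param depth_range integer vector of depth indices (1-based), or a
#'   length-2 `c(from, to)` range.
#' @return numeric matrix (bscan x aline).
#' @export
enface_projection <- function(vol3d, depth_range) {
  stopifnot(length(dim(vol3d)) == 3L)
  zr <- if (length(depth_range) == 2L)
    seq.int(depth_range[1], depth_range[2]) else as.integer(depth_range)
  if (length(zr) == 0L) stop("empty depth window")
  if (any(zr < 1L | zr > dim(vol3d)[2]))
    stop("depth window outside the raster")
  slab <- vol3d[, zr, , drop = FALSE]
  out <- colMeans(aperm(slab, c(2, 1, 3)))
  matrix(out, dim(vol3d)[1], dim(vol3d)[3])
}

#' Threshold an en-face angiogram into a vessel mask
#'
#' Marks pixels brighter than `mean + k_sd * SD` of the map, then removes
#' 8-connected components smaller than `min_area` pixels.
#'
#' @param enface numeric en-face map (bscan x aline), all finite.
#' @param k_sd threshold in standard deviations above the mean.
#' @param min_area smallest connected component kept, pixels.
#' @return list of class `vessel_mask`: logical `mask` and the numeric
#'   `threshold` used.
#' @export
vessel_mask <- function(enface, k_sd = 2, min_area = 5L) {
  stopifnot(is.matrix(enface))
  if (!all(is.finite(enface))) stop("en-face map must be finite")
  thr <- mean(enface) + k_sd * sd(as.vector(enface))
  m <- enface > thr
  if (any(m) && min_area > 1L) {
    lab <- label_components(m)
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_area)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  structure(list(mask = m, threshold = thr), class = "vessel_mask")
}
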