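# Internal numeric helpers shared across modules.

#' Box-filter a matrix with reflect padding
#'
#' Normalized rectangular (nearest-neighbour averaging) convolution. The
#' matrix is padded by edge reflection so the mean of a constant image is
#' preserved everywhere, including borders.
#'
#' @param m numeric matrix.
#' @param k integer length-2 kernel size (rows, cols); both odd and >= 1.
#' @return matrix of the same dimension.
#' @keywords internal
#' @noRd
box_blur <- function(m, k) {
  stopifnot(is.matrix(m), length(k) == 2L, all(k >= 1L))
  if (any(k %% 2L == 0L)) stop("box kernel dimensions must be odd")
  kr <- as.integer(k[1L]); kc <- as.integer(k[2L])
  if (kr == 1L && kc == 1L) return(m)
  hr <- kr %/% 2L; hc <- kc %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  if (hr >= nr || hc >= nc) stop("kernel larger than image")
  ridx <- c(rev(seq_len(hr) + 1L), seq_len(nr), nr - seq_len(hr))
  cidx <- c(rev(seq_len(hc) + 1L), seq_len(nc), nc - seq_len(hc))
  p <- m[ridx, cidx, drop = FALSE]
  # separable running mean via cumulative sums
  cs <- rbind(0, apply(p, 2L, cumsum))
  p <- (cs[(kr + 1L):(nr + kr), , drop = FALSE] -
        cs[1L:nr, , drop = FALSE]) / kr
  cs <- cbind(0, t(apply(p, 1L, cumsum)))
  (cs[, (kc + 1L):(nc + kc), drop = FALSE] -
   cs[, 1L:nc, drop = FALSE]) / kc
}

# Squared-Hann (cos^4) axial weighting centred at `center` with total
# support `length_px`; zero outside the support.
hann_sq_weight <- function(z, center, length_px) {
  u <- (z - center) / length_px
  w <- ifelse(abs(u) < 0.5, cos(pi * u)^4, 0)
  w
}

# Full width at half maximum of a sampled peak, in sample units, by linear
# interpolation of the half-maximum crossings around the global maximum.
fwhm_of <- function(y, x = seq_along(y) - 1) {
  i <- which.max(y)
  half <- y[i] / 2
  # walk left
  l <- i
  while (l > 1L && y[l - 1L] > half) l <- l - 1L
  r <- i
  n <- length(y)
  while (r < n && y[r + 1L] > half) r <- r + 1L
  if (l == 1L || r == n) return(NA_real_)
  xl <- x[l - 1L] + (x[l] - x[l - 1L]) * (half - y[l - 1L]) / (y[l] - y[l - 1L])
  xr <- x[r] + (x[r + 1L] - x[r]) * (y[r] - half) / (y[r] - y[r + 1L])
  xr - xl
}

# 8-connected labelling of a logical matrix. Two-pass union-find.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask & !is.na(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      nb <- integer(0)
      if (i > 1L && lab[i - 1L, j] > 0L) nb <- c(nb, lab[i - 1L, j])
      if (j > 1L) {
        if (lab[i, j - 1L] > 0L) nb <- c(nb, lab[i, j - 1L])
        if (i > 1L && lab[i - 1L, j - 1L] > 0L) nb <- c(nb, lab[i - 1L, j - 1L])
        if (i < nr && lab[i + 1L, j - 1L] > 0L) nb <- c(nb, lab[i + 1L, j - 1L])
      }
      if (length(nb) == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[i, j] <- nxt
      } else {
        roots <- vapply(unique(nb), find, integer(1))
        r0 <- min(roots)
        lab[i, j] <- r0
        for (r in roots) parent[r] <- r0
      }
    }
  }
  if (nxt == 0L) return(lab)
  # resolve and renumber
  roots <- vapply(seq_len(nxt), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  pos <- which(lab > 0L)
  lab[pos] <- remap[lab[pos]]
  lab
}

# Integer 2-D shift with zero fill (dz rows down, dx cols right for
# positive values).
shift_matrix <- function(m, dz, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dz
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

# Draw a filled disk on a logical matrix grid (row = bscan, col = aline).
disk_mask <- function(nrow, ncol, center, radius) {
  r <- matrix(seq_len(nrow), nrow, ncol)
  c <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

# Dice similarity of two logical masks.
dice <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
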