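#' OCT intensity volume
#'
#' Container for a 4-D OCT BM-scan intensity raster indexed
#' `(bscan, repeat, depth, aline)`. Depth index 1 is the most anterior
#' (vitreous) pixel. Intensities are linear-scale and nonnegative.
#'
#' @param data nonnegative numeric 4-D array, dimensions
#'   `(n_bscans, n_repeats, n_depth, n_alines)`.
#' @param axial_scale_um axial pixel pitch in tissue, micrometres per pixel.
#' @param lateral_scale_um lateral pitch between adjacent A-lines,
#'   micrometres per pixel.
#' @param meta named list of free-form metadata (seed, provenance, ...).
#' @return an object of class `oct_volume`.
#' @examples
#' v <- oct_volume(array(0, c(2, 3, 8, 4)), 2.53, 6.25)
#' dim(v$data)
#' @export
oct_volume <- function(data, axial_scale_um, lateral_scale_um,
                       meta = list()) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4-D array (bscan, repeat, depth, aline)")
  if (any(data < 0, na.rm = TRUE))
    stop("OCT intensities must be nonnegative")
  if (!is.numeric(axial_scale_um) || axial_scale_um <= 0)
    stop("`axial_scale_um` must be > 0")
  if (!is.numeric(lateral_scale_um) || lateral_scale_um <= 0)
    stop("`lateral_scale_um` must be > 0")
  structure(
    list(data = data,
         axial_scale_um = as.numeric(axial_scale_um),
         lateral_scale_um = as.numeric(lateral_scale_um),
         meta = meta),
    class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<oct_volume> %d B-scans x %d repeats x %d depth px x %d A-lines\n",
    d[1], d[2], d[3], d[4]))
  cat(sprintf("  axial %.3f um/px (tissue), lateral %.3f um/px\n",
              x$axial_scale_um, x$lateral_scale_um))
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) dim(x$data)

# Dimension helpers
n_bscans  <- function(vol) dim(vol$data)[1L]
n_repeats <- function(vol) dim(vol$data)[2L]
n_depth   <- function(vol) dim(vol$data)[3L]
n_alines  <- function(vol) dim(vol$data)[4L]

# Coerce an oct_volume or a bare 3-D/4-D array to a 3-D structural array
# (bscan, depth, aline); 4-D input is averaged over the repeat axis.
as_structural <- function(x) {
  a <- if (inherits(x, "oct_volume")) x$data else x
  nd <- length(dim(a))
  if (nd == 3L) return(a)
  if (nd == 4L) {
    if (dim(a)[2L] == 1L) {
      d <- dim(a)
      return(array(a, d[c(1L, 3L, 4L)]))
    }
    return(average_frames(a))
  }
  stop("expected a 3-D or 4-D intensity array")
}
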