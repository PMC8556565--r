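# Volume containers on disk: multi-page 32-bit TIFF for interchange
# (one page per (bscan, repeat) B-scan, rows = depth, columns = A-lines)
# with a JSON sidecar holding dimensions, pixel scales and metadata, plus
# native .rds for lossless intermediates. TIFF storage is defined on
# [0, 1], so intensities are normalised on write (power-of-two factor,
# recorded in the sidecar) and quantized to 32 bits (~2^-32 relative).

sidecar_path <- function(path) paste0(path, ".json")

#' Write an OCT volume to disk
#'
#' `.tif`/`.tiff` writes a multi-page 32-bit TIFF (page order: repeats
#' within B-scans) plus a `<path>.json` sidecar with the raster shape,
#' pixel scales, normalisation factor and metadata. `.rds` stores the
#' object losslessly.
#'
#' @param vol an [oct_volume()].
#' @param path output file path (`.tif`, `.tiff` or `.rds`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "oct_volume"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    saveRDS(vol, path)
    return(invisible(path))
  }
  if (!ext %in% c("tif", "tiff"))
    stop("unsupported volume format: .", ext)
  d <- dim(vol$data)
  # power-of-two normalisation: the division is exact in binary floating
  # point, so repeated write/read cycles are bit-stable
  scale <- 2^ceiling(log2(max(vol$data, 1e-12)))
  pages <- vector("list", d[1] * d[2])
  k <- 0L
  for (b in seq_len(d[1])) for (r in seq_len(d[2])) {
    k <- k + 1L
    pages[[k]] <- matrix(vol$data[b, r, , ] / scale, d[3], d[4])
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- vol$meta
  meta$config <- NULL  # not serialisable as flat JSON; keep scalars only
  side <- list(n_bscans = d[1], n_repeats = d[2], n_depth = d[3],
               n_alines = d[4],
               axial_scale_um = vol$axial_scale_um,
               lateral_scale_um = vol$lateral_scale_um,
               intensity_scale = scale, meta = meta)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an OCT volume from disk
#'
#' Reverses [write_volume()]. TIFF input requires the JSON sidecar; a
#' missing or incomplete sidecar is an error naming the missing
#' attribute, and a page count disagreeing with the declared raster is a
#' parse error.
#'
#' @param path `.tif`/`.tiff` (with sidecar) or `.rds` file.
#' @return an [oct_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    vol <- readRDS(path)
    if (!inherits(vol, "oct_volume")) stop("not an oct_volume rds")
    return(vol)
  }
  if (!ext %in% c("tif", "tiff"))
    stop("unsupported volume format: .", ext)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing sidecar metadata file: ", sp)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (k in c("n_bscans", "n_repeats", "n_depth", "n_alines",
              "axial_scale_um", "lateral_scale_um", "intensity_scale"))
    if (is.null(side[[k]]))
      stop("sidecar is missing required attribute '", k, "'")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != side$n_bscans * side$n_repeats)
    stop(sprintf(
      "TIFF holds %d pages but sidecar declares %d B-scans x %d repeats",
      length(pages), side$n_bscans, side$n_repeats))
  data <- array(0, c(side$n_bscans, side$n_repeats, side$n_depth,
                     side$n_alines))
  k <- 0L
  for (b in seq_len(side$n_bscans)) for (r in seq_len(side$n_repeats)) {
    k <- k + 1L
    pg <- pages[[k]]
    if (!all(dim(pg)[1:2] == c(side$n_depth, side$n_alines)))
      stop("TIFF page dimensions disagree with the sidecar raster")
    data[b, r, , ] <- pg * side$intensity_scale
  }
  meta <- side$meta
  oct_volume(data, side$axial_scale_um, side$lateral_scale_um,
             meta = if (is.null(meta)) list() else meta)
}

#' Write segmentation boundaries to CSV
#'
#' Long format: one row per (bscan, aline, boundary) with the depth in
#' pixels and micrometres; a JSON sidecar records the ONH geometry and
#' the parameter snapshot.
#'
#' @param seg a `segmentation_result`.
#' @param path output CSV path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  stopifnot(inherits(seg, "segmentation_result"))
  rows <- lapply(names(seg$boundaries), function(nm) {
    d <- seg$boundaries[[nm]]$depth
    data.frame(bscan = as.vector(row(d)), aline = as.vector(col(d)),
               boundary = nm, depth_px = as.vector(d),
               depth_um = as.vector(d) * seg$axial_scale_um,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  write.csv(tab, path, row.names = FALSE)
  side <- list(
    onh = list(center = seg$onh$center, width_px = seg$onh$width_px),
    axial_scale_um = seg$axial_scale_um,
    params = seg$params[!vapply(seg$params, is.null, logical(1))])
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a segmentation result back from its CSV + sidecar
#'
#' Inverse of [write_segmentation()] (the parameter snapshot is restored
#' as a plain list; the validity mask is recomputed from the boundary
#' `NaN` pattern and the ONH mask).
#'
#' @param path CSV written by [write_segmentation()].
#' @return a `segmentation_result`.
#' @export
read_segmentation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.csv(path)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  nb <- max(tab$bscan); na <- max(tab$aline)
  nms <- unique(tab$boundary)
  order_ref <- c("vitreous_NFL", "NFL_IPL", "IPL_INL", "OPL",
                 "OS_anterior", "RPE_posterior")
  nms <- c(intersect(order_ref, nms), setdiff(nms, order_ref))
  b <- lapply(nms, function(nm) {
    sub <- tab[tab$boundary == nm, ]
    m <- matrix(NaN, nb, na)
    m[cbind(sub$bscan, sub$aline)] <- sub$depth_px
    boundary_surface(m, nm)
  })
  names(b) <- nms
  ctr <- unlist(side$onh$center)
  width <- side$onh$width_px
  mask <- if (!is.null(ctr) && length(ctr) == 2 && width > 0)
    disk_mask(nb, na, ctr, width / 2) else matrix(FALSE, nb, na)
  valid <- !mask
  for (nm in nms) valid <- valid & is.finite(b[[nm]]$depth)
  structure(list(boundaries = b,
                 onh = list(center = ctr, width_px = width, mask = mask),
                 valid_mask = valid, params = side$params,
                 axial_scale_um = side$axial_scale_um),
            class = "segmentation_result")
}

#' Write phantom ground truth to plain-text artifacts
#'
#' Boundaries as long-format CSV (bscan, aline, boundary_name, depth_px)
#' and the vessel/ONH masks as single-page TIFFs.
#'
#' @param truth a `phantom_truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "phantom_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(truth$boundaries), function(nm) {
    d <- truth$boundaries[[nm]]
    data.frame(bscan = as.vector(row(d)), aline = as.vector(col(d)),
               boundary_name = nm, depth_px = as.vector(d),
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), file.path(dir, "boundaries.csv"),
            row.names = FALSE)
  tiff::writeTIFF(truth$vessel_mask * 1, file.path(dir, "vessel_mask.tif"))
  tiff::writeTIFF(truth$onh_mask * 1, file.path(dir, "onh_mask.tif"))
  invisible(dir)
}

#' Render one B-scan with boundary overlays
#'
#' Grayscale B-scan with the detected boundaries drawn on top, written to
#' a PNG when `file` is given, otherwise drawn on the active device.
#'
#' @param vol3d structural array (bscan, depth, aline).
#' @param seg a `segmentation_result`.
#' @param bscan B-scan index.
#' @param file optional PNG output path.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_bscan_boundaries <- function(vol3d, seg, bscan = 1L, file = NULL) {
  stopifnot(length(dim(vol3d)) == 3L)
  img <- matrix(vol3d[bscan, , ], dim(vol3d)[2], dim(vol3d)[3])
  if (!is.null(file)) {
    grDevices::png(file, width = 720, height = 560)
    on.exit(grDevices::dev.off())
  }
  nz <- nrow(img); na <- ncol(img)
  graphics::image(x = seq_len(na), y = seq_len(nz),
                  z = t(img)[, rev(seq_len(nz))]^0.5,
                  col = grDevices::gray.colors(256, 0, 1),
                  xlab = "A-line", ylab = "depth (px)", yaxt = "n",
                  main = sprintf("B-scan %d", bscan))
  graphics::axis(2, at = pretty(seq_len(nz)),
                 labels = rev(pretty(seq_len(nz))))
  cols <- c(vitreous_NFL = "blue", NFL_IPL = "orange", IPL_INL = "yellow",
            OPL = "magenta", OS_anterior = "cyan", RPE_posterior = "green")
  for (nm in names(seg$boundaries))
    graphics::lines(seq_len(na),
                    nz + 1 - seg$boundaries[[nm]]$depth[bscan, ],
                    col = cols[[nm]], lwd = 2)
  invisible(file)
}
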