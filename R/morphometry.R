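#' Axial pixel scale in tissue
#'
#' Corrects the native axial scaling measured in air by the tissue group
#' refractive index: a 3.42 um/pixel air pitch with index 1.35 becomes
#' 2.53 um/pixel in tissue.
#'
#' @param native_um_per_px_air axial pitch in air, um/pixel.
#' @param refractive_index tissue group refractive index.
#' @return axial pitch in tissue, um/pixel.
#' @examples
#' round(axial_scale(3.42, 1.35), 2)  # 2.53
#' @export
axial_scale <- function(native_um_per_px_air, refractive_index) {
  if (native_um_per_px_air <= 0 || refractive_index <= 0)
    stop("scale and refractive index must be positive")
  native_um_per_px_air / refractive_index
}

# Boundary pairs defining each reported layer. The four layers partition
# the total retina, so their thickness maps sum to the total exactly.
LAYER_DEFINITIONS <- list(
  NFL   = c("vitreous_NFL", "NFL_IPL"),
  IPL   = c("NFL_IPL", "IPL_INL"),
  INL   = c("IPL_INL", "OPL"),
  ORL   = c("OPL", "RPE_posterior"),
  total = c("vitreous_NFL", "RPE_posterior"))

#' Thickness map between two boundary surfaces
#'
#' Subtracts the depth of the anterior boundary from the posterior one
#' and scales to micrometres. `NaN` propagates (ONH, undetected A-lines).
#'
#' @param seg a `segmentation_result` from [segment_retina()], or a named
#'   list of `boundary_surface` objects.
#' @param upper,lower boundary names; `upper` must be anatomically
#'   anterior to `lower`.
#' @param scale_um axial pixel pitch in tissue (defaults to the scale
#'   recorded in `seg`).
#' @return numeric matrix (bscan x aline) of thickness in um.
#' @export
thickness_map <- function(seg, upper, lower, scale_um = NULL) {
  bnd <- if (inherits(seg, "segmentation_result")) seg$boundaries else seg
  if (is.null(scale_um))
    scale_um <- if (inherits(seg, "segmentation_result"))
      seg$axial_scale_um else stop("scale_um required")
  if (!upper %in% names(bnd) || !lower %in% names(bnd))
    stop("unknown boundary name")
  iu <- match(upper, names(bnd)); il <- match(lower, names(bnd))
  if (iu >= il) stop(sprintf("'%s' is not anterior to '%s'", upper, lower))
  (bnd[[lower]]$depth - bnd[[upper]]$depth) * scale_um
}

#' Layer thickness maps for the standard layer set
#'
#' Convenience wrapper computing NFL, IPL, INL, ORL and total retinal
#' thickness maps from one segmentation.
#'
#' @param seg a `segmentation_result`.
#' @param scale_um optional axial pitch override, um/pixel.
#' @return named list of thickness matrices (um).
#' @export
layer_thickness_maps <- function(seg, scale_um = NULL) {
  lapply(LAYER_DEFINITIONS, function(p)
    thickness_map(seg, p[1], p[2], scale_um))
}

#' Cylindrical region of interest
#'
#' @param center_xy ROI centre, (bscan, aline) pixels.
#' @param radius_um ROI radius in micrometres (51 um is a typical
#'   choice for a developing-mouse field).
#' @param lateral_scale_um lateral pixel pitch, um.
#' @return list of class `roi_spec` (centre, radius in um and pixels).
#' @export
roi_spec <- function(center_xy, radius_um = 51, lateral_scale_um = 1) {
  if (radius_um <= 0) stop("ROI radius must be positive")
  structure(list(center_xy = center_xy, radius_um = radius_um,
                 radius_px = radius_um / lateral_scale_um),
            class = "roi_spec")
}

#' Automatic ROI placement away from vessels and the ONH
#'
#' Chooses the ROI centre deterministically as the en-face position with
#' the greatest clearance from every excluded pixel (major vessels, ONH)
#' and from the field-of-view edge, subject to the ROI disk fitting
#' entirely inside the allowed region. Ties take the smallest (bscan,
#' aline).
#'
#' @param vessels a `vessel_mask` (or logical matrix) of major vessels.
#' @param onh_mask logical ONH exclusion matrix (or `NULL`).
#' @param radius_um ROI radius, um.
#' @param lateral_scale_um lateral pixel pitch, um.
#' @return an `roi_spec` with attribute `clearance_px`.
#' @export
select_roi <- function(vessels, onh_mask = NULL, radius_um = 51,
                       lateral_scale_um = 1) {
  vm <- if (inherits(vessels, "vessel_mask")) vessels$mask else vessels
  stopifnot(is.matrix(vm))
  excl <- vm
  if (!is.null(onh_mask)) excl <- excl | onh_mask
  allowed <- matrix(1, nrow(vm) + 2L, ncol(vm) + 2L)
  allowed[1, ] <- 0; allowed[nrow(allowed), ] <- 0
  allowed[, 1] <- 0; allowed[, ncol(allowed)] <- 0
  allowed[2:(nrow(vm) + 1L), 2:(ncol(vm) + 1L)][excl] <- 0
  dm <- EBImage::imageData(EBImage::distmap(allowed))
  clearance <- dm[2:(nrow(vm) + 1L), 2:(ncol(vm) + 1L)]
  r_px <- radius_um / lateral_scale_um
  feasible <- clearance > r_px
  if (!any(feasible))
    stop("no feasible ROI centre: radius too large for the unmasked field")
  best <- max(clearance)
  cand <- which(clearance >= best - 1e-9, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  out <- roi_spec(as.numeric(cand[1, ]), radius_um, lateral_scale_um)
  attr(out, "clearance_px") <- best
  out
}

#' Mean thickness inside a cylindrical ROI
#'
#' @param map thickness matrix in um (bscan x aline).
#' @param roi an `roi_spec`.
#' @return list with `mean_um` and `n` (non-`NaN` pixels used).
#' @export
roi_thickness <- function(map, roi) {
  stopifnot(inherits(roi, "roi_spec"), is.matrix(map))
  dm <- disk_mask(nrow(map), ncol(map), roi$center_xy, roi$radius_px)
  vals <- map[dm]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("ROI contains no valid thickness pixels")
  list(mean_um = mean(vals), n = length(vals))
}

#' Annular ROIs adjacent and distal to the ONH
#'
#' Builds two concentric annuli centred on the ONH: an adjacent band of
#' width `band_um` starting at the ONH rim, and a distal band of the same
#' width ending at the field-of-view edge. Exclusion masks (vessels, ONH)
#' are removed from both. Overlapping bands are an error, mirroring the
#' exclusion of samples whose regions overlay.
#'
#' @param onh list with `center` (bscan, aline) and `width_px`, as
#'   returned in a `segmentation_result`.
#' @param band_um band width, um (default 55).
#' @param lateral_scale_um lateral pixel pitch, um.
#' @param fov_radius_px field-of-view radius around the ONH centre in
#'   pixels (defaults to the largest inscribed radius).
#' @param dim_bscan,dim_aline en-face raster dimensions.
#' @param exclude optional logical matrix removed from both bands.
#' @return list with logical `adjacent` and `distal` masks and the band
#'   radii in pixels.
#' @export
band_rois <- function(onh, band_um = 55, lateral_scale_um = 1,
                      fov_radius_px = NULL,
                      dim_bscan, dim_aline, exclude = NULL) {
  if (is.null(onh$center) || onh$width_px <= 0)
    stop("band ROIs require a located ONH")
  ctr <- onh$center
  band_px <- band_um / lateral_scale_um
  if (is.null(fov_radius_px))
    fov_radius_px <- min(ctr[1] - 1, dim_bscan - ctr[1],
                         ctr[2] - 1, dim_aline - ctr[2])
  r_onh <- onh$width_px / 2
  if (r_onh + band_px > fov_radius_px - band_px)
    stop("adjacent and distal bands overlap: field of view too small ",
         "relative to the ONH")
  b <- matrix(seq_len(dim_bscan), dim_bscan, dim_aline)
  a <- matrix(seq_len(dim_aline), dim_bscan, dim_aline, byrow = TRUE)
  r <- sqrt((b - ctr[1])^2 + (a - ctr[2])^2)
  adjacent <- r >= r_onh & r <= r_onh + band_px
  distal <- r >= fov_radius_px - band_px & r <= fov_radius_px
  if (!is.null(exclude)) {
    adjacent <- adjacent & !exclude
    distal <- distal & !exclude
  }
  list(adjacent = adjacent, distal = distal,
       radii_px = c(adjacent_inner = r_onh,
                    adjacent_outer = r_onh + band_px,
                    distal_inner = fov_radius_px - band_px,
                    distal_outer = fov_radius_px))
}

#' Mean thickness difference between distal and adjacent bands
#'
#' @param total_map total retinal thickness matrix, um.
#' @param adjacent,distal logical band masks from [band_rois()].
#' @return list with `mean_adjacent`, `mean_distal` and
#'   `difference_um = distal - adjacent`.
#' @export
band_difference <- function(total_map, adjacent, distal) {
  va <- total_map[adjacent]; va <- va[is.finite(va)]
  vd <- total_map[distal];   vd <- vd[is.finite(vd)]
  if (length(va) == 0L) stop("adjacent band holds no valid pixels")
  if (length(vd) == 0L) stop("distal band holds no valid pixels")
  list(mean_adjacent = mean(va), mean_distal = mean(vd),
       difference_um = mean(vd) - mean(va))
}

#' Long-format thickness table for one segmented sample
#'
#' Measures every standard layer in each supplied ROI and returns records
#' ready for group statistics (one row per sample, layer and ROI).
#'
#' @param seg a `segmentation_result`.
#' @param rois list of `roi_spec` objects (named or not).
#' @param sample_id sample identifier.
#' @param age_label developmental time point label (e.g. `"P7"`).
#' @param scale_um optional axial pitch override.
#' @return data.frame with columns sample_id, age_label, layer, roi_id,
#'   thickness_um, n_alines.
#' @export
thickness_table <- function(seg, rois, sample_id = "sample",
                            age_label = NA_character_, scale_um = NULL) {
  maps <- layer_thickness_maps(seg, scale_um)
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  ids <- names(rois)
  if (is.null(ids)) ids <- sprintf("roi%d", seq_along(rois))
  rows <- list()
  for (i in seq_along(rois)) {
    for (layer in names(maps)) {
      m <- roi_thickness(maps[[layer]], rois[[i]])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, age_label = age_label, layer = layer,
        roi_id = ids[i], thickness_um = m$mean_um, n_alines = m$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
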