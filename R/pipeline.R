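# End-to-end workflow: simulate -> preprocess -> angiography -> segment
# -> quantify -> stats, driven by a structured-text (YAML) configuration.

pipeline_schema <- function() {
  list(
    seed = NULL, out_dir = NULL,
    stages = c("simulate", "preprocess", "angio", "segment",
               "quantify", "stats"),
    phantom = setdiff(names(formals(phantom_config)), "seed"),
    preprocess = c("background_subtract", "rolloff_decay", "register"),
    angiography = c("motion_robust", "k_sd", "min_area"),
    segmentation = names(formals(segmentation_params)),
    morphometry = c("roi_radius_um", "band_um", "bands"),
    sample = c("id", "age_label"))
}

#' Read and validate a pipeline configuration
#'
#' Loads a YAML configuration and validates it against the pipeline
#' schema; unknown keys at any level are rejected by name.
#'
#' @param path YAML file path, or a list already in memory.
#' @return validated configuration list of class `pipeline_config`.
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  schema <- pipeline_schema()
  extra <- setdiff(names(cfg), names(schema))
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  for (section in names(schema)) {
    allowed <- schema[[section]]
    if (is.null(allowed) || is.null(cfg[[section]])) next
    bad <- setdiff(names(cfg[[section]]), allowed)
    if (length(bad))
      stop(sprintf("unknown keys in section '%s': %s", section,
                   paste(bad, collapse = ", ")))
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$out_dir)) cfg$out_dir <- "octmorph_out"
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(cfg), f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order on a simulated phantom:
#' simulation, preprocessing (background subtraction, roll-off
#' correction, B-scan registration, frame averaging), motion-robust
#' speckle-variance angiography with vessel masking, layer segmentation,
#' ROI thickness quantification (plus ONH band analysis when an ONH is
#' present), and group summaries. Artifacts are written under
#' `config$out_dir`; a `manifest.json` records the configuration hash,
#' stage timings and produced files.
#'
#' @param config a `pipeline_config`, a YAML path, or a plain list.
#' @return invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
  else read_config(config)
  hash <- config_hash(cfg)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages %||%
    c("simulate", "preprocess", "angio", "segment", "quantify", "stats")
  timings <- list(); files <- character(0)
  tic <- function() proc.time()[["elapsed"]]
  res <- list(config_hash = hash)

  # --- simulate ------------------------------------------------------
  t0 <- tic()
  pcfg <- do.call(phantom_config,
                  c(cfg$phantom %||% list(), list(seed = cfg$seed)))
  ph <- make_phantom(pcfg)
  bg <- make_background(pcfg)
  if ("simulate" %in% stages) {
    write_volume(ph$volume, file.path(out, "volume.tif"))
    write_phantom_truth(ph$truth, file.path(out, "truth"))
    files <- c(files, "volume.tif", "truth/boundaries.csv")
  }
  timings$simulate <- tic() - t0
  vol <- ph$volume

  # --- preprocess ----------------------------------------------------
  t0 <- tic()
  pp <- cfg$preprocess %||% list()
  if (isTRUE(pp$background_subtract %||% TRUE))
    vol <- subtract_background(vol, bg)
  decay <- pp$rolloff_decay %||% pcfg$rolloff_decay
  vol <- correct_rolloff(vol, decay)
  if (isTRUE(pp$register %||% TRUE)) {
    reg <- register_bscans(vol)
    vol <- reg$registered
    write.csv(data.frame(bscan = seq_len(nrow(reg$shifts)), reg$shifts),
              file.path(out, "registration_shifts.csv"), row.names = FALSE)
    files <- c(files, "registration_shifts.csv")
  }
  structural <- average_frames(vol)
  timings$preprocess <- tic() - t0

  # --- segment (needed before angio en-face windowing) ---------------
  t0 <- tic()
  sparams <- do.call(segmentation_params, cfg$segmentation %||% list())
  seg <- segment_retina(structural, sparams,
                        axial_scale_um = vol$axial_scale_um)
  if ("segment" %in% stages) {
    write_segmentation(seg, file.path(out, "boundaries.csv"))
    files <- c(files, "boundaries.csv")
  }
  timings$segment <- tic() - t0
  res$segmentation <- seg

  # --- angiography ---------------------------------------------------
  t0 <- tic()
  acfg <- cfg$angiography %||% list()
  angio <- if (isTRUE(acfg$motion_robust %||% TRUE) && n_repeats(vol) >= 3L)
    motion_robust_variance(vol) else speckle_variance(vol)
  # en-face over the NFL depth band (vessels live in the superficial
  # plexus): median vitreous surface to median NFL posterior estimate
  v0 <- median(seg$boundaries$vitreous_NFL$depth, na.rm = TRUE)
  zwin <- c(max(1, floor(v0)),
            min(n_depth(vol), ceiling(v0 + 2 * sparams$nfl_prior_um /
                                        vol$axial_scale_um)))
  ef <- enface_projection(angio$variance, zwin)
  vmask <- vessel_mask(ef, k_sd = acfg$k_sd %||% 2,
                       min_area = acfg$min_area %||% 5L)
  if ("angio" %in% stages) {
    tiff::writeTIFF(ef / max(ef, 1e-12), file.path(out, "angio_enface.tif"))
    tiff::writeTIFF(vmask$mask * 1, file.path(out, "vessel_mask.tif"))
    files <- c(files, "angio_enface.tif", "vessel_mask.tif")
  }
  timings$angio <- tic() - t0
  res$angio <- angio; res$vessel_mask <- vmask

  # --- quantify ------------------------------------------------------
  if ("quantify" %in% stages) {
    t0 <- tic()
    mcfg <- cfg$morphometry %||% list()
    roi <- select_roi(vmask, seg$onh$mask,
                      radius_um = mcfg$roi_radius_um %||% 51,
                      lateral_scale_um = vol$lateral_scale_um)
    sample <- cfg$sample %||% list()
    tab <- thickness_table(seg, list(roi = roi),
                           sample_id = sample$id %||% "phantom",
                           age_label = sample$age_label %||% NA_character_)
    if (isTRUE(mcfg$bands %||% FALSE) && seg$onh$width_px > 0) {
      bands <- band_rois(seg$onh, band_um = mcfg$band_um %||% 55,
                         lateral_scale_um = vol$lateral_scale_um,
                         dim_bscan = n_bscans(vol),
                         dim_aline = n_alines(vol),
                         exclude = vmask$mask)
      total <- layer_thickness_maps(seg)$total
      bd <- band_difference(total, bands$adjacent, bands$distal)
      jsonlite::write_json(c(bd, list(config_hash = hash)),
                           file.path(out, "band_difference.json"),
                           auto_unbox = TRUE, digits = NA)
      files <- c(files, "band_difference.json")
      res$band_difference <- bd
    }
    write.csv(tab, file.path(out, "thickness.csv"), row.names = FALSE)
    files <- c(files, "thickness.csv")
    timings$quantify <- tic() - t0
    res$thickness <- tab
  }

  # --- stats ---------------------------------------------------------
  if ("stats" %in% stages && !is.null(res$thickness)) {
    t0 <- tic()
    sm <- summarize_groups(res$thickness)
    sm$outliers <- vapply(sm$outliers, function(v)
      paste(signif(v, 6), collapse = ";"), character(1))
    write.csv(sm, file.path(out, "summary.csv"), row.names = FALSE)
    files <- c(files, "summary.csv")
    timings$stats <- tic() - t0
    res$summary <- sm
  }

  manifest <- list(config_hash = hash, stages = stages,
                   timings_s = timings, files = files)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
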