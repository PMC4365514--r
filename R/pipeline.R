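#' Validate a run configuration
#'
#' Report-only check of a scene/run configuration: NDVI threshold range,
#' campaigns lacking an air temperature although flagged as thermal,
#' duplicated campaign ids, missing referenced files. Collects every
#' problem instead of stopping at the first.
#'
#' @param cfg A [scene_config()].
#' @param ndvi_threshold Segmentation threshold to be used with this run.
#' @param paths Optional character vector of file paths the run will read.
#' @return Data frame with columns `level` (`"error"`/`"warning"`) and
#'   `message`; zero rows when the configuration is clean.
#' @export
validate_config <- function(cfg, ndvi_threshold = 0.1, paths = character(0)) {
  probs <- list()
  add <- function(level, msg) probs[[length(probs) + 1L]] <<-
    data.frame(level = level, message = msg, stringsAsFactors = FALSE)
  if (!inherits(cfg, "scene_config")) {
    add("error", "cfg is not a scene_config")
  } else {
    camps <- cfg$campaigns
    if (anyDuplicated(camps$campaign_id))
      add("error", "duplicate campaign ids")
    for (i in seq_len(nrow(camps))) {
      if (isTRUE(camps$has_ir[i]) && !is.finite(camps$air_temp[i]))
        add("error", sprintf(
          "campaign %s: thermal sensor present but no air temperature; dT uncomputable",
          camps$campaign_id[i]))
    }
    if (!is.finite(cfg$intensity_threshold) || cfg$intensity_threshold < 0 ||
        cfg$intensity_threshold > 1)
      add("error", "intensity_threshold outside [0, 1]")
  }
  if (!is.finite(ndvi_threshold) || ndvi_threshold <= -1 || ndvi_threshold >= 1)
    add("error", sprintf("ndvi_threshold %.3g outside (-1, 1)", ndvi_threshold))
  for (p in paths) if (!file.exists(p))
    add("error", sprintf("missing file: %s", p))
  if (!length(probs))
    return(data.frame(level = character(0), message = character(0)))
  do.call(rbind, probs)
}

#' Register one sensor image against the AoI marker layout
#'
#' Detects the circular markers, matches them to the known AoI-frame
#' marker positions by cyclic order, and fits the projective transform
#' sensor -> AoI. Thermal images are up-scaled to the common resolution
#' first (bright polarity detection); optical images use the blue channel
#' with dark polarity.
#'
#' @param img A [sensor_image()].
#' @param markers_aoi `n x 2` matrix of AoI (row, col) marker positions.
#' @param ground_pixel_m Ground pixel of this sensor (m).
#' @param aoi_ground_pixel_m Ground pixel of the common frame (m).
#' @param marker_diameter_m Physical marker diameter (m).
#' @param thermal Is this the thermal sensor?
#' @param overrides Optional list of manual marker observations replacing
#'   the automatic detections (already in AoI marker order).
#' @return List: `model` ([fit_projective()] result), `markers` (matched
#'   detections, AoI order), `image` (the possibly up-scaled image whose
#'   frame the model maps from).
#' @export
register_sensor <- function(img, markers_aoi, ground_pixel_m,
                            aoi_ground_pixel_m, marker_diameter_m = 0.7,
                            thermal = FALSE, overrides = NULL) {
  work <- img
  if (thermal) {
    f <- ground_pixel_m / aoi_ground_pixel_m
    work <- upscale_thermal(img, ceiling(dim(img)[1:2] * f))
    eff_px <- aoi_ground_pixel_m
  } else {
    eff_px <- ground_pixel_m
  }
  r_px <- marker_diameter_m / 2 / eff_px
  if (is.null(overrides)) {
    det <- detect_markers(work, polarity = if (thermal) "bright" else "dark",
                          expected_radius_px = c(0.55 * r_px, 1.7 * r_px),
                          max_markers = nrow(markers_aoi) + 4L)
    det <- match_markers(det, markers_aoi)
  } else {
    det <- overrides
  }
  centers <- t(vapply(det, `[[`, numeric(2), "center"))
  model <- fit_projective(centers, markers_aoi)
  list(model = model, markers = det, image = work)
}

#' Run the full analysis pipeline on a simulated trial
#'
#' Orchestrates simulate -> register -> segment -> extract (-> stats) for
#' every requested campaign: renders the three field sub-arrays per
#' campaign, registers each sensor to the AoI frame via the markers,
#' warps with bicubic interpolation, computes the blue-band NDVI and the
#' two-step segmentation mask, rasterizes the plot map and extracts the
#' per-plot traits. Failures are isolated per campaign: the failing
#' campaign is recorded and the run continues. Writes `design.csv`,
#' `truth.csv`, `traits.csv` and a checksum manifest to `out_dir`; the
#' run is deterministic, so re-running reproduces identical files.
#'
#' @param cfg A [scene_config()].
#' @param out_dir Output directory (created if missing).
#' @param campaigns Campaign ids to process (default: all in `cfg`).
#' @param ndvi_threshold Plant NDVI threshold (default 0.1).
#' @param with_stats Also compute the repeatability profile for canopy
#'   cover and write `repeatability_cc.csv`.
#' @param ncc_check Cross-check optical/thermal marker positions against
#'   the B+NIR template by normalized cross-correlation and warn on
#'   offsets above 2 px.
#' @return List of class `run_result`: `records` (trait rows), `truth`,
#'   `design`, `campaign_table` (long format), `registration` (per
#'   campaign/sub-array/sensor rmse and marker count), `errors`,
#'   `manifest`.
#' @export
run_pipeline <- function(cfg = scene_config(), out_dir = tempfile("run"),
                         campaigns = NULL, ndvi_threshold = 0.1,
                         with_stats = FALSE, ncc_check = TRUE) {
  report <- validate_config(cfg, ndvi_threshold)
  if (any(report$level == "error"))
    stop(paste(c("invalid configuration:", report$message), collapse = "\n  "),
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- generate_design(cfg)
  profiles <- genotype_profiles(cfg)
  truth <- simulate_traits(design, profiles, cfg)
  if (is.null(campaigns)) campaigns <- cfg$campaigns$campaign_id
  g0 <- cfg$ground_pixel["bnir"]
  seg_cfg <- segmentation_config(ndvi_threshold = ndvi_threshold,
                                 intensity_threshold = cfg$intensity_threshold)
  records <- list(); reg_rows <- list(); errors <- list()
  for (cid in campaigns) {
    rec_c <- tryCatch({
      camp_rows <- list()
      for (sa in 1:3) {
        scn <- render_scene(design, truth, cid, cfg, sub_array = sa)
        sub_sel <- design$sub_array == sa
        reg <- list()
        for (sn in names(scn$images)) {
          reg[[sn]] <- register_sensor(
            scn$images[[sn]], scn$markers_aoi,
            ground_pixel_m = cfg$ground_pixel[sn],
            aoi_ground_pixel_m = g0,
            marker_diameter_m = cfg$marker_diameter,
            thermal = sn == "ir")
          reg_rows[[length(reg_rows) + 1L]] <- data.frame(
            campaign_id = cid, sub_array = sa, sensor = sn,
            n_markers = length(reg[[sn]]$markers),
            rmse = reg[[sn]]$model$rmse, stringsAsFactors = FALSE)
        }
        if (ncc_check && all(c("bnir", "rgb") %in% names(reg))) {
          check_marker_consistency(reg$bnir, reg$rgb, cid, sa)
        }
        wb <- warp_to_aoi(reg$bnir$image, reg$bnir$model, scn$aoi_shape)
        ndvi <- compute_ndvi(get_channel(wb, "B"), get_channel(wb, "NIR"),
                             campaign_id = cid)
        intensity <- (get_channel(wb, "B") + get_channel(wb, "NIR")) / 2
        mask <- segment_ndvi(ndvi, intensity, seg_cfg)
        thermal <- NULL
        if ("ir" %in% names(reg)) {
          wt <- warp_to_aoi(reg$ir$image, reg$ir$model, scn$aoi_shape)
          thermal <- get_channel(wt, "T")
          rm(wt)
        }
        labels <- rasterize_plot_map(design[sub_sel, ], scn$aoi_shape, g0)
        ci <- match(cid, cfg$campaigns$campaign_id)
        camp_rows[[sa]] <- extract_plot_traits(
          ndvi, mask, labels, thermal = thermal,
          air_temp = if (is.finite(cfg$campaigns$air_temp[ci]))
            cfg$campaigns$air_temp[ci] else NULL,
          campaign_id = cid)
        rm(scn, wb, ndvi, intensity, mask, thermal, labels, reg)
        gc(FALSE)
      }
      do.call(rbind, camp_rows)
    }, error = function(e) {
      errors[[cid]] <<- conditionMessage(e)
      warning(sprintf("campaign %s failed: %s", cid, conditionMessage(e)))
      NULL
    })
    if (!is.null(rec_c)) records[[cid]] <- rec_c
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  long <- seasonal_table(records, design,
                         data.frame(campaign_id = cfg$campaigns$campaign_id,
                                    tt = cfg$campaigns$tt))
  files <- character(0)
  write_det_csv <- function(d, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(d, p, row.names = FALSE)
    files <<- c(files, p)
    p
  }
  write_det_csv(design, "design.csv")
  write_det_csv(truth, "truth.csv")
  write_det_csv(records, "traits.csv")
  if (with_stats) {
    rp <- repeatability_profile(long[long$trait == "cc", ], "cc")
    write_det_csv(rp, "repeatability_cc.csv")
  }
  manifest <- list(
    seed = cfg$seed,
    campaigns = campaigns,
    ndvi_threshold = ndvi_threshold,
    intensity_threshold = cfg$intensity_threshold,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(list(records = records, truth = truth, design = design,
                 campaign_table = long,
                 registration = do.call(rbind, reg_rows),
                 errors = errors, manifest = manifest, out_dir = out_dir),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %d trait rows, %d campaigns, %d failed\n",
              nrow(x$records), length(unique(x$records$campaign_id)),
              length(x$errors)))
  invisible(x)
}

# NCC cross-check of marker consistency between the B+NIR template image
# and another optical sensor; offsets above tol flag suspect markers
check_marker_consistency <- function(reg_bnir, reg_other, cid, sa, tol = 3) {
  for (i in seq_along(reg_bnir$markers)) {
    res <- tryCatch(
      refine_by_ncc(reg_bnir$image, reg_other$image, reg_bnir$markers[[i]],
                    search_center = reg_other$markers[[i]]$center,
                    window_px = max(6L, round(reg_bnir$markers[[i]]$radius)),
                    slack_px = 4L),
      error = function(e) NULL)
    if (is.null(res)) next
    off <- res$center - round(reg_other$markers[[i]]$center)
    if (sqrt(sum(off^2)) > tol)
      warning(sprintf(
        "campaign %s sub-array %d: marker %d inconsistent between sensors (offset %.1f px); consider a manual override",
        cid, sa, i, sqrt(sum(off^2))))
  }
  invisible(NULL)
}

#' Write rendered scenes to disk as TIFF fixtures
#'
#' Writes, for each requested campaign and sub-array, the per-sensor
#' TIFFs (16-bit optical, 32-bit float thermal), the true homographies
#' (JSON) and the AoI marker positions (CSV), plus `design.csv` and
#' `truth.csv` -- the file-based interface for inspecting scenes or
#' feeding external tools.
#'
#' @param cfg A [scene_config()].
#' @param out_dir Output directory.
#' @param campaigns Campaign ids (default: first campaign only).
#' @return Invisibly, the manifest of written files.
#' @export
write_scene_fixtures <- function(cfg = scene_config(), out_dir,
                                 campaigns = cfg$campaigns$campaign_id[1]) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- generate_design(cfg)
  profiles <- genotype_profiles(cfg)
  truth <- simulate_traits(design, profiles, cfg)
  utils::write.csv(design, file.path(out_dir, "design.csv"), row.names = FALSE)
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  files <- c("design.csv", "truth.csv")
  for (cid in campaigns) {
    for (sa in 1:3) {
      scn <- render_scene(design, truth, cid, cfg, sub_array = sa)
      base <- sprintf("%s_sa%d", cid, sa)
      for (sn in names(scn$images)) {
        f <- sprintf("%s_%s.tif", base, sn)
        write_sensor_tiff(scn$images[[sn]], file.path(out_dir, f))
        files <- c(files, f)
      }
      jsonlite::write_json(
        lapply(scn$h_true, function(H) unclass(H)),
        file.path(out_dir, sprintf("%s_h_true.json", base)),
        digits = NA)
      mk <- as.data.frame(scn$markers_aoi)
      mk$marker_id <- seq_len(nrow(mk))
      utils::write.csv(mk, file.path(out_dir, sprintf("%s_markers.csv", base)),
                       row.names = FALSE)
      files <- c(files, sprintf("%s_h_true.json", base),
                 sprintf("%s_markers.csv", base))
    }
  }
  invisible(files)
}
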