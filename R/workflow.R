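#' Load a run configuration
#'
#' A single YAML or JSON file describes one correlation run: input paths,
#' transform models, detection parameters per stage, and the seed. CLI
#' flags (see `inst/cli/cryoclem`) override file values. Defaults are
#' filled for anything omitted.
#'
#' @param x path to a YAML/JSON file, or a named list.
#' @return A `run_config` list.
#' @export
load_config <- function(x) {
  cfg <- if (is.character(x)) {
    if (!file.exists(x)) stop("load_config: no such file: ", x)
    if (tolower(tools::file_ext(x)) %in% c("yml", "yaml")) yaml::read_yaml(x)
    else jsonlite::fromJSON(x, simplifyDataFrame = FALSE)
  } else x
  defaults <- list(
    seed = 1L,
    out_dir = "correlate_out",
    pixel_sizes = list(fm = 160, montage = 4, tomogram = 0.5432),
    channel_shift = list(model = "affine"),
    coarse = list(model = "similarity", bead_diameter_nm = 200,
                  fm_spot_diameter_nm = 400, threshold = 0.25,
                  max_dist_px = 15, robust = FALSE),
    fine = list(model = "similarity", gold_diameter_nm = 50,
                threshold = 0.35, max_dist_px = 25,
                search_halfwidth_px = 300, max_candidates = 30, robust = FALSE),
    overlay = TRUE, verbose = TRUE)
  cfg <- utils::modifyList(defaults, cfg)
  class(cfg) <- "run_config"
  cfg
}

.cfg_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  flat <- cfg[order(names(cfg))]
  jsonlite::write_json(flat, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, hint, verbose, expr) {
  if (verbose) message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s\n  hint: %s", name,
                 conditionMessage(e), hint), call. = FALSE))
}

.detect_points <- function(plane, diameter_nm, polarity, threshold) {
  det <- detect_fiducials(plane, detection_params(
    expected_diameter_nm = diameter_nm, pixel_size_nm = plane$pixel_size_nm,
    polarity = polarity, threshold = threshold))
  as.matrix(det[, c("x", "y")])
}

#' Run the full correlation workflow
#'
#' Executes the three-step correlation: (optional) channel-shift
#' correction from calibration bead lists, the coarse
#' fluorescence-to-montage stage on 200 nm beads, the fine
#' montage-to-tomogram stage on 50 nm gold, chaining, optional overlay
#' rendering, and a machine-readable report. Each stage either consumes
#' user-picked point CSVs or detects markers in the configured images.
#'
#' @param config a `run_config` (see [load_config()]), or a path to one.
#' @return The report list (also written to `<out_dir>/report.json`),
#'   with the fitted `chain` attached as attribute `"chain"`.
#' @export
run_workflow <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else load_config(config)
  v <- isTRUE(cfg$verbose)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  # channel shift ---------------------------------------------------------
  shift <- NULL
  if (!is.null(cfg$channel_shift$ref_points)) {
    shift <- .stage("channel-shift", "check the calibration bead CSVs pair the same beads in order", v, {
      ref <- read_points(cfg$channel_shift$ref_points)
      mov <- read_points(cfg$channel_shift$moving_points)
      estimate_channel_shift(ref, mov, model = cfg$channel_shift$model)
    })
  }

  # coarse stage: FM (PSD95 frame) -> montage -----------------------------
  coarse <- .stage("coarse", "supply coarse$fm_points/em_points CSVs or fm_bead_image + montage_image for detection", v, {
    fm_pts <- if (!is.null(cfg$coarse$fm_points)) {
      read_points(cfg$coarse$fm_points)$points
    } else {
      plane <- read_image(cfg$inputs$fm_bead_image, cfg$pixel_sizes$fm, "fm_beads")
      pts <- .detect_points(plane, cfg$coarse$fm_spot_diameter_nm, "bright",
                            cfg$coarse$threshold)
      if (!is.null(shift)) pts <- apply_transform(shift$transform, pts)
      pts
    }
    em_pts <- if (!is.null(cfg$coarse$em_points)) {
      read_points(cfg$coarse$em_points)$points
    } else {
      plane <- read_image(cfg$inputs$montage_image, cfg$pixel_sizes$montage, "montage")
      .detect_points(plane, cfg$coarse$bead_diameter_nm, "dark", cfg$coarse$threshold)
    }
    m <- match_correspondences(fm_pts, em_pts, initial = NULL,
                               max_dist_px = cfg$coarse$max_dist_px)
    if (isTRUE(cfg$coarse$robust))
      estimate_transform_robust(m$correspondences, cfg$coarse$model,
                                inlier_threshold_px = cfg$coarse$max_dist_px,
                                seed = cfg$seed,
                                source_frame = "fm", target_frame = "montage")
    else estimate_transform(m$correspondences, cfg$coarse$model,
                            source_frame = "fm", target_frame = "montage")
  })

  # fine stage: montage -> tomogram projection ----------------------------
  fine <- .stage("fine", "supply fine$em_points/tomo_points CSVs or montage_image + tomo_projection_image (or tomogram) for detection", v, {
    em_pts <- if (!is.null(cfg$fine$em_points)) {
      read_points(cfg$fine$em_points)$points
    } else {
      plane <- read_image(cfg$inputs$montage_image, cfg$pixel_sizes$montage, "montage")
      # gold is picked near the tomogram area: crop around the mapped probe
      ctr <- if (!is.null(cfg$probe$fm_points)) {
        pp <- read_points(cfg$probe$fm_points)$points
        colMeans(apply_transform(coarse$transform, pp))
      } else (dim(plane$pixels)[2:1] - 1) / 2
      hw <- cfg$fine$search_halfwidth_px
      r0 <- max(1, round(ctr[2]) + 1 - hw); r1 <- min(nrow(plane$pixels), round(ctr[2]) + 1 + hw)
      c0 <- max(1, round(ctr[1]) + 1 - hw); c1 <- min(ncol(plane$pixels), round(ctr[1]) + 1 + hw)
      crop <- image_plane(plane$pixels[r0:r1, c0:c1], plane$pixel_size_nm, "montage")
      det <- detect_fiducials(crop, detection_params(
        cfg$fine$gold_diameter_nm, crop$pixel_size_nm, "dark", cfg$fine$threshold))
      # keep the strongest candidates: gold outscores bead-edge responses
      # at the gold scale, and matching wants small sets
      det <- utils::head(det, cfg$fine$max_candidates)
      pts <- as.matrix(det[, c("x", "y")])
      pts[, 1] <- pts[, 1] + (c0 - 1); pts[, 2] <- pts[, 2] + (r0 - 1)
      pts
    }
    tomo_pts <- if (!is.null(cfg$fine$tomo_points)) {
      read_points(cfg$fine$tomo_points)$points
    } else {
      proj <- if (!is.null(cfg$inputs$tomo_projection_image)) {
        read_image(cfg$inputs$tomo_projection_image, cfg$pixel_sizes$tomogram, "tomogram")
      } else {
        stack <- read_image(cfg$inputs$tomogram, cfg$pixel_sizes$tomogram, "tomogram")
        zproject(stack, "min")
      }
      det <- detect_fiducials(proj, detection_params(
        cfg$fine$gold_diameter_nm, proj$pixel_size_nm, "dark", cfg$fine$threshold))
      as.matrix(utils::head(det, cfg$fine$max_candidates)[, c("x", "y")])
    }
    m <- match_correspondences(em_pts, tomo_pts, initial = NULL,
                               max_dist_px = cfg$fine$max_dist_px)
    if (isTRUE(cfg$fine$robust))
      estimate_transform_robust(m$correspondences, cfg$fine$model,
                                inlier_threshold_px = cfg$fine$max_dist_px,
                                seed = cfg$seed,
                                source_frame = "montage", target_frame = "tomogram")
    else estimate_transform(m$correspondences, cfg$fine$model,
                            source_frame = "montage", target_frame = "tomogram")
  })

  chain <- .stage("chain", "coarse and fine stages must share the montage frame", v,
                  build_chain(shift, coarse, fine))

  probe_out <- NULL
  if (!is.null(cfg$probe$fm_points)) {
    pp <- read_points(cfg$probe$fm_points)$points
    mapped <- map_through_chain(chain, pp)
    probe_out <- data.frame(fm_x = pp[, 1], fm_y = pp[, 2],
                            tomo_x = mapped[, 1], tomo_y = mapped[, 2])
  }

  if (isTRUE(cfg$overlay) && !is.null(cfg$inputs$fm_psd_image) &&
      !is.null(cfg$inputs$montage_image)) {
    .stage("overlay", "overlay needs fm_psd_image and montage_image", v, {
      em <- read_image(cfg$inputs$montage_image, cfg$pixel_sizes$montage, "montage")
      fm <- read_image(cfg$inputs$fm_psd_image, cfg$pixel_sizes$fm, "fm", "PSD95")
      rgb <- compose_overlay(em, list(list(plane = fm, transform = coarse$transform,
                                           color = "green")))
      tiff::writeTIFF(rgb, file.path(cfg$out_dir, "overlay_montage.tif"),
                      bits.per.sample = 32L)
    })
  }

  reg_summary <- function(r) list(
    model = r$transform$model,
    n_points = length(r$correspondences),
    matrix = as.numeric(t(r$transform$matrix)), offset = r$transform$offset,
    fre_rms_px = r$fre_rms_px,
    loo_tre_mean_px = if (is.null(r$loo_tre_px)) NA else mean(r$loo_tre_px, na.rm = TRUE))
  report <- list(
    package_version = as.character(utils::packageVersion("cryoclem")),
    seed = cfg$seed,
    config_hash = .cfg_hash(cfg),
    timestamp = format(Sys.time(), tz = "UTC"),
    channel_shift = if (is.null(shift)) NULL else reg_summary(shift),
    coarse = reg_summary(coarse),
    fine = reg_summary(fine),
    fm_to_tomogram = list(matrix = as.numeric(t(chain$fm_to_tomogram$matrix)),
                          offset = chain$fm_to_tomogram$offset),
    predicted_error_tomo_px = chain$predicted_error_px,
    probe = probe_out)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_transform(chain$fm_to_tomogram, file.path(cfg$out_dir, "fm_to_tomogram.json"))
  attr(report, "chain") <- chain
  invisible(report)
}
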