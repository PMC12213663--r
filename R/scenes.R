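#' Specification of a synthetic multi-scale correlation scene
#'
#' Emulates the imaging hierarchy of a bead-and-gold cryo-CLEM experiment:
#' a fluorescence frame (PSD95 channel plus a bead channel offset by a
#' chromatic shift), a mid-magnification EM montage, and a tomogram frame,
#' linked by ground-truth similarity transforms. 200 nm beads appear in
#' the fluorescence and montage frames, 50 nm gold in the montage and
#' tomogram frames, 10 nm gold (the tilt-alignment tracer) in the tomogram
#' frame only.
#'
#' @param seed integer; every random choice in the scene flows from it.
#' @param fm_pixel_nm,montage_pixel_nm,tomo_pixel_nm pixel sizes of the
#'   three frames (nm/px).
#' @param fm_size,montage_size,tomo_size image sizes in pixels
#'   (square frames).
#' @param tomo_nz number of z slices when a 3D tomogram is rendered.
#' @param n_beads number of 200 nm beads; `NULL` draws uniformly from
#'   8-15, the usual count for the coarse stage.
#' @param n_gold50 number of 50 nm gold particles; `NULL` draws from 6-15,
#'   the usual count for the fine stage.
#' @param n_gold10 number of 10 nm tracer gold particles.
#' @param n_psd number of PSD95 puncta.
#' @param n_chanbeads number of multicolor calibration beads for the
#'   channel-shift stage.
#' @param noise_sigma relative noise level (0 = noiseless rendering);
#'   Gaussian read noise with sd `noise_sigma * amplitude` plus Poisson
#'   shot noise in the fluorescence channels.
#' @param psf_fwhm_nm fluorescence PSF full width at half maximum; with the
#'   0.8 NA air objective this is ~400 nm, so 200 nm beads render as
#'   PSF-limited spots.
#' @param bead_diameter_nm,gold50_nm,gold10_nm marker diameters.
#' @param bead_min_sep_nm,gold50_min_sep_nm minimum center separations
#'   enforced during placement.
#' @param scale_jitter relative jitter of the inter-frame magnification
#'   around the pixel-size ratio.
#' @export
scene_spec <- function(seed,
                       fm_pixel_nm = 160, montage_pixel_nm = 4.0,
                       tomo_pixel_nm = 0.5432,
                       fm_size = 96L, montage_size = 2048L, tomo_size = 2048L,
                       tomo_nz = 48L,
                       n_beads = NULL, n_gold50 = NULL, n_gold10 = 20L,
                       n_psd = 1L, n_chanbeads = 20L,
                       noise_sigma = 0, psf_fwhm_nm = 400,
                       bead_diameter_nm = 200, gold50_nm = 50, gold10_nm = 10,
                       bead_min_sep_nm = 1000, gold50_min_sep_nm = 150,
                       scale_jitter = 0.005) {
  stopifnot(fm_pixel_nm > 0, montage_pixel_nm > 0, tomo_pixel_nm > 0,
            noise_sigma >= 0, psf_fwhm_nm > 0)
  if (!is.null(n_beads) && (n_beads < 8 || n_beads > 15))
    stop("scene_spec: n_beads must lie in [8, 15] (or NULL to draw from that range)")
  if (!is.null(n_gold50) && (n_gold50 < 6 || n_gold50 > 15))
    stop("scene_spec: n_gold50 must lie in [6, 15] (or NULL to draw from that range)")
  structure(as.list(environment()), class = "scene_spec")
}

# evaluate expr with a private RNG stream, leaving .Random.seed untouched
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.place_points <- function(n, lo, hi, min_sep, max_tries = 5000) {
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(pts) < n) {
    tries <- tries + 1
    if (tries > max_tries)
      stop(sprintf("cannot place %d markers with separation %.3g in [%.3g, %.3g] after %d tries",
                   n, min_sep, lo, hi, max_tries))
    p <- stats::runif(2, lo, hi)
    if (nrow(pts) == 0 || min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= min_sep^2)
      pts <- rbind(pts, p)
  }
  unname(pts)
}

#' Generate a ground-truth scene manifest
#'
#' Marker positions are drawn uniformly with minimum-separation rejection;
#' all per-frame coordinates are consistent with the true transforms to
#' machine precision. Deterministic for a fixed seed. Gold particles are
#' placed inside the tomogram field of view (which maps into the central
#' part of the montage), beads across the montage field, puncta inside the
#' tomogram field.
#'
#' @param spec a [scene_spec()].
#' @return A `scene_manifest`: the spec, the true transforms
#'   (`channel_shift` mapping the bead channel into the PSD95 channel,
#'   `fm_to_montage`, `montage_to_tomo`, and the composed
#'   `fm_to_tomogram`), and truth tables `beads`, `gold50`, `gold10`,
#'   `psd`, `chanbeads` with per-frame coordinates, plus a `visibility`
#'   table of marker diameters in pixels per frame.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  .with_seed(spec$seed, {
    n_beads <- if (is.null(spec$n_beads)) sample(8:15, 1) else spec$n_beads
    n_gold50 <- if (is.null(spec$n_gold50)) sample(6:15, 1) else spec$n_gold50

    ctr <- function(sz) (sz - 1) / 2
    # true transforms ------------------------------------------------------
    th1 <- stats::runif(1, -pi, pi)
    s1 <- (spec$fm_pixel_nm / spec$montage_pixel_nm) *
      (1 + stats::runif(1, -spec$scale_jitter, spec$scale_jitter))
    R1 <- matrix(c(cos(th1), sin(th1), -sin(th1), cos(th1)), 2, 2)
    off1 <- rep(ctr(spec$montage_size), 2) - s1 * as.numeric(R1 %*% rep(ctr(spec$fm_size), 2))
    fm_to_montage <- transform2d(s1 * R1, off1, "similarity", "fm", "montage")

    th2 <- stats::runif(1, -pi, pi)
    s2 <- (spec$montage_pixel_nm / spec$tomo_pixel_nm) *
      (1 + stats::runif(1, -spec$scale_jitter, spec$scale_jitter))
    R2 <- matrix(c(cos(th2), sin(th2), -sin(th2), cos(th2)), 2, 2)
    off2 <- rep(ctr(spec$tomo_size), 2) - s2 * as.numeric(R2 %*% rep(ctr(spec$montage_size), 2))
    montage_to_tomo <- transform2d(s2 * R2, off2, "similarity", "montage", "tomogram")

    # chromatic shift: bead channel -> PSD95 channel (small affine)
    thc <- stats::runif(1, -0.003, 0.003)
    sc <- 1 + stats::runif(1, -0.01, 0.01)
    Mc <- sc * matrix(c(cos(thc), sin(thc), -sin(thc), cos(thc)), 2, 2)
    Mc[1, 2] <- Mc[1, 2] + stats::runif(1, -0.002, 0.002)   # shear term
    channel_shift <- transform2d(Mc, stats::runif(2, -3, 3), "affine", "fm_beads", "fm")

    # placement ------------------------------------------------------------
    mont2fm <- invert_transform(fm_to_montage)
    tomo2mont <- invert_transform(montage_to_tomo)
    fm2tomo <- compose_transforms(montage_to_tomo, fm_to_montage)

    bead_margin <- max(60, 1.5 * spec$bead_diameter_nm / spec$montage_pixel_nm)
    beads_m <- .place_points(n_beads, bead_margin, spec$montage_size - 1 - bead_margin,
                             spec$bead_min_sep_nm / spec$montage_pixel_nm)
    gold_margin <- max(1.5 * spec$gold50_nm / spec$tomo_pixel_nm / 2 + 4,
                       min(120, 0.12 * spec$tomo_size))
    gold_t <- .place_points(n_gold50, gold_margin, spec$tomo_size - 1 - gold_margin,
                            spec$gold50_min_sep_nm / spec$tomo_pixel_nm)
    gold_m <- apply_transform(tomo2mont, gold_t)
    # keep beads clear of the gold particles in the montage
    min_cross <- (spec$bead_diameter_nm / 2 + spec$gold50_nm / 2 + 100) / spec$montage_pixel_nm
    for (k in seq_len(nrow(beads_m))) {
      tries <- 0
      while (nrow(gold_m) > 0 &&
             min((gold_m[, 1] - beads_m[k, 1])^2 + (gold_m[, 2] - beads_m[k, 2])^2) < min_cross^2) {
        tries <- tries + 1
        if (tries > 1000) stop("cannot separate beads from gold in the montage frame")
        beads_m[k, ] <- stats::runif(2, bead_margin, spec$montage_size - 1 - bead_margin)
      }
    }
    # tracer gold is kept clear of the 50 nm correlation markers (the
    # particles are dispersed to prevent clustering before freezing)
    gold10_t <- matrix(numeric(0), 0, 2)
    g10_sep <- 3 * spec$gold10_nm / spec$tomo_pixel_nm
    g10_clear <- min(100 / spec$tomo_pixel_nm, 0.1 * spec$tomo_size)
    tries <- 0
    while (nrow(gold10_t) < spec$n_gold10) {
      tries <- tries + 1
      if (tries > 5000) stop("cannot place tracer gold clear of the correlation markers")
      p <- stats::runif(2, 20, spec$tomo_size - 21)
      if (min((gold_t[, 1] - p[1])^2 + (gold_t[, 2] - p[2])^2) < g10_clear^2) next
      if (nrow(gold10_t) > 0 &&
          min((gold10_t[, 1] - p[1])^2 + (gold10_t[, 2] - p[2])^2) < g10_sep^2) next
      gold10_t <- rbind(gold10_t, p)
    }
    gold10_t <- unname(gold10_t)
    psd_margin <- min(max(400, 0.2 * spec$tomo_size), 0.35 * spec$tomo_size)
    psd_t <- .place_points(spec$n_psd, psd_margin, spec$tomo_size - 1 - psd_margin,
                           200 / spec$tomo_pixel_nm)
    cb_psd <- .place_points(spec$n_chanbeads, 6, spec$fm_size - 7, 6)

    beads_fm <- apply_transform(mont2fm, beads_m)
    fm2bead_ch <- invert_transform(channel_shift)
    beads_fmch <- apply_transform(fm2bead_ch, beads_fm)
    cb_bead <- apply_transform(fm2bead_ch, cb_psd)
    psd_fm <- apply_transform(invert_transform(fm2tomo), psd_t)
    psd_m <- apply_transform(tomo2mont, psd_t)

    vis <- data.frame(
      marker = c("bead", "bead", "gold50", "gold50", "gold10"),
      frame = c("fm", "montage", "montage", "tomogram", "tomogram"),
      diameter_px = c(max(spec$bead_diameter_nm, spec$psf_fwhm_nm) / spec$fm_pixel_nm,
                      spec$bead_diameter_nm / spec$montage_pixel_nm,
                      spec$gold50_nm / spec$montage_pixel_nm,
                      spec$gold50_nm / spec$tomo_pixel_nm,
                      spec$gold10_nm / spec$tomo_pixel_nm))
    vis$visible <- vis$diameter_px >= 1

    structure(list(
      spec = spec,
      channel_shift = channel_shift,
      fm_to_montage = fm_to_montage,
      montage_to_tomo = montage_to_tomo,
      fm_to_tomogram = fm2tomo,
      beads = data.frame(fm_x = beads_fm[, 1], fm_y = beads_fm[, 2],
                         fmch_x = beads_fmch[, 1], fmch_y = beads_fmch[, 2],
                         mont_x = beads_m[, 1], mont_y = beads_m[, 2]),
      gold50 = data.frame(mont_x = gold_m[, 1], mont_y = gold_m[, 2],
                          tomo_x = gold_t[, 1], tomo_y = gold_t[, 2]),
      gold10 = data.frame(tomo_x = gold10_t[, 1], tomo_y = gold10_t[, 2]),
      psd = data.frame(fm_x = psd_fm[, 1], fm_y = psd_fm[, 2],
                       mont_x = psd_m[, 1], mont_y = psd_m[, 2],
                       tomo_x = psd_t[, 1], tomo_y = psd_t[, 2]),
      chanbeads = data.frame(psd_x = cb_psd[, 1], psd_y = cb_psd[, 2],
                             bead_x = cb_bead[, 1], bead_y = cb_bead[, 2]),
      visibility = vis),
      class = "scene_manifest")
  })
}

#' @export
print.scene_manifest <- function(x, ...) {
  cat(sprintf("<scene_manifest seed %d> %d beads, %d gold50, %d gold10, %d puncta\n",
              x$spec$seed, nrow(x$beads), nrow(x$gold50), nrow(x$gold10), nrow(x$psd)))
  invisible(x)
}

# add radially symmetric spots onto an image; profile(r) in [0,1]
.add_spots <- function(img, centers, amplitude, profile, support) {
  H <- nrow(img); W <- ncol(img)
  for (k in seq_len(nrow(centers))) {
    cx <- centers[k, 1]; cy <- centers[k, 2]
    c0 <- max(1, floor(cx + 1 - support)); c1 <- min(W, ceiling(cx + 1 + support))
    r0 <- max(1, floor(cy + 1 - support)); r1 <- min(H, ceiling(cy + 1 + support))
    if (c0 > c1 || r0 > r1) next
    xs <- (c0:c1) - 1; ys <- (r0:r1) - 1
    r <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amplitude * profile(r)
  }
  img
}

#' Render the fluorescence channels of a scene
#'
#' Markers render as Gaussian spots of PSF-limited size sampled at pixel
#' centers. With `noise_sigma = 0` the image is exact (spot maxima at the
#' true sub-pixel positions); otherwise Poisson shot noise plus Gaussian
#' read noise of sd `noise_sigma * amplitude` is applied. Intensities are
#' kept inside a 16-bit-compatible range.
#'
#' @param manifest a `scene_manifest`.
#' @param channel `"psd95"` (puncta, the reference channel) or `"beads"`
#'   (200 nm beads, offset by the true chromatic shift).
#' @param amplitude,background photon counts of spot peak and background.
#' @return An [image_plane()] in the `"fm"` (or `"fm_beads"`) frame.
#' @export
render_fm <- function(manifest, channel = c("psd95", "beads"),
                      amplitude = 2000, background = 200) {
  channel <- match.arg(channel)
  spec <- manifest$spec
  sigma <- max(spec$bead_diameter_nm, spec$psf_fwhm_nm) / 2.3548 / spec$fm_pixel_nm
  centers <- if (channel == "psd95")
    cbind(manifest$psd$fm_x, manifest$psd$fm_y)
  else cbind(manifest$beads$fmch_x, manifest$beads$fmch_y)
  img <- matrix(background, spec$fm_size, spec$fm_size)
  img <- .add_spots(img, centers, amplitude,
                    function(r) exp(-r^2 / (2 * sigma^2)), ceiling(5 * sigma))
  img <- .apply_fm_noise(img, spec$noise_sigma * amplitude)
  image_plane(img, spec$fm_pixel_nm,
              frame_id = if (channel == "psd95") "fm" else "fm_beads",
              channel = if (channel == "psd95") "PSD95" else "beads")
}

#' Render the channel-shift calibration bead field
#'
#' The same multicolor beads seen in the reference (PSD95) and moving
#' (bead) channel, separated by the true chromatic shift.
#'
#' @inheritParams render_fm
#' @param channel `"ref"` or `"moving"`.
#' @export
render_calibration <- function(manifest, channel = c("ref", "moving"),
                               amplitude = 2000, background = 200) {
  channel <- match.arg(channel)
  spec <- manifest$spec
  sigma <- spec$psf_fwhm_nm / 2.3548 / spec$fm_pixel_nm
  centers <- if (channel == "ref")
    cbind(manifest$chanbeads$psd_x, manifest$chanbeads$psd_y)
  else cbind(manifest$chanbeads$bead_x, manifest$chanbeads$bead_y)
  img <- matrix(background, spec$fm_size, spec$fm_size)
  img <- .add_spots(img, centers, amplitude,
                    function(r) exp(-r^2 / (2 * sigma^2)), ceiling(5 * sigma))
  img <- .apply_fm_noise(img, spec$noise_sigma * amplitude)
  image_plane(img, spec$fm_pixel_nm,
              frame_id = if (channel == "ref") "fm" else "fm_beads",
              channel = paste0("calibration_", channel))
}

.apply_fm_noise <- function(img, read_sd) {
  if (read_sd <= 0) return(pmin(img, 65535))
  n <- length(img)
  noisy <- stats::rpois(n, pmax(img, 0)) + stats::rnorm(n, 0, read_sd)
  matrix(pmin(pmax(noisy, 0), 65535), nrow(img), ncol(img))
}

#' Render the EM views of a scene
#'
#' Electron-dense markers draw as dark soft-edged discs on a brighter
#' background, matching cryo-EM density contrast. Markers whose diameter
#' falls below one pixel in the requested frame are omitted (the fate of
#' 10 nm tracer gold at montage magnification); omissions are listed in
#' the manifest's `visibility` table and on the returned plane's
#' `"omitted"` attribute. With `noise_sigma > 0`, correlated background
#' texture plus Gaussian noise is added.
#'
#' @param manifest a `scene_manifest`.
#' @param frame `"montage"` (beads + 50 nm gold) or `"tomo_projection"`
#'   (50 nm and 10 nm gold).
#' @param background,depth background level and marker darkness (fraction
#'   of background).
#' @export
render_em <- function(manifest, frame = c("montage", "tomo_projection"),
                      background = 1000, depth = 0.6) {
  frame <- match.arg(frame)
  spec <- manifest$spec
  px <- if (frame == "montage") spec$montage_pixel_nm else spec$tomo_pixel_nm
  sz <- if (frame == "montage") spec$montage_size else spec$tomo_size
  markers <- if (frame == "montage") list(
    list(name = "bead", d = spec$bead_diameter_nm,
         centers = cbind(manifest$beads$mont_x, manifest$beads$mont_y)),
    list(name = "gold50", d = spec$gold50_nm,
         centers = cbind(manifest$gold50$mont_x, manifest$gold50$mont_y)))
  else list(
    list(name = "gold50", d = spec$gold50_nm,
         centers = cbind(manifest$gold50$tomo_x, manifest$gold50$tomo_y)),
    list(name = "gold10", d = spec$gold10_nm,
         centers = cbind(manifest$gold10$tomo_x, manifest$gold10$tomo_y)))
  img <- matrix(background, sz, sz)
  omitted <- character(0)
  for (m in markers) {
    rad <- m$d / px / 2
    if (2 * rad < 1) { omitted <- c(omitted, m$name); next }
    img <- .add_spots(img, m$centers, -depth * background,
                      function(r) pmin(pmax(rad + 0.5 - r, 0), 1), rad + 2)
  }
  if (spec$noise_sigma > 0) {
    tex <- EBImage::gblur(matrix(stats::rnorm(sz * sz), sz, sz), sigma = 3)
    img <- img + tex * (spec$noise_sigma * background * 2) +
      stats::rnorm(sz * sz, 0, spec$noise_sigma * background)
  }
  out <- image_plane(img, px,
                     frame_id = if (frame == "montage") "montage" else "tomogram",
                     channel = "EM")
  attr(out$pixels, "omitted") <- omitted
  out
}

#' Render a 3D tomogram with gold spheres
#'
#' Gold particles become dark spheres at random z (correct 3D extent,
#' clipped at the volume faces). Lateral size follows the spec's
#' `tomo_size`; keep it small in specs meant for 3D rendering, volumes are
#' `tomo_nz * tomo_size^2` voxels.
#'
#' @inheritParams render_em
#' @return A [tomogram_stack()] whose min z-projection shows every gold
#'   particle in the manifest.
#' @export
render_tomogram <- function(manifest, background = 1000, depth = 0.6) {
  spec <- manifest$spec
  sz <- spec$tomo_size; nz <- spec$tomo_nz
  if (as.numeric(sz)^2 * nz > 5e8)
    stop("render_tomogram: volume too large; use a spec with a smaller tomo_size/tomo_nz")
  vox <- array(background, dim = c(nz, sz, sz))
  centers <- cbind(manifest$gold50$tomo_x, manifest$gold50$tomo_y)
  g10 <- cbind(manifest$gold10$tomo_x, manifest$gold10$tomo_y)
  rad50 <- spec$gold50_nm / spec$tomo_pixel_nm / 2
  rad10 <- spec$gold10_nm / spec$tomo_pixel_nm / 2
  zc <- .with_seed(spec$seed + 1L, list(
    z50 = stats::runif(nrow(centers), 0, nz - 1),
    z10 = stats::runif(nrow(g10), 0, nz - 1)))
  draw <- function(vox, centers, zpos, rad) {
    for (k in seq_len(nrow(centers))) {
      for (z in seq_len(nz)) {
        dz <- (z - 1) - zpos[k]
        if (abs(dz) >= rad) next
        rz <- sqrt(rad^2 - dz^2)
        sl <- .add_spots(vox[z, , ], centers[k, , drop = FALSE],
                         -depth * background,
                         function(r) pmin(pmax(rz + 0.5 - r, 0), 1), rz + 2)
        vox[z, , ] <- sl
      }
    }
    vox
  }
  vox <- draw(vox, centers, zc$z50, rad50)
  if (nrow(g10) > 0 && 2 * rad10 >= 1) vox <- draw(vox, g10, zc$z10, rad10)
  if (spec$noise_sigma > 0)
    vox <- vox + stats::rnorm(length(vox), 0, spec$noise_sigma * background)
  tomogram_stack(vox, spec$tomo_pixel_nm, frame_id = "tomogram")
}

#' Generate a synapse phantom with known ground truth
#'
#' Builds two roughly parallel membrane traces separated by the requested
#' cleft width (plus smooth jitter), places vesicles on the presynaptic
#' side at gaps drawn to realize the requested state mix, and optionally
#' links vesicle pairs with connectors. All coordinates are in nm
#' (`pixel_size_nm = 1` unless overridden). Deterministic per seed.
#'
#' @param seed integer seed.
#' @param width_nm cleft width (nm).
#' @param width_jitter_sd sd of the smooth width modulation (nm).
#' @param n_vesicles total vesicle count on the presynaptic side.
#' @param state_mix named counts among `docked`, `tethered`, `fusing`,
#'   `fused`; the remainder are free. An infeasible mix (sum above
#'   `n_vesicles`) is an error.
#' @param n_connectors number of vesicle-vesicle connector segments.
#' @param length_nm lateral extent of the membrane traces.
#' @param pixel_size_nm annotation pixel size (coordinates are divided by
#'   it, so measurements are invariant to the choice).
#' @return List with `annotation` (a [synapse_annotation()]) and `truth`
#'   (true states, gaps, width settings, connector pairs).
#' @export
generate_synapse_phantom <- function(seed, width_nm = 20, width_jitter_sd = 1,
                                     n_vesicles = 30,
                                     state_mix = NULL,
                                     n_connectors = 0, length_nm = 600,
                                     pixel_size_nm = 1) {
  stopifnot(width_nm > 0, width_jitter_sd >= 0, n_vesicles >= 0)
  if (is.null(state_mix)) state_mix <- c(tethered = min(3, n_vesicles))
  mix <- c(docked = 0, tethered = 0, fusing = 0, fused = 0)
  mix[names(state_mix)] <- state_mix
  if (sum(mix) > n_vesicles)
    stop(sprintf("generate_synapse_phantom: state mix requires %d vesicles but n_vesicles is %d",
                 sum(mix), n_vesicles))
  .with_seed(seed, {
    x <- seq(0, length_nm, by = 2)
    amp <- stats::runif(1, 5, 12)
    lam <- stats::runif(1, 0.8, 1.5) * length_nm
    y0 <- 200
    pre_pts <- cbind(x, y0 + amp * sin(2 * pi * x / lam))
    # unit normals toward the postsynaptic side (below in display, +y)
    tang <- rbind(pre_pts[2, ] - pre_pts[1, ],
                  pre_pts[-1, , drop = FALSE] - pre_pts[-nrow(pre_pts), , drop = FALSE])
    tang <- tang / sqrt(rowSums(tang^2))
    nrm <- cbind(-tang[, 2], tang[, 1])    # right of travel = +y side
    jit <- if (width_jitter_sd > 0) {
      ph <- stats::runif(3, 0, 2 * pi)
      f <- stats::runif(3, 1.5, 4)
      raw <- rowSums(sapply(1:3, function(i) sin(2 * pi * f[i] * x / length_nm + ph[i])))
      raw * width_jitter_sd / stats::sd(raw)
    } else rep(0, length(x))
    post_pts <- pre_pts + nrm * (width_nm + jit)
    states <- sample(c(rep("docked", mix["docked"]), rep("tethered", mix["tethered"]),
                       rep("fusing", mix["fusing"]), rep("fused", mix["fused"]),
                       rep("free", n_vesicles - sum(mix))))
    ves <- list(); gaps <- numeric(n_vesicles)
    if (n_vesicles > 0) {
      xi <- seq(0.06, 0.94, length.out = n_vesicles) * length_nm
      xi <- xi + stats::runif(n_vesicles, -0.4, 0.4) * (length_nm / max(n_vesicles, 1)) * 0.5
      for (i in seq_len(n_vesicles)) {
        r <- stats::runif(1, 15, 25)
        gap <- switch(states[i],
                      docked = stats::runif(1, 0, 1.8),
                      tethered = stats::runif(1, 4, 9),
                      fusing = 0, fused = 0,
                      free = stats::runif(1, 30, 140))
        gaps[i] <- gap
        j <- which.min(abs(x - xi[i]))
        ctr <- pre_pts[j, ] - nrm[j, ] * (r + gap)   # cytosol side (-y)
        ves[[i]] <- vesicle(ctr / pixel_size_nm, r,
                            fusing = states[i] == "fusing",
                            fused = states[i] == "fused")
      }
    }
    conn <- NULL; conn_pairs <- NULL
    if (n_connectors > 0 && n_vesicles >= 2) {
      conn_pairs <- matrix(0L, n_connectors, 2)
      conn <- matrix(0, n_connectors, 4)
      for (k in seq_len(n_connectors)) {
        # link only clearly separated vesicles so each endpoint touches
        # exactly one vesicle
        for (try in 1:200) {
          ij <- sample(n_vesicles, 2)
          a <- ves[[ij[1]]]$center * pixel_size_nm
          b <- ves[[ij[2]]]$center * pixel_size_nm
          gap_ab <- sqrt(sum((b - a)^2)) -
            ves[[ij[1]]]$radius_nm - ves[[ij[2]]]$radius_nm
          if (gap_ab > 12) break
        }
        if (gap_ab <= 12)
          stop("generate_synapse_phantom: cannot place non-ambiguous connectors")
        conn_pairs[k, ] <- sort(ij)
        u <- (b - a) / sqrt(sum((b - a)^2))
        p1 <- a + u * ves[[ij[1]]]$radius_nm
        p2 <- b - u * ves[[ij[2]]]$radius_nm
        conn[k, ] <- c(p1, p2) / pixel_size_nm
      }
    }
    ann <- synapse_annotation(
      membranes = list(membrane_trace(pre_pts / pixel_size_nm, pixel_size_nm, "presynaptic"),
                       membrane_trace(post_pts / pixel_size_nm, pixel_size_nm, "postsynaptic")),
      vesicles = ves, connectors = conn, pixel_size_nm = pixel_size_nm)
    list(annotation = ann,
         truth = list(states = if (n_vesicles > 0) ifelse(states == "docked", "docked_or_primed",
                        ifelse(states == "tethered", "tethered_candidate",
                          ifelse(states == "fused", "fully_fused", states))) else character(0),
                      gaps_nm = gaps, width_nm = width_nm,
                      width_jitter_sd = width_jitter_sd,
                      connector_pairs = conn_pairs))
  })
}

#' Write a scene to disk
#'
#' Writes the fluorescence channels and calibration fields as 32-bit
#' TIFF, the montage and tomogram projection as MRC, truth point lists as
#' CSV, and the true transforms plus a manifest summary as JSON.
#'
#' @param manifest a `scene_manifest`.
#' @param dir output directory (created if needed).
#' @export
write_scene <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_image(render_fm(manifest, "psd95"), p("fm_psd95.tif"))
  write_image(render_fm(manifest, "beads"), p("fm_beads.tif"))
  write_image(render_calibration(manifest, "ref"), p("calib_ref.tif"))
  write_image(render_calibration(manifest, "moving"), p("calib_moving.tif"))
  write_image(render_em(manifest, "montage"), p("em_montage.mrc"))
  write_image(render_em(manifest, "tomo_projection"), p("tomo_projection.mrc"))
  wp <- function(df, cols, frame, px, file) {
    ps <- point_set(as.matrix(df[, cols]), frame, px)
    write_points(ps, p(file))
  }
  spec <- manifest$spec
  wp(manifest$beads, c("fm_x", "fm_y"), "fm", spec$fm_pixel_nm, "beads_fm.csv")
  wp(manifest$beads, c("fmch_x", "fmch_y"), "fm_beads", spec$fm_pixel_nm, "beads_fm_beadchannel.csv")
  wp(manifest$beads, c("mont_x", "mont_y"), "montage", spec$montage_pixel_nm, "beads_montage.csv")
  wp(manifest$gold50, c("mont_x", "mont_y"), "montage", spec$montage_pixel_nm, "gold50_montage.csv")
  wp(manifest$gold50, c("tomo_x", "tomo_y"), "tomogram", spec$tomo_pixel_nm, "gold50_tomogram.csv")
  wp(manifest$psd, c("fm_x", "fm_y"), "fm", spec$fm_pixel_nm, "psd_fm.csv")
  wp(manifest$psd, c("tomo_x", "tomo_y"), "tomogram", spec$tomo_pixel_nm, "psd_tomogram.csv")
  wp(manifest$chanbeads, c("psd_x", "psd_y"), "fm", spec$fm_pixel_nm, "chanbeads_ref.csv")
  wp(manifest$chanbeads, c("bead_x", "bead_y"), "fm_beads", spec$fm_pixel_nm, "chanbeads_moving.csv")
  write_transform(manifest$channel_shift, p("true_channel_shift.json"))
  write_transform(manifest$fm_to_montage, p("true_fm_to_montage.json"))
  write_transform(manifest$montage_to_tomo, p("true_montage_to_tomo.json"))
  write_transform(manifest$fm_to_tomogram, p("true_fm_to_tomogram.json"))
  jsonlite::write_json(list(seed = manifest$spec$seed,
                            n_beads = nrow(manifest$beads),
                            n_gold50 = nrow(manifest$gold50),
                            n_gold10 = nrow(manifest$gold10),
                            pixel_sizes_nm = list(fm = spec$fm_pixel_nm,
                                                  montage = spec$montage_pixel_nm,
                                                  tomogram = spec$tomo_pixel_nm),
                            visibility = manifest$visibility),
                       p("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate the registration chain at a given measurement noise
#'
#' Builds the coarse and fine correspondences from a scene's truth tables,
#' perturbs each stage's target-frame coordinates with iid Gaussian noise
#' (the same convention under which the fiducial-registration-error noise
#' law is stated), fits both stages, and maps the PSD95 probe point into
#' the tomogram frame.
#'
#' @param manifest a `scene_manifest`.
#' @param noise_px measurement noise sd, in the target frame's pixels, for
#'   each registration stage.
#' @param seed RNG seed for the noise draw.
#' @param model transform model for both stages.
#' @return List with `error_nm`, `error_tomo_px` (probe error vs ground
#'   truth), and the fitted `chain`.
#' @export
simulate_registration_chain <- function(manifest, noise_px = 0, seed = 1,
                                        model = "similarity") {
  spec <- manifest$spec
  .with_seed(seed, {
    jb <- matrix(stats::rnorm(2 * nrow(manifest$beads), 0, noise_px), ncol = 2)
    jg <- matrix(stats::rnorm(2 * nrow(manifest$gold50), 0, noise_px), ncol = 2)
    coarse <- estimate_transform(
      correspondences(cbind(manifest$beads$fm_x, manifest$beads$fm_y),
                      cbind(manifest$beads$mont_x, manifest$beads$mont_y) + jb),
      model = model, source_frame = "fm", target_frame = "montage")
    fine <- estimate_transform(
      correspondences(cbind(manifest$gold50$mont_x, manifest$gold50$mont_y),
                      cbind(manifest$gold50$tomo_x, manifest$gold50$tomo_y) + jg),
      model = model, source_frame = "montage", target_frame = "tomogram")
    chain <- build_chain(NULL, coarse, fine)
    probe <- map_through_chain(chain, cbind(manifest$psd$fm_x, manifest$psd$fm_y))
    err_px <- sqrt(rowSums((probe - cbind(manifest$psd$tomo_x, manifest$psd$tomo_y))^2))
    list(error_nm = max(err_px) * spec$tomo_pixel_nm,
         error_tomo_px = max(err_px), chain = chain)
  })
}
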