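#' Detection parameters for fiducial markers
#'
#' @param expected_diameter_nm apparent marker diameter in nm. For
#'   diffraction-limited fluorescent beads this is the rendered spot size,
#'   `max(bead diameter, PSF FWHM)`, not the physical bead size.
#' @param pixel_size_nm image pixel size in nm.
#' @param polarity `"bright"` (fluorescent spots) or `"dark"`
#'   (electron-dense beads/gold in EM contrast). Dark markers are handled
#'   by inverting the response, never by mutating the input image.
#' @param threshold relative response cutoff in (0, 1]: maxima below
#'   `threshold * max(response)` are discarded.
#' @param min_separation_factor minimum center-to-center distance between
#'   detections, as a multiple of the expected diameter.
#' @param refine sub-pixel refinement: `"gaussian"` (radial Gaussian
#'   least-squares fit, the precision option and default) or `"centroid"`
#'   (iterated background-subtracted centroid).
#' @export
detection_params <- function(expected_diameter_nm, pixel_size_nm,
                             polarity = c("bright", "dark"),
                             threshold = 0.25, min_separation_factor = 1.0,
                             refine = c("gaussian", "centroid")) {
  polarity <- match.arg(polarity)
  refine <- match.arg(refine)
  stopifnot(expected_diameter_nm > 0, pixel_size_nm > 0,
            threshold > 0, threshold <= 1, min_separation_factor > 0)
  structure(list(expected_diameter_nm = expected_diameter_nm,
                 pixel_size_nm = pixel_size_nm, polarity = polarity,
                 threshold = threshold,
                 min_separation_factor = min_separation_factor,
                 refine = refine),
            class = "detection_params")
}

.as_pixels <- function(image) {
  if (inherits(image, "image_plane")) image$pixels else as.matrix(image)
}

#' Detect and localize fiducial markers in a 2D image
#'
#' Band-pass blob detection tuned to the expected marker diameter: a
#' difference-of-Gaussians response is computed (inverted for dark
#' markers), local maxima above the relative threshold are extracted,
#' close pairs are suppressed keeping the higher score (equal scores keep
#' the smaller (row, column)), and each surviving peak is refined to
#' sub-pixel precision.
#'
#' @param image 2D numeric matrix or an [image_plane()]; at least 16 x 16.
#' @param params a [detection_params()] object. The expected diameter must
#'   be between 1 px and a quarter of the smaller image dimension.
#' @return A data frame with columns `x`, `y` (sub-pixel, 0-based),
#'   `radius_px`, `polarity`, `score`, sorted by descending score.
#' @export
detect_fiducials <- function(image, params) {
  stopifnot(inherits(params, "detection_params"))
  img <- .as_pixels(image)
  if (nrow(img) < 16 || ncol(img) < 16)
    stop("detect_fiducials: image must be at least 16 x 16 pixels")
  d <- params$expected_diameter_nm / params$pixel_size_nm
  if (d < 1)
    stop(sprintf(paste("detect_fiducials: expected diameter is %.3g px at %.3g nm/px;",
                       "markers below one pixel cannot be localized -- use a",
                       "higher-magnification image"), d, params$pixel_size_nm))
  if (d > min(dim(img)) / 4)
    stop("detect_fiducials: expected diameter exceeds a quarter of the image size")
  empty <- data.frame(x = numeric(0), y = numeric(0), radius_px = numeric(0),
                      polarity = character(0), score = numeric(0))
  work <- if (params$polarity == "dark") -img else img
  s1 <- max(d / (2 * sqrt(2)), 0.6)
  resp <- EBImage::gblur(work, sigma = s1) - EBImage::gblur(work, sigma = 1.6 * s1)
  rmax <- max(resp)
  if (!(rmax > 0)) return(empty)       # blank / constant image
  # noise floor: spurious response maxima sit within a few robust sd of the
  # band-pass response; genuine markers sit far above it at usable SNR
  floor_abs <- 8 * stats::mad(resp)
  peaks <- .local_maxima(resp, max(rmax * params$threshold, floor_abs))
  if (nrow(peaks) == 0) return(empty)
  peaks <- .suppress_close(peaks, params$min_separation_factor * d)
  # sub-pixel refinement on the polarity-normalized image
  win <- .odd_clamp(round(1.5 * d) + 2, dim(img))
  cent <- matrix(NA_real_, nrow(peaks), 2)
  radii <- numeric(nrow(peaks))
  keep <- logical(nrow(peaks))
  for (k in seq_len(nrow(peaks))) {
    seed <- c(peaks$col[k] - 1, peaks$row[k] - 1)
    w <- .shrink_window(seed, win, dim(img))
    if (w < 3) next
    ref <- tryCatch({
      if (params$refine == "gaussian") .refine_gaussian(work, seed, w)
      else .refine_centroid_iter(work, seed, w)
    }, error = function(e) NULL)
    if (is.null(ref)) next
    if (ref$x < 0 || ref$y < 0 || ref$x > ncol(img) - 1 || ref$y > nrow(img) - 1) next
    cent[k, ] <- c(ref$x, ref$y)
    radii[k] <- if (!is.null(ref$radius_px) && is.finite(ref$radius_px) && ref$radius_px > 0)
      ref$radius_px else d / 2
    keep[k] <- TRUE
  }
  out <- data.frame(x = cent[keep, 1], y = cent[keep, 2],
                    radius_px = radii[keep], polarity = params$polarity,
                    score = peaks$score[keep])
  out <- out[order(-out$score, out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.local_maxima <- function(resp, cutoff) {
  nr <- nrow(resp); nc <- ncol(resp)
  ok <- resp >= cutoff
  ok[c(1, nr), ] <- FALSE; ok[, c(1, nc)] <- FALSE
  ctr <- resp[2:(nr - 1), 2:(nc - 1)]
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ok[2:(nr - 1), 2:(nc - 1)] <- ok[2:(nr - 1), 2:(nc - 1)] &
      (ctr > resp[2:(nr - 1) + dr, 2:(nc - 1) + dc] |
         # plateau tie-break: the smaller (row, col) index wins
         (ctr == resp[2:(nr - 1) + dr, 2:(nc - 1) + dc] & (dr > 0 | (dr == 0 & dc > 0))))
  }
  idx <- which(ok, arr.ind = TRUE)
  data.frame(row = idx[, 1], col = idx[, 2], score = resp[idx])
}

.suppress_close <- function(peaks, min_dist) {
  ord <- order(-peaks$score, peaks$row, peaks$col)
  peaks <- peaks[ord, , drop = FALSE]
  taken <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (i == 1) { taken[1] <- TRUE; next }
    j <- which(taken)
    d2 <- (peaks$row[j] - peaks$row[i])^2 + (peaks$col[j] - peaks$col[i])^2
    if (all(d2 >= min_dist^2)) taken[i] <- TRUE
  }
  peaks[taken, , drop = FALSE]
}

.odd_clamp <- function(w, dims) {
  w <- max(3, as.integer(w))
  if (w %% 2 == 0) w <- w + 1L
  wmax <- min(dims) - 2L
  if (wmax %% 2 == 0) wmax <- wmax - 1L
  min(w, wmax)
}

.shrink_window <- function(seed, w, dims) {
  # largest odd window <= w fully inside the image around the seed
  cx <- round(seed[1]) + 1; cy <- round(seed[2]) + 1
  room <- min(cx - 1, dims[2] - cx, cy - 1, dims[1] - cy)
  min(w, 2L * as.integer(room) + 1L)
}

#' Sub-pixel refinement by background-subtracted centroid
#'
#' Computes the intensity-weighted centroid within an odd window after
#' local background subtraction (median of the window border) and polarity
#' normalization (the response is negated when the window center falls
#' below the background). A flat window returns the window center with
#' attribute `zero_contrast = TRUE`.
#'
#' @param image 2D numeric matrix or [image_plane()].
#' @param seed `(x, y)` position (0-based) to center the window on.
#' @param window_px odd window size >= 3; the window must lie fully inside
#'   the image, otherwise an error is raised.
#' @return Numeric `(x, y)` of the refined center.
#' @export
refine_subpixel <- function(image, seed, window_px) {
  img <- .as_pixels(image)
  if (window_px < 3 || window_px %% 2 == 0)
    stop("refine_subpixel: window_px must be odd and >= 3")
  p <- .window_patch(img, seed, window_px)  # errors when clipped
  vals <- p$patch - p$background
  core <- vals[2:(nrow(vals) - 1), 2:(ncol(vals) - 1)]
  if (sum(core) < 0) vals <- -vals
  w <- pmax(vals, 0)
  tot <- sum(w)
  if (tot <= 0 || max(vals) == min(vals)) {
    out <- c(x = p$cx - 1, y = p$cy - 1)
    attr(out, "zero_contrast") <- TRUE
    return(out)
  }
  xs <- (p$cols - 1); ys <- (p$rows - 1)
  out <- c(x = sum(t(w) * xs) / tot, y = sum(w * ys) / tot)
  attr(out, "zero_contrast") <- FALSE
  out
}

.window_patch <- function(img, seed, window_px) {
  h <- (window_px - 1) / 2
  cx <- round(seed[1]) + 1; cy <- round(seed[2]) + 1
  rows <- (cy - h):(cy + h); cols <- (cx - h):(cx + h)
  if (min(rows) < 1 || min(cols) < 1 || max(rows) > nrow(img) || max(cols) > ncol(img))
    stop("refine_subpixel: window clipped by the image border")
  patch <- img[rows, cols, drop = FALSE]
  border <- c(patch[1, ], patch[nrow(patch), ], patch[, 1], patch[, ncol(patch)])
  list(patch = patch, background = stats::median(border),
       rows = rows, cols = cols, cx = cx, cy = cy)
}

.refine_centroid_iter <- function(work, seed, window_px, max_iter = 10) {
  pos <- seed
  for (i in seq_len(max_iter)) {
    new <- refine_subpixel(work, pos, window_px)
    if (isTRUE(attr(new, "zero_contrast"))) break
    moved <- max(abs(round(new) - round(pos)))
    pos <- as.numeric(new)
    if (moved < 1) break     # window no longer recenters
  }
  list(x = pos[1], y = pos[2], radius_px = NULL)
}

# Radial Gaussian least-squares fit: I(r) = B + A exp(-r^2 / (2 s^2)).
# The center of any radially symmetric marker (Gaussian spot or soft-edged
# disc) is recovered without bias; sigma absorbs the profile shape.
.refine_gaussian <- function(work, seed, window_px) {
  p <- .window_patch(work, seed, window_px)
  z <- as.numeric(p$patch)
  xs <- rep(p$cols - 1, each = length(p$rows))
  ys <- rep(p$rows - 1, times = length(p$cols))
  c0 <- refine_subpixel(work, seed, window_px)
  if (isTRUE(attr(c0, "zero_contrast")))
    return(list(x = c0[1], y = c0[2], radius_px = NULL))
  B0 <- p$background
  A0 <- p$patch[p$cy - p$rows[1] + 1, p$cx - p$cols[1] + 1] - B0
  if (A0 == 0) A0 <- max(abs(z - B0)) * sign(sum(z - B0))
  s0 <- max(window_px / 6, 1)
  par <- c(c0[1], c0[2], log(s0), A0, B0)
  obj <- function(q) {
    s2 <- exp(2 * q[3])
    e <- exp(-((xs - q[1])^2 + (ys - q[2])^2) / (2 * s2))
    sum((q[5] + q[4] * e - z)^2)
  }
  grad <- function(q) {
    s2 <- exp(2 * q[3])
    dx <- xs - q[1]; dy <- ys - q[2]
    e <- exp(-(dx^2 + dy^2) / (2 * s2))
    r <- 2 * (q[5] + q[4] * e - z)
    g_amp <- sum(r * e)
    g_b <- sum(r)
    g_x <- sum(r * q[4] * e * dx / s2)
    g_y <- sum(r * q[4] * e * dy / s2)
    g_ls <- sum(r * q[4] * e * (dx^2 + dy^2) / s2)
    c(g_x, g_y, g_ls, g_amp, g_b)
  }
  fit <- stats::optim(par, obj, grad, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-14))
  sig <- exp(fit$par[3])
  list(x = fit$par[1], y = fit$par[2], radius_px = sig * sqrt(2 * log(2)))
}

#' Write / read detection tables
#'
#' CSV with columns `frame_id, x, y, radius_px, polarity, score`.
#'
#' @param detections data frame from [detect_fiducials()].
#' @param frame_id frame label written to every row.
#' @param path CSV path.
#' @export
write_detections <- function(detections, frame_id, path) {
  df <- cbind(frame_id = frame_id, detections)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("read_detections: missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}
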