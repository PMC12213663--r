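#' 2D image plane with physical metadata
#'
#' @param pixels numeric matrix, `pixels[row, col]`; point `(x, y)` =
#'   `(col - 1, row - 1)` (0-based, origin at the center of the top-left
#'   pixel).
#' @param pixel_size_nm pixel size in nm (> 0).
#' @param frame_id coordinate-frame label.
#' @param channel channel label (e.g. `"PSD95"`, `"beads"`, `"EM"`).
#' @export
image_plane <- function(pixels, pixel_size_nm, frame_id = "image",
                        channel = NA_character_) {
  pixels <- as.matrix(pixels)
  stopifnot(is.numeric(pixels), all(is.finite(pixels)), pixel_size_nm > 0)
  structure(list(pixels = pixels, pixel_size_nm = as.numeric(pixel_size_nm),
                 frame_id = frame_id, channel = channel),
            class = "image_plane")
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane '%s'%s> %d x %d px, %.4g nm/px\n", x$frame_id,
              if (is.na(x$channel)) "" else paste0(" [", x$channel, "]"),
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm))
  invisible(x)
}

#' Tomogram volume
#'
#' @param voxels 3D numeric array indexed `[z, y, x]`.
#' @param voxel_size_nm isotropic voxel size in nm.
#' @param frame_id frame label shared with the z-projection.
#' @export
tomogram_stack <- function(voxels, voxel_size_nm, frame_id = "tomogram") {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3, dim(voxels)[1] >= 1,
            voxel_size_nm > 0)
  structure(list(voxels = voxels, voxel_size_nm = as.numeric(voxel_size_nm),
                 frame_id = frame_id),
            class = "tomogram_stack")
}

#' Z-projection of a tomogram
#'
#' Per-pixel reduction of the volume along z. The default is `min`:
#' electron-dense gold is dark in EM contrast, so a minimum projection
#' shows every particle in the volume in one image.
#'
#' @param stack a [tomogram_stack()].
#' @param method `"min"`, `"mean"` or `"max"`.
#' @return An [image_plane()] in the tomogram frame.
#' @export
zproject <- function(stack, method = c("min", "mean", "max")) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "tomogram_stack"))
  nz <- dim(stack$voxels)[1]
  slices <- lapply(seq_len(nz), function(z) stack$voxels[z, , ])
  px <- switch(method,
               min = Reduce(pmin, slices),
               max = Reduce(pmax, slices),
               mean = Reduce(`+`, slices) / nz)
  image_plane(px, stack$voxel_size_nm, frame_id = stack$frame_id, channel = "EM")
}

#' Warp an image through a planar transform
#'
#' Inverse-mapped resampling with bilinear interpolation: output pixel `p`
#' takes the value of the source at `t^{-1}(p)`, so `t` maps source
#' coordinates into the target frame. Pixels that map outside the source
#' are filled with `fill` and flagged in the validity mask stored as
#' attribute `"valid"` on the result's pixels.
#'
#' @param src an [image_plane()] (or matrix).
#' @param t `transform2d` mapping source -> target coordinates.
#' @param target_shape `c(rows, cols)` of the output.
#' @param fill value for out-of-source pixels (default 0).
#' @param target_pixel_size_nm pixel size recorded on the output (defaults
#'   to the source pixel size divided by the transform's scale factor).
#' @export
warp_image <- function(src, t, target_shape, fill = 0,
                       target_pixel_size_nm = NULL) {
  img <- .as_pixels(src)
  ti <- invert_transform(t)    # errors on singular transform
  nr <- target_shape[1]; nc <- target_shape[2]
  xs <- rep(0:(nc - 1), each = nr)
  ys <- rep(0:(nr - 1), times = nc)
  sp <- cbind(xs, ys) %*% t(ti$matrix)
  sx <- sp[, 1] + ti$offset[1]
  sy <- sp[, 2] + ti$offset[2]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0;  fy <- sy - y0
  H <- nrow(img); W <- ncol(img)
  eps <- 1e-9   # keep exact-edge samples valid under rounding
  valid <- sx >= -eps & sy >= -eps & sx <= W - 1 + eps & sy <= H - 1 + eps
  # clamp the upper edge so x0+1/y0+1 stay in range for exact-edge samples
  x0c <- pmin(pmax(x0, 0), W - 2); y0c <- pmin(pmax(y0, 0), H - 2)
  fxc <- sx - x0c; fyc <- sy - y0c
  i00 <- y0c + 1 + x0c * H
  v <- (1 - fxc) * (1 - fyc) * img[i00] +
       fxc * (1 - fyc) * img[i00 + H] +
       (1 - fxc) * fyc * img[i00 + 1] +
       fxc * fyc * img[i00 + H + 1]
  v[!valid] <- fill
  out <- matrix(v, nr, nc)
  attr(out, "valid") <- matrix(valid, nr, nc)
  if (inherits(src, "image_plane")) {
    ps <- if (is.null(target_pixel_size_nm))
      src$pixel_size_nm / transform_scale(t) else target_pixel_size_nm
    plane <- image_plane(out, ps,
                         frame_id = if (is.na(t$target_frame)) src$frame_id else t$target_frame,
                         channel = src$channel)
    plane$pixels <- out   # keep the validity attribute
    plane
  } else out
}

#' Render a multi-channel fluorescence/EM overlay
#'
#' The EM base is rendered grayscale (min-max normalized); each
#' fluorescence channel is warped into the EM frame through its transform,
#' min-max normalized over its valid (in-field) pixels and additively
#' blended in its color. Deterministic: no random state involved.
#'
#' @param base_em an [image_plane()], the EM frame.
#' @param fm_channels list of channels, each a list with elements `plane`
#'   (an `image_plane`), `transform` (`transform2d` mapping the FM frame
#'   into the EM frame) and `color` (length-3 RGB weights in \[0, 1\] or a
#'   name like `"green"`).
#' @param alpha blending weight of the fluorescence channels.
#' @return An `rows x cols x 3` RGB array in \[0, 1\].
#' @export
compose_overlay <- function(base_em, fm_channels = list(), alpha = 0.8) {
  stopifnot(inherits(base_em, "image_plane"))
  g <- .minmax(base_em$pixels)
  rgb <- array(rep(g, 3), dim = c(nrow(g), ncol(g), 3))
  for (ch in fm_channels) {
    stopifnot(inherits(ch$plane, "image_plane"), inherits(ch$transform, "transform2d"))
    tt <- ch$transform
    if (!is.na(tt$target_frame) && !is.na(base_em$frame_id) &&
        tt$target_frame != base_em$frame_id)
      stop(sprintf("compose_overlay: channel transform targets frame '%s', EM base is '%s'",
                   tt$target_frame, base_em$frame_id))
    w <- warp_image(ch$plane, tt, dim(base_em$pixels))
    msk <- attr(w$pixels, "valid")
    wn <- .minmax(w$pixels, mask = msk)
    col <- .as_color(ch$color)
    for (k in 1:3) rgb[, , k] <- rgb[, , k] + alpha * col[k] * wn
  }
  rgb[rgb > 1] <- 1
  rgb
}

.minmax <- function(m, mask = NULL) {
  v <- if (is.null(mask)) m else m[mask]
  rng <- range(v)
  out <- if (diff(rng) == 0) m * 0 else (m - rng[1]) / diff(rng)
  if (!is.null(mask)) out[!mask] <- 0
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

.as_color <- function(col) {
  if (is.character(col))
    return(as.numeric(grDevices::col2rgb(col)) / 255)
  stopifnot(length(col) == 3)
  as.numeric(col)
}

#' Enumerate the 8 dihedral orientations of an image
#'
#' The grid's coordinate letters fix the relative orientation of the LM
#' and EM views only up to rotation and mirroring; this enumerates the 8
#' candidate orientations (4 rotations x optional flip). Each variant is
#' tagged with the exact `transform2d` mapping the variant's coordinates
#' back onto the original image, so `warp_image(variant, transform)`
#' reproduces the original. When an EM reference image of the same shape
#' is supplied, variants are scored by normalized cross-correlation to
#' assist the (ultimately user-made) choice.
#'
#' @param lm an [image_plane()] or matrix.
#' @param reference optional matrix/`image_plane` to score variants against.
#' @return A list of 8 entries: `pixels`, `transform` (variant -> original
#'   frame), `label`, and `score` (NCC, `NA` without a reference).
#' @export
enumerate_orientations <- function(lm, reference = NULL) {
  img <- .as_pixels(lm)
  ref <- if (is.null(reference)) NULL else .as_pixels(reference)
  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]   # 90 deg CCW in display
  flip <- function(m) m[, ncol(m):1, drop = FALSE]        # mirror left-right
  out <- vector("list", 8)
  i <- 0
  for (f in c(FALSE, TRUE)) for (k in 0:3) {
    i <- i + 1
    m <- if (f) flip(img) else img
    for (r in seq_len(k)) m <- rot90(m)
    out[[i]] <- list(pixels = m,
                     transform = .orientation_transform(dim(img), k, f),
                     label = sprintf("rot%d%s", 90 * k, if (f) "_flip" else ""),
                     score = if (is.null(ref) || !all(dim(ref) == dim(m))) NA_real_
                             else .ncc(ref, m))
  }
  out
}

# Exact mapping variant pixel coords -> original pixel coords, recovered
# from three reference pixels pushed through the index mapping. One CCW
# rotation sends original (x, y) to (y, w - 1 - x) where w is the width
# before that rotation; the mirror sends x to w - 1 - x.
.orientation_transform <- function(dims, k, f) {
  fwd <- function(p) {                 # original (x, y) -> variant (x, y)
    x <- p[1]; y <- p[2]; w <- dims[2]; h <- dims[1]
    if (f) x <- (w - 1) - x
    if (k > 0) for (r in seq_len(k)) {
      nx <- y; ny <- (w - 1) - x
      x <- nx; y <- ny
      tmp <- w; w <- h; h <- tmp
    }
    c(x, y)
  }
  o <- fwd(c(0, 0))
  Mf <- cbind(fwd(c(1, 0)) - o, fwd(c(0, 1)) - o)   # original -> variant, exact
  M <- solve(Mf)
  transform2d(M, as.numeric(-M %*% o), "rigid")
}

.ncc <- function(a, b) {
  a <- as.numeric(a) - mean(a); b <- as.numeric(b) - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}
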