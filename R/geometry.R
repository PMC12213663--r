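#' Planar transforms between imaging coordinate frames
#'
#' All coordinates in this package follow one convention: 0-based pixel
#' indices, a point `(x, y)` means `(column, row)`, and the origin sits at
#' the center of the top-left pixel. A `transform2d` maps points of its
#' source frame into its target frame as `matrix %*% p + offset`.
#'
#' @param matrix 2x2 linear part (acts on column vectors `(x, y)`).
#' @param offset length-2 translation, in target-frame pixels.
#' @param model one of `"translation"`, `"rigid"`, `"similarity"`,
#'   `"affine"`. The linear part of a rigid/similarity transform must be a
#'   (scaled) rotation, possibly composed with a reflection; the reflection
#'   is recorded by the sign of the determinant.
#' @param source_frame,target_frame frame labels used to check that
#'   transforms are chained between compatible frames.
#' @return An object of class `transform2d`.
#' @export
transform2d <- function(matrix = diag(2), offset = c(0, 0),
                        model = c("affine", "similarity", "rigid", "translation"),
                        source_frame = NA_character_, target_frame = NA_character_) {
  model <- match.arg(model)
  matrix <- base::matrix(as.numeric(matrix), 2, 2)
  offset <- as.numeric(offset)
  stopifnot(length(offset) == 2, all(is.finite(matrix)), all(is.finite(offset)))
  d <- det(matrix)
  if (abs(d) < .Machine$double.eps * 100)
    stop("transform2d: linear part is singular (|det| ~ 0)")
  if (model %in% c("translation", "rigid", "similarity")) {
    s <- sqrt(abs(d))
    R <- matrix / s
    # scaled rotation (or rotation * reflection) => R t(R) = I
    if (max(abs(crossprod(R) - diag(2))) > 1e-6)
      stop("transform2d: linear part of a ", model,
           " transform must be a scaled rotation (optionally reflected)")
    if (model == "translation" && max(abs(matrix - diag(2))) > 1e-9)
      stop("transform2d: translation model requires an identity linear part")
    if (model == "rigid" && abs(s - 1) > 1e-6)
      stop("transform2d: rigid model cannot carry scale ", signif(s, 6))
  }
  structure(list(model = model, matrix = matrix, offset = offset,
                 source_frame = source_frame, target_frame = target_frame),
            class = "transform2d")
}

#' Identity transform
#' @inheritParams transform2d
#' @export
transform_identity <- function(source_frame = NA_character_,
                               target_frame = source_frame) {
  transform2d(diag(2), c(0, 0), "translation", source_frame, target_frame)
}

#' Pure translation
#' @param dx,dy shift in target-frame pixels.
#' @inheritParams transform2d
#' @export
transform_translation <- function(dx, dy, source_frame = NA_character_,
                                  target_frame = NA_character_) {
  transform2d(diag(2), c(dx, dy), "translation", source_frame, target_frame)
}

#' Similarity transform from angle, scale, translation
#'
#' @param theta rotation angle in radians, counter-clockwise in the
#'   `(x right, y down)` pixel frame.
#' @param scale isotropic scale factor (> 0).
#' @param dx,dy translation, target-frame pixels.
#' @param reflect if `TRUE`, compose with a reflection about the x axis
#'   (applied before rotation); the determinant of the result is negative.
#' @inheritParams transform2d
#' @export
transform_similarity <- function(theta = 0, scale = 1, dx = 0, dy = 0,
                                 reflect = FALSE,
                                 source_frame = NA_character_,
                                 target_frame = NA_character_) {
  stopifnot(scale > 0)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  if (reflect) R <- R %*% diag(c(1, -1))
  transform2d(scale * R, c(dx, dy), "similarity", source_frame, target_frame)
}

#' @export
print.transform2d <- function(x, ...) {
  cat(sprintf("<transform2d %s> %s -> %s\n", x$model,
              x$source_frame, x$target_frame))
  cat(sprintf("  matrix: [% .6g % .6g; % .6g % .6g]  offset: (% .6g, % .6g)\n",
              x$matrix[1, 1], x$matrix[1, 2], x$matrix[2, 1], x$matrix[2, 2],
              x$offset[1], x$offset[2]))
  if (x$model %in% c("rigid", "similarity"))
    cat(sprintf("  scale %.6g, rotation %.4g deg, reflected: %s\n",
                transform_scale(x), transform_angle(x) * 180 / pi,
                transform_is_reflected(x)))
  invisible(x)
}

#' Isotropic scale factor of a transform's linear part
#' @param t a `transform2d`.
#' @export
transform_scale <- function(t) sqrt(abs(det(t$matrix)))

#' Rotation angle (radians) of a rigid/similarity transform
#' @param t a `transform2d`.
#' @export
transform_angle <- function(t) {
  M <- t$matrix
  if (det(M) < 0) M <- M %*% diag(c(1, -1))
  atan2(M[2, 1], M[1, 1])
}

#' Does the transform include a reflection?
#' @param t a `transform2d`.
#' @export
transform_is_reflected <- function(t) det(t$matrix) < 0

#' Apply a transform to points
#'
#' @param t a `transform2d`.
#' @param p a length-2 vector, an n x 2 matrix of `(x, y)` rows, or a
#'   [point_set()].
#' @return Points in the target frame, same shape as the input (a
#'   `point_set` keeps its metadata but is relabelled to the target frame).
#' @export
apply_transform <- function(t, p) {
  stopifnot(inherits(t, "transform2d"))
  if (inherits(p, "point_set")) {
    out <- p
    out$points <- apply_transform(t, p$points)
    out$frame_id <- if (is.na(t$target_frame)) p$frame_id else t$target_frame
    return(out)
  }
  vec <- is.null(dim(p))
  m <- if (vec) matrix(as.numeric(p), 1, 2) else as.matrix(p)
  stopifnot(ncol(m) == 2)
  out <- m %*% t(t$matrix)
  out[, 1] <- out[, 1] + t$offset[1]
  out[, 2] <- out[, 2] + t$offset[2]
  if (vec) as.numeric(out) else out
}

#' Invert a transform
#' @param t a `transform2d`; its linear part must be invertible.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "transform2d"))
  if (abs(det(t$matrix)) < .Machine$double.eps * 100)
    stop("invert_transform: singular linear part")
  Mi <- solve(t$matrix)
  transform2d(Mi, as.numeric(-Mi %*% t$offset), t$model,
              source_frame = t$target_frame, target_frame = t$source_frame)
}

.MODEL_ORDER <- c(translation = 1, rigid = 2, similarity = 3, affine = 4)

#' Compose two transforms
#'
#' `compose_transforms(a, b)` maps `p` to `a(b(p))`: `b` is applied first.
#' The model of the result is the least restrictive of the two. Frame
#' labels must chain (`b`'s target is `a`'s source) unless either is `NA`.
#'
#' @param a,b `transform2d` objects.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "transform2d"), inherits(b, "transform2d"))
  if (!is.na(a$source_frame) && !is.na(b$target_frame) &&
      a$source_frame != b$target_frame)
    stop(sprintf("compose_transforms: frames do not chain ('%s' -> '%s' then '%s' -> '%s')",
                 b$source_frame, b$target_frame, a$source_frame, a$target_frame))
  model <- names(.MODEL_ORDER)[max(.MODEL_ORDER[a$model], .MODEL_ORDER[b$model])]
  transform2d(a$matrix %*% b$matrix,
              as.numeric(a$matrix %*% b$offset) + a$offset, model,
              source_frame = b$source_frame, target_frame = a$target_frame)
}

#' Serialize a transform to JSON
#'
#' The JSON carries `model`, `matrix` (row-major, 4 numbers), `offset`,
#' `source_frame` and `target_frame`.
#'
#' @param t a `transform2d`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @export
write_transform <- function(t, path = NULL) {
  stopifnot(inherits(t, "transform2d"))
  obj <- list(model = t$model,
              matrix = as.numeric(t(t$matrix)),  # row-major
              offset = t$offset,
              source_frame = t$source_frame, target_frame = t$target_frame)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read a transform from JSON
#' @param path file path or a JSON string produced by [write_transform()].
#' @export
read_transform <- function(path) {
  obj <- jsonlite::fromJSON(path)
  transform2d(matrix(obj$matrix, 2, 2, byrow = TRUE), obj$offset, obj$model,
              source_frame = if (is.null(obj$source_frame)) NA_character_ else obj$source_frame,
              target_frame = if (is.null(obj$target_frame)) NA_character_ else obj$target_frame)
}

#' Named set of 2D fiducial coordinates
#'
#' The currency of every registration step: an ordered list of `(x, y)`
#' positions in one image frame, with optional physical pixel size.
#'
#' @param points n x 2 numeric matrix (or data frame) of `(x, y)` rows.
#' @param frame_id non-empty frame label.
#' @param pixel_size_nm physical size of one pixel in nanometres (optional).
#' @export
point_set <- function(points, frame_id, pixel_size_nm = NA_real_) {
  m <- as.matrix(points)
  if (length(m) == 0) m <- matrix(numeric(0), 0, 2)
  stopifnot(ncol(m) == 2, all(is.finite(m)))
  if (!is.character(frame_id) || length(frame_id) != 1 || !nzchar(frame_id))
    stop("point_set: frame_id must be a non-empty string")
  if (!is.na(pixel_size_nm) && pixel_size_nm <= 0)
    stop("point_set: pixel_size_nm must be > 0")
  dimnames(m) <- list(NULL, c("x", "y"))
  structure(list(points = m, frame_id = frame_id,
                 pixel_size_nm = as.numeric(pixel_size_nm)),
            class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set '%s'> %d points", x$frame_id, nrow(x$points)))
  if (!is.na(x$pixel_size_nm)) cat(sprintf(", %.4g nm/px", x$pixel_size_nm))
  cat("\n")
  invisible(x)
}

#' @export
length.point_set <- function(x) nrow(x$points)

#' Paired source/target landmark correspondences
#'
#' @param source,target n x 2 matrices (or `point_set`s) of paired points;
#'   row i of `source` corresponds to row i of `target`.
#' @param weight non-negative per-pair weights (default 1).
#' @return A `correspondences` object: list with `source`, `target`
#'   (n x 2 matrices) and `weight`.
#' @export
correspondences <- function(source, target, weight = NULL) {
  s <- if (inherits(source, "point_set")) source$points else as.matrix(source)
  t <- if (inherits(target, "point_set")) target$points else as.matrix(target)
  if (length(s) == 0) s <- matrix(numeric(0), 0, 2)
  if (length(t) == 0) t <- matrix(numeric(0), 0, 2)
  if (nrow(s) != nrow(t))
    stop("correspondences: source and target must pair up row by row")
  if (is.null(weight)) weight <- rep(1, nrow(s))
  if (any(weight < 0)) stop("correspondences: weights must be >= 0")
  structure(list(source = s, target = t, weight = as.numeric(weight)),
            class = "correspondences")
}

#' @export
length.correspondences <- function(x) nrow(x$source)
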