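#' Landmark-based transform estimation
#'
#' Weighted least-squares fits of planar transforms to point
#' correspondences, the core of the multi-scale correlation workflow:
#' the coarse stage registers the fluorescence image to the EM montage via
#' 200 nm beads, the fine stage registers the montage to the tomogram
#' z-projection via 50 nm gold.
#'
#' Model minima: translation needs 1 pair, rigid and similarity 2
#' non-coincident pairs, affine 3 non-collinear pairs.
#'
#' @name register
NULL

.model_min_points <- function(model)
  switch(model, translation = 1L, rigid = 2L, similarity = 2L, affine = 3L)

.fit_linear <- function(src, tgt, w, model, allow_reflection = TRUE) {
  # weighted fits on centered coordinates; returns list(matrix, offset)
  W <- w / sum(w)
  cs <- colSums(src * W); ct <- colSums(tgt * W)
  X <- sweep(src, 2, cs); Y <- sweep(tgt, 2, ct)
  if (model == "translation") {
    M <- diag(2)
  } else if (model == "affine") {
    A <- crossprod(X * W, X)            # 2x2 scatter
    if (rcond(A) < 1e-12)
      stop("estimate_transform: degenerate geometry (collinear points) for affine model")
    B <- crossprod(X * W, Y)            # X'WY
    M <- t(solve(A, B))
  } else {                               # rigid / similarity (Procrustes)
    S <- crossprod(Y * W, X)            # target x source covariance
    if (max(abs(S)) < .Machine$double.eps * 100 || sum(W * rowSums(X^2)) == 0)
      stop("estimate_transform: degenerate geometry (coincident points) for ", model, " model")
    sv <- svd(S)
    D <- diag(2)
    if (!allow_reflection && det(sv$u %*% t(sv$v)) < 0) D <- diag(c(1, -1))
    R <- sv$u %*% D %*% t(sv$v)
    if (model == "similarity") {
      s <- sum(diag(D) * sv$d) / sum(W * rowSums(X^2))
      if (s <= 0) stop("estimate_transform: non-positive scale; configuration degenerate")
      M <- s * R
    } else M <- R
  }
  list(matrix = M, offset = ct - as.numeric(M %*% cs))
}

.residuals_px <- function(M, offset, src, tgt) {
  pred <- src %*% t(M)
  pred[, 1] <- pred[, 1] + offset[1]; pred[, 2] <- pred[, 2] + offset[2]
  tgt - pred
}

.fre_rms <- function(res, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(res))
  sqrt(sum(w * rowSums(res^2)) / sum(w))
}

#' Fit a transform to landmark correspondences
#'
#' Weighted least squares: the similarity (and rigid) fit uses the
#' closed-form orthogonal-Procrustes solution with isotropic scale, the
#' affine fit normal equations on centered coordinates. Reports per-point
#' residuals in the target frame, the fiducial registration error
#' (`fre_rms_px`, the RMS residual norm) and, when one more pair than the
#' model minimum is available, leave-one-out target registration error
#' estimates (`loo_tre_px`): each point's prediction error under the fit
#' made from all other points.
#'
#' @param corr a [correspondences()] object (or anything coercible via
#'   `correspondences(source, target)`).
#' @param model `"translation"`, `"rigid"`, `"similarity"` or `"affine"`.
#' @param allow_reflection permit a negative-determinant (mirrored) fit for
#'   rigid/similarity models; LM and EM views of a grid are routinely
#'   mirrored, so this defaults to `TRUE`.
#' @param source_frame,target_frame frame labels stored on the transform.
#' @return A `registration_result`: list with `transform`,
#'   `correspondences`, `residuals_px` (n x 2), `fre_rms_px`, `loo_tre_px`
#'   (length n or `NULL`).
#' @export
estimate_transform <- function(corr,
                               model = c("similarity", "affine", "rigid", "translation"),
                               allow_reflection = TRUE,
                               source_frame = NA_character_,
                               target_frame = NA_character_) {
  model <- match.arg(model)
  stopifnot(inherits(corr, "correspondences"))
  n <- length(corr)
  nmin <- .model_min_points(model)
  if (n < nmin)
    stop(sprintf("estimate_transform: %s model needs at least %d correspondences, got %d",
                 model, nmin, n))
  if (any(corr$weight > 0) == FALSE)
    stop("estimate_transform: all weights are zero")
  fit <- .fit_linear(corr$source, corr$target, corr$weight, model, allow_reflection)
  res <- .residuals_px(fit$matrix, fit$offset, corr$source, corr$target)
  loo <- NULL
  if (n >= nmin + 1) {
    loo <- vapply(seq_len(n), function(i) {
      f <- tryCatch(
        .fit_linear(corr$source[-i, , drop = FALSE], corr$target[-i, , drop = FALSE],
                    corr$weight[-i], model, allow_reflection),
        error = function(e) NULL)
      if (is.null(f)) return(NA_real_)
      r <- .residuals_px(f$matrix, f$offset,
                         corr$source[i, , drop = FALSE], corr$target[i, , drop = FALSE])
      sqrt(sum(r^2))
    }, numeric(1))
  }
  structure(list(
    transform = transform2d(fit$matrix, fit$offset, model, source_frame, target_frame),
    correspondences = corr,
    residuals_px = res,
    fre_rms_px = .fre_rms(res, corr$weight),
    loo_tre_px = loo),
    class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result %s> %d correspondences\n",
              x$transform$model, length(x$correspondences)))
  cat(sprintf("  FRE (rms): %.4g px", x$fre_rms_px))
  if (!is.null(x$loo_tre_px))
    cat(sprintf("   LOO TRE (mean): %.4g px", mean(x$loo_tre_px, na.rm = TRUE)))
  cat("\n")
  print(x$transform)
  invisible(x)
}

#' Chromatic channel-shift correction from paired bead positions
#'
#' Multicolor beads imaged in two channels give paired positions; the
#' fitted transform maps the moving channel into the reference channel
#' frame and is applied to all subsequent images of the moving channel.
#' Chromatic shift varies across the field, so the default model is
#' affine.
#'
#' @param ref_points,moving_points `point_set`s (or n x 2 matrices) paired
#'   in order: the same beads seen in the reference and moving channel.
#' @param model transform model, default `"affine"`.
#' @return A `registration_result` whose transform maps moving -> reference.
#' @export
estimate_channel_shift <- function(ref_points, moving_points, model = "affine") {
  ref <- if (inherits(ref_points, "point_set")) ref_points else point_set(ref_points, "reference")
  mov <- if (inherits(moving_points, "point_set")) moving_points else point_set(moving_points, "moving")
  if (length(ref) != length(mov))
    stop("estimate_channel_shift: point lists must be paired in order (same beads, two channels)")
  estimate_transform(correspondences(mov$points, ref$points), model = model,
                     source_frame = mov$frame_id, target_frame = ref$frame_id)
}

.mutual_nn <- function(A, B, max_dist) {
  # one-to-one mutual nearest neighbours within max_dist; returns index pairs
  if (nrow(A) == 0 || nrow(B) == 0) return(cbind(integer(0), integer(0)))
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  ja <- max.col(-d2, ties.method = "first")            # nearest B for each A
  ib <- max.col(-t(d2), ties.method = "first")         # nearest A for each B
  keep <- which(ib[ja] == seq_len(nrow(A)) &
                d2[cbind(seq_len(nrow(A)), ja)] <= max_dist^2)
  cbind(keep, ja[keep])
}

#' Match fiducials between two images
#'
#' One-to-one pairing of detections (or picked points) in two frames. With
#' an initial transform, pairs are mutual nearest neighbours after mapping
#' the source through it. Without one, an exhaustive hypothesis search over
#' source/target point pairs proposes two-point similarity alignments
#' (both handedness variants) and keeps the hypothesis with the largest
#' mutual-nearest-neighbour consensus (ties: smallest total distance);
#' intended for small marker sets (n <= 30 per side).
#'
#' @param source,target n x 2 matrices of `(x, y)` positions, `point_set`s,
#'   or detection data frames with `x`/`y` columns.
#' @param initial optional `transform2d` mapping source -> target.
#' @param max_dist_px matching gate in target-frame pixels.
#' @param min_size smallest acceptable matching (default 3, enough for any
#'   model here); fewer matches raise an error.
#' @return A list: `pairs` (m x 2 matrix of source/target row indices),
#'   `correspondences` (a [correspondences()] object), and `hypothesis`
#'   (the aligning transform used, `NULL` when `initial` was given).
#' @export
match_correspondences <- function(source, target, initial = NULL,
                                  max_dist_px, min_size = 3L) {
  as_xy <- function(p) {
    if (inherits(p, "point_set")) return(p$points)
    if (is.data.frame(p)) return(as.matrix(p[, c("x", "y")]))
    as.matrix(p)
  }
  A <- as_xy(source); B <- as_xy(target)
  if (nrow(A) == 0 || nrow(B) == 0)
    stop("match_correspondences: empty point list")
  if (!is.null(initial)) {
    pairs <- .mutual_nn(apply_transform(initial, A), B, max_dist_px)
    hyp <- NULL
  } else {
    if (nrow(A) > 30 || nrow(B) > 30)
      stop("match_correspondences: exhaustive search supports at most 30 points per side; supply an initial transform")
    best <- list(n = -1L, cost = Inf, pairs = NULL, t = NULL)
    ia <- utils::combn(nrow(A), 2)
    for (k in seq_len(ncol(ia))) {
      i <- ia[1, k]; j <- ia[2, k]
      la <- sqrt(sum((A[j, ] - A[i, ])^2))
      if (la == 0) next
      for (p in seq_len(nrow(B))) for (q in seq_len(nrow(B))) {
        if (p == q) next
        for (refl in c(FALSE, TRUE)) {
          t2 <- .two_point_similarity(A[i, ], A[j, ], B[p, ], B[q, ], refl)
          if (is.null(t2)) next
          pr <- .mutual_nn(apply_transform(t2, A), B, max_dist_px)
          if (nrow(pr) < best$n) next
          TA <- apply_transform(t2, A[pr[, 1], , drop = FALSE])
          cost <- sum(sqrt(rowSums((TA - B[pr[, 2], , drop = FALSE])^2)))
          if (nrow(pr) > best$n || cost < best$cost)
            best <- list(n = nrow(pr), cost = cost, pairs = pr, t = t2)
        }
      }
    }
    pairs <- best$pairs; hyp <- best$t
    if (is.null(pairs)) pairs <- cbind(integer(0), integer(0))
  }
  if (nrow(pairs) < min_size)
    stop(sprintf("match_correspondences: no matching of size >= %d found (best: %d)",
                 min_size, nrow(pairs)))
  list(pairs = unname(pairs),
       correspondences = correspondences(A[pairs[, 1], , drop = FALSE],
                                         B[pairs[, 2], , drop = FALSE]),
       hypothesis = hyp)
}

.two_point_similarity <- function(a1, a2, b1, b2, reflect = FALSE) {
  # exact similarity mapping a1->b1, a2->b2 (with optional mirror)
  va <- a2 - a1; vb <- b2 - b1
  la2 <- sum(va^2)
  if (la2 == 0 || sum(vb^2) == 0) return(NULL)
  if (reflect) va <- c(va[1], -va[2])
  # complex ratio gives rotation+scale
  s <- complex(real = vb[1], imaginary = vb[2]) / complex(real = va[1], imaginary = va[2])
  M <- matrix(c(Re(s), Im(s), -Im(s), Re(s)), 2, 2)
  if (reflect) M <- M %*% diag(c(1, -1))
  off <- b1 - as.numeric(M %*% a1)
  tryCatch(transform2d(M, off, "similarity"), error = function(e) NULL)
}

#' Robust (consensus) transform estimation
#'
#' RANSAC-style fit guarding against mis-picked markers: minimal subsets
#' are sampled, the consensus set of correspondences whose residual is
#' within `inlier_threshold_px` is maximized, and the transform is refit by
#' least squares on the consensus. Deterministic for a fixed `seed`; the
#' global RNG state is left untouched.
#'
#' @inheritParams estimate_transform
#' @param inlier_threshold_px residual gate defining the consensus set.
#' @param max_iterations number of random minimal samples.
#' @param seed integer seed (required; no hidden global RNG state).
#' @return A `registration_result` with an extra `inlier_mask` logical
#'   vector.
#' @export
estimate_transform_robust <- function(corr, model = c("similarity", "affine", "rigid", "translation"),
                                      inlier_threshold_px = 2,
                                      max_iterations = 500L, seed,
                                      allow_reflection = TRUE,
                                      source_frame = NA_character_,
                                      target_frame = NA_character_) {
  model <- match.arg(model)
  stopifnot(inherits(corr, "correspondences"))
  if (missing(seed)) stop("estimate_transform_robust: seed is required")
  n <- length(corr)
  nmin <- .model_min_points(model)
  if (n < nmin)
    stop(sprintf("estimate_transform_robust: %s model needs at least %d correspondences", model, nmin))
  rng <- .seeded_rng(seed)
  best <- list(n = -1L, rss = Inf, mask = NULL)
  for (it in seq_len(max_iterations)) {
    idx <- rng$sample(n, nmin)
    f <- tryCatch(.fit_linear(corr$source[idx, , drop = FALSE],
                              corr$target[idx, , drop = FALSE],
                              rep(1, nmin), model, allow_reflection),
                  error = function(e) NULL)
    if (is.null(f)) next
    r <- .residuals_px(f$matrix, f$offset, corr$source, corr$target)
    ok <- sqrt(rowSums(r^2)) <= inlier_threshold_px
    rss <- sum(r[ok, , drop = FALSE]^2)
    if (sum(ok) > best$n || (sum(ok) == best$n && rss < best$rss))
      best <- list(n = sum(ok), rss = rss, mask = ok)
  }
  need <- if (n > nmin) nmin + 1L else nmin
  if (is.null(best$mask) || best$n < need)
    stop(sprintf("estimate_transform_robust: consensus of %d below the %d required for a trustworthy %s fit",
                 max(best$n, 0L), need, model))
  sub <- correspondences(corr$source[best$mask, , drop = FALSE],
                         corr$target[best$mask, , drop = FALSE],
                         corr$weight[best$mask])
  out <- estimate_transform(sub, model, allow_reflection, source_frame, target_frame)
  out$inlier_mask <- best$mask
  out
}

# Self-contained RNG: keeps robust estimation reproducible without touching
# the session's .Random.seed.
.seeded_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  env$sample <- function(n, k) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- sample.int(n, k)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    out
  }
  env
}

#' Chain the correlation stages into one mapping
#'
#' Composes the channel-shift correction, the coarse (bead) stage and the
#' fine (gold) stage into a single fluorescence-to-tomogram transform. The
#' coarse stage's target frame must be the fine stage's source frame.
#' The predicted end-to-end error propagates each stage's mean leave-one-out
#' TRE through the downstream scale factor:
#' `sqrt((s_fine * tre_coarse)^2 + tre_fine^2)` in tomogram pixels.
#'
#' @param fm_shift `transform2d` (or `registration_result`) correcting the
#'   shift between the two fluorescence channels; may be `NULL` when the
#'   probe channel is the registration channel.
#' @param coarse `registration_result` for the fluorescence -> montage
#'   stage (200 nm beads).
#' @param fine `registration_result` for the montage -> tomogram stage
#'   (50 nm gold).
#' @return A `correlation_chain`: list with the inputs, the composed
#'   `fm_to_tomogram` transform and `predicted_error_px` (tomogram pixels,
#'   `NA` when either stage lacks a TRE estimate).
#' @export
build_chain <- function(fm_shift, coarse, fine) {
  stopifnot(inherits(coarse, "registration_result"),
            inherits(fine, "registration_result"))
  tc <- coarse$transform; tf <- fine$transform
  if (!is.na(tc$target_frame) && !is.na(tf$source_frame) &&
      tc$target_frame != tf$source_frame)
    stop(sprintf("build_chain: coarse target frame '%s' does not match fine source frame '%s'",
                 tc$target_frame, tf$source_frame))
  shift_t <- if (is.null(fm_shift)) NULL
             else if (inherits(fm_shift, "registration_result")) fm_shift$transform
             else fm_shift
  fm2tomo <- compose_transforms(tf, tc)
  s_fine <- transform_scale(tf)
  tre_c <- if (!is.null(coarse$loo_tre_px)) mean(coarse$loo_tre_px, na.rm = TRUE) else NA_real_
  tre_f <- if (!is.null(fine$loo_tre_px)) mean(fine$loo_tre_px, na.rm = TRUE) else NA_real_
  structure(list(fm_channel_shift = shift_t, fm_to_montage = coarse,
                 montage_to_tomogram = fine, fm_to_tomogram = fm2tomo,
                 predicted_error_px = sqrt((s_fine * tre_c)^2 + tre_f^2)),
            class = "correlation_chain")
}

#' @export
print.correlation_chain <- function(x, ...) {
  cat("<correlation_chain>\n")
  cat(sprintf("  coarse FRE %.4g px | fine FRE %.4g px | predicted end-to-end error %.4g tomo px\n",
              x$fm_to_montage$fre_rms_px, x$montage_to_tomogram$fre_rms_px,
              x$predicted_error_px))
  print(x$fm_to_tomogram)
  invisible(x)
}

#' Map a fluorescence-frame point into the tomogram frame
#'
#' Applies the channel-shift correction (when the point is given in the
#' moving channel) and the composed chain.
#'
#' @param chain a `correlation_chain`.
#' @param p point(s), vector or n x 2 matrix.
#' @param from_moving_channel apply the channel-shift correction first.
#' @export
map_through_chain <- function(chain, p, from_moving_channel = FALSE) {
  stopifnot(inherits(chain, "correlation_chain"))
  if (from_moving_channel) {
    if (is.null(chain$fm_channel_shift))
      stop("map_through_chain: chain has no channel-shift transform")
    p <- apply_transform(chain$fm_channel_shift, p)
  }
  apply_transform(chain$fm_to_tomogram, p)
}
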