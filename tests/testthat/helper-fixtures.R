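# shared fixtures: random transforms, nearest-neighbour distances

random_similarity <- function(scale_range = c(0.5, 3), reflect = FALSE) {
  transform_similarity(theta = stats::runif(1, -pi, pi),
                       scale = stats::runif(1, scale_range[1], scale_range[2]),
                       dx = stats::runif(1, -50, 50), dy = stats::runif(1, -50, 50),
                       reflect = reflect)
}

random_affine <- function(max_cond = 1e3) {
  repeat {
    M <- matrix(stats::rnorm(4, sd = 1), 2, 2) + diag(2)
    if (abs(det(M)) > 0.05 && kappa(M) < max_cond) break
  }
  transform2d(M, stats::runif(2, -50, 50), "affine")
}

random_transform <- function(model) {
  switch(model,
         translation = transform_translation(stats::runif(1, -30, 30),
                                             stats::runif(1, -30, 30)),
         rigid = transform_similarity(stats::runif(1, -pi, pi), 1,
                                      stats::runif(1, -30, 30), stats::runif(1, -30, 30)),
         similarity = random_similarity(),
         affine = random_affine())
}

# per-row distance from each point in A to its nearest point in B
nn_dist <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(apply(d2, 1, min), 0))
}

# independent similarity least-squares oracle: exhaustive rotation grid with
# per-angle linear solve for scale/offset, then 1D refinement -- shares no
# code path with the closed-form Procrustes fit
similarity_oracle <- function(src, tgt) {
  sse_at <- function(theta) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    rx <- src %*% t(R)
    # minimize ||s * rx + t - tgt||^2 in (s, t)
    rxc <- sweep(rx, 2, colMeans(rx)); tc <- sweep(tgt, 2, colMeans(tgt))
    s <- sum(rxc * tc) / sum(rxc^2)
    off <- colMeans(tgt) - s * colMeans(rx)
    sum((s * rx + rep(1, nrow(src)) %o% off - tgt)^2)
  }
  grid <- seq(-pi, pi, length.out = 721)
  vals <- vapply(grid, sse_at, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(sse_at, c(lo, hi), tol = 1e-14)
  sqrt(opt$objective / nrow(src))   # RMS residual (FRE)
}
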