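# small fixture builders shared across test files; everything is built in
# code under fixed seeds, nothing is read from disk

tiny_gen <- function(..., n_vertices_per_hemi = 60L, n_frames = 96L,
                     seed = 11L) {
  generator_params(n_vertices_per_hemi = n_vertices_per_hemi,
                   n_frames = n_frames, seed = seed, ...)
}

# a one-hemisphere line of vertices at given x offsets (mm)
line_space <- function(offsets, hemi = "L") {
  surface_space(cbind(offsets, 0, 0), rep(hemi, length(offsets)))
}

# exactly mirror-symmetric two-hemisphere space from left coords
mirror_space <- function(cl, jitter = 0, seed = 1L) {
  set.seed(seed)
  cr <- cl
  cr[, 1L] <- -cr[, 1L]
  if (jitter > 0) cr <- cr + matrix(rnorm(length(cr), sd = jitter),
                                    nrow(cr), 3L)
  surface_space(rbind(cl, cr), rep(c("L", "R"), each = nrow(cl)))
}

rand_left_coords <- function(n, seed = 1L, radius = 50) {
  set.seed(seed)
  u <- matrix(rnorm(3L * n), n, 3L)
  u <- u / sqrt(rowSums(u^2))
  u[, 1L] <- -abs(u[, 1L])
  u * radius * runif(n, 0.95, 1.05)
}

make_ts <- function(data, tr = 0.8, ...) dense_timeseries(data, tr, ...)

# brute-force FCD oracle: full correlation matrix via stats::cor
oracle_fcd_counts <- function(ts, space, threshold = 0.6,
                              sign = "positive", scope = "global") {
  X <- t(ts$data[, ts$frame_mask, drop = FALSE])
  suppressWarnings(R <- stats::cor(X))
  R[!is.finite(R)] <- 0
  diag(R) <- 0
  A <- if (sign == "positive") R > threshold else R < -threshold
  hemi <- as.integer(space$hemisphere)
  same <- outer(hemi, hemi, "==")
  M <- switch(scope, global = A, ipsi = A & same, contra = A & !same)
  unname(rowSums(M))
}
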