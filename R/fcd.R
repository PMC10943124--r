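#' Parameters for functional connectivity density mapping
#'
#' @param threshold correlation threshold, strictly inside (0, 1);
#'   default 0.6 (the conventional gFCD threshold).
#' @param sign `"positive"` counts edges with r > threshold, `"negative"`
#'   edges with r < -threshold.
#' @param scope `"global"` counts edges to all other grayordinates,
#'   `"ipsi"` restricts to the same hemisphere, `"contra"` to the opposite
#'   hemisphere.
#' @param log_base transform applied to counts: `"natural"` (ln, with
#'   count 0 mapped to 0), `"log10"`, or `"none"` (raw counts).
#' @return Object of class `fcd_params`.
#' @export
fcd_params <- function(threshold = 0.6,
                       sign = c("positive", "negative"),
                       scope = c("global", "ipsi", "contra"),
                       log_base = c("natural", "log10", "none")) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie strictly inside (0, 1)")
  structure(list(threshold = threshold, sign = match.arg(sign),
                 scope = match.arg(scope), log_base = match.arg(log_base)),
            class = "fcd_params")
}

apply_log_rule <- function(counts, log_base) {
  switch(log_base,
         natural = ifelse(counts > 0, log(counts), 0),
         log10 = ifelse(counts > 0, log10(counts), 0),
         none = as.numeric(counts))
}

#' Functional connectivity density (thresholded-degree) mapping
#'
#' For each grayordinate, counts the edges (Pearson correlations beyond
#' the threshold, over retained frames only) to all other grayordinates,
#' optionally restricted to the same or the opposite hemisphere, and
#' applies the configured logarithm to obtain gFCD.  The correlation
#' matrix is computed in row chunks; results are bit-identical across
#' chunk sizes because every correlation is the same dot product of the
#' same standardized rows.  Zero-variance rows participate with r = 0 (no
#' edges, count 0).  The self-correlation is always excluded.
#'
#' @param ts a preprocessed [dense_timeseries()] (filtered and censored);
#'   at least 3 retained frames, not excluded.
#' @param space the [surface_space()] declaring the hemisphere of each row.
#' @param params an [fcd_params()] object.
#' @param chunk_size rows per chunk (memory knob; does not affect values).
#' @param rows optional integer vector of 1-based vertex indices for which
#'   to compute counts (edges are still counted against all vertices);
#'   other vertices get `NA`.  Used for ROI-restricted fast paths.
#' @return Object of class `fcd_result`: `counts` and `gfcd`
#'   ([scalar_map()]s), `params`, `n_frames_used`.
#' @export
compute_fcd <- function(ts, space, params = fcd_params(),
                        chunk_size = 256L, rows = NULL) {
  stopifnot(inherits(ts, "dense_timeseries"),
            inherits(space, "surface_space"),
            inherits(params, "fcd_params"))
  if (isTRUE(ts$excluded))
    stop("subject is flagged excluded; no maps may be computed")
  if (nrow(ts$data) != space$n)
    stop(sprintf("time series has %d rows but space has %d vertices",
                 nrow(ts$data), space$n))
  frames <- retained_frames(ts)
  if (length(frames) < 3L)
    stop("fewer than 3 retained frames")
  X <- ts$data[, frames, drop = FALSE]
  Xs <- standardize_rows(X)
  n <- space$n
  hemi_int <- as.integer(space$hemisphere)
  target <- if (is.null(rows)) seq_len(n) else sort(unique(as.integer(rows)))
  if (any(target < 1L | target > n)) stop("'rows' out of range")
  thr <- params$threshold
  counts <- rep(NA_real_, n)
  zv <- attr(Xs, "zero_variance")
  for (start in seq(1L, length(target), by = chunk_size)) {
    idx <- target[start:min(start + chunk_size - 1L, length(target))]
    R <- tcrossprod(Xs[idx, , drop = FALSE], Xs)
    A <- if (params$sign == "positive") R > thr else R < -thr
    if (params$scope == "global") {
      cnt <- rowSums(A)
    } else {
      same <- outer(hemi_int[idx], hemi_int, "==")
      cnt <- if (params$scope == "ipsi") rowSums(A & same)
             else rowSums(A & !same)
    }
    if (params$sign == "positive" && params$scope != "contra")
      cnt <- cnt - as.numeric(!zv[idx] & diag_hits(R, idx, thr))
    counts[idx] <- cnt
  }
  cm <- scalar_map(counts, space, name = paste0("fcd_counts_", params$scope),
                   units = "edges")
  gm <- scalar_map(apply_log_rule(counts, params$log_base), space,
                   name = paste0("gfcd_", params$scope), units = "")
  structure(list(counts = cm, gfcd = gm, params = params,
                 n_frames_used = length(frames)),
            class = "fcd_result")
}

# whether the self-correlation entry of each chunk row exceeded threshold
diag_hits <- function(R, idx, thr) {
  R[cbind(seq_along(idx), idx)] > thr
}

standardize_rows <- function(X) {
  mu <- rowMeans(X)
  Xc <- X - mu
  ss <- sqrt(rowSums(Xc^2))
  zv <- ss < 1e-12
  ss[zv] <- 1
  Xs <- Xc / ss
  Xs[zv, ] <- 0
  attr(Xs, "zero_variance") <- zv
  Xs
}

#' @export
print.fcd_result <- function(x, ...) {
  cat(sprintf("fcd_result: scope %s, sign %s, threshold %g, %d frames\n",
              x$params$scope, x$params$sign, x$params$threshold,
              x$n_frames_used))
  print(x$counts)
  invisible(x)
}

#' Verify the ipsi/contra decomposition of global FCD
#'
#' The edge set of every vertex partitions exactly into same-hemisphere
#' and opposite-hemisphere edges, so at identical threshold and sign
#' `counts(global) == counts(ipsi) + counts(contra)` must hold vertex-wise.
#' A violation is a hard error naming the first offending vertex.
#'
#' @inheritParams compute_fcd
#' @return Invisibly, a list with the three `fcd_result`s and
#'   `max_abs_diff` (always 0 on success).
#' @export
fcd_scope_decomposition_check <- function(ts, space, params = fcd_params(),
                                          chunk_size = 256L) {
  p <- function(scope) fcd_params(params$threshold, params$sign, scope,
                                  params$log_base)
  g <- compute_fcd(ts, space, p("global"), chunk_size)
  i <- compute_fcd(ts, space, p("ipsi"), chunk_size)
  c_ <- compute_fcd(ts, space, p("contra"), chunk_size)
  diff <- g$counts$values - (i$counts$values + c_$counts$values)
  bad <- which(diff != 0)
  if (length(bad))
    stop(sprintf("scope decomposition violated at vertex %d (global %g != ipsi %g + contra %g)",
                 bad[1L], g$counts$values[bad[1L]],
                 i$counts$values[bad[1L]], c_$counts$values[bad[1L]]))
  invisible(list(global = g, ipsi = i, contra = c_,
                 max_abs_diff = 0))
}
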