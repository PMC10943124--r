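#' Mean time series of a seed ROI
#'
#' Unweighted mean of the member vertex rows, restricted to retained
#' frames.
#'
#' @param ts a [dense_timeseries()] with at least 3 retained frames.
#' @param roi an [roi_from_center()] ROI whose members lie in the space.
#' @return Numeric vector, one value per retained frame.
#' @export
seed_timeseries <- function(ts, roi) {
  stopifnot(inherits(ts, "dense_timeseries"), inherits(roi, "roi"))
  if (length(roi$members) == 0L) stop("ROI has no members")
  if (max(roi$members) > nrow(ts$data))
    stop("ROI members exceed the number of vertices")
  frames <- retained_frames(ts)
  if (length(frames) < 3L) stop("fewer than 3 retained frames")
  colMeans(ts$data[roi$members, frames, drop = FALSE])
}

#' Seed-based functional connectivity map
#'
#' Correlates the seed ROI's mean series with every vertex series over the
#' retained frames and Fisher-transforms the result,
#' `z = atanh(r)` after clipping `|r| <= 1 - 1e-7`.  Zero-variance target
#' vertices get `NaN`.  Seed vertices are not excluded from the target
#' map (matching the averaged-ROI-correlation convention); ROI-level
#' statistics downstream handle self-overlap explicitly.
#'
#' @inheritParams seed_timeseries
#' @return Object of class `seed_fc_map`: `z` (a [scalar_map()] of Fisher
#'   z), `seed` (the ROI), `n_frames_used`.
#' @param space the [surface_space()] of the rows.
#' @export
seed_fc_map <- function(ts, roi, space) {
  stopifnot(inherits(space, "surface_space"))
  if (nrow(ts$data) != space$n)
    stop("time series and space disagree on the number of vertices")
  s <- seed_timeseries(ts, roi)
  sc <- s - mean(s)
  snorm <- sqrt(sum(sc^2))
  if (snorm < 1e-12) stop("seed mean series has zero variance")
  frames <- retained_frames(ts)
  X <- ts$data[, frames, drop = FALSE]
  Xc <- X - rowMeans(X)
  xnorm <- sqrt(rowSums(Xc^2))
  zv <- xnorm < 1e-12
  xnorm[zv] <- 1
  r <- as.vector(Xc %*% sc) / (xnorm * snorm)
  r[zv] <- NaN
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  structure(list(z = scalar_map(z, space,
                                name = paste0("rsfc_z_", roi$name),
                                units = "z"),
                 seed = roi, n_frames_used = length(frames)),
            class = "seed_fc_map")
}

#' @export
print.seed_fc_map <- function(x, ...) {
  cat(sprintf("seed_fc_map: seed '%s' (%d members), %d frames\n",
              x$seed$name, length(x$seed$members), x$n_frames_used))
  print(x$z)
  invisible(x)
}
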