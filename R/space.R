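#' Grayordinate surface space
#'
#' A `surface_space` is the universe of grayordinates for one subject or
#' cohort: one row of 3-D coordinates (mm) per vertex, a left/right
#' hemisphere label per vertex, and an optional parcel id.  Vertices are
#' addressed by R's 1-based index in memory; on-disk dialects use 0-based
#' ids and are converted at the I/O boundary.
#'
#' @param coords numeric matrix, N x 3, finite, columns x (left-right),
#'   y (posterior-anterior), z (inferior-superior), in mm.
#' @param hemisphere character or factor of length N with values `"L"` or
#'   `"R"` (case-insensitive `"left"`/`"right"` accepted).
#' @param parcel optional integer vector of length N of parcel ids.
#' @return An object of class `surface_space` with elements `coords`,
#'   `hemisphere` (factor with levels `L`, `R`), `parcel`, and `n`.
#' @examples
#' sp <- surface_space(rbind(c(-10, 0, 0), c(10, 0, 0)), c("L", "R"))
#' sp$n
#' @export
surface_space <- function(coords, hemisphere, parcel = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("'coords' must have 3 columns (x, y, z in mm)")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords)))
    stop("'coords' contains non-finite values")
  n <- nrow(coords)
  hemi <- normalize_hemi(hemisphere)
  if (length(hemi) != n)
    stop("'hemisphere' must have one label per vertex")
  if (n == 0L)
    stop("space must contain at least one vertex")
  if (!is.null(parcel)) {
    parcel <- as.integer(parcel)
    if (length(parcel) != n)
      stop("'parcel' must have one id per vertex")
  }
  structure(
    list(coords = unname(coords), hemisphere = hemi, parcel = parcel, n = n),
    class = "surface_space"
  )
}

normalize_hemi <- function(h) {
  h <- toupper(as.character(h))
  h[h %in% c("LEFT", "LH")] <- "L"
  h[h %in% c("RIGHT", "RH")] <- "R"
  if (!all(h %in% c("L", "R")))
    stop("hemisphere labels must be 'L'/'R' (or 'left'/'right')")
  factor(h, levels = c("L", "R"))
}

#' @export
print.surface_space <- function(x, ...) {
  cat(sprintf("surface_space: %d vertices (L: %d, R: %d)%s\n",
              x$n, sum(x$hemisphere == "L"), sum(x$hemisphere == "R"),
              if (is.null(x$parcel)) "" else ", parcellated"))
  invisible(x)
}

#' Per-grayordinate scalar map
#'
#' One real value per vertex of a [surface_space()] (`NA`/`NaN` encodes
#' "undefined", e.g. zero-variance targets).  Used for gFCD, Fisher-z
#' connectivity, laterality and t-score maps.
#'
#' @param values numeric vector, one per vertex.
#' @param space the [surface_space()] the map lives on.
#' @param name short map name (e.g. `"gfcd"`).
#' @param units unit string (`""` for unitless).
#' @return Object of class `scalar_map` with `values`, `space`, `name`,
#'   `units`.
#' @export
scalar_map <- function(values, space, name = "map", units = "") {
  stopifnot(inherits(space, "surface_space"))
  values <- as.numeric(values)
  if (length(values) != space$n)
    stop(sprintf("map has %d values but space has %d vertices",
                 length(values), space$n))
  structure(list(values = values, space = space, name = name, units = units),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  ok <- is.finite(x$values)
  cat(sprintf("scalar_map '%s': %d vertices, %d defined, range [%.4g, %.4g]\n",
              x$name, length(x$values), sum(ok),
              if (any(ok)) min(x$values[ok]) else NA,
              if (any(ok)) max(x$values[ok]) else NA))
  invisible(x)
}

same_space <- function(a, b) {
  a$space$n == b$space$n &&
    identical(a$space$hemisphere, b$space$hemisphere)
}

#' Spherical region of interest around a center vertex
#'
#' Members are all vertices of the center's hemisphere whose Euclidean
#' distance (on the supplied midthickness-style coordinates) to the center
#' is at most `radius`.  Geodesic distance is not implemented; the
#' `metric` argument exists so that configurations are explicit.
#'
#' @param space a [surface_space()].
#' @param center_vertex 1-based vertex index of the ROI center.
#' @param radius ROI radius in mm, > 0.
#' @param name ROI name (e.g. `"Ml"`, `"Mr"`).
#' @param metric distance convention; only `"euclidean"` is implemented.
#' @return Object of class `roi`: `name`, `center_vertex`, `radius`,
#'   `hemisphere`, `members` (sorted 1-based vertex indices).
#' @examples
#' sp <- surface_space(cbind(c(-1, -6, -20, 5), 0, 0),
#'                     c("L", "L", "L", "R"))
#' roi_from_center(sp, 1, 10)$members  # 1 and 2; 3 is 19 mm away
#' @export
roi_from_center <- function(space, center_vertex, radius, name = "roi",
                            metric = c("euclidean")) {
  stopifnot(inherits(space, "surface_space"))
  metric <- match.arg(metric)
  center_vertex <- as.integer(center_vertex)
  if (length(center_vertex) != 1L || is.na(center_vertex) ||
      center_vertex < 1L || center_vertex > space$n)
    stop("'center_vertex' must be a valid 1-based vertex index")
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("'radius' must be a positive length in mm")
  hemi <- space$hemisphere[center_vertex]
  on_hemi <- which(space$hemisphere == hemi)
  d2 <- colSums((t(space$coords[on_hemi, , drop = FALSE]) -
                   space$coords[center_vertex, ])^2)
  members <- sort(on_hemi[d2 <= radius^2])
  structure(list(name = name, center_vertex = center_vertex,
                 radius = radius, hemisphere = as.character(hemi),
                 members = members),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("roi '%s': center %d (%s hemi), radius %g mm, %d members\n",
              x$name, x$center_vertex, x$hemisphere, x$radius,
              length(x$members)))
  invisible(x)
}

#' Interhemispheric homologous vertex pairing
#'
#' Matches each left-hemisphere vertex to its mirror twin on the right
#' hemisphere.  Left coordinates are reflected in the left-right (x) axis
#' about `box_center`; each reflected vertex is matched to the nearest
#' right-hemisphere vertex, with one-to-one assignment enforced greedily in
#' ascending order of match residual (ties broken by lower vertex index).
#' The overall quality of the correspondence is summarized by the Pearson
#' correlation between the mirrored-left and matched-right coordinates,
#' pooled over all three axes.
#'
#' If the hemispheres have unequal sizes, `min(nL, nR)` pairs are formed
#' and the number of unmatched vertices is recorded with a warning.
#'
#' @param space a [surface_space()] with both hemispheres non-empty.
#' @param box_center length-3 numeric, mm; the reflection center.  Default
#'   `NULL` uses the actual bounding-box center of the space.  For real
#'   fs_LR-registered data the conventional value is `c(180, 218, 180)`.
#' @return Object of class `homologous_pairing`: `pairs` (data.frame with
#'   1-based `left`, `right`), `match_residual` (mm per pair),
#'   `coordinate_correlation`, `n_unmatched`, `box_center`.
#' @export
build_homologous_pairing <- function(space, box_center = NULL) {
  stopifnot(inherits(space, "surface_space"))
  left <- which(space$hemisphere == "L")
  right <- which(space$hemisphere == "R")
  if (length(left) == 0L || length(right) == 0L)
    stop("both hemispheres must be non-empty")
  if (is.null(box_center)) {
    rng <- apply(space$coords, 2L, range)
    box_center <- colMeans(rng)
  }
  if (length(box_center) != 3L || !all(is.finite(box_center)))
    stop("'box_center' must be a finite 3-vector (mm)")
  mirL <- space$coords[left, , drop = FALSE]
  mirL[, 1L] <- 2 * box_center[1L] - mirL[, 1L]
  cR <- space$coords[right, , drop = FALSE]

  nL <- length(left); nR <- length(right)
  n_pairs <- min(nL, nR)
  if (nL != nR)
    warning(sprintf("hemispheres have unequal sizes (%d vs %d); %d vertices unmatched",
                    nL, nR, abs(nL - nR)))
  # full residual matrix; greedy ascending-residual one-to-one assignment,
  # deterministic ties by (residual, left index, right index)
  d2 <- outer(rowSums(mirL^2), rowSums(cR^2), "+") - 2 * tcrossprod(mirL, cR)
  d2[d2 < 0] <- 0
  ord <- order(d2, row(d2), col(d2))
  li <- ((ord - 1L) %% nL) + 1L
  ri <- ((ord - 1L) %/% nL) + 1L
  l_free <- rep(TRUE, nL); r_free <- rep(TRUE, nR)
  pl <- integer(n_pairs); pr <- integer(n_pairs); res <- numeric(n_pairs)
  k <- 0L
  for (m in seq_along(ord)) {
    i <- li[m]; j <- ri[m]
    if (l_free[i] && r_free[j]) {
      k <- k + 1L
      pl[k] <- i; pr[k] <- j
      res[k] <- sqrt(sum((mirL[i, ] - cR[j, ])^2))
      l_free[i] <- FALSE; r_free[j] <- FALSE
      if (k == n_pairs) break
    }
  }
  o <- order(pl)
  pl <- pl[o]; pr <- pr[o]; res <- res[o]
  cc <- stats::cor(as.vector(mirL[pl, , drop = FALSE]),
                   as.vector(cR[pr, , drop = FALSE]))
  structure(list(
    pairs = data.frame(left = left[pl], right = right[pr]),
    match_residual = res,
    coordinate_correlation = cc,
    n_unmatched = abs(nL - nR),
    box_center = as.numeric(box_center)
  ), class = "homologous_pairing")
}

#' @export
print.homologous_pairing <- function(x, ...) {
  cat(sprintf(paste0("homologous_pairing: %d pairs, coordinate correlation %.4f,",
                     " median residual %.3g mm, %d unmatched\n"),
              nrow(x$pairs), x$coordinate_correlation,
              stats::median(x$match_residual), x$n_unmatched))
  invisible(x)
}
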