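#' Connectivity-based handedness index
#'
#' The normalized difference between the average gFCD in the right-hand
#' motor area Ml (left hemisphere) and the left-hand motor area Mr (right
#' hemisphere):
#' \deqn{I_H = \frac{gFCD(Ml) - gFCD(Mr)}{gFCD(Ml) + gFCD(Mr)}}
#' Positive values indicate right-hand-area dominance (the right-handed
#' direction, correlating positively with a questionnaire handedness
#' score whose right pole is +100).  The gFCD map should already be
#' grand-mean scaled across subjects (see [grand_mean_scale()]); note
#' that per-subject multiplicative scaling cancels in the ratio.
#'
#' @param gfcd a [scalar_map()] of gFCD values.
#' @param ml,mr the Ml (left-hemisphere) and Mr (right-hemisphere) motor
#'   ROIs.
#' @param subject_id subject identifier carried into the record.
#' @param eps denominator guard; `|gfcd(Ml) + gfcd(Mr)| <= eps` yields
#'   `NaN` with a warning.
#' @return A one-row data.frame: `subject_id`, `gfcd_ml`, `gfcd_mr`,
#'   `handedness_index`.
#' @export
handedness_index <- function(gfcd, ml, mr, subject_id = "subject",
                             eps = 1e-9) {
  stopifnot(inherits(gfcd, "scalar_map"), inherits(ml, "roi"),
            inherits(mr, "roi"))
  gml <- mean(gfcd$values[ml$members])
  gmr <- mean(gfcd$values[mr$members])
  denom <- gml + gmr
  ih <- if (!is.finite(denom) || abs(denom) <= eps) {
    warning("handedness index undefined (denominator ~ 0); returning NaN")
    NaN
  } else (gml - gmr) / denom
  data.frame(subject_id = subject_id, gfcd_ml = gml, gfcd_mr = gmr,
             handedness_index = ih, stringsAsFactors = FALSE)
}

#' Vertex-wise laterality index of hand-motor connectivity
#'
#' For each grayordinate, the normalized difference of its connectivity
#' (Fisher z by default) with the Ml and Mr seeds:
#' \deqn{\Delta(v) = \frac{z_{Ml}(v) - z_{Mr}(v)}{|z_{Ml}(v)| + |z_{Mr}(v)|}}
#' so `|Delta| <= 1` wherever defined, positive meaning stronger coupling
#' with the right-hand (Ml) network.  Vertices with
#' `|z_Ml| + |z_Mr| < eps` (or NaN inputs) are `NaN`.
#'
#' @param z_ml,z_mr [seed_fc_map()]s of the Ml and Mr seeds on the same
#'   space.
#' @param eps denominator guard.
#' @return Object of class `laterality_map`: `delta` (a [scalar_map()]),
#'   `seed_names`.
#' @export
laterality_map <- function(z_ml, z_mr, eps = 1e-9) {
  stopifnot(inherits(z_ml, "seed_fc_map"), inherits(z_mr, "seed_fc_map"))
  if (!same_space(z_ml$z, z_mr$z))
    stop("the two seed maps are not on the same space")
  a <- z_ml$z$values
  b <- z_mr$z$values
  denom <- abs(a) + abs(b)
  delta <- ifelse(is.finite(denom) & denom >= eps, (a - b) / denom, NaN)
  structure(list(delta = scalar_map(delta, z_ml$z$space, name = "delta",
                                    units = ""),
                 seed_names = c(z_ml$seed$name, z_mr$seed$name)),
            class = "laterality_map")
}

#' ROI-level laterality of hand-motor connectivity
#'
#' Computes, for each ROI, the mean seed-connectivity (Fisher z) with the
#' Ml and Mr seeds and the laterality index on those ROI means (not the
#' mean of the vertex-wise map): `(mean z_Ml - mean z_Mr) /
#' (|mean z_Ml| + |mean z_Mr|)`.
#'
#' @param z_ml,z_mr [seed_fc_map()]s on a shared space.
#' @param rois list of [roi_from_center()] ROIs.
#' @param eps denominator guard.
#' @return data.frame with one row per ROI: `roi`, `z_ml`, `z_mr`,
#'   `delta`.
#' @export
roi_laterality_table <- function(z_ml, z_mr, rois, eps = 1e-9) {
  stopifnot(is.list(rois), length(rois) > 0L)
  rows <- lapply(rois, function(r) {
    a <- mean(z_ml$z$values[r$members], na.rm = TRUE)
    b <- mean(z_mr$z$values[r$members], na.rm = TRUE)
    denom <- abs(a) + abs(b)
    data.frame(roi = r$name, z_ml = a, z_mr = b,
               delta = if (is.finite(denom) && denom >= eps)
                 (a - b) / denom else NaN,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Interhemispheric asymmetry of a scalar map
#'
#' For every homologous pair, `value(right) - value(left)`; positive means
#' rightward asymmetry.  Pairs whose vertices are unmatched do not exist
#' by construction; vertices left unmatched by the pairing are skipped and
#' counted in the pairing object itself.
#'
#' @param map a [scalar_map()] on the space the pairing was built on.
#' @param pairing a [build_homologous_pairing()] result.
#' @return data.frame with `left`, `right` (1-based indices) and
#'   `asymmetry`.
#' @export
asymmetry_map <- function(map, pairing) {
  stopifnot(inherits(map, "scalar_map"),
            inherits(pairing, "homologous_pairing"))
  if (max(pairing$pairs$left, pairing$pairs$right) > length(map$values))
    stop("pairing refers to vertices outside the map's space")
  data.frame(left = pairing$pairs$left, right = pairing$pairs$right,
             asymmetry = map$values[pairing$pairs$right] -
               map$values[pairing$pairs$left])
}

#' Functional specialization index of parcels
#'
#' Each parcel carries three association weights in `[0, 1]` for the
#' auditory, somatosensory and visual domains (an RGB convention).  The
#' pairwise absolute differences
#' `S1 = |aud - som|`, `S2 = |aud - vis|`, `S3 = |som - vis|`
#' yield the raw index `max(S) - mean(S)`; raw indices are normalized by
#' the maximum across the parcel set (when positive), so the most
#' specialized parcel scores 1.
#'
#' @param rgb numeric matrix or data.frame, parcels x 3 (auditory,
#'   somatosensory, visual), values in `[0, 1]`.
#' @param parcel_id optional parcel identifiers.
#' @return data.frame with `parcel_id`, the weights, `s1`, `s2`, `s3`,
#'   `raw`, `index`.
#' @export
specialization_index <- function(rgb, parcel_id = NULL) {
  rgb <- as.matrix(rgb)
  if (nrow(rgb) == 0L) stop("empty parcel list")
  if (ncol(rgb) != 3L) stop("'rgb' must have 3 columns (aud, som, vis)")
  if (any(!is.finite(rgb)) || any(rgb < 0 | rgb > 1))
    stop("association weights must lie in [0, 1]")
  if (is.null(parcel_id)) parcel_id <- seq_len(nrow(rgb))
  s1 <- abs(rgb[, 1L] - rgb[, 2L])
  s2 <- abs(rgb[, 1L] - rgb[, 3L])
  s3 <- abs(rgb[, 2L] - rgb[, 3L])
  raw <- pmax(s1, s2, s3) - (s1 + s2 + s3) / 3
  mx <- max(raw)
  index <- if (mx > 0) raw / mx else raw
  data.frame(parcel_id = parcel_id, aud = rgb[, 1L], som = rgb[, 2L],
             vis = rgb[, 3L], s1 = s1, s2 = s2, s3 = s3, raw = raw,
             index = index)
}
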