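#' Dense surface time series
#'
#' One subject's grayordinates-by-frames signal matrix together with the
#' repetition time, the framewise-displacement (FD) trace and a boolean
#' frame mask.  Frames with `frame_mask == FALSE` are never used by any
#' downstream correlation.
#'
#' @param data numeric matrix, vertices x frames (arbitrary BOLD units).
#' @param tr repetition time in seconds.
#' @param fd numeric vector of per-frame FD in mm; defaults to zeros.
#' @param frame_mask logical per frame; defaults to all `TRUE`.
#' @param subject_id subject identifier string.
#' @return Object of class `dense_timeseries` with fields `data`, `tr`,
#'   `fd`, `frame_mask`, `subject_id`, `excluded` (logical; set by
#'   [censor_high_motion()] when too few frames survive).
#' @export
dense_timeseries <- function(data, tr, fd = NULL, frame_mask = NULL,
                             subject_id = "subject") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("'tr' must be a positive scalar (seconds)")
  nt <- ncol(data)
  if (is.null(fd)) fd <- numeric(nt)
  if (is.null(frame_mask)) frame_mask <- rep(TRUE, nt)
  if (length(fd) != nt || length(frame_mask) != nt)
    stop("'fd' and 'frame_mask' must have one entry per frame")
  bad <- which(!is.finite(data))
  if (length(bad))
    stop(sprintf("non-finite entry at [vertex %d, frame %d]",
                 ((bad[1L] - 1L) %% nrow(data)) + 1L,
                 ((bad[1L] - 1L) %/% nrow(data)) + 1L))
  structure(list(data = data, tr = tr, fd = as.numeric(fd),
                 frame_mask = as.logical(frame_mask),
                 subject_id = as.character(subject_id),
                 excluded = FALSE),
            class = "dense_timeseries")
}

#' @export
print.dense_timeseries <- function(x, ...) {
  cat(sprintf("dense_timeseries '%s': %d vertices x %d frames, tr = %gs, %d retained%s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr,
              sum(x$frame_mask), if (x$excluded) " [EXCLUDED]" else ""))
  invisible(x)
}

retained_frames <- function(ts) which(ts$frame_mask)

supported_formats <- c("tsv", "bin")

resolve_format <- function(format) {
  if (format %in% c("cifti_dtseries", "hdf5_matrix"))
    stop(sprintf(paste0("format '%s' requires CIFTI/HDF5 support not available ",
                        "in this build; use one of: %s"),
                 format, paste(supported_formats, collapse = ", ")))
  match.arg(format, supported_formats)
}

sidecar_path <- function(stem) paste0(stem, ".json")

#' Write a dense time series to disk
#'
#' Two dialects are supported: `"tsv"` (tab-separated matrix written with 17
#' significant digits; portable, round-trips doubles exactly) and `"bin"`
#' (raw little-endian doubles; bit-exact and compact).  Both carry a JSON
#' sidecar `<stem>.json` with `tr`, `fd`, `subject_id` and the matrix shape.
#'
#' @param ts a [dense_timeseries()].
#' @param stem file stem; `<stem>.tsv`/`<stem>.bin` and `<stem>.json` are
#'   written.
#' @param format `"tsv"` or `"bin"`.
#' @return `stem`, invisibly.
#' @export
write_dense_timeseries <- function(ts, stem, format = c("tsv", "bin")) {
  stopifnot(inherits(ts, "dense_timeseries"))
  format <- resolve_format(format[1L])
  meta <- list(tr = ts$tr, fd = ts$fd, subject_id = ts$subject_id,
               n_vertices = nrow(ts$data), n_frames = ncol(ts$data),
               format = format)
  jsonlite::write_json(meta, sidecar_path(stem), auto_unbox = TRUE,
                       digits = NA)
  if (format == "tsv") {
    con <- file(paste0(stem, ".tsv"), "w")
    on.exit(close(con))
    writeLines(apply(ts$data, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = "\t")), con)
  } else {
    con <- file(paste0(stem, ".bin"), "wb")
    on.exit(close(con))
    writeBin(as.vector(ts$data), con, size = 8L, endian = "little")
  }
  invisible(stem)
}

#' Read a dense time series
#'
#' Reads a matrix written by [write_dense_timeseries()].  The JSON sidecar
#' must supply `tr`; a missing `fd` defaults to zeros.  The returned series
#' has an all-true frame mask (censoring is re-applied downstream from the
#' FD trace).
#'
#' @param stem file stem (without extension).
#' @param format `"tsv"` or `"bin"`.
#' @param space optional [surface_space()]; if given, the row count must
#'   equal the space size.
#' @return A [dense_timeseries()].
#' @export
read_dense_timeseries <- function(stem, format = c("tsv", "bin"),
                                  space = NULL) {
  format <- resolve_format(format[1L])
  sc <- sidecar_path(stem)
  if (!file.exists(sc)) stop(sprintf("missing sidecar '%s'", sc))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$tr)) stop("sidecar does not declare 'tr'")
  if (format == "tsv") {
    path <- paste0(stem, ".tsv")
    if (!file.exists(path)) stop(sprintf("missing file '%s'", path))
    x <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                     colClasses = "numeric"))
    dimnames(x) <- NULL
  } else {
    path <- paste0(stem, ".bin")
    if (!file.exists(path)) stop(sprintf("missing file '%s'", path))
    nv <- as.integer(meta$n_vertices); nt <- as.integer(meta$n_frames)
    con <- file(path, "rb")
    on.exit(close(con))
    x <- matrix(readBin(con, "double", n = nv * nt, size = 8L,
                        endian = "little"), nrow = nv, ncol = nt)
  }
  if (!is.null(space) && nrow(x) != space$n)
    stop(sprintf("matrix has %d rows but declared space has %d vertices",
                 nrow(x), space$n))
  fd <- meta$fd
  if (is.null(fd)) fd <- numeric(ncol(x))
  dense_timeseries(x, tr = meta$tr, fd = fd,
                   subject_id = if (is.null(meta$subject_id)) "subject"
                                else meta$subject_id)
}

#' Write/read a surface space as TSV
#'
#' Columns: `vertex_id` (0-based on disk), `hemi` (`L`/`R`), `x`, `y`, `z`
#' (mm) and optional `parcel`.
#'
#' @param space a [surface_space()].
#' @param path TSV file path.
#' @return `path` invisibly (write); a [surface_space()] (read).
#' @export
write_surface_space <- function(space, path) {
  stopifnot(inherits(space, "surface_space"))
  df <- data.frame(vertex_id = seq_len(space$n) - 1L,
                   hemi = as.character(space$hemisphere),
                   x = sprintf("%.17g", space$coords[, 1L]),
                   y = sprintf("%.17g", space$coords[, 2L]),
                   z = sprintf("%.17g", space$coords[, 3L]))
  if (!is.null(space$parcel)) df$parcel <- space$parcel
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surface_space
#' @export
read_surface_space <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("vertex_id", "hemi", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("space TSV must have columns vertex_id, hemi, x, y, z")
  df <- df[order(df$vertex_id), , drop = FALSE]
  if (!identical(as.integer(df$vertex_id), seq_len(nrow(df)) - 1L))
    stop("vertex_id must be dense 0-based [0, N)")
  surface_space(cbind(df$x, df$y, df$z), df$hemi,
                parcel = if ("parcel" %in% names(df)) df$parcel else NULL)
}

#' Write/read a scalar map as TSV
#'
#' Columns `vertex_id` (0-based on disk) and `value`; a JSON sidecar keeps
#' `name` and `units`.
#'
#' @param map a [scalar_map()].
#' @param stem file stem; `<stem>.tsv` and `<stem>.json` are written.
#' @param space the [surface_space()] to attach on read.
#' @return `stem` invisibly (write); a [scalar_map()] (read).
#' @export
write_scalar_map <- function(map, stem) {
  stopifnot(inherits(map, "scalar_map"))
  jsonlite::write_json(list(name = map$name, units = map$units,
                            n = length(map$values)),
                       sidecar_path(stem), auto_unbox = TRUE, digits = NA)
  con <- file(paste0(stem, ".tsv"), "w")
  on.exit(close(con))
  writeLines(c("vertex_id\tvalue",
               sprintf("%d\t%.17g", seq_along(map$values) - 1L, map$values)),
             con)
  invisible(stem)
}

#' @rdname write_scalar_map
#' @export
read_scalar_map <- function(stem, space) {
  meta <- jsonlite::read_json(sidecar_path(stem), simplifyVector = TRUE)
  df <- utils::read.table(paste0(stem, ".tsv"), sep = "\t", header = TRUE)
  df <- df[order(df$vertex_id), , drop = FALSE]
  scalar_map(df$value, space, name = meta$name, units = meta$units)
}

#' Export a homologous pairing as TSV
#'
#' Columns `left_id`, `right_id` (0-based on disk) and `residual_mm`.
#'
#' @param pairing a [build_homologous_pairing()] result.
#' @param path TSV path.
#' @export
write_pairing <- function(pairing, path) {
  stopifnot(inherits(pairing, "homologous_pairing"))
  df <- data.frame(left_id = pairing$pairs$left - 1L,
                   right_id = pairing$pairs$right - 1L,
                   residual_mm = pairing$match_residual)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
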