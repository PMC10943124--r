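#' Study configuration
#'
#' Bundles every knob of a full synthetic study: generator parameters,
#' preprocessing, FCD thresholding, statistics and the
#' discovery/replication split.  The whole report is regenerable from a
#' config plus its master seed.
#'
#' @param n_per_group subjects per handedness group.
#' @param gen a [generator_params()] object (its seed is the study's
#'   master seed).
#' @param band_low,band_high pass band, Hz.
#' @param filter_order Butterworth order.
#' @param fd_threshold frame-censoring threshold, mm.
#' @param min_retained_fraction subject-exclusion threshold on the
#'   retained-frame fraction.
#' @param fcd_threshold edge threshold for FCD.
#' @param log_base gFCD log rule (see [fcd_params()]).
#' @param alpha_fdr vertex-wise FDR level.
#' @param split_fraction discovery fraction of the cohort (default 0.505,
#'   which sends 303 of every 600-subject group to discovery: 909/891 on
#'   a 600/600/600 cohort).
#' @param covariates covariate columns used for residualization and the
#'   ROI models.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_per_group = 60L,
                         gen = generator_params(),
                         band_low = 0.01, band_high = 0.10,
                         filter_order = 4L,
                         fd_threshold = 0.5,
                         min_retained_fraction = 0.5,
                         fcd_threshold = 0.6,
                         log_base = "natural",
                         alpha_fdr = 0.05,
                         split_fraction = 0.505,
                         covariates = c("mean_fd", "age_months", "sex",
                                        "race", "site")) {
  stopifnot(inherits(gen, "generator_params"))
  structure(list(n_per_group = as.integer(n_per_group), gen = gen,
                 band_low = band_low, band_high = band_high,
                 filter_order = as.integer(filter_order),
                 fd_threshold = fd_threshold,
                 min_retained_fraction = min_retained_fraction,
                 fcd_threshold = fcd_threshold, log_base = log_base,
                 alpha_fdr = alpha_fdr, split_fraction = split_fraction,
                 covariates = covariates),
            class = "study_config")
}

#' Stratified discovery/replication split
#'
#' Splits the cohort into two disjoint subsets stratified by group and
#' sex.  Within each group the discovery target is
#' `round(fraction * n_group)`, allocated across sex strata by largest
#' remainder, so per-stratum counts deviate from the stratified target by
#' at most one and per-group totals are exact.  Deterministic under the
#' seed (substream `split`).
#'
#' @param cohort a [generate_cohort()] table (or any data.frame with
#'   `group` and `sex`).
#' @param fraction discovery fraction.
#' @param seed integer seed.
#' @return list with `discovery` and `replication` data.frames.
#' @export
split_discovery_replication <- function(cohort, fraction = 0.505,
                                        seed = 1L) {
  stopifnot(all(c("group", "sex") %in% names(cohort)))
  counts <- table(cohort$group)
  if (any(counts < 4L)) stop("need at least 4 subjects per group")
  set.seed(derive_seed(seed, "split"))
  disc_idx <- integer(0)
  for (g in sort(unique(cohort$group))) {
    rows_g <- which(cohort$group == g)
    target <- round(fraction * length(rows_g))
    sexes <- sort(unique(cohort$sex[rows_g]))
    strata <- lapply(sexes, function(s) rows_g[cohort$sex[rows_g] == s])
    exact <- fraction * lengths(strata)
    base <- pmin(floor(exact), lengths(strata))
    extra <- target - sum(base)
    room <- lengths(strata) - base
    o <- order(exact - base, decreasing = TRUE)
    while (extra > 0 && any(room > 0)) {
      for (k in o) {                     # one unit per stratum per sweep
        if (extra == 0) break
        if (room[k] > 0) {
          base[k] <- base[k] + 1L
          room[k] <- room[k] - 1L
          extra <- extra - 1L
        }
      }
    }
    for (k in seq_along(strata))
      disc_idx <- c(disc_idx,
                    sort(sample(strata[[k]], base[k])))
  }
  list(discovery = cohort[sort(disc_idx), , drop = FALSE],
       replication = cohort[setdiff(seq_len(nrow(cohort)), disc_idx), ,
                            drop = FALSE])
}

# multi-response analogue of residualize_group (rows must be finite)
residualize_matrix <- function(Y, covariates) {
  covariates <- as.data.frame(covariates)
  keep <- vapply(covariates, function(col) length(unique(col)) > 1L,
                 logical(1L))
  covariates <- covariates[, keep, drop = FALSE]
  if (ncol(covariates) == 0L) return(Y)
  for (j in seq_along(covariates))
    if (is.character(covariates[[j]]) || is.logical(covariates[[j]]))
      covariates[[j]] <- factor(covariates[[j]])
  X <- stats::model.matrix(~ ., data = covariates)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient covariate design in residualize_matrix")
  res <- stats::lm.fit(X, Y)$residuals
  sweep(res, 2L, colMeans(Y), "+")
}

#' Run a full synthetic handedness-laterality study
#'
#' Stage order: generate space and cohort; per subject generate the
#' series, band-pass filter (full series), censor high-motion frames
#' (subjects with too few retained frames are excluded with a logged
#' reason), compute FCD in all scopes plus the negative-threshold
#' control, compute Ml/Mr seed maps and the vertex-wise laterality map;
#' then grand-mean scale the ROI gFCD (sex x race strata) into
#' handedness-index records, split into discovery/replication, and for
#' the whole cohort and each split: index-score correlations, vertex-wise
#' L-vs-R contrasts (on per-group residualized maps) with BH-FDR,
#' asymmetry one- and two-sample contrasts over homologous pairs, Dice
#' consistency of the per-group asymmetry masks, and per-subject ROI
#' laterality tables.
#'
#' @param config a [study_config()].
#' @param verbose print stage progress.
#' @return Object of class `study_report`; see the package vignette for
#'   the field dictionary.
#' @export
run_study <- function(config = study_config(), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  gp <- config$gen
  say <- function(...) if (verbose) message(sprintf(...))
  say("generating space and cohort (seed %d)", gp$seed)
  sg <- generate_space(gp)
  cohort <- generate_cohort(config$n_per_group, gp)
  n <- nrow(cohort)
  nv <- sg$space$n
  pairing <- build_homologous_pairing(sg$space)

  scopes <- c("global", "ipsi", "contra")
  gfcd <- lapply(scopes, function(s) matrix(NA_real_, n, nv))
  names(gfcd) <- scopes
  gfcd_neg <- matrix(NA_real_, n, nv)
  z_ml <- matrix(NA_real_, n, nv)
  z_mr <- matrix(NA_real_, n, nv)
  delta <- matrix(NA_real_, n, nv)
  asym <- matrix(NA_real_, n, nrow(pairing$pairs))
  exclusions <- character(0)

  say("processing %d subjects", n)
  for (i in seq_len(n)) {
    ts <- generate_subject_timeseries(sg, cohort[i, ], gp)
    ts <- bandpass(ts, config$band_low, config$band_high,
                   config$filter_order)
    ts <- censor_high_motion(ts, config$fd_threshold,
                             config$min_retained_fraction)
    if (ts$excluded) {
      exclusions <- c(exclusions,
                      sprintf("%s: retained fraction %.2f < %.2f",
                              cohort$subject_id[i],
                              attr(ts, "retained_fraction"),
                              config$min_retained_fraction))
      next
    }
    for (s in scopes) {
      res <- compute_fcd(ts, sg$space,
                         fcd_params(config$fcd_threshold, "positive", s,
                                    config$log_base))
      gfcd[[s]][i, ] <- res$gfcd$values
    }
    gfcd_neg[i, ] <- compute_fcd(ts, sg$space,
                                 fcd_params(config$fcd_threshold,
                                            "negative", "global",
                                            config$log_base))$gfcd$values
    ml_map <- seed_fc_map(ts, sg$ml, sg$space)
    mr_map <- seed_fc_map(ts, sg$mr, sg$space)
    z_ml[i, ] <- ml_map$z$values
    z_mr[i, ] <- mr_map$z$values
    delta[i, ] <- laterality_map(ml_map, mr_map)$delta$values
    gmap <- scalar_map(gfcd$global[i, ], sg$space)
    asym[i, ] <- asymmetry_map(gmap, pairing)$asymmetry
  }
  kept <- is.finite(gfcd$global[, 1L])
  if (mean(kept) < 0.5)
    stop(sprintf("%d of %d subjects excluded; aborting (%s ...)",
                 sum(!kept), n, exclusions[1L]))

  say("index records and split")
  gml <- rowMeans(gfcd$global[, sg$ml$members, drop = FALSE])
  gmr <- rowMeans(gfcd$global[, sg$mr$members, drop = FALSE])
  strata <- interaction(cohort$sex, cohort$race, drop = TRUE)
  overall <- rowMeans(gfcd$global)
  scale_f <- rep(NA_real_, n)
  scale_f[kept] <- grand_mean_scale(overall[kept],
                                    droplevels(strata[kept])) /
    overall[kept]
  rec <- data.frame(subject_id = cohort$subject_id, group = cohort$group,
                    ehis_score = cohort$ehis_score,
                    gfcd_ml = gml * scale_f, gfcd_mr = gmr * scale_f,
                    stringsAsFactors = FALSE)
  rec$handedness_index <- (rec$gfcd_ml - rec$gfcd_mr) /
    (rec$gfcd_ml + rec$gfcd_mr)
  split <- split_discovery_replication(cohort, config$split_fraction,
                                       gp$seed)
  rec$split <- ifelse(cohort$subject_id %in% split$discovery$subject_id,
                      "discovery", "replication")

  index_ehis <- function(rows) {
    ok <- rows & is.finite(rec$handedness_index)
    ct <- stats::cor.test(rec$handedness_index[ok], rec$ehis_score[ok])
    data.frame(n = sum(ok), r = unname(ct$estimate), p = ct$p.value)
  }
  correlations <- rbind(
    cbind(sample = "all", index_ehis(rep(TRUE, n))),
    cbind(sample = "discovery", index_ehis(rec$split == "discovery")),
    cbind(sample = "replication", index_ehis(rec$split == "replication")))

  say("group contrasts")
  covs <- cohort[, config$covariates, drop = FALSE]
  resid_by_group <- function(Y) {
    out <- Y
    for (g in unique(cohort$group)) {
      rows <- cohort$group == g & kept
      out[rows, ] <- residualize_matrix(Y[rows, , drop = FALSE],
                                        covs[rows, , drop = FALSE])
    }
    out
  }
  contrast_lr <- function(Y, rows = rep(TRUE, n)) {
    Yr <- resid_by_group(Y)
    two_sample_t_map(Yr[cohort$group == "L" & kept & rows, , drop = FALSE],
                     Yr[cohort$group == "R" & kept & rows, , drop = FALSE],
                     alpha_fdr = config$alpha_fdr, space = sg$space)
  }
  contrasts <- list(
    gfcd_global = contrast_lr(gfcd$global),
    gfcd_ipsi = contrast_lr(gfcd$ipsi),
    gfcd_contra = contrast_lr(gfcd$contra),
    gfcd_negative = contrast_lr(gfcd_neg),
    delta = contrast_lr(delta))

  say("asymmetry")
  pair_space <- surface_space(
    sg$space$coords[pairing$pairs$right, , drop = FALSE],
    rep("R", nrow(pairing$pairs)))
  asym_one_sample <- lapply(c(L = "L", R = "R", M = "M"), function(g)
    one_sample_t_map(asym[cohort$group == g & kept, , drop = FALSE],
                     alpha_fdr = config$alpha_fdr, space = pair_space))
  asym_lr <- two_sample_t_map(asym[cohort$group == "L" & kept, ,
                                   drop = FALSE],
                              asym[cohort$group == "R" & kept, ,
                                   drop = FALSE],
                              alpha_fdr = config$alpha_fdr,
                              space = pair_space)
  dice_pairs <- utils::combn(c("L", "R", "M"), 2L, simplify = FALSE)
  dice_tab <- do.call(rbind, lapply(dice_pairs, function(pr) {
    a <- asym_one_sample[[pr[1L]]]
    b <- asym_one_sample[[pr[2L]]]
    data.frame(groups = paste(pr, collapse = "-"),
               dice_rightward = dice(a$q_mask & a$t$values > 0,
                                     b$q_mask & b$t$values > 0),
               dice_leftward = dice(a$q_mask & a$t$values < 0,
                                    b$q_mask & b$t$values < 0))
  }))

  say("ROI laterality tables")
  roi_delta <- data.frame(
    subject_id = cohort$subject_id, group = cohort$group,
    split = rec$split,
    delta_ml = rowMeans(delta[, sg$ml$members, drop = FALSE]),
    delta_mr = rowMeans(delta[, sg$mr$members, drop = FALSE]),
    stringsAsFactors = FALSE)

  group_mean_gfcd <- do.call(rbind, lapply(c("L", "R", "M"), function(g)
    colMeans(gfcd$global[cohort$group == g & kept, , drop = FALSE])))
  rownames(group_mean_gfcd) <- c("L", "R", "M")

  structure(list(
    config = config,
    space = sg,
    pairing = pairing,
    cohort = cohort,
    subject_index = rec,
    correlations = correlations,
    contrasts = contrasts,
    asymmetry = list(one_sample = asym_one_sample, l_vs_r = asym_lr,
                     dice = dice_tab),
    roi_delta = roi_delta,
    group_mean_gfcd = group_mean_gfcd,
    exclusions = exclusions,
    provenance = list(
      seed = gp$seed,
      package_version = as.character(utils::packageVersion("handlat")),
      r_version = R.version.string,
      processing_order = "generate -> bandpass -> censor -> fcd/seedfc -> indices -> residualize -> contrasts",
      date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report: %d subjects (%d excluded), %d vertices\n",
              nrow(x$cohort), length(x$exclusions), x$space$space$n))
  cat("index-score correlations:\n")
  print(x$correlations, row.names = FALSE)
  cat(sprintf("L-vs-R gFCD contrast: %d significant vertices at pFDR < %g\n",
              sum(x$contrasts$gfcd_global$q_mask, na.rm = TRUE),
              x$config$alpha_fdr))
  invisible(x)
}

#' Write a study report to plain files
#'
#' Emits TSV tables (subject index, correlations, ROI laterality, Dice,
#' exclusions), scalar-map TSVs for the main contrasts and group means,
#' and a JSON provenance snapshot.
#'
#' @param report a [run_study()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  w(report$subject_index, "subject_index.tsv")
  w(report$correlations, "index_ehis_correlations.tsv")
  w(report$roi_delta, "roi_delta.tsv")
  w(report$asymmetry$dice, "asymmetry_dice.tsv")
  if (length(report$exclusions))
    writeLines(report$exclusions, file.path(out_dir, "exclusions.txt"))
  for (nm in names(report$contrasts))
    write_scalar_map(report$contrasts[[nm]]$t,
                     file.path(out_dir, paste0("t_", nm)))
  write_pairing(report$pairing, file.path(out_dir, "pairing.tsv"))
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
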