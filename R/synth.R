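#' Parameters of the synthetic cohort generator
#'
#' The generator emulates the statistical structure the analysis relies
#' on: a mirror-symmetric left/right vertex cloud, BOLD-like signals with
#' posterior connectivity hubs, homotopic coupling between mirror twins,
#' hand-motor patches whose intra-hemispheric coupling depends on
#' handedness, framewise-displacement traces with censorable spikes, and
#' questionnaire-style handedness scores.  Signals follow a latent-factor
#' (low-rank plus noise) model so generation costs O(vertices x frames).
#'
#' Loadings are expressed relative to `noise_sd`.  With the defaults the
#' population correlation between two hand-motor members is
#' `w^2 / (w^2 + lambda^2 + 1) ~ 0.61`, i.e. sitting at the r > 0.6 edge
#' threshold, so a handedness-dependent shift of the coupling `w` moves
#' suprathreshold edge counts in the direction the analysis expects
#' (right-handers: left motor patch up, right motor patch down).
#'
#' @param n_vertices_per_hemi vertices per hemisphere (>= 50).
#' @param n_frames frames per subject (>= 64).
#' @param tr repetition time, seconds (default 0.8, a typical multiband
#'   acquisition).
#' @param hub_fraction fraction of each hemisphere assigned to the
#'   posterior hub set.
#' @param hub_coupling loading of hub vertices on the shared hub factor.
#' @param homotopic_rho target correlation between mirror twins induced by
#'   the shared homotopic factor (loading `sqrt(rho/(1-rho)) * noise_sd`).
#' @param motor_coupling_base baseline loading of hand-motor members on
#'   their hemisphere's motor factor.
#' @param motor_asymmetry_effect handedness-dependent shift of the motor
#'   coupling; a subject with handedness score `s` gets
#'   `w(Ml) = base + effect * s/100` and `w(Mr) = base - effect * s/100`.
#' @param noise_sd standard deviation of the private vertex noise.
#' @param fd_spike_rate per-frame probability of a censorable motion spike
#'   (FD drawn in 0.6-1.5 mm).
#' @param fd_baseline_mean,fd_baseline_sd baseline FD distribution
#'   (|Normal|, mm); defaults match a typical developmental cohort
#'   (mean ~ 0.12 mm).
#' @param roi_radius hand-motor ROI radius, mm.
#' @param brain_radius nominal hemisphere shell radius, mm.
#' @param jitter_sd coordinate jitter of the right hemisphere, mm
#'   (0 = exact mirror).
#' @param neighbor_radius_factor,neighbor_weight the motor factor also
#'   loads (at `neighbor_weight * w`) on same-hemisphere vertices within
#'   `neighbor_radius_factor * roi_radius` of the ROI center.
#' @param seed master seed; all randomness flows from named substreams of
#'   it, so any subject is regenerable in isolation.
#' @return Object of class `generator_params`.
#' @export
generator_params <- function(n_vertices_per_hemi = 200L,
                             n_frames = 256L,
                             tr = 0.8,
                             hub_fraction = 0.15,
                             hub_coupling = 1.5,
                             homotopic_rho = 0.3,
                             motor_coupling_base = 1.5,
                             motor_asymmetry_effect = 0.25,
                             noise_sd = 1,
                             fd_spike_rate = 0.05,
                             fd_baseline_mean = 0.12,
                             fd_baseline_sd = 0.04,
                             roi_radius = 10,
                             brain_radius = 50,
                             jitter_sd = 0,
                             neighbor_radius_factor = 1.8,
                             neighbor_weight = 0.5,
                             seed = 1L) {
  p <- list(n_vertices_per_hemi = as.integer(n_vertices_per_hemi),
            n_frames = as.integer(n_frames), tr = tr,
            hub_fraction = hub_fraction, hub_coupling = hub_coupling,
            homotopic_rho = homotopic_rho,
            motor_coupling_base = motor_coupling_base,
            motor_asymmetry_effect = motor_asymmetry_effect,
            noise_sd = noise_sd, fd_spike_rate = fd_spike_rate,
            fd_baseline_mean = fd_baseline_mean,
            fd_baseline_sd = fd_baseline_sd,
            roi_radius = roi_radius, brain_radius = brain_radius,
            jitter_sd = jitter_sd,
            neighbor_radius_factor = neighbor_radius_factor,
            neighbor_weight = neighbor_weight,
            seed = as.integer(seed))
  for (nm in c("hub_fraction", "homotopic_rho", "fd_spike_rate"))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop(sprintf("'%s' must lie in [0, 1]", nm))
  if (p$n_frames < 64L) stop("'n_frames' must be >= 64")
  if (p$n_vertices_per_hemi < 50L)
    stop("'n_vertices_per_hemi' must be >= 50")
  structure(p, class = "generator_params")
}

# deterministic substream seed derivation (kept below 2^31)
derive_seed <- function(seed, tag) {
  u <- utf8ToInt(tag)
  h <- sum(u * seq_along(u)) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483647)
}

#' Generate a mirror-symmetric synthetic surface space
#'
#' Samples the left hemisphere on a jittered spherical shell restricted to
#' x < 0 and mirrors it exactly (plus optional coordinate jitter) to the
#' right hemisphere, so the ground-truth homologous pairing is vertex i on
#' the left with vertex `n + i` on the right.  Designated hand-motor
#' patches at mirrored dorsal locations define the Ml (left) and Mr
#' (right) ROIs, and the posterior `hub_fraction` of each hemisphere forms
#' the hub set.
#'
#' @param params a [generator_params()] object.
#' @return Object of class `synthetic_space`: `space` (a
#'   [surface_space()]), `ml`, `mr` (ROIs), `pairing_truth` (data.frame
#'   `left`, `right`), `hubs` (vertex indices, both hemispheres),
#'   `ml_nbr`, `mr_nbr` (neighborhood vertex sets), `params`.
#' @export
generate_space <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(derive_seed(params$seed, "space"))
  n <- params$n_vertices_per_hemi
  u <- matrix(stats::rnorm(3L * n), n, 3L)
  u <- u / sqrt(rowSums(u^2))
  u[, 1L] <- -abs(u[, 1L])                       # left hemisphere: x < 0
  rad <- params$brain_radius * stats::runif(n, 0.95, 1.05)
  cl <- u * rad
  cr <- cl
  cr[, 1L] <- -cr[, 1L]                          # exact mirror
  if (params$jitter_sd > 0)
    cr <- cr + matrix(stats::rnorm(3L * n, sd = params$jitter_sd), n, 3L)
  coords <- rbind(cl, cr)
  space <- surface_space(coords, rep(c("L", "R"), each = n))

  # hand-motor patch: dorsal, slightly anterior and lateral
  target <- params$brain_radius * c(-0.35, 0.15, 0.92) /
    sqrt(sum(c(-0.35, 0.15, 0.92)^2))
  ml_center <- which.min(colSums((t(cl) - target)^2))
  ml <- roi_from_center(space, ml_center, params$roi_radius, name = "Ml")
  mr <- roi_from_center(space, n + ml_center, params$roi_radius, name = "Mr")

  nbr <- function(center, hemi_ids) {
    d2 <- colSums((t(space$coords[hemi_ids, , drop = FALSE]) -
                     space$coords[center, ])^2)
    hemi_ids[d2 <= (params$neighbor_radius_factor * params$roi_radius)^2]
  }
  ml_nbr <- setdiff(nbr(ml_center, seq_len(n)), ml$members)
  mr_nbr <- setdiff(nbr(n + ml_center, n + seq_len(n)), mr$members)

  # posterior hubs (low y), symmetric, excluding the motor system
  n_hub <- max(1L, round(params$hub_fraction * n))
  cand <- setdiff(seq_len(n), c(ml$members, ml_nbr))
  hubs_l <- cand[order(cl[cand, 2L])][seq_len(min(n_hub, length(cand)))]
  hubs <- c(hubs_l, n + hubs_l)                  # mirror twins on the right

  structure(list(space = space, ml = ml, mr = mr,
                 pairing_truth = data.frame(left = seq_len(n),
                                            right = n + seq_len(n)),
                 hubs = hubs, ml_nbr = ml_nbr, mr_nbr = mr_nbr,
                 params = params),
            class = "synthetic_space")
}

#' @export
print.synthetic_space <- function(x, ...) {
  cat(sprintf("synthetic_space: %d vertices/hemi, Ml %d members, %d hubs/hemi\n",
              x$params$n_vertices_per_hemi, length(x$ml$members),
              length(x$hubs) / 2L))
  invisible(x)
}

#' Generate one subject's dense time series
#'
#' Latent-factor model: private Gaussian noise per vertex, a shared hub
#' factor over the posterior hub set, a homotopic factor shared between
#' each mirror pair, and per-hemisphere hand-motor factors whose loadings
#' depend on the subject's handedness score (see [generator_params()]).
#' The FD trace mixes a |Normal| baseline with Bernoulli motion spikes
#' above the 0.5 mm censoring threshold.  The series is white in time;
#' band-limiting is applied by the pipeline's filter stage.
#'
#' All randomness comes from the substream `subject_<id>` of the master
#' seed, so a subject is bit-reproducible in isolation and group labels
#' with `motor_asymmetry_effect = 0` have no effect on the distribution.
#'
#' @param sspace a [generate_space()] result.
#' @param subject one cohort row (list/data.frame row) with `subject_id`
#'   and `ehis_score`.
#' @param params a [generator_params()]; defaults to the space's.
#' @return A [dense_timeseries()].
#' @export
generate_subject_timeseries <- function(sspace, subject, params = NULL) {
  stopifnot(inherits(sspace, "synthetic_space"))
  if (is.null(params)) params <- sspace$params
  set.seed(derive_seed(params$seed, paste0("subject_", subject$subject_id)))
  n <- sspace$space$n
  nt <- params$n_frames
  Y <- matrix(stats::rnorm(n * nt, sd = params$noise_sd), n, nt)

  h <- stats::rnorm(nt)
  Y[sspace$hubs, ] <- Y[sspace$hubs, ] + params$hub_coupling *
    matrix(h, length(sspace$hubs), nt, byrow = TRUE)

  if (params$homotopic_rho > 0) {
    lam <- sqrt(params$homotopic_rho / (1 - params$homotopic_rho)) *
      params$noise_sd
    G <- matrix(stats::rnorm(nrow(sspace$pairing_truth) * nt), ncol = nt)
    Y[sspace$pairing_truth$left, ] <- Y[sspace$pairing_truth$left, ] +
      lam * G
    Y[sspace$pairing_truth$right, ] <- Y[sspace$pairing_truth$right, ] +
      lam * G
  }

  shift <- params$motor_asymmetry_effect * subject$ehis_score / 100
  w_ml <- max(0, params$motor_coupling_base + shift)
  w_mr <- max(0, params$motor_coupling_base - shift)
  f_l <- stats::rnorm(nt)
  f_r <- stats::rnorm(nt)
  add_factor <- function(Y, ids, w, f) {
    if (length(ids) && w > 0)
      Y[ids, ] <- Y[ids, ] + w * matrix(f, length(ids), nt, byrow = TRUE)
    Y
  }
  Y <- add_factor(Y, sspace$ml$members, w_ml, f_l)
  Y <- add_factor(Y, sspace$ml_nbr, params$neighbor_weight * w_ml, f_l)
  Y <- add_factor(Y, sspace$mr$members, w_mr, f_r)
  Y <- add_factor(Y, sspace$mr_nbr, params$neighbor_weight * w_mr, f_r)

  fd <- abs(stats::rnorm(nt, params$fd_baseline_mean, params$fd_baseline_sd))
  spikes <- stats::runif(nt) < params$fd_spike_rate
  fd[spikes] <- stats::runif(sum(spikes), 0.6, 1.5)

  dense_timeseries(Y, tr = params$tr, fd = fd,
                   subject_id = as.character(subject$subject_id))
}

#' Generate a balanced synthetic cohort table
#'
#' Balanced left- (L), right- (R) and mixed-handed (M) groups with
#' questionnaire-style handedness items on the scale
#' \{100, 50, 0, -50, -100\} (right pole positive; four items, the score is
#' their mean), and covariates drawn from distributions typical of a
#' large developmental cohort: age ~ 9-11 years, ~43% girls, five
#' race/ethnicity strata, four sites, three scanner vendors, baseline
#' FD ~ 0.12 mm, brain volume ~ 1215 mL.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param params a [generator_params()].
#' @return data.frame of class `cohort_table` with columns `subject_id`,
#'   `group`, `ehis_item1..4`, `ehis_score`, `age_months`, `sex`, `race`,
#'   `site`, `scanner`, `mean_fd`, `brain_volume_ml`.
#' @export
generate_cohort <- function(n_per_group, params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 2L) stop("'n_per_group' must be >= 2")
  set.seed(derive_seed(params$seed, "cohort"))
  groups <- rep(c("L", "R", "M"), each = n_per_group)
  n <- length(groups)
  items <- matrix(NA_real_, n, 4L)
  for (i in seq_len(n)) {
    items[i, ] <- switch(groups[i],
      R = sample(c(100, 50), 4L, replace = TRUE, prob = c(0.75, 0.25)),
      L = sample(c(-100, -50), 4L, replace = TRUE, prob = c(0.75, 0.25)),
      M = sample(c(50, 0, -50), 4L, replace = TRUE, prob = c(0.3, 0.4, 0.3)))
  }
  score <- rowMeans(items)
  df <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    group = groups,
    ehis_item1 = items[, 1L], ehis_item2 = items[, 2L],
    ehis_item3 = items[, 3L], ehis_item4 = items[, 4L],
    ehis_score = score,
    age_months = round(stats::rnorm(n, 120, 7.5)),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.43, 0.57)),
    race = sample(c("White", "Hispanic", "AfricanAmerican", "Asian", "Other"),
                  n, replace = TRUE,
                  prob = c(0.53, 0.18, 0.18, 0.02, 0.09)),
    site = sample(paste0("site", 1:4), n, replace = TRUE),
    scanner = sample(c("Siemens", "GE", "Philips"), n, replace = TRUE,
                     prob = c(0.64, 0.24, 0.12)),
    mean_fd = abs(stats::rnorm(n, params$fd_baseline_mean,
                               params$fd_baseline_sd)) + 0.01,
    brain_volume_ml = round(stats::rnorm(n, 1215, 108)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Fast per-subject handedness index through the real pipeline stages
#'
#' Generates a subject, censors high-motion frames, band-pass filters and
#' computes the global-scope gFCD restricted to the Ml/Mr member rows
#' (identical arithmetic to the full map, just fewer target rows), then
#' the handedness index.  Used by the effect-size calibration and by
#' large-replicate tests; returns `NA` values for excluded subjects.
#'
#' @param sspace a [generate_space()] result.
#' @param subject a cohort row.
#' @param params a [generator_params()].
#' @param fcd_threshold edge threshold.
#' @return one-row data.frame as from [handedness_index()] plus `excluded`.
#' @export
subject_handedness_index <- function(sspace, subject, params = NULL,
                                     fcd_threshold = 0.6) {
  if (is.null(params)) params <- sspace$params
  ts <- generate_subject_timeseries(sspace, subject, params)
  ts <- bandpass(ts)
  ts <- censor_high_motion(ts)
  if (ts$excluded)
    return(data.frame(subject_id = as.character(subject$subject_id),
                      gfcd_ml = NA_real_, gfcd_mr = NA_real_,
                      handedness_index = NA_real_, excluded = TRUE,
                      stringsAsFactors = FALSE))
  res <- compute_fcd(ts, sspace$space,
                     fcd_params(threshold = fcd_threshold),
                     rows = c(sspace$ml$members, sspace$mr$members))
  out <- handedness_index(res$gfcd, sspace$ml, sspace$mr,
                          subject_id = subject$subject_id)
  out$excluded <- FALSE
  out
}

#' Calibrate the motor asymmetry effect to a target design effect size
#'
#' Finds the `motor_asymmetry_effect` for which the generator's design
#' Cohen's d on the handedness index (right- vs left-handers, computed
#' through the real pipeline stages on a fixed calibration cohort with
#' common random numbers across candidate effects) equals `target_d`.
#' Monotone root finding on the effect; the calibration cohort uses the
#' substream `calibrate` of the master seed.
#'
#' @param target_d target Cohen's d (right minus left group).
#' @param params a [generator_params()] (its `motor_asymmetry_effect` is
#'   ignored).
#' @param n_per_group calibration cohort size per group.
#' @param interval search interval for the effect.
#' @param tol root-finding tolerance on the effect.
#' @return list: `effect` (calibrated value), `design_d` (achieved d at
#'   the root), `n_per_group`.
#' @export
calibrate_motor_effect <- function(target_d = 0.75,
                                   params = generator_params(),
                                   n_per_group = 80L,
                                   interval = c(0.02, 0.8),
                                   tol = 0.005) {
  cal_params <- params
  cal_params$seed <- derive_seed(params$seed, "calibrate")
  cohort <- generate_cohort(n_per_group, cal_params)
  cohort <- cohort[cohort$group %in% c("L", "R"), , drop = FALSE]
  sspace <- generate_space(cal_params)
  design_d <- function(effect) {
    p <- cal_params
    p$motor_asymmetry_effect <- effect
    idx <- vapply(seq_len(nrow(cohort)), function(i)
      subject_handedness_index(sspace, cohort[i, ], p)$handedness_index,
      numeric(1L))
    ok <- is.finite(idx)
    cohens_d(idx[ok & cohort$group == "R"], idx[ok & cohort$group == "L"])
  }
  f <- function(e) design_d(e) - target_d
  lo <- f(interval[1L]); hi <- f(interval[2L])
  if (lo * hi > 0)
    stop("target effect size not bracketed by 'interval'")
  root <- stats::uniroot(f, interval, f.lower = lo, f.upper = hi,
                         tol = tol)
  list(effect = root$root, design_d = root$f.root + target_d,
       n_per_group = n_per_group)
}
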