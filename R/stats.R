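maps_to_matrix <- function(maps) {
  if (is.matrix(maps)) return(maps)
  stopifnot(is.list(maps), length(maps) >= 1L)
  n <- length(maps[[1L]]$values)
  do.call(rbind, lapply(maps, function(m) {
    stopifnot(inherits(m, "scalar_map"))
    if (length(m$values) != n) stop("maps are not on a shared space")
    m$values
  }))
}

map_space <- function(maps, space) {
  if (!is.null(space)) return(space)
  if (is.list(maps) && inherits(maps[[1L]], "scalar_map"))
    return(maps[[1L]]$space)
  stop("'space' must be supplied when maps are given as a matrix")
}

#' Vertex-wise two-sample t contrast
#'
#' Pooled-variance (Student) two-sample t test at every vertex, two-sided,
#' with per-vertex NaN handling: subjects with undefined values at a
#' vertex are dropped there and the degrees of freedom adjusted.  Vertices
#' with zero variance in both groups (or fewer than 2 defined subjects in
#' either group) are `NaN`.  Benjamini-Hochberg FDR is applied across
#' defined vertices.
#'
#' @param group_a,group_b lists of [scalar_map()]s (or subjects x vertices
#'   matrices) of pre-residualized values; at least 2 subjects per group.
#' @param alpha_fdr FDR level for the significance mask.
#' @param space required when matrices are supplied.
#' @return Object of class `group_contrast`: `t`, `p`, `q` ([scalar_map()]s),
#'   `df` (per-vertex), `q_mask` (logical), `alpha_fdr`, `n_a`, `n_b`.
#' @export
two_sample_t_map <- function(group_a, group_b, alpha_fdr = 0.05,
                             space = NULL) {
  A <- maps_to_matrix(group_a)
  B <- maps_to_matrix(group_b)
  if (nrow(A) < 2L || nrow(B) < 2L)
    stop("need at least 2 subjects per group")
  if (ncol(A) != ncol(B)) stop("groups are not on a shared space")
  space <- map_space(group_a, space)
  okA <- is.finite(A); okB <- is.finite(B)
  nA <- colSums(okA); nB <- colSums(okB)
  A[!okA] <- 0; B[!okB] <- 0
  mA <- colSums(A) / nA; mB <- colSums(B) / nB
  ssA <- pmax(colSums(A^2) - nA * mA^2, 0)
  ssB <- pmax(colSums(B^2) - nB * mB^2, 0)
  df <- nA + nB - 2
  valid <- nA >= 2 & nB >= 2
  sp2 <- (ssA + ssB) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tval <- ifelse(valid & se > 0, (mA - mB) / se, NaN)
  pval <- 2 * stats::pt(-abs(tval), df)
  fdr <- fdr_bh(pval, alpha_fdr)
  new_group_contrast(tval, pval, fdr, df, space, alpha_fdr,
                     n_a = nrow(A), n_b = nrow(B))
}

#' Vertex-wise one-sample t contrast
#'
#' Two-sided one-sample t test against `mu` at every vertex (used e.g. for
#' asymmetry maps: is right - left different from 0?).  A vertex with zero
#' variance and a mean different from `mu` gets a finite sentinel
#' `t = +/- 1e9` with a warning (so maps serialize finitely); zero
#' variance with mean equal to `mu` gives `t = 0`.
#'
#' @param maps list of [scalar_map()]s or a subjects x vertices matrix.
#' @param mu null value (default 0).
#' @inheritParams two_sample_t_map
#' @return A `group_contrast` (see [two_sample_t_map()]); `n_b` is `NA`.
#' @export
one_sample_t_map <- function(maps, mu = 0, alpha_fdr = 0.05, space = NULL) {
  A <- maps_to_matrix(maps)
  if (nrow(A) < 2L) stop("need at least 2 subjects")
  space <- map_space(maps, space)
  ok <- is.finite(A)
  n <- colSums(ok)
  A0 <- A; A0[!ok] <- 0
  m <- colSums(A0) / n
  ss <- colSums(A0^2) - n * m^2
  ss[ss < 0] <- 0
  df <- n - 1
  sd <- sqrt(ss / df)
  se <- sd / sqrt(n)
  tval <- rep(NaN, ncol(A))
  valid <- n >= 2
  nz <- valid & se > 0
  tval[nz] <- (m[nz] - mu) / se[nz]
  degen <- valid & se == 0
  if (any(degen)) {
    hit <- degen & abs(m - mu) > 0
    if (any(hit)) {
      warning(sprintf("%d zero-variance vertices with nonzero mean; t set to +/-1e9",
                      sum(hit)))
      tval[hit] <- sign(m[hit] - mu) * 1e9
    }
    tval[degen & abs(m - mu) == 0] <- 0
  }
  pval <- 2 * stats::pt(-abs(tval), df)
  fdr <- fdr_bh(pval, alpha_fdr)
  new_group_contrast(tval, pval, fdr, df, space, alpha_fdr,
                     n_a = nrow(A), n_b = NA_integer_)
}

new_group_contrast <- function(tval, pval, fdr, df, space, alpha_fdr,
                               n_a, n_b) {
  structure(list(
    t = scalar_map(tval, space, name = "t"),
    p = scalar_map(pval, space, name = "p"),
    q = scalar_map(fdr$q, space, name = "q"),
    df = df,
    q_mask = fdr$mask,
    alpha_fdr = alpha_fdr,
    n_a = n_a, n_b = n_b
  ), class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("group_contrast: %d vertices, %d significant at pFDR < %g (n = %s vs %s)\n",
              length(x$t$values), sum(x$q_mask, na.rm = TRUE), x$alpha_fdr,
              x$n_a, ifelse(is.na(x$n_b), "-", x$n_b)))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `alpha` over the non-NA p-values; NAs are
#' excluded from the multiplicity count `m` and return `NA` in both
#' outputs.  Adjusted q-values are the usual monotone step-up values
#' `q_(i) = min_{j >= i} m p_(j) / j` (with the extra
#' `sum(1/i)` factor under `method = "BY"`).
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @param alpha FDR level.
#' @param method `"BH"` (independent/PRDS) or `"BY"` (arbitrary
#'   dependence).
#' @return list with `mask` (logical: rejected) and `q` (adjusted
#'   q-values).
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.04), alpha = 0.05)$mask  # all TRUE
#' @export
fdr_bh <- function(p, alpha = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  m <- sum(ok)
  q <- rep(NA_real_, length(p))
  mask <- rep(NA, length(p))
  if (m == 0L) return(list(mask = as.logical(mask), q = q))
  ps <- p[ok]
  o <- order(ps)
  ranked <- ps[o]
  cm <- if (method == "BY") sum(1 / seq_len(m)) else 1
  qs <- rev(cummin(rev(m * cm * ranked / seq_len(m))))
  qs <- pmin(qs, 1)
  qq <- numeric(m)
  qq[o] <- qs
  q[ok] <- qq
  mask[ok] <- qq <= alpha
  list(mask = mask, q = q)
}

#' Cohen's d effect size
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_p` with the
#' unbiased pooled standard deviation.
#'
#' @param a,b numeric vectors, at least 2 values each.
#' @return scalar d.
#' @export
cohens_d <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("need at least 2 values per group")
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  (mean(a) - mean(b)) / sp
}

#' Dice overlap coefficient of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks are identical by
#' convention and score 1 (a message notes when this is triggered).
#' NA entries are treated as FALSE.
#'
#' @param mask_a,mask_b logical vectors on a shared space.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  mask_a <- as.logical(mask_a); mask_b <- as.logical(mask_b)
  if (length(mask_a) != length(mask_b))
    stop("masks are not on a shared space")
  mask_a[is.na(mask_a)] <- FALSE
  mask_b[is.na(mask_b)] <- FALSE
  sa <- sum(mask_a); sb <- sum(mask_b)
  if (sa + sb == 0L) {
    message("dice: both masks empty; returning 1 by convention")
    return(1)
  }
  2 * sum(mask_a & mask_b) / (sa + sb)
}

#' ROI-level group model (ANCOVA)
#'
#' Linear model of a per-subject ROI measure on the (categorical) group
#' plus covariates, reporting the overall group effect (F test) and all
#' pairwise group contrasts (t tests from the fitted coefficient
#' covariance).  On balanced designs with constant covariates the
#' pairwise t equals the pooled two-sample t.
#'
#' @param values numeric per-subject ROI means.
#' @param cohort data.frame with a `group` column (factor/character) and
#'   the covariate columns.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @return list: `group_f`, `group_p`, `df`, `pairwise` (data.frame with
#'   `contrast`, `estimate`, `se`, `t`, `p`), `model` (the `lm` fit).
#' @export
roi_group_model <- function(values, cohort, covariates = character()) {
  cohort <- as.data.frame(cohort)
  if (!"group" %in% names(cohort)) stop("'cohort' must have a 'group' column")
  miss <- setdiff(covariates, names(cohort))
  if (length(miss))
    stop(sprintf("unknown covariates: %s", paste(miss, collapse = ", ")))
  dat <- cohort[, c("group", covariates), drop = FALSE]
  dat$group <- factor(dat$group)
  keep <- c(TRUE, vapply(covariates, function(cn)
    length(unique(dat[[cn]])) > 1L, logical(1L)))
  dat <- dat[, keep, drop = FALSE]
  dat$.y <- as.numeric(values)
  fit <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank-deficient design; aliased terms: %s",
                 paste(bad, collapse = ", ")))
  }
  av <- stats::anova(fit)
  g_row <- which(rownames(av) == "group")
  vc <- stats::vcov(fit)
  cf <- stats::coef(fit)
  lev <- levels(dat$group)
  combs <- utils::combn(lev, 2L, simplify = FALSE)
  pw <- do.call(rbind, lapply(combs, function(pr) {
    # contrast pr[2] - pr[1] in treatment coding relative to lev[1]
    w <- stats::setNames(numeric(length(cf)), names(cf))
    n2 <- paste0("group", pr[2L]); n1 <- paste0("group", pr[1L])
    if (n2 %in% names(w)) w[n2] <- 1
    if (n1 %in% names(w)) w[n1] <- -1
    est <- sum(w * cf)
    se <- sqrt(drop(t(w) %*% vc %*% w))
    tv <- est / se
    data.frame(contrast = paste(pr[2L], "-", pr[1L]), estimate = est,
               se = se, t = tv,
               p = 2 * stats::pt(-abs(tv), fit$df.residual),
               stringsAsFactors = FALSE)
  }))
  list(group_f = av[g_row, "F value"], group_p = av[g_row, "Pr(>F)"],
       df = fit$df.residual, pairwise = pw, model = fit)
}
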