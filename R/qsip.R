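#' Allocate qPCR copies to ASVs within each sequenced fraction
#'
#' Distributes each sequenced fraction's 16S copy total (SQ) across ASVs in
#' proportion to their read counts:
#' `copies[i, k] = reads[i, k] / sum_i(reads[i, k]) * SQ[k]`.
#' Fractions with zero total reads contribute zero copies (with a message).
#' Column sums therefore equal SQ for every fraction with reads
#' (conservation).
#'
#' @param m A [feature_count_matrix()].
#' @param rep A [gradient_replicate()]; its sequenced fractions are used.
#' @param asvs Optional character vector restricting the ASV set (e.g. a
#'   per-treatment inclusion set from [filter_per_replicate()]).
#' @return An object of class `copy_table`: list with `copies` (ASV x
#'   fraction matrix), `density` (per fraction, g/mL), `sq`, `fraction`,
#'   `treatment`, `replicate`.
#' @export
taxon_copies <- function(m, rep, asvs = NULL) {
  stopifnot(inherits(m, "fcm"), inherits(rep, "gradient_replicate"))
  fr <- rep$fractions[rep$fractions$sequenced, , drop = FALSE]
  if (nrow(fr) == 0L) stop("gradient replicate has no sequenced fractions")
  key <- paste(rep$treatment, rep$replicate, fr$fraction, sep = ":")
  missing <- setdiff(key, m$samples$sample)
  if (length(missing))
    stop("no counts for sequenced fraction(s): ", paste(missing, collapse = ", "))
  counts <- m$counts[, key, drop = FALSE]
  if (!is.null(asvs)) counts <- counts[intersect(rownames(counts), asvs), ,
                                       drop = FALSE]
  tot <- colSums(counts)
  if (any(tot == 0))
    message(sum(tot == 0), " fraction(s) with zero total reads contribute zero copies")
  share <- sweep(counts, 2L, ifelse(tot > 0, tot, 1), "/")
  share[, tot == 0] <- 0
  copies <- sweep(share, 2L, fr$copies, "*")
  structure(list(copies = copies, density = fr$density, sq = fr$copies,
                 fraction = fr$fraction, treatment = rep$treatment,
                 replicate = rep$replicate),
            class = "copy_table")
}

#' Abundance-weighted mean buoyant density per ASV
#'
#' `W = sum_k(density_k * copies_k) / sum_k(copies_k)` over the sequenced
#' fractions of one replicate. ASVs with zero copies everywhere get `NA`
#' (a missing profile, not zero).
#'
#' @param ct A `copy_table` from [taxon_copies()].
#' @return data.frame with columns `asv`, `W` (g/mL) and `total_copies`.
#' @export
weighted_mean_density <- function(ct) {
  stopifnot(inherits(ct, "copy_table"))
  tot <- rowSums(ct$copies)
  W <- as.vector(ct$copies %*% ct$density) / ifelse(tot > 0, tot, NA_real_)
  data.frame(asv = rownames(ct$copies), W = W, total_copies = tot,
             stringsAsFactors = FALSE)
}

#' SQ-weighted mean buoyant density of a whole gradient
#'
#' The community-level weighted average DNA density of one replicate,
#' weighting every fraction's density by its qPCR copy total. Summarise a
#' treatment as mean +/- SD over its technical replicates with
#' [treatment_weighted_density()].
#'
#' @param rep A [gradient_replicate()]; all fractions must carry SQ values.
#' @return Weighted mean density, g/mL.
#' @export
bulk_weighted_density <- function(rep) {
  stopifnot(inherits(rep, "gradient_replicate"))
  fr <- rep$fractions
  if (anyNA(fr$copies)) stop("all fractions must have copy (SQ) values")
  tot <- sum(fr$copies)
  if (tot <= 0) stop("zero total copies in gradient")
  sum(fr$density * fr$copies) / tot
}

#' @rdname bulk_weighted_density
#' @param reps List of `gradient_replicate`s from one treatment.
#' @return For `treatment_weighted_density()`: list with `mean`, `sd`, and
#'   the per-replicate densities `W`.
#' @export
treatment_weighted_density <- function(reps) {
  W <- vapply(reps, bulk_weighted_density, numeric(1))
  list(mean = mean(W), sd = stats::sd(W), W = W)
}

#' GC content from unlabeled buoyant density
#'
#' Inverts the linear GC-density relation:
#' `GC = (W_light - gc_intercept) / gc_slope`. Values outside \[0, 1\] are
#' returned as-is with a warning (they indicate an implausible density).
#'
#' @param W_light Unlabeled weighted mean density, g/mL (vectorised).
#' @param constants An [isotope_constants()] object.
#' @return GC content (fraction, nominally 0-1).
#' @export
gc_from_density <- function(W_light, constants = isotope_constants()) {
  G <- (W_light - constants$gc_intercept) / constants$gc_slope
  out <- !is.na(G) & (G < -1e-9 | G > 1 + 1e-9)
  if (any(out))
    warning(sum(out), " GC value(s) outside [0, 1]; implausible W_light")
  G
}

#' Light and maximally heavy DNA molecular weights
#'
#' `M_light = mw_gc_slope * GC + mw_intercept`;
#' `M_heavymax = heavy_gc_slope * GC + heavy_offset + M_light` (the molecular
#' weight if every carbon were \eqn{^{13}}C).
#'
#' @param G GC content (vectorised).
#' @inheritParams gc_from_density
#' @return data.frame with columns `M_light`, `M_heavymax` (g/mol).
#' @export
molecular_weights <- function(G, constants = isotope_constants()) {
  M_light <- constants$mw_gc_slope * G + constants$mw_intercept
  M_heavymax <- constants$heavy_gc_slope * G + constants$heavy_offset + M_light
  data.frame(M_light = M_light, M_heavymax = M_heavymax)
}

#' Excess atom fraction from one labeled/unlabeled density pair
#'
#' The core qSIP transform. With GC inferred from the unlabeled reference
#' density, the labeled molecular weight is
#' `M_lab = (W_lab / W_light) * M_light` and
#' `EAF = (M_lab - M_light) / (M_heavymax - M_light) * (1 - nat13c)`.
#' Negative values are preserved (no clamping), so the confidence-interval
#' incorporator criterion remains meaningful; the theoretical maximum is
#' `1 - nat13c`.
#'
#' @param W_lab Labeled-treatment weighted mean density, g/mL (vectorised).
#' @param W_light Unlabeled reference weighted mean density, g/mL.
#' @inheritParams gc_from_density
#' @return Excess \eqn{^{13}}C atom fraction (dimensionless).
#' @export
eaf_per_replicate <- function(W_lab, W_light, constants = isotope_constants()) {
  G <- (W_light - constants$gc_intercept) / constants$gc_slope
  mw <- molecular_weights(G, constants)
  M_lab <- (W_lab / W_light) * mw$M_light
  (M_lab - mw$M_light) / (mw$M_heavymax - mw$M_light) * (1 - constants$nat13c)
}

# fast row medians for the bootstrap (columns are resampled replicates)
row_medians <- function(x) {
  if (ncol(x) == 1L) return(x[, 1L])
  if (ncol(x) == 3L && !anyNA(x)) {
    a <- x[, 1L]; b <- x[, 2L]; c <- x[, 3L]
    return(pmax(pmin(a, b), pmin(pmax(a, b), c)))
  }
  apply(x, 1L, stats::median, na.rm = TRUE)
}

#' Fit per-ASV excess atom fractions with bootstrap confidence intervals
#'
#' The central model-fitting function. For every ASV it computes the
#' abundance-weighted mean buoyant density in each labeled and each unlabeled
#' technical replicate, converts the density shift against the mean unlabeled
#' reference into a \eqn{^{13}}C excess atom fraction per labeled replicate,
#' takes the median across labeled replicates as the point estimate, and
#' attaches a percentile bootstrap confidence interval obtained by resampling
#' the labeled and unlabeled replicate sets independently with replacement
#' (the technical replicate is the replication unit). An ASV is called an
#' incorporator when the lower confidence bound exceeds zero (strictly).
#'
#' ASVs absent from every unlabeled replicate have no density reference and
#' are excluded with a logged reason; ASVs absent from every labeled
#' replicate are likewise excluded.
#'
#' @param m A [feature_count_matrix()] covering both treatments.
#' @param gradients List of [gradient_replicate()]s (e.g. from
#'   [read_gradient_table()]) containing the labeled and unlabeled
#'   treatments' replicates.
#' @param labeled,unlabeled Treatment ids of the \eqn{^{13}}C treatment and
#'   the \eqn{^{12}}C reference.
#' @param asvs Optional ASV inclusion set (per-treatment set from
#'   [filter_per_replicate()]).
#' @param n_boot Bootstrap iterations.
#' @param ci_level Confidence level (default 0.90).
#' @param seed Integer seed; required for reproducible intervals.
#' @param constants An [isotope_constants()] object.
#'
#' @return An object of class `qsip`: list with `estimates` (data.frame:
#'   `asv`, `median_eaf`, `ci_low`, `ci_high`, `incorporator`,
#'   `rel_abundance`, plus one `eaf_rep<j>` column per labeled replicate),
#'   `excluded`, `W_lab`, `W_light` matrices, and the call settings.
#' @seealso [incorporator_summary()], [plot.qsip()], [eaf_regression()]
#' @export
qsip <- function(m, gradients, labeled, unlabeled, asvs = NULL,
                 n_boot = 1000, ci_level = 0.90, seed = NULL,
                 constants = isotope_constants()) {
  tr_of <- vapply(gradients, function(g) g$treatment, "")
  lab_reps <- gradients[tr_of == labeled]
  unl_reps <- gradients[tr_of == unlabeled]
  if (!length(lab_reps)) stop("no gradient replicates for labeled treatment ", labeled)
  if (!length(unl_reps)) stop("no gradient replicates for unlabeled treatment ", unlabeled)

  W_of <- function(reps) {
    cols <- lapply(reps, function(r) {
      wm <- weighted_mean_density(taxon_copies(m, r, asvs))
      stats::setNames(wm$W, wm$asv)
    })
    ids <- rownames(m$counts)
    if (!is.null(asvs)) ids <- intersect(ids, asvs)
    do.call(cbind, lapply(cols, function(cc) cc[ids]))
  }
  W_lab <- W_of(lab_reps)
  W_light <- W_of(unl_reps)
  rownames(W_lab) <- rownames(W_light) <-
    if (is.null(asvs)) rownames(m$counts) else intersect(rownames(m$counts), asvs)

  no_ref <- rowSums(!is.na(W_light)) == 0
  no_lab <- rowSums(!is.na(W_lab)) == 0
  excluded <- data.frame(
    asv = c(rownames(W_light)[no_ref & !no_lab],
            rownames(W_lab)[no_lab & !no_ref],
            rownames(W_lab)[no_lab & no_ref]),
    reason = c(rep("absent from all unlabeled replicates", sum(no_ref & !no_lab)),
               rep("absent from all labeled replicates", sum(no_lab & !no_ref)),
               rep("absent from both treatments", sum(no_lab & no_ref))),
    stringsAsFactors = FALSE)
  if (nrow(excluded))
    message(nrow(excluded), " ASV(s) excluded from EAF estimation (no density profile)")
  keep <- !(no_ref | no_lab)
  W_lab <- W_lab[keep, , drop = FALSE]
  W_light <- W_light[keep, , drop = FALSE]

  Wl_mean <- rowMeans(W_light, na.rm = TRUE)
  eaf_reps <- eaf_per_replicate(W_lab, Wl_mean, constants)  # ASV x labeled rep
  point <- row_medians(eaf_reps)

  nL <- ncol(W_lab); nU <- ncol(W_light)
  if (!is.null(seed)) set.seed(seed)
  alpha <- (1 - ci_level) / 2
  boot <- matrix(NA_real_, n_boot, nrow(W_lab))
  for (b in seq_len(n_boot)) {
    iL <- sample.int(nL, nL, replace = TRUE)
    iU <- sample.int(nU, nU, replace = TRUE)
    wl <- rowMeans(W_light[, iU, drop = FALSE], na.rm = TRUE)
    boot[b, ] <- row_medians(eaf_per_replicate(W_lab[, iL, drop = FALSE], wl,
                                               constants))
  }
  ci <- apply(boot, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE, names = FALSE)

  # mean per-sample relative read abundance over the labeled treatment
  lab_cols <- m$samples$sample[m$samples$treatment == labeled]
  sub <- m$counts[, lab_cols, drop = FALSE]
  prop <- sweep(sub, 2L, pmax(colSums(sub), 1), "/")
  rel <- rowMeans(prop)[rownames(W_lab)]

  est <- data.frame(asv = rownames(W_lab), median_eaf = point,
                    ci_low = ci[1L, ], ci_high = ci[2L, ],
                    incorporator = ci[1L, ] > 0,
                    rel_abundance = rel, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(eaf_reps)))
    est[[paste0("eaf_rep", j)]] <- eaf_reps[, j]
  rownames(est) <- NULL

  structure(list(estimates = est, excluded = excluded,
                 W_lab = W_lab, W_light = W_light,
                 labeled = labeled, unlabeled = unlabeled,
                 n_boot = n_boot, ci_level = ci_level, seed = seed,
                 constants = constants, call = match.call()),
            class = "qsip")
}

#' @export
print.qsip <- function(x, ...) {
  cat(sprintf("qSIP fit: %s vs %s reference\n", x$labeled, x$unlabeled))
  cat(sprintf("  %d ASVs, %d excluded; bootstrap n = %d, CI level = %.0f%%\n",
              nrow(x$estimates), nrow(x$excluded), x$n_boot, 100 * x$ci_level))
  s <- incorporator_summary(x)
  cat(sprintf("  %d incorporator(s) (lower CI > 0), %.1f%% of community reads\n",
              s$n_incorporators, 100 * s$relative_abundance))
  invisible(x)
}

#' @export
summary.qsip <- function(object, ...) {
  s <- incorporator_summary(object)
  est <- object$estimates
  out <- list(labeled = object$labeled, unlabeled = object$unlabeled,
              n_asvs = nrow(est), n_excluded = nrow(object$excluded),
              n_incorporators = s$n_incorporators,
              relative_abundance = s$relative_abundance,
              eaf_range = range(est$median_eaf),
              top = est[order(-est$median_eaf),
                        c("asv", "median_eaf", "ci_low", "ci_high",
                          "incorporator")][seq_len(min(10L, nrow(est))), ])
  class(out) <- "summary.qsip"
  out
}

#' @export
print.summary.qsip <- function(x, ...) {
  cat(sprintf("qSIP fit: %s against %s\n", x$labeled, x$unlabeled))
  cat(sprintf("ASVs analysed: %d (+%d excluded)\n", x$n_asvs, x$n_excluded))
  cat(sprintf("Incorporators: %d (%.1f%% of community reads)\n",
              x$n_incorporators, 100 * x$relative_abundance))
  cat(sprintf("Median EAF range: [%.3f, %.3f]\n", x$eaf_range[1], x$eaf_range[2]))
  cat("Top ASVs by median EAF:\n")
  print(x$top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.qsip <- function(object, ...) {
  stats::setNames(object$estimates$median_eaf, object$estimates$asv)
}

#' @export
confint.qsip <- function(object, parm, level, ...) {
  ci <- as.matrix(object$estimates[, c("ci_low", "ci_high")])
  rownames(ci) <- object$estimates$asv
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
as.data.frame.qsip <- function(x, ...) x$estimates

#' Plot per-ASV excess atom fractions with confidence intervals
#'
#' Horizontal point-and-interval chart, ASVs ordered by median EAF;
#' incorporators (lower CI > 0) are drawn filled and marked with `*`.
#'
#' @param x A [qsip()] fit.
#' @param n_max Show at most this many ASVs (highest EAF first).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.qsip <- function(x, n_max = 40L, ...) {
  est <- x$estimates[order(x$estimates$median_eaf), , drop = FALSE]
  if (nrow(est) > n_max) est <- utils::tail(est, n_max)
  y <- seq_len(nrow(est))
  graphics::plot(est$median_eaf, y, xlim = range(est$ci_low, est$ci_high, 0),
                 pch = ifelse(est$incorporator, 16, 1), yaxt = "n",
                 xlab = expression({}^13 * "C excess atom fraction"),
                 ylab = "", ...)
  graphics::segments(est$ci_low, y, est$ci_high, y)
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = y, labels = paste0(est$asv,
                                            ifelse(est$incorporator, " *", "")),
                 las = 1, cex.axis = 0.6)
  invisible(x)
}

#' Incorporator calls and their community share
#'
#' An ASV is a \eqn{^{13}}C incorporator when the lower bound of its EAF
#' confidence interval is strictly greater than zero. The summary also
#' reports the summed mean relative read abundance of the incorporators
#' across the labeled treatment's sequenced-fraction samples.
#'
#' @param x A [qsip()] fit or its `estimates` data.frame (needs columns
#'   `ci_low` and, for the abundance share, `rel_abundance`).
#' @return List with `n_incorporators`, `incorporators` (ASV ids) and
#'   `relative_abundance` (summed share, 0-1; `NA` if unavailable).
#' @export
incorporator_summary <- function(x) {
  est <- if (inherits(x, "qsip")) x$estimates else x
  inc <- est$ci_low > 0
  rel <- if ("rel_abundance" %in% names(est))
    sum(est$rel_abundance[inc]) else NA_real_
  list(n_incorporators = sum(inc), incorporators = est$asv[inc],
       relative_abundance = rel)
}
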