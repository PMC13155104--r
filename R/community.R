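#' Relative abundance by taxon at a rank
#'
#' Aggregates ASV reads to a taxonomic rank and converts to per-sample
#' proportions. With `rank = "phylum-class"` (hybrid mode) Proteobacteria
#' are reported at class level (Alphaproteobacteria, Gammaproteobacteria,
#' ...) while all other phyla stay at phylum level, the usual convention for
#' marine 16S barplots.
#'
#' @param m A [feature_count_matrix()].
#' @param tax Taxonomy data.frame from [parse_taxonomy()].
#' @param rank One of the taxonomy ranks, or `"phylum-class"`.
#' @param by Aggregate columns per `"sample"` or pool reads per
#'   `"treatment"` before converting to proportions (one composite community
#'   per incubation).
#' @return Matrix taxa x samples of proportions (columns sum to 1).
#'   Zero-read samples yield `NA` with a warning.
#' @export
relative_abundance <- function(m, tax, rank = "phylum", by = c("sample", "treatment")) {
  by <- match.arg(by)
  tax <- tax[match(rownames(m$counts), tax$asv), , drop = FALSE]
  if (identical(rank, "phylum-class")) {
    taxon <- ifelse(grepl("Proteobacteria", tax$phylum, ignore.case = TRUE),
                    tax$class, tax$phylum)
  } else {
    if (!rank %in% names(tax)) stop("rank not present in taxonomy: ", rank)
    taxon <- tax[[rank]]
  }
  taxon[is.na(taxon) | taxon == ""] <- "unassigned"
  counts <- m$counts
  if (by == "treatment") {
    grp <- factor(m$samples$treatment, levels = unique(m$samples$treatment))
    counts <- vapply(levels(grp), function(g)
      rowSums(counts[, grp == g, drop = FALSE]), numeric(nrow(counts)))
  }
  agg <- rowsum(counts, group = taxon)
  tot <- colSums(agg)
  if (any(tot == 0)) warning("zero-read sample(s); proportions undefined (NA)")
  sweep(agg, 2L, ifelse(tot > 0, tot, NA_real_), "/")
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` in nats over taxa with positive counts.
#'
#' @param x Numeric vector of counts/abundances, or a matrix with samples in
#'   columns.
#' @return H (nats); vectorised over columns for matrices.
#' @export
shannon_index <- function(x) {
  if (is.matrix(x)) return(apply(x, 2L, shannon_index))
  x <- x[!is.na(x)]
  if (sum(x) <= 0) stop("Shannon index undefined for an all-zero sample")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = sum(|a_i - b_i|) / sum(a_i + b_i)` between all sample pairs
#' (samples in rows).
#'
#' @param x Non-negative abundance matrix, samples in rows.
#' @return A `dist` object.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  zero <- rowSums(x) == 0
  if (sum(zero) >= 2L) stop("two all-zero samples: dissimilarity undefined")
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ])
  }
  stats::as.dist(d)
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers the squared distance matrix, eigendecomposes, and returns
#' the top-`k` axes ordered by eigenvalue, with per-axis explained-variance
#' proportions (relative to the sum of positive eigenvalues). Negative
#' eigenvalues are reported in the diagnostics, not corrected.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param k Number of axes requested.
#' @return List with `points` (n x k coordinates), `eig` (all eigenvalues),
#'   `explained` (proportions for the returned axes) and `negative_eig`.
#' @export
pcoa <- function(d, k = 2L) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  k_req <- k
  k <- min(k, n - 1L)
  cm <- stats::cmdscale(d, k = k, eig = TRUE)
  pts <- cm$points
  # cmdscale silently drops axes with non-positive eigenvalues
  if (ncol(pts) < k_req)
    warning(sprintf("only %d informative axis/axes available (requested %d)",
                    ncol(pts), k_req))
  eig <- cm$eig
  pos <- sum(eig[eig > 0])
  list(points = pts,
       eig = eig,
       explained = eig[seq_len(ncol(pts))] / pos,
       negative_eig = eig[eig < 0])
}

permanova_stats <- function(d2, groups) {
  # d2: full squared-distance matrix; one-way partition of squared distances
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  g <- length(unique(groups))
  Fstat <- (ss_between / (g - 1)) / (ss_within / (n - g))
  c(R2 = ss_between / ss_total, F = Fstat)
}

#' One-way PERMANOVA
#'
#' Partitions the squared dissimilarities of a distance matrix between and
#' within groups: `R2 = SS_between / SS_total`, pseudo-F with
#' `(g - 1, n - g)` degrees of freedom, and a permutation p-value
#' `p = (1 + #permuted F >= observed) / (1 + n_perm)` from seeded label
#' permutations. With `exhaustive = TRUE` all `n!` label arrangements are
#' enumerated instead and `p` is the exact fraction (identity included) with
#' `F >= observed` — feasible for small n only.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param groups Group labels, one per sample (>= 2 groups, none spanning
#'   the whole sample set).
#' @param n_perm Number of random permutations.
#' @param seed Integer seed for the permutations.
#' @param exhaustive Enumerate all label permutations (n <= 8 recommended).
#' @return List with `R2`, `F`, `p`, `df`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL,
                      exhaustive = FALSE) {
  d <- as.matrix(stats::as.dist(d))
  groups <- as.character(groups)
  n <- nrow(d)
  if (length(groups) != n) stop("one group label per sample required")
  g <- length(unique(groups))
  if (g < 2L) stop("need at least 2 groups")
  if (any(table(groups) == n)) stop("a group equals the whole sample set")
  d2 <- d^2
  obs <- permanova_stats(d2, groups)

  if (exhaustive) {
    perms <- all_permutations(n)
    Fs <- apply(perms, 1L, function(p) permanova_stats(d2, groups[p])["F"])
    p_val <- mean(Fs >= obs["F"] - 1e-12)
    n_used <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    Fs <- replicate(n_perm,
                    permanova_stats(d2, groups[sample.int(n)])["F"])
    p_val <- (1 + sum(Fs >= obs["F"] - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  list(R2 = unname(obs["R2"]), F = unname(obs["F"]), p = p_val,
       df = c(between = g - 1L, within = n - g), n_perm = n_used)
}

all_permutations <- function(n) {
  if (n > 8L) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  # insert n at every position of each (n-1)-permutation
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (r in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      out[row, ] <- append(sub[r, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' Disjoint Venn regions of incorporator sets
#'
#' Partitions the union of per-treatment incorporator sets into the
#' `2^n - 1` disjoint regions of the n-set Venn diagram ("taurine",
#' "taurine∩methionine", ...). Region counts sum to the size of the union.
#'
#' @param sets Named list of character vectors (ASV ids per treatment).
#' @return List with `regions` (named list of ASV id vectors) and `counts`.
#' @export
venn_partition <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  nm <- names(sets)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, 1L,
                                                   dimnames = list(NULL, nm))
  regions <- list()
  for (size in seq_along(nm)) {
    for (combo in utils::combn(nm, size, simplify = FALSE)) {
      inside <- rowSums(membership[, combo, drop = FALSE]) == length(combo) &
        rowSums(membership) == length(combo)
      regions[[paste(combo, collapse = "∩")]] <- universe[inside]
    }
  }
  list(regions = regions, counts = lengths(regions))
}

#' Ordinary least squares between two EAF profiles
#'
#' Fits `y ~ x` over ASVs shared by two treatments (typically the medians of
#' ASVs significantly labeled in both) and reports the slope, intercept,
#' R-squared, adjusted R-squared (`1 - (1 - R2)(n - 1)/(n - 2)`), the F
#' statistic and its p-value.
#'
#' @param x,y Paired EAF values (same ASVs, same order).
#' @return List with `slope`, `intercept`, `r2`, `adj_r2`, `F`, `p`,
#'   `residuals`, `n` and the underlying `lm` fit.
#' @seealso [pair_incorporators()] to build the pairing from two [qsip()]
#'   fits.
#' @export
eaf_regression <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired ASVs")
  if (stats::sd(x) == 0) stop("x is constant; regression undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = sm$r.squared,
       adj_r2 = sm$adj.r.squared,
       F = unname(sm$fstatistic[1L]),
       p = stats::pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
                     lower.tail = FALSE),
       residuals = stats::residuals(fit),
       n = n, fit = fit)
}

#' Pair EAF estimates of two treatments by ASV
#'
#' @param fit_a,fit_b Two [qsip()] fits (or their `estimates` data.frames).
#' @param mode `"co-incorporators"` keeps only ASVs called incorporators in
#'   both treatments (the convention for cross-substrate regressions);
#'   `"shared"` keeps every ASV estimated in both.
#' @return data.frame with columns `asv`, `eaf_a`, `eaf_b`.
#' @export
pair_incorporators <- function(fit_a, fit_b,
                               mode = c("co-incorporators", "shared")) {
  mode <- match.arg(mode)
  ea <- if (inherits(fit_a, "qsip")) fit_a$estimates else fit_a
  eb <- if (inherits(fit_b, "qsip")) fit_b$estimates else fit_b
  if (mode == "co-incorporators") {
    ea <- ea[ea$incorporator, , drop = FALSE]
    eb <- eb[eb$incorporator, , drop = FALSE]
  }
  shared <- intersect(ea$asv, eb$asv)
  data.frame(asv = shared,
             eaf_a = ea$median_eaf[match(shared, ea$asv)],
             eaf_b = eb$median_eaf[match(shared, eb$asv)],
             stringsAsFactors = FALSE)
}

#' Rainbow test for linearity
#'
#' Orders the pairs by `x`, fits OLS on the central
#' `ceiling(center_fraction * n)` subset and on all `n` points, and compares
#' fits: `F = ((RSS_full - RSS_sub)/(n - n_sub)) / (RSS_sub/(n_sub - 2))`
#' with `(n - n_sub, n_sub - 2)` degrees of freedom. If the central subset
#' fits no better than the full data the relationship is deemed linear.
#' `F` is defined as 0 when `RSS_full <= RSS_sub` numerically (perfectly
#' linear data).
#'
#' @param x,y Numeric vectors (n >= 6).
#' @param center_fraction Fraction of points in the central subset.
#' @return List with `F`, `p`, `df`, `n`, `n_sub`.
#' @export
rainbow_test <- function(x, y, center_fraction = 0.5) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 6L) stop("need at least 6 points")
  m <- ceiling(center_fraction * n)
  if (m < 3L) stop("central subset must contain at least 3 points")
  ord <- order(x)
  start <- floor((n - m) / 2) + 1L
  sub <- ord[start:(start + m - 1L)]
  rss <- function(xx, yy) sum(stats::resid(stats::lm(yy ~ xx))^2)
  rss_full <- rss(x, y)
  rss_sub <- rss(x[sub], y[sub])
  if (rss_full <= rss_sub + 1e-12 * max(1, rss_sub)) {
    Fstat <- 0
  } else {
    Fstat <- ((rss_full - rss_sub) / (n - m)) / (rss_sub / (m - 2L))
  }
  list(F = Fstat, p = stats::pf(Fstat, n - m, m - 2L, lower.tail = FALSE),
       df = c(n - m, m - 2L), n = n, n_sub = m)
}
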