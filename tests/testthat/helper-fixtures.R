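# Shared fixtures and independent oracles for the test suite.
# Everything here is generated in code; the synthetic_* helpers construct
# stand-ins shaped like the study's supplementary tables (they are synthetic,
# engineered to the published summary values at construction time).

make_gradient <- function(treatment = "T", replicate = 1,
                          density = seq(1.67, 1.70, length.out = 6),
                          copies = rep(100, length(density)), ...) {
  gradient_replicate(treatment, replicate, density, copies, ...)
}

# small two-treatment count matrix with taxonomy for filtering tests
toy_dataset <- function() {
  asv <- c("A1", "A2", "A3", "A4", "A5")
  samples <- expand.grid(fraction = as.character(1:3), replicate = 1:2,
                         treatment = c("tx", "ty"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("treatment", "replicate", "fraction")]
  set.seed(42)
  counts <- matrix(rpois(length(asv) * nrow(samples), 20), length(asv),
                   dimnames = list(asv, NULL))
  tax <- parse_taxonomy(data.frame(
    asv = asv,
    taxon = c("d__Bacteria; p__Bacteroidota; c__Bacteroidia; o__Flavobacteriales; f__Flavobacteriaceae; g__Ulvibacter",
              "d__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Burkholderiales; f__Burkholderiaceae; g__Ralstonia",
              "d__Bacteria; p__Cyanobacteria; c__Cyanobacteriia; o__Chloroplast",
              "d__Bacteria; p__Verrucomicrobiota; c__Verrucomicrobiae; o__Verrucomicrobiales; f__Akkermansiaceae; g__Haloferula",
              "d__Bacteria; p__Planctomycetota; c__Planctomycetes; o__Pirellulales; g__Gimesia")))
  list(counts = feature_count_matrix(counts, samples), taxonomy = tax)
}

# --- independent, loop-based EAF chain oracle -------------------------------
# Recomputes copies -> W -> GC -> molecular weights -> EAF with explicit
# loops and scalar arithmetic, sharing no code with the package internals.
oracle_eaf_chain <- function(reads_lab, sq_lab, dens_lab,
                             reads_unl, sq_unl, dens_unl) {
  # reads_*: list over replicates of ASV x fraction matrices
  W_of <- function(reads, sq, dens) {
    W <- matrix(NA_real_, nrow(reads[[1]]), length(reads))
    rownames(W) <- rownames(reads[[1]])
    for (j in seq_along(reads)) {
      for (i in seq_len(nrow(reads[[j]]))) {
        num <- 0; den <- 0
        for (k in seq_len(ncol(reads[[j]]))) {
          tot <- sum(reads[[j]][, k])
          if (tot == 0) next
          cop <- reads[[j]][i, k] / tot * sq[[j]][k]
          num <- num + dens[[j]][k] * cop
          den <- den + cop
        }
        if (den > 0) W[i, j] <- num / den
      }
    }
    W
  }
  W_lab <- W_of(reads_lab, sq_lab, dens_lab)
  W_unl <- W_of(reads_unl, sq_unl, dens_unl)
  out <- matrix(NA_real_, nrow(W_lab), ncol(W_lab),
                dimnames = dimnames(W_lab))
  for (i in seq_len(nrow(W_lab))) {
    wl <- mean(W_unl[i, ], na.rm = TRUE)
    if (!is.finite(wl)) next
    G <- (wl - 1.646057) / 0.083506
    Ml <- 0.496 * G + 307.691
    Mh <- -0.4987282 * G + 9.974564 + Ml
    for (j in seq_len(ncol(W_lab))) {
      if (is.na(W_lab[i, j])) next
      Mlab <- W_lab[i, j] / wl * Ml
      out[i, j] <- (Mlab - Ml) / (Mh - Ml) * (1 - 0.01111233)
    }
  }
  out
}

# random small qSIP fixture: returns raw pieces plus package objects
random_qsip_fixture <- function(seed, n_asv = 6, n_frac = 8, n_rep = 3) {
  set.seed(seed)
  dens <- lapply(seq_len(2 * n_rep), function(j)
    sort(seq(1.67, 1.67 + 0.006 * (n_frac - 1), by = 0.006) +
           rnorm(1, 0, 5e-4)))
  reads <- lapply(seq_len(2 * n_rep), function(j) {
    m <- matrix(rpois(n_asv * n_frac, 30), n_asv,
                dimnames = list(sprintf("A%02d", seq_len(n_asv)), NULL))
    m
  })
  sq <- lapply(seq_len(2 * n_rep), function(j) runif(n_frac, 500, 5000))

  gradients <- list()
  cols <- list(); samp <- list()
  for (j in seq_len(2 * n_rep)) {
    tr <- if (j <= n_rep) "lab" else "unl"
    r <- ((j - 1) %% n_rep) + 1
    gradients[[paste(tr, r, sep = ":")]] <-
      gradient_replicate(tr, r, dens[[j]], sq[[j]],
                         fraction = seq_len(n_frac))
    cols[[j]] <- reads[[j]]
    samp[[j]] <- data.frame(treatment = tr, replicate = r,
                            fraction = as.character(seq_len(n_frac)))
  }
  m <- feature_count_matrix(do.call(cbind, cols), do.call(rbind, samp))
  list(m = m, gradients = gradients,
       reads_lab = reads[seq_len(n_rep)], sq_lab = sq[seq_len(n_rep)],
       dens_lab = dens[seq_len(n_rep)],
       reads_unl = reads[n_rep + seq_len(n_rep)],
       sq_unl = sq[n_rep + seq_len(n_rep)],
       dens_unl = dens[n_rep + seq_len(n_rep)])
}

# --- independent exhaustive PERMANOVA ---------------------------------------
perms_rec <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms_rec(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

brute_permanova_p <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  stat <- function(g) {
    sst <- sum(d2[upper.tri(d2)]) / n
    ssw <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1) {
        sub <- d2[idx, idx]
        ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    k <- length(unique(g))
    ((sst - ssw) / (k - 1)) / (ssw / (n - k))
  }
  obs <- stat(groups)
  Fs <- vapply(perms_rec(seq_len(n)), function(p) stat(groups[p]), 0)
  mean(Fs >= obs - 1e-12)
}

# --- synthetic stand-ins shaped like the supplementary tables ---------------

# gradient replicates engineered so the treatment-level SQ-weighted density
# reproduces a chosen mean: symmetric density grid + Gaussian SQ around W
synthetic_density_gradients <- function(treatment, W_reps) {
  lapply(seq_along(W_reps), function(r) {
    offs <- seq(-0.018, 0.018, by = 0.006)
    gradient_replicate(treatment, r,
                       density = W_reps[r] + offs,
                       copies = 1e5 * dnorm(offs, 0, 0.008),
                       fraction = seq_along(offs))
  })
}

# residuals orthogonal to (1, x) scaled for an exact target R^2
make_regression_pair <- function(x, slope, intercept, r2) {
  n <- length(x)
  e0 <- resid(lm(sin(seq_len(n)) ~ x))
  ss_reg <- slope^2 * sum((x - mean(x))^2)
  ss_res <- ss_reg * (1 - r2) / r2
  e <- e0 * sqrt(ss_res / sum(e0^2))
  intercept + slope * x + e
}

# EAF summary tables shaped like the study's qSIP-stats supplement, with the
# venn structure and regression strengths engineered at construction time
synthetic_qsip_stats <- function() {
  inc_row <- function(asv, eaf) data.frame(
    asv = asv, median_eaf = eaf, ci_low = pmax(eaf * 0.5, 1e-4),
    ci_high = eaf * 1.5, incorporator = TRUE, stringsAsFactors = FALSE)
  null_row <- function(asv, n) data.frame(
    asv = asv, median_eaf = seq(-0.02, 0.02, length.out = n),
    ci_low = -0.05, ci_high = 0.05, incorporator = FALSE,
    stringsAsFactors = FALSE)

  hyp <- sprintf("hASV%03d", 1:87)
  d <- hyp[1:8]; e <- hyp[9:11]; f <- hyp[12:16]; g <- hyp[17:23]
  h <- hyp[24:33]
  tau_inc <- c(d, e, f, g)                      # 23
  met_inc <- c(d, e)                            # 11
  glu_inc <- c(d, f, h)                         # 23
  x_tau <- seq(0.10, 0.42, length.out = 23)
  names(x_tau) <- tau_inc
  # methionine medians: exact adjusted R2 = 0.95 on the 11 co-incorporators
  r2_tm <- 1 - (1 - 0.95) * (11 - 2) / (11 - 1)
  y_met <- make_regression_pair(x_tau[met_inc], 0.7, 0.01, r2_tm)
  # glucose medians: exact adjusted R2 = 0.41 on the 13 co-incorporators
  co_tg <- c(d, f)
  r2_tg <- 1 - (1 - 0.41) * (13 - 2) / (13 - 1)
  y_glu <- make_regression_pair(x_tau[co_tg], 0.5, 0.02, r2_tg)

  tab <- function(inc_ids, inc_eaf, universe) {
    rbind(inc_row(inc_ids, inc_eaf),
          null_row(setdiff(universe, inc_ids),
                   length(setdiff(universe, inc_ids))))
  }
  oxi <- sprintf("oASV%03d", 1:44)
  a <- oxi[1]; b <- oxi[2:5]; cc <- oxi[6:17]
  list(
    hypoxic_taurine = tab(tau_inc, unname(x_tau), hyp),
    hypoxic_methionine = tab(met_inc, unname(y_met), hyp[1:86]),
    hypoxic_glucose = tab(glu_inc,
                          c(unname(y_glu), seq(0.1, 0.3, length.out = 10)),
                          hyp[1:84]),
    oxic_methionine = tab(c(a, b), seq(0.05, 0.2, length.out = 5), oxi),
    oxic_glucose = tab(c(a, cc), seq(0.05, 0.3, length.out = 13), oxi[1:43]),
    oxic_taurine = null_row(oxi[1:42], 42),
    regions = list(d = d, e = e, f = f, g = g, h = h, a = a, b = b, c = cc),
    x_tau = x_tau, y_met = y_met, y_glu = y_glu, co_tg = co_tg)
}
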