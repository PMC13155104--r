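test_that("relative abundance sums to one and supports the hybrid rank", {
  d <- toy_dataset()
  ra <- relative_abundance(d$counts, d$taxonomy, rank = "phylum")
  expect_equal(unname(colSums(ra)), rep(1, ncol(ra)), tolerance = 1e-12)

  # two taxa with reads (66, 34) -> (0.66, 0.34)
  m <- feature_count_matrix(rbind(A = 66, B = 34),
                            data.frame(treatment = "t", replicate = 1,
                                       fraction = "1"))
  tax <- parse_taxonomy(data.frame(asv = c("A", "B"),
                                   taxon = c("Bacteria;Bacteroidota",
                                             "Bacteria;Planctomycetota")))
  ra2 <- relative_abundance(m, tax, rank = "phylum")
  expect_equal(as.vector(ra2[c("Bacteroidota", "Planctomycetota"), 1]),
               c(0.66, 0.34))

  # hybrid mode reports Proteobacteria at class level
  ra3 <- relative_abundance(d$counts, d$taxonomy, rank = "phylum-class")
  expect_true("Gammaproteobacteria" %in% rownames(ra3))
  expect_false("Proteobacteria" %in% rownames(ra3))

  # aggregation conserves totals: proportions * total reads = taxon reads
  tot <- sum(d$counts$counts)
  pooled <- relative_abundance(d$counts, d$taxonomy, rank = "phylum",
                               by = "treatment")
  reads_by_tr <- vapply(unique(d$counts$samples$treatment), function(g)
    sum(d$counts$counts[, d$counts$samples$treatment == g]), 0)
  expect_equal(sum(sweep(pooled, 2, reads_by_tr, "*")), tot)
})

test_that("Shannon index matches hand computations and vegan", {
  expect_equal(shannon_index(rep(25, 4)), log(4))
  expect_equal(shannon_index(c(100, 0, 0)), 0)
  expect_equal(shannon_index(c(5, 3, 2)), 1.0297, tolerance = 1e-4)
  expect_error(shannon_index(c(0, 0)), "all-zero")
  skip_if_not_installed("vegan")
  set.seed(2)
  x <- matrix(rpois(60, 20), 10)
  expect_equal(unname(shannon_index(x)),
               unname(vegan::diversity(t(x), index = "shannon")))
})

test_that("Bray-Curtis has the documented fixed points and matches vegan", {
  x <- rbind(s1 = c(1, 1, 0), s2 = c(0, 1, 1), s3 = c(1, 1, 0),
             s4 = c(2, 0, 0), s5 = c(0, 0, 7))
  d <- as.matrix(bray_curtis(x))
  expect_equal(d["s1", "s3"], 0)          # identical samples
  expect_equal(d["s4", "s5"], 1)          # disjoint supports
  expect_equal(d["s1", "s2"], 0.5)        # hand computation
  skip_if_not_installed("vegan")
  set.seed(5)
  y <- matrix(runif(40), 8)
  expect_equal(as.vector(bray_curtis(y)),
               as.vector(vegan::vegdist(y, method = "bray")))
})

test_that("PCoA recovers known geometry", {
  # three equidistant points: two equal positive eigenvalues
  d3 <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  p3 <- pcoa(d3, k = 2)
  expect_equal(p3$eig[1], p3$eig[2], tolerance = 1e-9)
  expect_gt(p3$eig[2], 0)

  # points on a line: one dominant axis recovering spacing up to sign
  z <- c(0, 1, 2.5, 4, 7)
  dz <- stats::dist(cbind(z))
  pz <- pcoa(dz, k = 2)
  expect_gt(pz$explained[1], 0.999)
  ax1 <- pz$points[, 1]
  if (cor(ax1, z) < 0) ax1 <- -ax1
  expect_equal(ax1 - mean(ax1), z - mean(z), tolerance = 1e-9)

  # duplicated sample -> coincident coordinates
  w <- rbind(a = c(0, 0), b = c(1, 0), b2 = c(1, 0), c = c(0, 2))
  pw <- pcoa(stats::dist(w), k = 2)
  expect_equal(pw$points["b", ], pw$points["b2", ], tolerance = 1e-12)
})

test_that("PERMANOVA separates clusters, respects symmetry, matches brute force", {
  # two tight, well-separated clusters of 3
  set.seed(8)
  pts <- rbind(matrix(rnorm(9, 0, 0.05), 3), matrix(rnorm(9, 10, 0.05), 3))
  d <- stats::dist(pts)
  groups <- rep(c("a", "b"), each = 3)
  ex <- permanova(d, groups, exhaustive = TRUE)
  expect_gt(ex$R2, 0.9)
  expect_equal(ex$p, brute_permanova_p(d, groups))

  # swapping group labels leaves R2 and F unchanged
  sw <- permanova(d, rep(c("b", "a"), each = 3), exhaustive = TRUE)
  expect_equal(sw$R2, ex$R2)
  expect_equal(sw$F, ex$F)

  # null case: random labels on exchangeable samples -> large p, small R2
  set.seed(9)
  pts0 <- matrix(rnorm(14), 7)
  d0 <- stats::dist(pts0)
  g0 <- c("a", "b", "a", "b", "a", "b", "a")
  ex0 <- permanova(d0, g0, exhaustive = TRUE)
  expect_equal(ex0$p, brute_permanova_p(d0, g0))
  expect_gt(ex0$p, 0.05)
  expect_lt(ex0$R2, 0.5)

  # permutation p-value is seeded and reproducible
  p1 <- permanova(d, groups, n_perm = 99, seed = 3)$p
  p2 <- permanova(d, groups, n_perm = 99, seed = 3)$p
  expect_identical(p1, p2)

  expect_error(permanova(d, rep("a", 6)), "2 groups")
})

test_that("PERMANOVA agrees with vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(12)
  pts <- rbind(matrix(rnorm(12, 0, 1), 4), matrix(rnorm(12, 2, 1), 4))
  d <- stats::dist(pts)
  grp <- rep(c("x", "y"), each = 4)
  got <- permanova(d, grp, n_perm = 999, seed = 1)
  ad <- vegan::adonis2(d ~ grp, permutations = 999)
  expect_equal(got$R2, ad$R2[1], tolerance = 1e-10)
  expect_equal(got$F, ad$F[1], tolerance = 1e-10)
})

test_that("venn partition regions are disjoint and exhaustive", {
  expect_equal(venn_partition(list(x = "A", y = "A"))$counts[["x∩y"]], 1)

  disj <- venn_partition(list(x = "A", y = "B", z = "C"))
  expect_equal(unname(disj$counts[c("x", "y", "z")]), c(1, 1, 1))
  expect_equal(sum(disj$counts), 3)

  set.seed(4)
  sets <- list(t = sample(LETTERS, 12), m = sample(LETTERS, 8),
               g = sample(LETTERS, 15))
  vp <- venn_partition(sets)
  expect_equal(sum(vp$counts), length(unique(unlist(sets))))
  all_ids <- unlist(vp$regions)
  expect_equal(anyDuplicated(all_ids), 0L)
  # each region's members belong to exactly its sets
  for (nm in names(vp$regions)) {
    inside <- strsplit(nm, "∩")[[1]]
    for (id in vp$regions[[nm]]) {
      expect_setequal(names(sets)[vapply(sets, function(s) id %in% s, TRUE)],
                      inside)
    }
  }
})

test_that("EAF regression reports OLS statistics correctly", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  r <- suppressWarnings(eaf_regression(x, x))  # lm warns on a perfect fit
  expect_equal(r$slope, 1)
  expect_equal(r$adj_r2, 1)

  # standardized inputs: R2 equals squared Pearson correlation
  set.seed(6)
  xx <- rnorm(30); yy <- 0.5 * xx + rnorm(30)
  r2 <- eaf_regression(scale(xx)[, 1], scale(yy)[, 1])
  expect_equal(r2$r2, cor(xx, yy)^2, tolerance = 1e-12)

  # independence: adjusted R2 near zero for most seeds
  hits <- 0
  for (s in 1:40) {
    set.seed(s)
    rn <- eaf_regression(rnorm(50), rnorm(50))
    if (abs(rn$adj_r2) < 0.1) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.9)

  expect_error(eaf_regression(c(1, 2), c(1, 2)), "3")
  expect_error(eaf_regression(rep(1, 5), rnorm(5)), "constant")
})

test_that("rainbow linearity test flags curvature but not lines", {
  x <- seq(-1, 1, length.out = 40)
  lin <- rainbow_test(x, 2 + 3 * x)
  expect_equal(lin$F, 0)
  expect_equal(lin$p, 1)

  quad <- rainbow_test(x, x^2)
  expect_lt(quad$p, 0.01)

  # invariant to pair relabeling (order of input points)
  set.seed(10)
  y <- x^2 + rnorm(40, 0, 0.05)
  perm <- sample(40)
  r1 <- rainbow_test(x, y)
  r2 <- rainbow_test(x[perm], y[perm])
  expect_equal(r1$F, r2$F)
  expect_equal(r1$p, r2$p)
})

test_that("rainbow test agrees with lmtest::raintest", {
  skip_if_not_installed("lmtest")
  # n chosen so fraction * n is integral: both implementations then use the
  # same central subset (they differ in rounding for odd subset sizes)
  set.seed(14)
  x <- sort(rnorm(40)); y <- 1 + 2 * x + 0.5 * x^2 + rnorm(40, 0, 0.3)
  ours <- rainbow_test(x, y, center_fraction = 0.5)
  ref <- lmtest::raintest(y ~ x, fraction = 0.5, order.by = ~ x)
  expect_equal(ours$F, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-9)
})

test_that("co-incorporator pairing keeps ASVs labeled in both treatments", {
  a <- data.frame(asv = c("x", "y", "z"), median_eaf = c(0.3, 0.2, 0.1),
                  ci_low = c(0.1, 0.05, -0.1),
                  incorporator = c(TRUE, TRUE, FALSE))
  b <- data.frame(asv = c("x", "z", "w"), median_eaf = c(0.25, 0.15, 0.4),
                  ci_low = c(0.1, 0.05, 0.2),
                  incorporator = c(TRUE, TRUE, TRUE))
  co <- pair_incorporators(a, b)
  expect_equal(co$asv, "x")
  sh <- pair_incorporators(a, b, mode = "shared")
  expect_setequal(sh$asv, c("x", "z"))
})
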