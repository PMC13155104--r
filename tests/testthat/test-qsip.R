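test_that("fraction SQ is allocated proportionally to reads and conserved", {
  m <- feature_count_matrix(
    rbind(A = c(30), B = c(70)),
    data.frame(treatment = "t", replicate = 1, fraction = "1"))
  g <- gradient_replicate("t", 1, 1.68, 1000, fraction = "1")
  ct <- taxon_copies(m, g)
  expect_equal(as.vector(ct$copies), c(300, 700))

  # conservation on a random fixture: column sums equal SQ per fraction
  fx <- random_qsip_fixture(5)
  ct2 <- taxon_copies(fx$m, fx$gradients[["lab:1"]])
  expect_equal(unname(colSums(ct2$copies)), fx$sq_lab[[1]])

  # an ASV absent from a fraction receives zero copies there
  m3 <- feature_count_matrix(
    rbind(A = c(10, 0), B = c(10, 5)),
    data.frame(treatment = "t", replicate = 1, fraction = c("1", "2")))
  g3 <- gradient_replicate("t", 1, c(1.68, 1.686), c(100, 100),
                           fraction = c("1", "2"))
  expect_equal(taxon_copies(m3, g3)$copies["A", 2], 0, ignore_attr = TRUE)
})

test_that("weighted mean density matches hand arithmetic", {
  m <- feature_count_matrix(
    rbind(A = c(100, 300), B = c(50, 0), C = c(0, 0)),
    data.frame(treatment = "t", replicate = 1, fraction = c("1", "2")))
  g <- gradient_replicate("t", 1, c(1.68, 1.70), c(150, 300),
                          fraction = c("1", "2"))
  ct <- taxon_copies(m, g)
  wm <- weighted_mean_density(ct)
  # A: copies (100, 300) at (1.68, 1.70) -> 1.695
  expect_equal(wm$W[wm$asv == "A"], 1.695)
  # single occupied fraction -> that density
  expect_equal(wm$W[wm$asv == "B"], 1.68)
  # all-zero ASV -> missing, not zero
  expect_true(is.na(wm$W[wm$asv == "C"]))
})

test_that("bulk weighted density behaves under symmetry and dominance", {
  sym <- make_gradient(density = seq(1.67, 1.70, length.out = 6),
                       copies = rep(100, 6))
  expect_equal(bulk_weighted_density(sym), mean(c(1.67, 1.70)))
  dom <- make_gradient(density = seq(1.67, 1.70, length.out = 6),
                       copies = c(1, 1, 1e6, 1, 1, 1))
  expect_equal(bulk_weighted_density(dom), 1.682, tolerance = 1e-4)
  expect_error(bulk_weighted_density(
    make_gradient(copies = rep(0, 6))), "zero total")
})

test_that("GC and molecular-weight transforms match the protocol arithmetic", {
  cst <- isotope_constants()
  expect_equal(gc_from_density(1.646057, cst), 0)
  expect_equal(gc_from_density(1.646057 + 0.083506, cst), 1)
  expect_equal(gc_from_density(1.6880, cst), 0.502275, tolerance = 1e-6)

  mw0 <- molecular_weights(0, cst)
  expect_equal(mw0$M_light, 307.691)
  expect_equal(mw0$M_heavymax, 317.665564)
  mw5 <- molecular_weights(0.5, cst)
  expect_equal(mw5$M_light, 307.939)
  expect_equal(mw5$M_heavymax, 317.664200, tolerance = 1e-9)
  # heavy gain is ~9.97 g/mol and decreases with GC
  gain <- molecular_weights(seq(0, 1, 0.1), cst)
  expect_true(all(diff(gain$M_heavymax - gain$M_light) < 0))
})

test_that("the EAF transform hits its fixed points and oracle", {
  cst <- isotope_constants()
  expect_equal(eaf_per_replicate(1.6880, 1.6880, cst), 0)

  # fully labeled DNA: M_lab = M_heavymax -> EAF = 1 - nat13c
  G <- gc_from_density(1.6880, cst)
  mw <- molecular_weights(G, cst)
  W_full <- 1.6880 * mw$M_heavymax / mw$M_light
  expect_equal(eaf_per_replicate(W_full, 1.6880, cst), 0.98888767)

  # independent step-by-step arithmetic agrees to 1e-12
  W_lab <- 1.6980; W_light <- 1.6880
  G <- (1.6880 - 1.646057) / 0.083506
  Ml <- 0.496 * G + 307.691
  Mh <- -0.4987282 * G + 9.974564 + Ml
  Mlab <- W_lab / W_light * Ml
  expected <- (Mlab - Ml) / (Mh - Ml) * (1 - 0.01111233)
  expect_equal(eaf_per_replicate(W_lab, W_light, cst), expected,
               tolerance = 1e-12)

  # negative shifts stay negative (no clamping)
  expect_lt(eaf_per_replicate(1.6800, 1.6880, cst), 0)
})

test_that("EAF is monotone in W_lab and invariant to SQ rescaling", {
  cst <- isotope_constants()
  W <- seq(1.68, 1.72, by = 0.002)
  expect_true(all(diff(eaf_per_replicate(W, 1.6880, cst)) > 0))

  fx <- random_qsip_fixture(9)
  g <- fx$gradients[["lab:2"]]
  scaled <- gradient_replicate(g$treatment, g$replicate,
                               g$fractions$density,
                               g$fractions$copies * 37.5,
                               fraction = g$fractions$fraction)
  w1 <- weighted_mean_density(taxon_copies(fx$m, g))$W
  w2 <- weighted_mean_density(taxon_copies(fx$m, scaled))$W
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("vectorized EAF chain equals the loop-based oracle on 50 fixtures", {
  for (seed in 1:50) {
    fx <- random_qsip_fixture(seed, n_asv = 4, n_frac = 6)
    fit <- qsip(fx$m, fx$gradients, "lab", "unl", n_boot = 2, seed = 1)
    oracle <- oracle_eaf_chain(fx$reads_lab, fx$sq_lab, fx$dens_lab,
                               fx$reads_unl, fx$sq_unl, fx$dens_unl)
    got <- as.matrix(fit$estimates[, c("eaf_rep1", "eaf_rep2", "eaf_rep3")])
    rownames(got) <- fit$estimates$asv
    expect_equal(got, oracle[rownames(got), ], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate replicate structures give the documented estimates", {
  # identical labeled and unlabeled gradients -> EAF 0, CI straddles 0 is
  # degenerate at 0, not an incorporator
  dens <- seq(1.67, by = 0.006, length.out = 8)
  reads <- matrix(rep(c(50, 100, 200, 400, 300, 150, 70, 30), each = 2),
                  2, byrow = TRUE, dimnames = list(c("A", "B"), NULL))
  reads["A", ] <- rev(reads["A", ])
  sq <- c(200, 500, 900, 1200, 800, 400, 150, 60)
  gradients <- list(); cols <- list(); samp <- list()
  for (tr in c("lab", "unl")) for (r in 1:3) {
    gradients[[paste(tr, r, sep = ":")]] <-
      gradient_replicate(tr, r, dens, sq, fraction = 1:8)
    cols[[length(cols) + 1]] <- reads
    samp[[length(samp) + 1]] <- data.frame(treatment = tr, replicate = r,
                                           fraction = as.character(1:8))
  }
  m <- feature_count_matrix(do.call(cbind, cols), do.call(rbind, samp))
  fit <- qsip(m, gradients, "lab", "unl", n_boot = 200, seed = 4)
  expect_equal(fit$estimates$median_eaf, c(0, 0), tolerance = 1e-12)
  expect_false(any(fit$estimates$incorporator))

  # constant positive density shift, zero variance -> degenerate CI above 0
  gr2 <- gradients
  for (r in 1:3) {
    g <- gr2[[paste("lab", r, sep = ":")]]
    gr2[[paste("lab", r, sep = ":")]] <-
      gradient_replicate("lab", r, g$fractions$density + 0.01,
                         g$fractions$copies, fraction = g$fractions$fraction)
  }
  fit2 <- qsip(m, gr2, "lab", "unl", n_boot = 200, seed = 4)
  expect_true(all(fit2$estimates$incorporator))
  expect_equal(fit2$estimates$ci_low, fit2$estimates$median_eaf,
               tolerance = 1e-9)
  expect_equal(fit2$estimates$ci_high, fit2$estimates$median_eaf,
               tolerance = 1e-9)
})

test_that("bootstrap intervals are reproducible under a seed", {
  fx <- random_qsip_fixture(21)
  f1 <- qsip(fx$m, fx$gradients, "lab", "unl", n_boot = 100, seed = 7)
  f2 <- qsip(fx$m, fx$gradients, "lab", "unl", n_boot = 100, seed = 7)
  f3 <- qsip(fx$m, fx$gradients, "lab", "unl", n_boot = 100, seed = 8)
  expect_identical(f1$estimates, f2$estimates)
  expect_false(identical(f1$estimates$ci_low, f3$estimates$ci_low))
})

test_that("ASVs without an unlabeled reference are excluded with a reason", {
  fx <- random_qsip_fixture(13, n_asv = 4)
  # zero out one ASV in all unlabeled samples
  idx <- fx$m$samples$treatment == "unl"
  fx$m$counts["A01", idx] <- 0
  suppressMessages(
    fit <- qsip(fx$m, fx$gradients, "lab", "unl", n_boot = 10, seed = 1))
  expect_false("A01" %in% fit$estimates$asv)
  expect_match(fit$excluded$reason[fit$excluded$asv == "A01"], "unlabeled")
})

test_that("incorporator calling is strict at zero and summarises abundance", {
  est <- data.frame(asv = c("a", "b", "c"),
                    median_eaf = c(0.2, 0.1, 0.05),
                    ci_low = c(0.05, 0, -0.01),
                    rel_abundance = c(0.25, 0.3, 0.1))
  s <- incorporator_summary(est)
  expect_equal(s$n_incorporators, 1L)       # ci_low = 0 exactly is NOT called
  expect_equal(s$incorporators, "a")
  expect_equal(s$relative_abundance, 0.25)
})
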