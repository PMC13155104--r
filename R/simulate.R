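#' Simulator parameters for synthetic SIP gradients
#'
#' Defaults emulate the study design this package targets: 3 technical
#' ultracentrifugation replicates, 20 fractions spanning 1.65--1.77 g/mL
#' (0.006 g/mL fraction width, inside the conventional 0.005--0.007
#' fractionation interval), Gaussian within-gradient density spread of
#' 0.004 g/mL per taxon, 10% lognormal qPCR noise, multinomial sequencing at
#' 1e4 reads per fraction, and a small replicate-level density jitter.
#'
#' @param n_fractions Fractions per gradient.
#' @param density_range Gradient density span, g/mL.
#' @param sigma_density Within-gradient density spread of a taxon's DNA,
#'   g/mL. `0` puts all mass in the fraction containing the taxon's mean.
#' @param replicate_density_jitter SD of the per-replicate density
#'   calibration offset (the whole measured density scale of one
#'   ultracentrifugation run shifts by one draw), g/mL. This is the
#'   run-to-run fractionation variability that technical SIP replicates
#'   exist to capture, and the main source of between-replicate EAF spread.
#' @param seq_depth Reads per fraction (multinomial); `Inf` for noise-free
#'   proportional counts.
#' @param qpcr_cv Lognormal coefficient of variation of fraction SQ values;
#'   `0` disables qPCR noise.
#' @param n_replicates Technical replicates per treatment.
#' @param total_copies 16S copies loaded per gradient (scales SQ).
#' @return List of class `sip_sim_params`.
#' @export
simulate_params <- function(n_fractions = 20L,
                            density_range = c(1.65, 1.77),
                            sigma_density = 0.004,
                            replicate_density_jitter = 0.001,
                            seq_depth = 1e4,
                            qpcr_cv = 0.10,
                            n_replicates = 3L,
                            total_copies = 1e7) {
  stopifnot(n_fractions >= 2L, length(density_range) == 2L,
            density_range[1] < density_range[2],
            sigma_density >= 0, replicate_density_jitter >= 0,
            seq_depth > 0, qpcr_cv >= 0, n_replicates >= 1L,
            total_copies > 0)
  structure(list(n_fractions = as.integer(n_fractions),
                 density_range = density_range,
                 sigma_density = sigma_density,
                 replicate_density_jitter = replicate_density_jitter,
                 seq_depth = seq_depth, qpcr_cv = qpcr_cv,
                 n_replicates = as.integer(n_replicates),
                 total_copies = total_copies),
            class = "sip_sim_params")
}

sim_lineage_pool <- function() {
  c("Bacteria;Bacteroidota;Bacteroidia;Flavobacteriales;Flavobacteriaceae;Ulvibacter",
    "Bacteria;Bacteroidota;Bacteroidia;Flavobacteriales;Flavobacteriaceae;Lutibacter",
    "Bacteria;Bacteroidota;Bacteroidia;Flavobacteriales;Flavobacteriaceae;Tenacibaculum",
    "Bacteria;Bacteroidota;Bacteroidia;Flavobacteriales;Flavobacteriaceae;NS4 marine group",
    "Bacteria;Bacteroidota;Bacteroidia;Flavobacteriales;Flavobacteriaceae;NS5 marine group",
    "Bacteria;Bacteroidota;Bacteroidia;Flavobacteriales;Flavobacteriaceae;Polaribacter",
    "Bacteria;Bacteroidota;Bacteroidia;Sphingobacteriales;NS11-12 marine group;uncultured",
    "Bacteria;Bacteroidota;Kapabacteria;Kapabacteriales;uncultured;uncultured",
    "Bacteria;Proteobacteria;Gammaproteobacteria;Oceanospirillales;Oleiphilaceae;Oleiphilus",
    "Bacteria;Proteobacteria;Gammaproteobacteria;Thiomicrospirales;Thioglobaceae;SUP05 cluster",
    "Bacteria;Proteobacteria;Alphaproteobacteria;Kordiimonadales;Kordiimonadaceae;uncultured",
    "Bacteria;Verrucomicrobiota;Verrucomicrobiae;Verrucomicrobiales;Akkermansiaceae;Haloferula",
    "Bacteria;Planctomycetota;Planctomycetes;Pirellulales;Pirellulaceae;Gimesia",
    "Bacteria;Actinobacteriota;Actinobacteria;Microtrichales;Microtrichaceae;Candidatus Aquiluna")
}

sim_contaminant_pool <- function() {
  c("Bacteria;Proteobacteria;Gammaproteobacteria;Burkholderiales;Burkholderiaceae;Ralstonia",
    "Bacteria;Proteobacteria;Gammaproteobacteria;Burkholderiales;Comamonadaceae;Variovorax",
    "Bacteria;Firmicutes;Bacilli;Lactobacillales;Streptococcaceae;Streptococcus")
}

sim_organelle_lineage <- function() {
  "Eukaryota;Cyanobacteria;Cyanobacteriia;Chloroplast;Chloroplast;Chloroplast"
}

#' Simulate ground truth for a multi-substrate qSIP experiment
#'
#' Draws per-ASV GC content, Dirichlet relative abundances and lineages
#' (including designated contaminant and organelle spike-ins), and assigns
#' which ASVs are truly labeled under each \eqn{^{13}}C substrate. The
#' `"oxic-like"` scenario labels no ASV under taurine (methionine and
#' glucose sets overlap in one ASV); the `"hypoxic-like"` scenario uses the
#' overlapping region structure of a stratified-fjord experiment, with the
#' taurine/methionine co-labeled ASVs given correlated true EAFs
#' (`eaf_methionine ~ 0.7 * eaf_taurine`, mimicking taurine preference).
#'
#' @param n_asvs Number of genuine (banded) ASVs, >= 2.
#' @param scenario `"hypoxic-like"`, `"oxic-like"` or `"custom"` (no
#'   labeling; set the `eaf` matrix yourself).
#' @param eaf_range Range from which positive true EAFs are drawn.
#' @param n_contaminants,n_organelles Spike-in counts appended after the
#'   genuine ASVs.
#' @param seed Integer seed (mandatory for reproducible truth).
#' @return Object of class `sip_truth`: list with `asv` (data.frame: id,
#'   gc, abundance, lineage, contaminant, organelle), `eaf` (ASV x substrate
#'   matrix of true EAFs) and `scenario`.
#' @export
simulate_truth <- function(n_asvs = 100L,
                           scenario = c("hypoxic-like", "oxic-like", "custom"),
                           eaf_range = c(0.05, 0.45),
                           n_contaminants = 3L, n_organelles = 1L,
                           seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(n_asvs >= 2L)
  min_n <- c("hypoxic-like" = 33L, "oxic-like" = 17L, custom = 2L)[[scenario]]
  if (n_asvs < min_n)
    stop(sprintf("scenario '%s' needs at least %d ASVs for its labeling map",
                 scenario, min_n))
  set.seed(seed)
  n_extra <- n_contaminants + n_organelles
  ids <- c(sprintf("ASV%03d", seq_len(n_asvs)),
           if (n_contaminants) sprintf("CONT%02d", seq_len(n_contaminants)),
           if (n_organelles) sprintf("ORG%02d", seq_len(n_organelles)))
  gc <- stats::runif(n_asvs + n_extra, 0.3, 0.7)
  ab <- stats::rgamma(n_asvs + n_extra, shape = 1)
  # spike-ins get a modest, controlled share of the community
  ab[seq_len(n_extra) + n_asvs] <- sum(ab[seq_len(n_asvs)]) * 0.02
  ab <- ab / sum(ab)
  lineage <- c(sample(sim_lineage_pool(), n_asvs, replace = TRUE),
               if (n_contaminants) sample(sim_contaminant_pool(),
                                          n_contaminants, replace = TRUE),
               if (n_organelles) rep(sim_organelle_lineage(), n_organelles))
  substrates <- c("13C-taurine", "13C-methionine", "13C-glucose")
  eaf <- matrix(0, n_asvs + n_extra, 3L, dimnames = list(ids, substrates))

  pick <- function(k, used) sample(setdiff(seq_len(n_asvs), used), k)
  if (scenario == "oxic-like") {
    # regions: methionine-and-glucose = 1, methionine only = 4, glucose only = 12
    used <- integer()
    a <- pick(1L, used); used <- c(used, a)
    b <- pick(4L, used); used <- c(used, b)
    cc <- pick(12L, used)
    for (i in c(a, b)) eaf[i, "13C-methionine"] <- stats::runif(1, eaf_range[1], eaf_range[2])
    for (i in c(a, cc)) eaf[i, "13C-glucose"] <- stats::runif(1, eaf_range[1], eaf_range[2])
  } else if (scenario == "hypoxic-like") {
    # regions: all three = 8; DOS only (taurine+methionine) = 3;
    # taurine+glucose = 5; taurine only = 7; glucose only = 10
    used <- integer()
    d <- pick(8L, used); used <- c(used, d)
    e <- pick(3L, used); used <- c(used, e)
    f <- pick(5L, used); used <- c(used, f)
    g <- pick(7L, used); used <- c(used, g)
    h <- pick(10L, used)
    tau <- c(d, e, f, g)
    eaf[tau, "13C-taurine"] <- stats::runif(length(tau), eaf_range[1], eaf_range[2])
    dos <- c(d, e)          # methionine co-labeled, correlated, weaker
    eaf[dos, "13C-methionine"] <-
      pmax(0.02, 0.7 * eaf[dos, "13C-taurine"] + stats::rnorm(length(dos), 0, 0.01))
    glu <- c(d, f, h)
    eaf[glu, "13C-glucose"] <- ifelse(
      eaf[glu, "13C-taurine"] > 0,
      pmax(0.02, 0.5 * eaf[glu, "13C-taurine"] + stats::rnorm(length(glu), 0, 0.05)),
      stats::runif(length(glu), eaf_range[1], eaf_range[2]))
  }
  cst <- isotope_constants()
  if (any(eaf > 1 - cst$nat13c)) stop("true EAF exceeds 1 - nat13c")

  structure(
    list(asv = data.frame(
           asv = ids, gc = gc, abundance = ab, lineage = lineage,
           contaminant = c(rep(FALSE, n_asvs), rep(TRUE, n_contaminants),
                           rep(FALSE, n_organelles)),
           organelle = c(rep(FALSE, n_asvs + n_contaminants),
                         rep(TRUE, n_organelles)),
           stringsAsFactors = FALSE),
         eaf = eaf, scenario = scenario, seed = seed),
    class = "sip_truth")
}

# expected copies of each ASV in each fraction, given fraction boundaries
sim_expected_copies <- function(truth, bounds, treatment, params, cst) {
  centers <- (bounds[-1L] + bounds[-length(bounds)]) / 2
  asv <- truth$asv
  n <- nrow(asv)
  W_light <- cst$gc_intercept + cst$gc_slope * asv$gc
  eaf <- if (treatment %in% colnames(truth$eaf)) truth$eaf[, treatment]
         else rep(0, n)
  mw <- molecular_weights(asv$gc, cst)
  M_lab <- mw$M_light + eaf / (1 - cst$nat13c) * (mw$M_heavymax - mw$M_light)
  W <- W_light * M_lab / mw$M_light          # exact inverse of the EAF chain

  lo <- utils::head(bounds, -1L); hi <- bounds[-1L]
  expected <- matrix(0, n, length(centers),
                     dimnames = list(asv$asv, NULL))
  for (i in seq_len(n)) {
    if (asv$contaminant[i]) {
      # reagent background: density-uniform, not banded
      mass <- (hi - lo) / (max(bounds) - min(bounds))
    } else if (params$sigma_density == 0) {
      mass <- as.numeric(W[i] >= lo & W[i] < hi)
    } else {
      mass <- stats::pnorm(hi, W[i], params$sigma_density) -
        stats::pnorm(lo, W[i], params$sigma_density)
    }
    expected[i, ] <- params$total_copies * asv$abundance[i] * mass
  }
  trunc_mass <- 1 - rowSums(expected) / (params$total_copies * asv$abundance)
  if (any(trunc_mass[!asv$contaminant] > 0.01))
    warning("density range truncates > 1% of banded mass for ",
            sum(trunc_mass[!asv$contaminant] > 0.01), " ASV(s)")
  list(expected = expected, centers = centers, W = W)
}

#' Simulate a full synthetic qSIP dataset
#'
#' Generates gradient tables, an ASV count matrix and a taxonomy table for a
#' set of treatments from known ground truth. Each ASV's unlabeled mean
#' density follows from its GC content; labeled mean densities follow from
#' the true EAF through the exact inverse of the EAF transform, so simulator
#' and estimator are inverses in the noise-free limit. Per fraction,
#' expected copies are the Gaussian density-band mass falling inside the
#' fraction's boundaries; SQ values receive lognormal qPCR noise and read
#' counts are multinomial at fixed depth. Contaminant spike-ins are
#' density-uniform (reagent background).
#'
#' @param truth A [simulate_truth()] object.
#' @param params A [simulate_params()] object.
#' @param treatments Treatments to simulate; defaults to the three
#'   \eqn{^{13}}C substrates plus the `"12C-mix"` reference.
#' @param seed Integer seed.
#' @return List with `gradients` (list of [gradient_replicate()]),
#'   `counts` (a [feature_count_matrix()]), `taxonomy` (data.frame) and
#'   `truth`.
#' @export
simulate_dataset <- function(truth, params = simulate_params(),
                             treatments = c(colnames(truth$eaf), "12C-mix"),
                             seed = 1L) {
  stopifnot(inherits(truth, "sip_truth"), inherits(params, "sip_sim_params"))
  set.seed(seed)
  cst <- isotope_constants()
  bounds0 <- seq(params$density_range[1], params$density_range[2],
                 length.out = params$n_fractions + 1L)
  gradients <- list()
  count_cols <- list()
  samples <- list()
  for (tr in treatments) {
    for (r in seq_len(params$n_replicates)) {
      # replicate-level density calibration offset: the run's measured
      # density scale is shifted relative to where the DNA truly bands,
      # the dominant run-to-run variability technical replicates capture
      eps <- stats::rnorm(1, 0, params$replicate_density_jitter)
      ec <- sim_expected_copies(truth, bounds0, tr, params, cst)
      ec$centers <- ec$centers + eps
      sq_noise <- if (params$qpcr_cv > 0) {
        sdlog <- sqrt(log(1 + params$qpcr_cv^2))
        stats::rlnorm(length(ec$centers), -sdlog^2 / 2, sdlog)
      } else rep(1, length(ec$centers))
      sq <- colSums(ec$expected) * sq_noise
      reads <- matrix(0L, nrow(ec$expected), ncol(ec$expected),
                      dimnames = dimnames(ec$expected))
      for (k in seq_along(ec$centers)) {
        pk <- ec$expected[, k]
        if (sum(pk) <= 0) next
        if (is.finite(params$seq_depth)) {
          reads[, k] <- stats::rmultinom(1L, params$seq_depth, pk)[, 1L]
        } else {
          reads[, k] <- round(pk / sum(pk) * 1e6)
        }
      }
      key <- paste(tr, r, seq_along(ec$centers), sep = ":")
      gradients[[paste(tr, r, sep = ":")]] <-
        gradient_replicate(tr, r, density = ec$centers, copies = sq,
                           fraction = seq_along(ec$centers))
      count_cols[[length(count_cols) + 1L]] <- reads
      samples[[length(samples) + 1L]] <-
        data.frame(treatment = tr, replicate = r,
                   fraction = as.character(seq_along(ec$centers)),
                   stringsAsFactors = FALSE)
    }
  }
  counts <- feature_count_matrix(do.call(cbind, count_cols),
                                 do.call(rbind, samples))
  taxonomy <- parse_taxonomy(data.frame(asv = truth$asv$asv,
                                        taxon = truth$asv$lineage,
                                        stringsAsFactors = FALSE))
  list(gradients = gradients, counts = counts, taxonomy = taxonomy,
       truth = truth)
}

#' Estimator-recovery report against simulated truth
#'
#' Compares a [qsip()] fit with the simulator's ground truth for one labeled
#' treatment: bias, RMSE, sensitivity (incorporators called among truly
#' labeled ASVs) and false-positive rate (called among `true EAF = 0`),
#' overall and by true-EAF stratum.
#'
#' @param truth A [simulate_truth()] object.
#' @param fit A [qsip()] fit of one labeled treatment.
#' @param treatment Substrate column of `truth$eaf`; defaults to the fit's
#'   labeled treatment.
#' @param strata Stratum boundaries on true EAF.
#' @return data.frame with one row per stratum plus an `overall` row.
#' @export
recovery_report <- function(truth, fit, treatment = fit$labeled,
                            strata = c(0, 0.05, 0.2, 0.5, 1)) {
  stopifnot(inherits(truth, "sip_truth"))
  est <- if (inherits(fit, "qsip")) fit$estimates else fit
  shared <- intersect(est$asv, rownames(truth$eaf))
  if (!length(shared)) stop("truth and estimates share no ASVs")
  true_eaf <- truth$eaf[shared, treatment]
  e <- est[match(shared, est$asv), , drop = FALSE]
  err <- e$median_eaf - true_eaf

  row_of <- function(idx, label) {
    labeled <- true_eaf[idx] > 0
    data.frame(
      stratum = label, n = length(idx),
      bias = if (length(idx)) mean(err[idx]) else NA_real_,
      rmse = if (length(idx)) sqrt(mean(err[idx]^2)) else NA_real_,
      sensitivity = if (any(labeled)) mean(e$incorporator[idx][labeled]) else NA_real_,
      fpr = if (any(!labeled)) mean(e$incorporator[idx][!labeled]) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- row_of(seq_along(shared), "overall")
  out <- rbind(out, row_of(which(true_eaf == 0), "null"))
  for (s in seq_len(length(strata) - 1L)) {
    idx <- which(true_eaf > strata[s] & true_eaf <= strata[s + 1L])
    out <- rbind(out, row_of(idx, sprintf("(%g, %g]", strata[s], strata[s + 1L])))
  }
  rownames(out) <- NULL
  out
}
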