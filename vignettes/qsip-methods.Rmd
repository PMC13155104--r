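---
title: "Methods: qSIP excess atom fractions, incorporator calling, and the bottle oxygen model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qSIP excess atom fractions, incorporator calling, and the bottle oxygen model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fjordsip)
```

## The measurement model

DNA-qSIP infers how much ¹³C a taxon incorporated into its DNA from how far
its DNA bands shift in a CsCl density gradient. The package's data model
mirrors the laboratory workflow:

- a **gradient replicate** is one ultracentrifugation/fractionation run of
  one incubation's DNA: an ordered set of fractions with buoyant density
  $\rho_k$ (g/mL) and a qPCR copy total $SQ_k$ (16S copies). Fractions are
  stored in ascending density; the collection order is kept as provenance
  and checked for monotonicity by `validate_gradient()`.
- sequencing each fraction gives per-ASV read counts, and copies are
  allocated proportionally:
  $c_{ik} = \frac{r_{ik}}{\sum_i r_{ik}} SQ_k$. Column sums are conserved by
  construction, which the test suite asserts exactly.
- the taxon's density is the copy-weighted mean
  $W = \sum_k \rho_k c_{ik} / \sum_k c_{ik}$ over the sequenced fractions.
  An ASV with no copies anywhere has *no* density (a missing value), never
  zero.

The density shift converts to an excess atom fraction (EAF) through the
standard linear GC–density relation and the GC-dependent molecular weight of
DNA (constants in `isotope_constants()`, overridable for sensitivity
analyses):

$$GC = \frac{W_{light} - 1.646057}{0.083506},\quad
  M_{light} = 0.496\,GC + 307.691,$$
$$M_{heavy} = -0.4987282\,GC + 9.974564 + M_{light},\quad
  M_{lab} = \frac{W_{lab}}{W_{light}} M_{light},$$
$$EAF = \frac{M_{lab} - M_{light}}{M_{heavy} - M_{light}}\,(1 - 0.01111233).$$

Assumptions worth keeping in mind: the GC–density relation holds for
unlabeled DNA banding at equilibrium; the unlabeled reference treatment
measures each ASV's $W_{light}$ without isotope effects; and relative read
abundance within a fraction is proportional to 16S copy share. Negative
EAFs are preserved (no clamping at zero) — they are the natural null
fluctuations against which the confidence-interval criterion works; the
theoretical maximum $1 - 0.01111233 \approx 0.989$ is asserted, not
enforced.

## Replication and uncertainty

The replication unit is the **technical ultracentrifugation replicate**
(typically three per treatment), which captures run-to-run fractionation
variability — the dominant methodological uncertainty in qSIP. `qsip()`
computes one EAF per labeled replicate against the *mean* unlabeled
$W_{light}$, reports the median across labeled replicates, and builds a 90%
percentile bootstrap interval by resampling the labeled and unlabeled
replicate sets independently with replacement (1000 iterations by default,
seeded). An ASV is an incorporator iff the lower bound is strictly above
zero. Resampling the two treatments jointly-but-independently was a design
choice left open by the replication structure; it propagates reference
uncertainty into the interval, which matters because with three replicates
a labeled-only resample would collapse to the min/max of three values.

ASVs absent from every unlabeled replicate have no reference and are
excluded with a logged reason rather than imputed.

## The filtering cascade

`filter_features()` reproduces the conventional three-stage ASV QC for
qSIP amplicon data, in order: (1) removal of blocklisted contaminant genera
(case-insensitive substring at any rank; *Ralstonia*, *Variovorax*,
*Streptococcus* ship as defaults, extensible by file) plus
mitochondria/chloroplast organelle reads; (2) a global low-abundance
threshold (keep $\geq$ 10 reads overall); (3) a per-treatment rule keeping
an ASV only where it exceeds 10 reads in *every* replicate of that
treatment. The asymmetry — stage 2 keeps at the threshold, stage 3 requires
strictly more — follows the conventional wording of the two rules; both are
parameters. Stage 3 produces inclusion metadata only: counts are never
modified, and the ledger records every removal with the read share it
carried at that stage.

## Community statistics

Composition, Shannon diversity (natural log), Bray–Curtis dissimilarity,
PCoA (classical metric scaling via `stats::cmdscale`; negative eigenvalues
reported, not corrected) and a one-way PERMANOVA are provided for
incubation-level summaries. Ordination inputs default to one composite
community per incubation (reads pooled over its sequenced fractions),
because fraction-level ordination conflates density structure with
composition. The PERMANOVA permutes labels with a seed, or exhaustively
enumerates all arrangements for small n, where its p-value is exact; NMDS
is deliberately out of scope (PCoA is deterministic and testable).

Cross-substrate comparison pairs ASVs called incorporators in **both**
treatments (the `"shared"` mode exists for sensitivity analyses), fits OLS
(`stats::lm`) and reports $R^2$, adjusted $R^2$, $F$ and $p$. Linearity is
checked with a Rainbow-type test: OLS on the central half of the x-ordered
data versus all points,
$F = \frac{(RSS_{full} - RSS_{sub})/(n - n_{sub})}{RSS_{sub}/(n_{sub}-2)}$,
with $F := 0$ when the full-data RSS is numerically no larger than the
subset's (perfectly linear data).

## The bottle oxygen model

Static 1-L incubations of hypoxic water sit under an air headspace, so some
oxygen invades during a 48-h incubation. `bottle_o2()` quantifies how much
of the water column that can actually affect:

$$\partial_t C = D\,\partial_z^2 C - R,\qquad
  C(0, t) = C_{surface},\qquad \partial_z C(H, t) = 0,$$

with zero-order respiration $R$ switching off where $C = 0$. Defaults are
declared assumptions, all configurable: column height 12 cm (1-L bottle of
~10 cm diameter), surface boundary 350 µM (air equilibrium near 4–5 °C at
salinity ~19), molecular diffusivity $1.3\times10^{-5}$ cm²/s (cold
seawater, unstirred — no turbulence term), hypoxia threshold 63 µM,
respiration spanning the literature range 30–400 nmol O₂ L⁻¹ h⁻¹ for
comparable fjords. A Dirichlet air-equilibrium boundary is the *most
generous* oxygen supply consistent with the setup (no interfacial transfer
resistance), so hypoxic volume fractions computed here are conservative
lower bounds in spirit.

Numerics: explicit finite differences, $dz$ = 0.1 cm by default,
$dt = 0.4\,dz^2/D$ (inside the $D\,dt/dz^2 \le 0.5$ stability limit; an
unstable user-requested $dt$ is refined with a warning), concentration
clamped at zero, mirror node for the no-flux bottom. The discrete mass
budget (interface flux minus integrated respiration) is tracked per step
and the test suite requires it to close to well under 1% while no clamping
is active; halving $dz$ moves the 48-h hypoxic fraction by less than 0.02.
The closed-form `depletion_time()` (e.g. 35 h at 14 µM and 400 nmol O₂ L⁻¹
h⁻¹) is the $D = 0$ limit and the PDE reduces to it exactly, which is
tested. The companion check — that a large majority of the column stays
below 63 µM over 48 h across the whole respiration range — comes out near
74–77% under these defaults: the 63 µM contour sits roughly $2\sqrt{Dt}$
(~3 cm) below the interface because the boundary concentration is far above
the threshold.

## What the simulator emulates — and what it does not

`simulate_truth()` + `simulate_dataset()` generate gradients with known
per-ASV EAF so estimator behaviour is measurable. Design, with defaults
chosen once to resemble published gradient profiles:

- 20 fractions spanning 1.65–1.77 g/mL (0.006 g/mL width, inside the
  conventional 0.005–0.007 fractionation interval) — the span covers
  unlabeled bands for GC 0.3–0.7 plus shifts up to EAF ≈ 0.95 without
  truncation;
- Gaussian within-gradient density spread, $\sigma$ = 0.004 g/mL, so a
  taxon occupies ~6–10 fractions as in real profiles;
- a per-replicate **density calibration offset** (SD 0.001 g/mL): each
  ultracentrifugation run's measured density scale shifts as a whole
  relative to where the DNA truly bands. This is the run-to-run
  fractionation variability that motivates technical replicates, and the
  main source of between-replicate EAF spread;
- 10% lognormal qPCR noise on fraction SQ; multinomial sequencing at 10⁴
  reads per fraction (uniform depth by default; `Inf` gives noise-free
  proportional counts for round-trip tests);
- labeled mean densities produced by the *exact inverse* of the EAF
  transform, making simulator and estimator inverses in the noise-free
  continuous limit;
- contaminant spike-ins as density-uniform reads (reagent background) and
  an organelle lineage for the filter tests. Because background is uniform
  while genuine taxa band, contaminants dominate reads in empty flanking
  fractions — which is also why real studies sequence only peak-spanning
  fractions;
- scenario labeling maps: `"oxic-like"` labels no taurine ASVs;
  `"hypoxic-like"` uses overlapping substrate sets (8 triple-labeled, 3
  DOS-only, 5 taurine+glucose, 7 taurine-only, 10 glucose-only) with
  methionine EAFs correlated to and ~0.7× the taurine EAFs of co-labeled
  ASVs.

The simulator does **not** emulate: read-level error or chimeras, GC- or
length-dependent amplification bias, isotope effects on banding width,
depth variation between libraries (available as an option only), biological
replication, or cross-feeding. Passing recovery tests therefore show the
*inference chain* is correct and calibrated under the stated noise model;
they cannot certify field data free of those unmodeled effects.

Under the default noise model, the test suite requires (and the acceptance
suite re-checks) a median-EAF RMSE ≤ 0.05 over true EAFs spanning 0–0.95,
90% CI coverage within [80%, 98%] over 200 simulated cases, and a null
false-positive rate ≤ 10% for the incorporator call — run the suite to see
the realized values. Problem sizes in the tests (tens of ASVs, 3+3
replicates, a few hundred bootstrap iterations for the simulation studies)
were chosen as the smallest designs representative of the target study's
scale.

## Degenerate inputs and tie-breaks

- Peak detection for QC breaks ties toward the lower density, keeping
  reports deterministic.
- Zero-read fractions contribute zero copies and are logged, not dropped.
- A zero-variance replicate set yields a degenerate bootstrap interval at
  the point estimate — an ASV shifted identically in all replicates is
  called an incorporator with an interval of width zero.
- `ci_low = 0` exactly is *not* an incorporator (strict inequality).
- Missing SQ is allowed only for non-sequenced fractions; density must
  always be present.

## Known limitations

- With three technical replicates the bootstrap is coarse; intervals are
  honest but their coverage depends on the between-replicate variance being
  representative, and single-bottle designs cannot separate biological from
  technical variation.
- The per-ASV reference requires the ASV to be detectable in the unlabeled
  treatment; taxa that bloom only under labeling are excluded rather than
  estimated.
- The bottle model is 1-D with uniform cross-section and an ideal
  air-equilibrium boundary; real bottles have shoulder geometry and
  interfacial transfer resistance, both of which reduce oxygen invasion.
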