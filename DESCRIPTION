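Package: fjordsip
Title: Quantitative Stable Isotope Probing of Density-Gradient Amplicon Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for DNA quantitative stable isotope probing (qSIP) of
    marine amplicon datasets: density-gradient fraction data model and
    quality control, the ASV contaminant/abundance filtering cascade,
    per-taxon excess atom fraction (EAF) estimation with bootstrap
    confidence intervals over technical ultracentrifugation replicates,
    incorporator calling, community statistics (relative abundance,
    Shannon diversity, Bray-Curtis, PCoA, PERMANOVA), cross-substrate
    incorporator comparison, an incubation-bottle oxygen
    diffusion-respiration model, and a synthetic gradient simulator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    lmtest,
    jsonlite
Config/testthat/edition: 3
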