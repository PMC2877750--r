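Package: methylskin
Title: Bead-Level Methylation Array and Bisulfite Amplicon Analysis for Skin
    Aging Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for Infinium HumanMethylation27-style bead
    arrays applied to human skin: channel-wise quantile normalization of raw
    bead intensities, detection P-values from negative-control beads
    (Mann-Whitney against the negative bead pool, Benjamini-Hochberg adjusted
    before taking the per-probe minimum), beta-value computation, delta-beta /
    Wilcoxon / Benjamini-Hochberg differential methylation calling with
    CpG-island and X-chromosome stratification, ratio-over-sum (RS) curves and
    a Gaussian-null global methylation-shift test. Includes a synthetic
    bead-level data generator that reproduces the bimodal beta architecture of
    skin methylomes (with planted age, sun-exposure, tissue and sex effects)
    and a per-CpG methylation caller for deep bisulfite amplicon reads with
    deamination-efficiency QC and array concordance checks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
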