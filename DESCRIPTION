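Package: erpoly
Title: Forward Simulation and Inference for Polygenic Adaptation in
    Evolve-and-Resequence Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wright-Fisher forward simulation of polygenic adaptation after a
    shift in trait optimum, with controllable founder linkage disequilibrium,
    and the matching Evolve-and-Resequence inference chain: Pool-seq count
    sampling in the popoolation2 sync dialect, temporal effective population
    size estimation, drift- and noise-aware chi-squared and
    Cochran-Mantel-Haenszel tests for candidate SNPs, haplotype-block
    reconstruction from correlated allele-frequency trajectories,
    selection-coefficient estimation from logit-linear trajectories, and
    replicate-parallelism and diversity summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
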