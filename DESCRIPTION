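Package: ultrametric
Title: Ultrametric Staging of Spawning Progression in Serial-Spawning Fish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated staging of female serial-spawning fish from whole-mount
    ovarian micrographs. Detects and measures stained oocytes, builds oocyte
    size frequency distributions (OSFDs) with cohort, bimodality, tail and
    hiatus annotation, computes the oocyte ratio (OR, previtellogenic over
    developing oocyte counts) and assigns the four-level oocyte ratio category
    (ORC) used to rank spawning progression. Companion metrics include
    previtellogenic-oocyte fecundity, Weibel point-count stereology of
    post-ovulatory follicles, atresia prevalence and intensity, allometric
    condition factors and the gonadosomatic index, plus the nonparametric
    group comparisons (Kruskal-Wallis, pairwise Wilcoxon with
    Benjamini-Hochberg adjustment) used to validate the staging. A seeded
    synthetic generator renders ground-truthed micrographs and spawning
    cohorts so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    purrr,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
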