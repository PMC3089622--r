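Package: phyloassembly
Title: Phylogenetic Community Assembly Analysis for Experimental Grassland Plots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community-phylogenetics analysis of experimentally assembled
    grassland communities undergoing natural colonization and extinction.
    Implements phylogenetic diversity (PD, rooted at the community ancestor
    and excluding the path to the tree root), mean nearest neighbor distance
    (MNND) and mean pairwise distance (MPD); richness-preserving null
    communities with clade constraints (e.g. at least one grass) and
    rank-based two-tailed dispersion tests; per-plot colonist and extinction
    relatedness tests with clade-exclusion and colonists-as-residents
    variants; compositional (Jaccard) and phylogenetic convergence analyses;
    diversity-productivity regressions and the legume-covariate ANCOVA; and
    a synthetic data generator emulating a BIODEPTH-style sown-diversity
    experiment with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
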