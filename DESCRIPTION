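Package: grasshydro
Title: Leaf Hydraulic Anatomy, Drought Simulation and Comparative
    Statistics for C3 and C4 Grasses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for contrasting the leaf hydraulic systems of C3 and
    C4 grasses. Estimates theoretical xylem conductance of parallel leaf
    vein systems from conduit anatomy using Poiseuille's law for
    elliptical conduits, partitions leaf hydraulic conductance into
    xylem and outside-xylem components, fits linear hydraulic
    vulnerability curves, couples sigmoidal stomatal closure and linear
    hydraulic decline to C3 (Farquhar-type) and simplified C4
    assimilation models in a quasi-static soil dry-down simulator, and
    provides phylogenetic comparative statistics (PGLS with maximum
    likelihood Pagel's lambda, simulation-based phylogenetic ANOVA,
    phylogenetic reduced major axis regression) implemented from first
    principles. A synthetic-data module generates ultrametric trees with
    repeated C4 origins, pathway-contrasted lognormal trait tables,
    per-vein-order conduit anatomy and noisy vulnerability curves so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    phytools
Config/testthat/edition: 3
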