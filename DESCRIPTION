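Package: cavecomm
Title: Null-Model Analysis of Cave Community Incidence Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the null-model analysis of species-by-site
    presence-absence (incidence) matrices from insular habitats such as
    caves. Implements checkerboard-based segregation (C-score) and
    nestedness (NODF) metrics with equiprobable, proportional and
    fixed-fixed randomization ensembles and standardized effect sizes;
    taxonomic step-distance matrices and the net relatedness index (NRI)
    from ranked classifications; proportional beta-diversity partitioning,
    occupancy and endemism summaries, and allometric richness scaling;
    longitude-sorted shifting-window analyses with a principal-coordinate
    spatial eigenvector covariate; main-effects linear models reporting
    partial eta-squared; and seeded synthetic-data generators (random,
    nested, checkerboard and drift-assembled metacommunities, ranked
    taxonomies, site metadata and categorical traits) so the whole
    pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    picante,
    jsonlite
Config/testthat/edition: 3
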