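Package: facemasc
Title: Facial Masculinity Scoring and Sexual Dimorphism Analysis from 3D
    Facial Landmarks
Version: 0.1.0
Authors@R:
    person("facemasc", "developers", email = "facemasc@example.org",
           role = c("aut", "cre"))
Description: Morphometric analysis of sexual dimorphism in 3D face scans.
    Computes eleven landmark-based facial distances (three straight-line,
    eight surface geodesics approximated by shortest paths over a refined
    mesh edge graph) and a landmark-triangle facial area from triangulated
    meshes with 13 anthropometric landmarks; trains a two-class linear
    discriminant on the distance vector and maps faces onto a 0-20 facial
    masculinity score; provides the accompanying statistical layer (Welch's
    t from raw data or printed summaries with Satterthwaite degrees of
    freedom, Mann-Whitney rank-sum with exact small-sample p-values,
    pooled-SD Cohen's d with normal-approximation confidence intervals,
    one-way ANOVA from summaries, Tukey HSD, and minimum-sample-size power
    search on the noncentral F distribution); and ships a synthetic-data
    generator (sexually dimorphic multivariate-normal cohorts and
    deformed-ellipsoid face meshes with on-surface landmarks) plus a
    pipeline and command-line interface that reproduce a
    sibling/control/proband study design end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
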