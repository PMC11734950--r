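Package: whalerisk
Title: Baleen Whale Habitat Suitability and Vessel Encounter Risk Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for presence-only ensemble species distribution modelling of
    baleen whales and for mapping their relative risk of encountering vessels.
    Provides regular lat/lon grid construction with point-to-cell aggregation
    and regridding, a synthetic-data generator (spatially autocorrelated
    environmental fields, effort-biased sightings, vessel-activity surfaces,
    zero-inflated incident counts, acoustic detection records) with known
    ground truth, TSS-weighted ensembles of GLM, random-forest and
    maximum-entropy members with cross-validation and permutation variable
    importance, normalized whale- and vessel-occupancy surfaces and their
    encounter-risk product, zero-inflated negative-binomial and Poisson
    incident regressions with Moran's I residual diagnostics, and spatial
    overlap statistics (Schoener's D, Warren's I, Spearman correlation) with
    a vessel-permutation significance test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    glmmTMB,
    glmnet,
    ranger,
    jsonlite,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
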