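Package: bonescore
Title: Composite Skeletal Phenotype Scores from Micro-CT and Mechanical Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for harmonizing and comparing skeletal phenotypes across
    mouse cohorts and micro-CT methodologies. Bone variable panels are
    standardized within mouse model (stratified by sex and age), pooled, and
    reduced to per-animal trabecular and cortical composite scores weighted by
    first-principal-component loadings. A factorial statistics layer provides
    assumption gating (Shapiro-Wilk with a log-transform fallback, Levene),
    Type III factorial ANOVA with sum-to-zero coding, a Welch reassessment,
    Sidak pairwise comparisons, Bonferroni contrasts, chi-square goodness of
    fit for transmission ratios and group-mean correlation. Supporting
    computations include three-point-bend mechanical property extraction
    (stiffness, 0.2 percent offset yield, resilience, toughness) and cortical
    cross-section geometry from binary masks (areas, perimeters, radial
    profiles, principal second moments of area). A synthetic-cohort generator
    produces correlated bone-variable panels, bend curves and annular masks so
    the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    MASS,
    car,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    withr,
    png,
    tiff
Config/testthat/edition: 3
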