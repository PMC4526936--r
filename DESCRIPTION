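Package: varreport
Title: Interactive Personal Genomics Variant Reports and Comprehension Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating consumer-facing personal
    genomics variant reports. Provides a validated data model for annotated
    gene-variant reports (impact, evidence certainty, clinical importance,
    population frequency, linked conditions), deterministic layout engines for
    seven report designs (sortable table, bar chart, bubble graph, treemap,
    heat map, zoomable treemap, zoomable partition) with an impact-by-certainty
    hue/saturation color encoding, self-contained HTML/SVG renderers with
    side-panel tooltips and a clickable glossary, a nine-item comprehension
    quiz with a brute-force answer oracle and 0-10 grading rubric, seeded
    synthetic dataset and participant-response generators, and the statistical
    pipeline for between-condition comparison: per-condition summaries,
    one-way ANOVA, and Tukey-Kramer post hoc tests built on a numerically
    integrated studentized range distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
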