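Package: citesum
Title: Citable Views and Citation Summaries for Curated Databases
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns a hierarchically organised curated database -- nodes with
    contributor sets and outgoing bibliographic references -- into a
    recommended set of citable views and machine-generated citation
    summaries.  Provides Jaccard-distance stress measures over families of
    author sets, correlation clustering of authorship similarity on signed
    graphs, a bottom-up view-recommendation procedure with curator review
    flags, rendering of summary documents with bibliographic and
    Dublin-Core-style metadata exports, and change-driven re-versioning of
    published summaries.  Includes a synthetic-hierarchy generator with
    planted authorship blocks so every stage can be exercised without access
    to a production database.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
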