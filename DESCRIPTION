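Package: caerank
Title: Ranking Conclusive Association Entities in Biomedical Titles and Abstracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies conclusive association entities (CAEs) - the genes,
    diseases and chemicals specifically involved in the associations an
    article concludes - among dictionary-detected candidate entities in
    article titles and abstracts. Provides sentence segmentation,
    author-abbreviation resolution and dictionary-based candidate detection
    against a CTD-style vocabulary; frequency, rareness, co-occurrence,
    concentration and locality indicators; typical fusion scorers (TFIDF,
    BM25e, ESe, CCSEe, eGRABe) and learning-based fusion by pairwise linear
    ranking; ranking evaluation (MAP, precision at X, percentage of articles
    with a top-X hit) with cross-validation and paired significance tests;
    probability-gain distribution analysis; frequency-recency maps for
    curation support; and a synthetic corpus generator with tunable
    class contrasts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tibble,
    dplyr,
    rlang,
    e1071,
    ggplot2,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
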