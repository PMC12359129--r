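Package: hespat
Title: Entropy-Weighted CoCoSo Ranking and Tier Clustering of Health-Security Indicators
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-criteria assessment pipeline for bounded country-by-indicator
    score matrices such as the six-pillar Global Health Security Index. Computes
    objective indicator weights by the Shannon entropy method, ranks countries
    with the Combined Compromise Solution (CoCoSo) and four comparator methods
    (TOPSIS, EDAS, WASPAS, VIKOR), partitions composite scores into performance
    tiers by seeded k-means with elbow diagnostics, and quantifies temporal and
    regional shifts in weights, ranks and tiers. Includes a synthetic-data
    generator with planted dispersion profiles and performance tiers for
    validation studies, and a reproducible multi-period pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    readxl
Config/testthat/edition: 3
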