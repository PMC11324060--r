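Package: fraggraph
Title: Fragment-Combination Graph Analysis for Pseudo-Natural-Product Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies compound libraries into pseudo-natural products (PNP),
    natural-product-like (NPL), natural products (NP) and NonPNP compounds by
    detecting natural-product fragments in standardized structures and typing
    every pairwise fragment combination (spiro, edge and bridge fusions,
    monopodal and bipodal connections) into fragment-combination graphs (FCGs).
    Includes structure standardization with racemization and deglycosylation
    via Open Babel, Murcko scaffold catalogs, the heavy-atom-normalized
    spatial complexity score (nSPS), scaffold-based screening-subset
    selection, a PAINS triage step, and induction/cluster-subprofile analysis
    of cell-painting morphological profiles, plus a synthetic-fixture
    generator with per-molecule ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    ChemmineR,
    ChemmineOB,
    uwot,
    testthat (>= 3.0.0)
SystemRequirements: Open Babel (obabel on the PATH)
Config/testthat/edition: 3
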