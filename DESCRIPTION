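Package: traitmod
Title: Trait-Module Association, Permutation Omnibus Testing and Causal
    Mediation for Brain Co-Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links a behavioral trait to brain gene co-expression modules,
    neuropathology, cognitive decline and Alzheimer's dementia through a
    tested, reusable pipeline: covariate-adjusted linear association scans
    at the module, gene and SNP level; a permutation-based omnibus test of
    the full module P-value distribution with empirical quantile-quantile
    confidence envelopes; Benjamini-Hochberg gene-level FDR scans;
    region-specific pathology associations; instrumental-variable
    pleiotropy screening; and a quasi-Bayesian linear causal-mediation
    engine (average causal mediation and direct effects) including chain
    mediation over a trait -> module -> tangle pathology -> cognitive
    decline -> dementia sequence. A synthetic cohort generator emulating a
    community-based aging study with planted effects makes every stage
    testable without access to controlled data.
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
    yaml,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
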