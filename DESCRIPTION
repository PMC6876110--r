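Package: metabonet
Title: Disease-Associated Metabolite Networks and Candidate Metabolite
    Prioritization
Version: 0.1.0
Authors@R:
    person("Metabonet", "Developers", email = "metabonet@example.org",
           role = c("aut", "cre"))
Description: Builds weighted metabolite-metabolite networks from
    disease-metabolite association tables by modified collaborative
    filtering over disease functional similarities, fuses them with
    literature text-mining evidence via a noisy-OR rule, and prioritizes
    candidate disease-related metabolites by random walk with restart.
    Includes ontology-based disease similarity (gene-set cross-connectivity
    normalized by the most informative common ancestor), a two-snapshot
    ranking evaluation harness with Mann-Whitney AUC, a synthetic fixture
    generator with planted module structure, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
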