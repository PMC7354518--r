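Package: kcvkit
Title: Chlorovirus Kcv Potassium-Channel Gene Diversity and Single-Channel Gating Analysis
Version: 0.1.0
Authors@R: person("kcvkit", "maintainers", email = "kcvkit@example.org", role = c("aut", "cre"))
Description: Tools for surveying the diversity of the miniature viral potassium
    channel (Kcv) genes carried by chloroviruses. Provides degenerate-primer
    in-silico PCR with IUPAC ambiguity codes, unique-haplotype collapse with
    multiplicity accounting, translation and pairwise divergence, progressive
    multiple alignment with domain-aware conservation profiling of the
    two-transmembrane channel architecture (selectivity filter, turret, pore
    helix, transmembrane helices), neighbor-joining phylogeny on p-distances
    with Newick output, a seeded generator of kcv-like gene families with
    known ground truth, and a two-state Markov single-channel gating simulator
    with half-amplitude idealization, open-probability and unitary-conductance
    estimation including the flicker-gating bandwidth artifact.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
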