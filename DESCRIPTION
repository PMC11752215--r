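Package: nlrscan
Title: Identification and Classification of Plant NLR Immune Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Annotates nucleotide-binding leucine-rich-repeat (NLR) plant
    immune receptors in protein sequences. Profile-HMM hits for the CC, RPW8,
    TIR, NB-ARC, C-JID and MADA models (via HMMER or precomputed tables) are
    merged into domains, 17 short NLR-associated motifs are screened with a
    deterministic position-specific scoring predictor, LRR domains are
    assembled from chains of LxxLxL motifs, and each protein receives a
    domain-architecture string and a CNL/RNL/TNL/NL (or partial) class. NLR
    and NB-ARC sequences are extracted as FASTA, with full domain and motif
    tables; an ultra mode retains NB-ARC-less fragments. Includes a synthetic
    fixture generator with an independent rule evaluator and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
SystemRequirements: HMMER3 (hmmsearch, hmmbuild) for the live profile-search
    pathway; not needed when precomputed hit tables are supplied.
Config/testthat/edition: 3
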