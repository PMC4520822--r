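Package: ampliseek
Title: Degenerate-Primer Surveys of Protein-Coding Marker Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for culture-independent surveys of protein-coding marker
    genes amplified with degenerate primers, developed around the bacterial
    wax ester synthase/diacylglycerol acyltransferase (WS/DGAT) family.
    Covers the full desk-side chain: conserved-block discovery in protein
    alignments and codon-usage-aware reverse translation into IUPAC
    degenerate primer pairs; in-silico PCR with mismatch and 3'-anchor
    control; clone-library processing (size filtering, primer trimming,
    in-silico RFLP dereplication with HhaI/HincII, frame selection,
    active-site motif screening, split-half chimera flagging);
    distance-based sequence typing at a cutoff with Jukes-Cantor and Kimura
    protein corrections; neighbour-joining trees with bootstrap supports and
    Fitch parsimony scoring; and a synthetic clone-library generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
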