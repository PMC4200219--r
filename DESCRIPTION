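Package: neuropep
Title: Neuropeptide Prohormone Mining, Mass Spectrometry Matching and
    Peptide Family Analysis
Version: 0.1.0
Authors@R:
    person("neuropep", "developers", email = "neuropep@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering neuropeptide prohormone precursors in
    protein or nucleotide sequence sets and following the peptides through
    to mass-spectrometric confirmation and family-level comparison.
    Candidate precursors are flagged by dibasic (KK/KR/RK/RR) cleavage
    motifs, repeat structure and a transparent signal-peptide heuristic;
    peptides are matured in silico (dibasic cleavage, C-terminal amidation
    via Gly removal, N-terminal pyroglutamate), their monoisotopic and
    average masses and a/b/y/immonium fragment ions are predicted, and
    predictions are matched to MALDI peak lists under ppm tolerances with
    a binomial-tail spectrum score.  Peptide families are assigned by
    sequence motifs, clustered by Smith-Waterman similarity networks with
    Karlin-Altschul p-value edges, and compared by neighbor-joining trees
    with bootstrap support.  A synthetic-proteome generator with ground
    truth makes every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    optparse
Config/testthat/edition: 3
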