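Package: prolamap
Title: Curation, Classification and Coeliac-Toxic-Motif Mapping of
    Prolamin Seed Storage Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for building and analysing curated
    databases of cereal seed storage prolamins (gliadins, glutenins,
    hordeins, secalins, avenins). Reads FASTA in the UniProt, NCBI and
    plain header dialects; deduplicates and screens records with an
    auditable curation report; classifies sequences into prolamin groups
    from proline+glutamine content, cysteine skeletons, repeat-motif
    grammars and global-alignment identity to master sequences; builds
    average-distance (UPGMA) trees; maps panels of coeliac toxic peptide
    motifs by exact matching and reports unique-motif counts, densities
    and interval-union sequence coverage; and performs in-silico
    chymotryptic digestion to nominate unique marker peptides under
    mass-spectrometry-style length and precursor-mass filters. A
    synthetic prolamin family generator with exact ground truth makes
    every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
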