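Package: ctenomito
Title: Comparative Mitogenomics of Compact AT-Rich Circular Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the comparative analysis of highly reduced, AT-rich
    circular mitochondrial genomes such as those of ctenophores (comb
    jellies). Provides homology-guided annotation of protein genes, rRNAs
    and unidentified reading frames on circular coordinates; detection of
    genetic-code reassignment from conserved alignment columns; circular
    gene-order comparison by breakpoint distances, normalized breakpoint
    distances and synteny blocks; base-composition, codon-usage,
    non-coding and perfect-repeat statistics; iterative read-overlap
    contig elongation with circularization; and a synthetic mitogenome
    generator with a truth ledger so every analysis can be exercised
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
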