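Package: indelmark
Title: Genome-Wide InDel Marker Design and In Silico Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automates the development of genome-wide insertion/deletion
    (InDel) markers that discriminate a cultivated crop group from its wild
    relatives, as practised for rice (Oryza sativa) and the AA-genome wild
    species. From a reference genome and a panel of related assemblies the
    pipeline selects evenly spaced repeat-poor bait windows, extracts
    orthologous regions by unique k-mer anchor chaining, projects banded
    affine-gap alignments into a reference-anchored multiple alignment,
    screens for InDels whose allele-length gap separates cultivars from wild
    species, designs PCR primer pairs in conserved flanks under
    agarose-gel constraints, and predicts band patterns by in-silico PCR.
    Genotyping analytics reproduce marker validation categories,
    polymorphism counts, species-level marker sets, two-band (heterozygosity)
    frequencies, and introgression detection in backcross progeny. A
    synthetic genome panel simulator with full ground truth makes every
    stage testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
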