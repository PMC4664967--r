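Package: slsplice
Title: Spliced-Leader Trans-Splicing Discovery and Annotation for Copepod
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and exploiting spliced-leader (SL)
    trans-splicing in calanoid copepod sequence data. Discovers a degenerate
    SL consensus from the 5' ends of full-length cDNAs, screens transcript
    sets for full or partial SL matches, annotates SL-trimmed mRNAs
    (first-AUG open reading frame, UTR lengths, Kozak context,
    polyadenylation signals and poly(A) tails, homopolymer repeats, codon
    usage, ribosomal-protein completeness), annotates slRNA gene units in
    genomic sequence (exon/intron spans, GU splice donor, Sm-binding site,
    tandem arrays and 5S rDNA clustering), and evaluates slRNA secondary
    structure with a deterministic base-pair-maximization fold. Includes a
    synthetic-data generator with full truth tables so every stage can be
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
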