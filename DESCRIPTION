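Package: tssops
Title: Primary Transcriptome Annotation for Bacteria from 5'-Enriched RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates a bacterial primary transcriptome from strand-specific
    read-start profiles of a 5'-triphosphate-enriched library (Cappable-seq or
    dRNA-seq style) and an unenriched control. Calls transcription start sites
    (TSS) by thresholding a log2 enrichment score on depth-normalized read
    starts, classifies TSS positionally (primary, intragenic, antisense,
    other), discovers sigma-70 style -35/-10 promoter boxes and ribosome
    binding sites with a ZOOPS expectation-maximization motif finder,
    categorizes 5'-UTR lengths including leaderless transcripts, reconstructs
    primary operons from junction-spanning read counts and condition-specific
    sub-operons from internal TSS, and summarizes differential expression with
    M/A statistics and a negative-binomial Wald test. Ships a ground-truthed
    synthetic-study generator (genome, promoters, read-start libraries,
    junction coverage, replicate counts) so the whole pipeline can be
    exercised and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
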