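Package: tagdge
Title: Tag-Based Digital Gene Expression Profiling for Staged Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for NlaIII/MmeI tag-based digital gene expression
    (DGE, SAGE-style) profiling across ordered developmental stages. Builds a
    virtual 21-bp reference tag database (CATG anchor plus 17 bp) from a
    transcriptome FASTA, cleans raw tag libraries (adaptor, ambiguous-base and
    singleton filters), maps clean tags with at most one mismatch and
    classifies them as unambiguous, ambiguous or unknown, quantifies genes as
    tags per million clean tags (TPM) with proportional multi-read
    distribution, tests pairwise differential expression with the
    Audic-Claverie exact test plus Benjamini-Hochberg FDR, partitions calls
    into developmental processes with Venn overlaps, clusters expression
    trajectories by Pearson-distance k-means with figure-of-merit model
    selection, performs sequencing saturation analysis, and validates against
    qRT-PCR delta-delta-Ct ratios. Includes a synthetic-data generator with
    known ground truth for benchmarking the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
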