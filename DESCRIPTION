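Package: chromseq
Title: Single-Chromosome Sequencing Analysis: Scaffold Assignment and
    Misassembly Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of sequencing data from physically isolated (flow-sorted
    or microdissected) chromosomes. Provides primer/adapter trimming for
    whole-genome-amplified reads, SAM/BAM ingestion, coordinate-based PCR
    duplicate removal, mapping-quality and alignment-length filtering, merging
    of overlapping mapped reads into distinct positions, detection of
    position-dense regions by distance clustering with exact binomial
    enrichment tests, assignment of unplaced assembly scaffolds to the sampled
    chromosome, and classification of off-target dense regions as assembly
    discordances versus putative translocations using contig-boundary
    correspondence. Includes a seedable synthetic isolated-chromosome read
    simulator (reference assembly, AGP contig map, ground truth, FASTQ reads
    and truth alignments) so that every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
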