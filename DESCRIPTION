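Package: allelesort
Title: Allele-Specific Tagging and Sorting of Alignments to N-Masked Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns aligned sequencing reads to their allele of origin in
    hybrid (F1) genomes. Builds N-masked or personalised (full-sequence)
    reference genomes for single-hybrid and dual-hybrid crosses by filtering
    strain variant calls from a VCF file, then tags reads aligned to the
    masked genome with their allelic origin (unassignable, genome 1,
    genome 2, or conflicting) by inspecting read bases at masked SNP
    positions via the CIGAR and MD fields, and finally sorts tagged
    single-end, paired-end, bisulfite or Hi-C alignments into
    allele-specific output files. Includes a deterministic simulator that
    generates a toy diploid system (reference, VCF, reads of known allelic
    origin) for validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
SystemRequirements: samtools (only for BAM input/output; plain SAM needs none)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
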