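# allelesort

Allele-specific tagging and sorting of sequencing alignments using
N-masked reference genomes.

## The problem

In a diploid (F1 hybrid) sample, reads overlapping heterozygous SNPs can
be assigned to their allele of origin, enabling allele-specific analysis
of expression (ASE), transcription-factor or histone binding (ASB), DNA
methylation (ASM) and chromatin contacts. Aligning to a plain reference
biases mapping toward the reference allele. The workflow implemented
here removes that bias by **N-masking**: every known SNP position is
replaced by the ambiguity base `N` before alignment, so both alleles of
a read place equally well at the same coordinate; allelic origin is then
recovered after alignment from the read bases over the masked positions.

For each aligned read the tagger computes, from the MD field and CIGAR
alone (no genome needed at this stage):

- the read offsets whose reference base is `N` (masked SNPs),
- their genomic positions (CIGAR walk over `M`/`I`/`D`/`N` operations),
- a verdict per position against the SNP annotation
  (allele 1 / allele 2 / neither),

and appends the tag `XX:Z:UA` (unassignable), `G1`, `G2`, or `CF`
(conflicting: evidence for both genomes in one read). The sorter then
partitions the tagged file, combining mate tags for paired-end data and
mapping Hi-C pairs to the six unordered contact categories `G1-G1`,
`G2-G2`, `G1-UA`, `G2-UA`, `G1-G2`, `UA-UA`. Bisulfite libraries get
strand-aware rules: C/T SNPs are unusable on the forward
(CT-converted) strand and G/A SNPs on the reverse strand, and at usable
C-involving positions both methylation states (C and T) match the C
allele.

The package also builds the masked genomes: single-hybrid (reference ×
strain) and dual-hybrid (strain 1 × strain 2, with the annotation
re-referenced to strain 1 and shared-identical variants excluded), from
a VCF with per-sample genotypes and confidence flags.

It targets genomic DNA alignments (ChIP-seq, ATAC-seq, re-sequencing),
spliced RNA-seq, Bismark-style bisulfite data and HiCUP-style Hi-C
pairs. Aligners must disable soft-clipping and emit MD fields.

## Worked example

Simulate a toy diploid system (reference, strain VCF, N-masked genome,
reads of known allelic origin), then tag and sort:

```r
library(allelesort)

cfg <- sim_config(seed = 1, n_chromosomes = 1, chromosome_length = 20000,
                  snp_density = 0.003, n_reads = 1000)
d   <- simulate_dataset(cfg, "demo")        # ref.fa, strain.vcf, masked.fa,
                                            # reads.sam, truth.tsv
idx <- build_snp_index(d$snps)
print(idx)
#> SNP index: 60 SNPs on 1 chromosome(s)

res <- tag_alignments("demo/reads.sam", idx)
print(res$report)
#> Allele tagging report
#>   reads_seen: 1000
#>   unassignable: 871 (87.10%)
#>   genome1: 64 (6.40%)
#>   genome2: 65 (6.50%)
#>   conflicting: 0 (0.00%)
#>   unmapped_skipped: 0 (0.00%)
#>   cigar_unsupported: 0 (0.00%)
#>   snp_positions_examined: 139
#>   bisulfite_positions_skipped: 0
#>   neither_allele_basecalls: 0

s <- sort_alignments(res$output)
print(s$report)
#> Allele sorting report
#>   reads_seen: 1000
#>   genome1: 64 (6.40%)
#>   genome2: 65 (6.50%)
#>   unassigned: 871 (87.10%)
#>   conflicting: 0 (0.00%)
#>   conflicting_suppressed: 0
```

With uniform read placement most 50 bp reads overlap no SNP (60 SNPs in
20 kb), hence the large unassignable fraction; every read that does
cover a SNP is assigned to its true allele (error-free simulation), and
conflicts are absent. The sorter wrote `reads.allele_flagged.genome1.sam`,
`.genome2.sam` and `.unassigned.sam`; conflicting reads are suppressed
unless `conflicting = TRUE`.

Genome preparation from a VCF:

```r
prepare_single_hybrid("strain.vcf", strain = "CAST_EiJ",
                      reference = "ref.fa", out_dir = "prep")
# -> CAST_EiJ_N-masked.fa, all_SNPs_CAST_EiJ.txt.gz, SNP_filtering_report.txt
```

A thin CLI wraps the same functions:

```sh
exec/allelesort prepare --vcf strain.vcf --reference ref.fa \
    --strain CAST_EiJ -o prep
exec/allelesort split reads.bam --snp-file prep/all_SNPs_CAST_EiJ.txt.gz -o out
```

## Scope

Alignment itself is upstream (Bowtie2/STAR/HISAT2/Bismark/HiCUP all
work against the masked genomes). InDel-based discrimination, CRAM,
methylation extraction and downstream quantitation are out of scope; see
the methods vignette (`vignettes/allele-specific-sorting.Rmd`) for the
model, parameter and design details.
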