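---
title: "Allele-specific read sorting with N-masked genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific read sorting with N-masked genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelesort)
```

## The problem

Sequencing reads from a diploid (F1 hybrid) sample carry information about
which of the two parental alleles they came from, but only at positions
where the two haplotypes differ. Aligning all reads to a single reference
biases the alignment toward the reference allele: reads from the
non-reference haplotype carry mismatches and map less efficiently. The
approach implemented here eliminates that bias by *N-masking*: every known
SNP position in the reference is replaced with the ambiguity base `N`
before alignment, so reads from either allele align equally well to the
same coordinate. After alignment, each read is assigned to an allele by
inspecting the read bases that sit over the masked positions.

The package implements the full workflow:

1. **Genome preparation** — filter strain variant calls from a VCF and
   build the N-masked (and optionally personalised, i.e. full-sequence)
   genome plus a SNP annotation file.
2. **Tagging (stage I)** — for each aligned read, recover the masked
   positions it covers from its MD string, map them to read offsets
   through the CIGAR, compare the read bases to the two annotated
   alleles, and append an `XX:Z:` tag: `UA` (unassignable), `G1`
   (genome 1), `G2` (genome 2) or `CF` (conflicting).
3. **Sorting (stage II)** — partition the tagged file into
   allele-specific outputs, combining mate tags for paired-end and Hi-C
   libraries.

Alignment itself is upstream and out of scope: any aligner that supports
ambiguity bases and emits MD fields (with soft-clipping disabled) can be
used, and bisulfite input is expected to come from a Bismark-style
aligner that records the genome conversion strand.

## Genome preparation

`filter_strain_snps()` retains a VCF call only if all of the following
hold: the strain's genotype is homozygous for a non-reference allele; the
per-sample confidence flag (FORMAT field `FI` by default, matching the
shape of large strain-variation call sets) passes; both REF and the
genotype-selected ALT are single bases; and the reference genome actually
carries the REF base at that position. Multi-allelic records are handled
by selecting the ALT allele the genotype indexes; if that allele is not a
single base the call is skipped as not-a-SNP, which keeps the annotation
SNP-only and the coordinate system unshifted (InDel incorporation is
deliberately out of scope for the same reason).

Three policies were genuinely open and are fixed as follows:

* **Absent confidence field.** Rejected by default — the conservative
  reading of "high confidence" — with `accept_unflagged = TRUE` to retain
  such calls for VCFs that carry no per-sample flag.
* **Counter precedence.** A call failing several checks is counted once:
  missing genotype, then low confidence, then heterozygous, then
  homozygous-reference, then not-a-SNP, then genome/REF mismatch. The
  summary obeys the conservation law
  `total_seen = retained + sum(skipped_*)` on every run, and report
  rendering re-checks it.
* **Genome/REF disagreement.** A warning plus substitution, recorded in
  the mask report's disagreement list, rather than a fatal error:
  assembly-patch drift between a genome build and a variant call set is
  common, and a loud record is more useful than a crash. Chromosome names
  are matched exactly — no `chr`-prefix fuzzing — because a silent
  mismatch is worse than a loud failure.

For a **dual hybrid** (neither allele is the reference strain) the
annotation is re-referenced: strain 1's full-sequence genome becomes the
new reference, and each position becomes `(strain1 base, strain2 base)`.
Positions where both strains carry the same ALT are no longer
polymorphic between the two hybrids and are excluded (counted as
`skipped_shared_identical`). The builder asserts that every output
record's allele 1 equals the strain-1 genome base, which catches
orientation bugs structurally. Exclusion is applied after per-strain
confidence filtering, matching the order of the preparation steps.

## Tagging

The tagger never needs the genome: the MD field encodes the reference
bases at every mismatch, so a masked position is visible as a reference
`N` in MD. The per-read pipeline is:

1. `masked_positions_from_md()` walks the MD string (match run-lengths,
   substituted reference bases, `^`-prefixed deletions) alongside the
   CIGAR-derived list of aligned bases. MD omits insertions; because the
   walk advances over *aligned* columns only, insertion adjustment falls
   out automatically.
2. `cigar_map()` supplies the genomic position of each aligned base
   (`M` consumes read and genome, `I` read only, `D`/`N` genome only; `=`
   and `X` are treated as `M` since they are coordinate-equivalent).
   Soft/hard clips and padding are unsupported — clipped alignments can
   place reads in poorly annotated regions and break the end-to-end match
   assumption — so such reads are rejected and counted.
3. `observe()` looks up each masked genomic position in the SNP index
   (masked-but-unknown positions are silently ignored) and scores the
   read base: allele 1, allele 2, or `neither` (including read-base `N`).
4. `classify()` reduces the verdicts: evidence for both alleles → `CF`;
   one allele → `G1`/`G2`; otherwise `UA`.

`neither` verdicts are counted but ignored for classification: a
sequencing error at a SNP should not manufacture a conflict, and `CF` is
reserved for genuine evidence of both genomes in one read. Reads rejected
for unsupported CIGARs, MD/CIGAR inconsistencies, or unmapped status are
still emitted (as `XX:Z:UA`) in dedicated report buckets, so the tagged
file is a same-order superset of the input and downstream pairing never
breaks. Order preservation is asserted by test.

**Bisulfite rules.** After conversion, C→T differences on the forward
(CT-converted) strand are indistinguishable from methylation state, as
are G→A differences on the reverse strand, so such SNPs are unusable on
that strand (counted as `bisulfite_positions_skipped`) while remaining
fully informative on the opposite strand. At usable SNPs involving a C
on the forward strand, both methylation states match: read base C *or* T
matches an allele-C; symmetrically G/A on the reverse strand. If the
dual-state rule makes one read base match both alleles, the observation
carries no information and is scored `neither`. The strand comes from the
aligner's genome-conversion tag (`XG:Z:CT`/`GA`); bisulfite mode without
that tag is fatal rather than guessed from the reverse flag, because a
wrong strand silently flips the exclusion rule. Bisulfite mode switches
on automatically when the first records carry conversion tags. Masked
positions receive no methylation call upstream (they appear as `.` in the
call string), and the tagger reads only the sequence and MD fields, so
SNP positions are never interpreted as methylation evidence.

## Sorting

Single-end reads are routed by their own tag. For paired-end libraries
mate tags are combined: a `CF` mate or opposing `G1`/`G2` evidence makes
the pair conflicting; otherwise any single-genome evidence assigns the
pair; two `UA` mates stay unassigned. This table maximises assignable
pairs while never mixing alleles, and is consistent with the Hi-C
grouping where `G1-UA` counts as genome-1 evidence. Conflicting
reads/pairs are suppressed by default and materialised with
`conflicting = TRUE`; sorting can be re-run stand-alone on a tagged file
to change options without re-tagging, and is deterministic (asserted by
an idempotence test).

Mates are paired by name adjacency; if a read name recurs
non-adjacently the file is first name-sorted with a stable (radix) sort,
so equal-named records keep their relative order. Mate-less records are
singletons, routed by their own tag, optionally to separate `.st` files.

Hi-C input (HiCUP-shaped, strictly name-adjacent pairs — violation is
fatal) maps to the six unordered contact categories `G1-G1`, `G2-G2`,
`G1-UA`, `G2-UA`, `G1-G2`, `UA-UA`; `(G2, G1)` normalises to `G1-G2`
because proximity contacts have no directionality. Pairs containing a
`CF` mate are suppressed by default.

## The simulator

`simulate_dataset()` generates the toy diploid system the tests and the
acceptance script run on: a uniform-random reference, a strain VCF whose
retainable calls are known by construction (plus deliberate negatives —
heterozygous, fail-flag, indel-ALT and, for two strains, shared-identical
records), and reads drawn alternately from the two full-sequence allele
genomes, written as SAM against the N-masked reference with POS, CIGAR
and MD computed exactly as an aligner would report them. Optional
features: per-read 1–3 bp indels, one 50–500 bp splice gap, per-base
substitution errors, bisulfite conversion with `XG` tags (conversion is
applied per cytosine with probability `1 - methylation_rate`; no CpG
context model), and paired/Hi-C name-adjacent mates. One sub-seed per
file type keeps outputs byte-identical under a fixed seed even when only
part of the generator runs.

The default configuration — 2 chromosomes × 100 kb, SNP density
0.0025/bp (≈500 SNPs), 10,000 error-free 50 bp reads, 5,000 per allele —
is the package's reference validation condition, small enough to run in
seconds on one CPU yet large enough to exercise every SNP-overlap
configuration. What the simulator does *not* emulate: realistic base
quality and error profiles, PCR duplicates, CpG-context methylation,
repeat-induced mismapping, or real Hi-C fragment/ligation structure.
Passing tests therefore demonstrate the correctness of the assignment
logic given correct alignments, not robustness to alignment artefacts in
real libraries.

## Validation

The test suite checks, among others:

* **Oracle equivalence.** Over 1,000 randomised alignments containing
  I/D/N operations and sequencing errors, MD-based masked-position
  discovery agrees exactly with a brute-force padded-alignment
  reconstruction that compares the read to the masked genome base by
  base (an independent code path that never reads MD). The simulator's
  MD strings are validated the same way against an independent
  column-wise MD builder.
* **Perfect recovery.** On the reference condition, 100% of allele-1
  reads tag `G1`, 100% of allele-2 reads tag `G2`, zero conflicts; reads
  placed to cover no SNP are 100% `UA`.
* **Conservation.** Tag-report categories sum to the input read count;
  with all outputs enabled the sort partitions the input exactly
  (read-name multiset equality).
* **Exhaustive tables.** All 16 ordered tag pairs for paired-end
  combination and Hi-C categorisation (with symmetry), and all 12
  ordered allele pairs × 2 strands for the bisulfite usability rule.

`scripts/acceptance.R` recomputes these quantities from scratch on
freshly simulated data and writes them as JSON.

## Numerical and degenerate-input choices

* Coordinates are 1-based and fully closed throughout (SAM/VCF native);
  no half-open interval is ever serialised.
* The SNP annotation file is a fixed 5-column gzip-compressed layout
  (ID, chromosome, position, strand placeholder `1`, `allele1/allele2`)
  so preparation and tagging interoperate bit-exactly; readers
  auto-detect compression.
* Duplicate SNPs at one position are fatal at index build (annotation
  corruption), as are identical alleles in a SNP record.
* MD grammar accepted: `[0-9]+(([A-Z]|\^[A-Z]+)[0-9]+)*`, with leading
  and trailing zero-length match runs tolerated; an MD string whose
  aligned-base count disagrees with the CIGAR rejects that read only.
* Empty inputs degrade gracefully: zero records produce empty outputs
  and zeroed reports; zero retained SNPs in genome preparation is fatal
  with the filter summary printed.
* The SNP index and genome are held in memory; at mouse scale this is a
  few GB, in line with the tools this workflow interoperates with.

## Limitations

InDel-based allele discrimination, CRAM, indexed BAM access, methylation
extraction and downstream quantitation are out of scope. BAM input/output
shells out to samtools (plain SAM needs no external tool). The
paired-end tag-combination table beyond the documented disagreement rule
is this package's own design choice, stated above.
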