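# Stage I: CIGAR walking, MD parsing, base observation and classification.

test_that("cigar_map handles M/D/I/N and rejects clipped reads", {
  # simple match
  m <- cigar_map(make_view(10, "5M", "AAAAA"))
  expect_equal(m$offsets, 0:4)
  expect_equal(m$gpos, 10:14)

  # deletion: genome advances, read does not (oracle-derived)
  m <- cigar_map(make_view(10, "2M2D3M", "AAAAA"))
  expect_equal(m$offsets, c(0, 1, 2, 3, 4))
  expect_equal(m$gpos, c(10, 11, 14, 15, 16))

  # splice + insertion (oracle-derived): insertions 4,5 unaligned
  m <- cigar_map(make_view(10, "2M3N2M2I1M", "AAAAAAA"))
  expect_equal(m$offsets, c(0, 1, 2, 3, 6))
  expect_equal(m$gpos, c(10, 11, 15, 16, 17))

  # = and X are M-equivalents
  m <- cigar_map(make_view(10, "2=1X2=", "AAAAA"))
  expect_equal(m$offsets, 0:4)
  expect_equal(m$gpos, 10:14)

  # soft-clipping and other unsupported operations
  expect_null(cigar_map(make_view(10, "3S5M", "AAAAAAAA")))
  expect_null(cigar_map(make_view(10, "5M2H", "AAAAA")))
})

test_that("cigar_map agrees with the padded-alignment oracle", {
  genome <- c(chr1 = strrep("ACGTN", 40))
  cases <- c("10M", "4M2D6M", "3M2I5M", "2M100N8M", "1M1I1M1D1M2N2M",
             "5M3D2M4I3M")
  for (cig in cases) {
    qlen <- sum(as.integer(
      regmatches(cig, gregexpr("[0-9]+(?=[MI])", cig, perl = TRUE))[[1]]))
    seq <- strrep("A", qlen)
    got <- cigar_map(make_view(7, cig, seq))
    want <- oracle_cigar_map(genome, "chr1", 7, cig, seq)
    expect_equal(got$offsets, want$offsets, info = cig)
    expect_equal(got$gpos, want$gpos, info = cig)
  }
})

test_that("masked_positions_from_md finds reference Ns, adjusting for indels", {
  v <- make_view(10, "10M", "ACGTACGTAC", md = "4N5")
  expect_equal(masked_positions_from_md(v), 4L)

  # insertion before a ref-N shifts later MD offsets by the insert length
  v <- make_view(10, "4M2I4M", "ACGTTTACGT", md = "3N4")
  expect_equal(masked_positions_from_md(v), 3L)
  v <- make_view(10, "4M2I4M", "ACGTTTACGT", md = "5N2")
  expect_equal(masked_positions_from_md(v), 7L)   # 5 aligned + 2 inserted

  # no mismatches: no masked positions
  v <- make_view(10, "10M", "ACGTACGTAC", md = "10")
  expect_equal(masked_positions_from_md(v), integer(0))

  # deletions consume MD ^-blocks, not read offsets
  v <- make_view(10, "4M2D4M", "ACGTACGT", md = "4^CA2N1")
  expect_equal(masked_positions_from_md(v), 6L)

  # leading/trailing zero match-lengths tolerated
  v <- make_view(10, "4M", "ACGT", md = "0N3")
  expect_equal(masked_positions_from_md(v), 0L)

  # MD inconsistent with CIGAR: per-read rejection (NULL)
  v <- make_view(10, "4M", "ACGT", md = "2N5")
  expect_null(masked_positions_from_md(v))

  # absent MD is fatal with guidance
  expect_error(masked_positions_from_md(make_view(10, "4M", "ACGT")),
               "MD")
})

test_that("MD-based masked-position discovery equals the brute-force oracle", {
  # randomised alignments over an N-masked genome, with I/D/N operations
  cfg <- sim_config(seed = 101, n_chromosomes = 2, chromosome_length = 5000,
                    snp_density = 0.01, n_reads = 1000, indel_rate = 0.4,
                    splice_rate = 0.4, error_rate = 0.02,
                    snp_coverage = "force")
  ref <- simulate_reference(cfg)
  snps <- simulate_vcf(ref, cfg)$truth[[1]]
  sim <- simulate_reads(ref, snps, cfg)
  recs <- sam_read(write_sam(sim$sam[-seq_len(3)],
                             withr::local_tempfile(fileext = ".sam")))
  parsed <- strsplit(recs$records, "\t", fixed = TRUE)
  discrepancies <- 0L
  for (p in parsed) {
    md <- sub("^MD:Z:", "", grep("^MD:Z:", p, value = TRUE))
    v <- make_view(as.integer(p[[4]]), p[[6]], p[[10]], md = md,
                   chrom = p[[3]])
    got <- masked_positions_from_md(v)
    want <- oracle_masked_offsets(sim$masked, p[[3]], as.integer(p[[4]]),
                                  p[[6]], p[[10]])
    if (!identical(sort(got), sort(as.integer(want)))) {
      discrepancies <- discrepancies + 1L
    }
  }
  expect_equal(discrepancies, 0L)
})

test_that("observe assigns verdicts against the SNP index", {
  idx <- build_snp_index(data.frame(
    id = c("s1", "s2"), chrom = "chr1", pos = c(14L, 17L),
    allele1 = c("C", "G"), allele2 = c("T", "A")))
  # read base T at SNP(C/T) -> allele2
  v <- make_view(10, "10M", "AAAATAAAAA", md = "4N5")
  expect_equal(observe(v, idx)$verdict, "allele2")
  # read base C -> allele1
  v <- make_view(10, "10M", "AAAACAAAAA", md = "4N5")
  expect_equal(observe(v, idx)$verdict, "allele1")
  # read base G at SNP(C/T) -> neither
  v <- make_view(10, "10M", "AAAAGAAAAA", md = "4N5")
  expect_equal(observe(v, idx)$verdict, "neither")
  # read base N -> neither
  v <- make_view(10, "10M", "AAAANAAAAA", md = "4N5")
  expect_equal(observe(v, idx)$verdict, "neither")
  # masked position absent from the index: no observation emitted
  v <- make_view(10, "10M", "AAAAAATAAA", md = "6N3")
  expect_equal(nrow(observe(v, idx)), 0L)
  # two SNPs, one per allele -> one observation each
  v <- make_view(10, "10M", "AAAACAAAAA", md = "4N2N2")
  obs <- observe(v, idx)
  expect_equal(obs$verdict, c("allele1", "allele2"))
})

test_that("duplicate SNP positions are fatal on index build", {
  expect_error(build_snp_index(data.frame(
    id = c("a", "b"), chrom = "chr1", pos = c(5L, 5L),
    allele1 = c("C", "C"), allele2 = c("T", "G"))), "duplicate")
})

test_that("classify follows the allele-evidence rule", {
  expect_equal(classify(character(0)), "UA")
  expect_equal(classify(c("allele1", "allele1")), "G1")
  expect_equal(classify(c("allele2")), "G2")
  expect_equal(classify(c("allele1", "allele2")), "CF")
  expect_equal(classify(c("neither")), "UA")
  expect_equal(classify(c("skipped_bisulfite")), "UA")

  # cross-check against brute-force enumeration of verdict multisets
  verdicts <- c("allele1", "allele2", "neither", "skipped_bisulfite")
  brute <- function(v) {
    has1 <- "allele1" %in% v; has2 <- "allele2" %in% v
    if (has1 && has2) "CF" else if (has1) "G1" else if (has2) "G2" else "UA"
  }
  for (n in 0:3) {
    combos <- if (n == 0) list(character(0)) else
      asplit(as.matrix(expand.grid(rep(list(verdicts), n),
                                   stringsAsFactors = FALSE)), 1)
    for (v in combos) {
      expect_equal(classify(as.character(v)), brute(as.character(v)))
    }
  }
})

test_that("tag_alignments tags a known-truth fixture and preserves order", {
  idx <- build_snp_index(data.frame(
    id = c("s1", "s2"), chrom = "chr1", pos = c(14L, 30L),
    allele1 = c("C", "G"), allele2 = c("T", "A")))
  # 6 reads: 2 allele1, 2 allele2, 1 no SNP, 1 conflicting
  recs <- c(
    sam_record("r3", 0, "chr1", 10, "10M", "AAAACAAAAA", md = "4N5"),
    sam_record("r1", 0, "chr1", 10, "10M", "AAAACAAAAA", md = "4N5"),
    sam_record("r5", 0, "chr1", 10, "10M", "AAAATAAAAA", md = "4N5"),
    sam_record("r2", 0, "chr1", 26, "10M", "AAAAAAAAAA", md = "4N5"),
    sam_record("r4", 0, "chr1", 50, "10M", "AAAAAAAAAA", md = "10"),
    sam_record("r6", 0, "chr1", 12, "20M", "AACAAAAAAAAAAAAAAAAA",
               md = "2N15N1"))
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(recs, f)
  res <- tag_alignments(f, idx, report_path = NULL)
  expect_equal(res$report$genome1, 2L)
  expect_equal(res$report$genome2, 2L)
  expect_equal(res$report$unassignable, 1L)
  expect_equal(res$report$conflicting, 1L)
  # order preserved
  expect_equal(read_names_of(res$output),
               c("r3", "r1", "r5", "r2", "r4", "r6"))
  tags <- sapply(strsplit(sam_read(res$output)$records, "\tXX:Z:"), `[[`, 2)
  expect_equal(tags, c("G1", "G1", "G2", "G2", "UA", "CF"))
})

test_that("unmapped and clipped reads are emitted UA and counted separately", {
  idx <- build_snp_index(data.frame(id = "s", chrom = "chr1", pos = 14L,
                                    allele1 = "C", allele2 = "T"))
  recs <- c(
    sam_record("u1", 4, "*", 0, "*", "ACGT"),
    sam_record("c1", 0, "chr1", 10, "2S8M", "AAAAACAAAA", md = "4N3"),
    sam_record("ok", 0, "chr1", 10, "10M", "AAAACAAAAA", md = "4N5"))
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(recs, f)
  res <- tag_alignments(f, idx, report_path = NULL)
  r <- res$report
  expect_equal(r$unmapped_skipped, 1L)
  expect_equal(r$cigar_unsupported, 1L)
  expect_equal(r$genome1, 1L)
  expect_equal(r$reads_seen, 3L)
  # conservation: categories sum to input count
  expect_equal(r$unassignable + r$genome1 + r$genome2 + r$conflicting +
                 r$unmapped_skipped + r$cigar_unsupported, r$reads_seen)
  # all reads present in output, clipped/unmapped as UA
  recs_out <- sam_read(res$output)$records
  expect_equal(length(recs_out), 3L)
  expect_match(recs_out[1], "XX:Z:UA")
  expect_match(recs_out[2], "XX:Z:UA")
})

test_that("perfect recovery: error-free reads tag to their true allele", {
  cfg <- sim_config(seed = 5, n_chromosomes = 2, chromosome_length = 10000,
                    snp_density = 0.005, n_reads = 400,
                    snp_coverage = "force")
  ref <- simulate_reference(cfg)
  snps <- simulate_vcf(ref, cfg)$truth[[1]]
  sim <- simulate_reads(ref, snps, cfg)
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(sim$sam, f)
  res <- tag_alignments(f, build_snp_index(snps), report_path = NULL)
  tags <- sapply(strsplit(sam_read(res$output)$records, "\tXX:Z:"), `[[`, 2)
  truth <- sim$truth
  expect_true(all(tags[truth$allele == 1] == "G1"))
  expect_true(all(tags[truth$allele == 2] == "G2"))
  expect_equal(res$report$conflicting, 0L)
})

test_that("bisulfite auto-detection engages on conversion-tagged input", {
  idx <- build_snp_index(data.frame(id = "s", chrom = "chr1", pos = 14L,
                                    allele1 = "C", allele2 = "A"))
  recs <- sam_record("b1", 0, "chr1", 10, "10M", "AAAATAAAAA", md = "4N5",
                     extra = "XG:Z:CT")
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(recs, f)
  expect_message(res <- tag_alignments(f, idx, report_path = NULL),
                 "bisulfite mode enabled")
  # read T matches allele C under the dual-state rule -> G1
  expect_match(sam_read(res$output)$records, "XX:Z:G1")
})
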