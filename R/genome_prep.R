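# Strain SNP filtering and construction of N-masked / full-sequence genomes
# for single-hybrid and dual-hybrid crosses.

new_filter_summary <- function(counters) {
  stopifnot(is.list(counters), "total_seen" %in% names(counters),
            "retained" %in% names(counters))
  structure(counters, class = "filter_summary")
}

validate_filter_summary <- function(x) {
  skipped <- unlist(x[startsWith(names(x), "skipped_")])
  if (x$total_seen != x$retained + sum(skipped)) {
    stop("filter summary violates conservation: total_seen != retained + ",
         "sum(skipped_*)")
  }
  invisible(x)
}

#' @export
print.filter_summary <- function(x, ...) {
  cat("SNP filtering summary\n")
  for (k in names(x)) cat(sprintf("  %s: %d\n", k, x[[k]]))
  invisible(x)
}

#' Filter strain SNPs from parsed VCF calls
#'
#' Retains a call only if the strain's genotype is homozygous for a
#' non-reference allele, its per-sample confidence flag passes, both REF
#' and the genotype-selected ALT are single bases in `{A,C,G,T}`, and the
#' genome base at the call position equals REF. Retained calls become SNP
#' records with `allele1 = REF base` and `allele2 = strain ALT base`.
#'
#' Calls failing several checks are counted once, in this precedence:
#' missing genotype, low confidence, heterozygous, homozygous-reference,
#' not a SNP, genome/REF mismatch (which also covers chromosomes absent
#' from the genome, with a warning).
#'
#' @param calls Data frame from [parse_vcf()].
#' @param strain Sample name whose genotype is filtered.
#' @param genome Genome map from [read_fasta()].
#' @param accept_unflagged Retain calls whose confidence field is absent
#'   (default `FALSE`: treated as not high-confidence).
#' @return A list with `snps` (SNP data frame) and `summary`
#'   (a `filter_summary`).
#' @export
filter_strain_snps <- function(calls, strain, genome,
                               accept_unflagged = FALSE) {
  gt_col <- paste0("gt_", strain)
  fi_col <- paste0("fi_", strain)
  if (!gt_col %in% names(calls)) {
    stop("strain '", strain, "' not present in parsed calls")
  }
  n <- nrow(calls)
  cnt <- list(total_seen = n, retained = 0L, skipped_low_confidence = 0L,
              skipped_heterozygous = 0L, skipped_homozygous_ref = 0L,
              skipped_not_snp = 0L, skipped_ref_mismatch = 0L,
              skipped_missing_genotype = 0L)
  keep_id <- character(0); keep_chrom <- character(0)
  keep_pos <- integer(0); keep_a1 <- character(0); keep_a2 <- character(0)
  warned_chroms <- character(0)
  if (n) {
    gts <- strsplit(calls[[gt_col]], "[/|]")
    alts <- strsplit(calls$alt, ",", fixed = TRUE)
    for (i in seq_len(n)) {
      gt <- gts[[i]]
      if (is.na(calls[[gt_col]][i]) || length(gt) != 2L ||
          any(gt == ".") || anyNA(suppressWarnings(as.integer(gt)))) {
        cnt$skipped_missing_genotype <- cnt$skipped_missing_genotype + 1L
        next
      }
      fi <- calls[[fi_col]][i]
      if (fi == "fail" || (fi == "absent" && !accept_unflagged)) {
        cnt$skipped_low_confidence <- cnt$skipped_low_confidence + 1L
        next
      }
      g <- as.integer(gt)
      if (g[1L] != g[2L]) {
        cnt$skipped_heterozygous <- cnt$skipped_heterozygous + 1L
        next
      }
      if (g[1L] == 0L) {
        cnt$skipped_homozygous_ref <- cnt$skipped_homozygous_ref + 1L
        next
      }
      ref <- calls$ref[i]
      alt_list <- alts[[i]]
      if (g[1L] > length(alt_list)) {
        cnt$skipped_missing_genotype <- cnt$skipped_missing_genotype + 1L
        next
      }
      alt <- alt_list[g[1L]]
      if (!ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T")) {
        cnt$skipped_not_snp <- cnt$skipped_not_snp + 1L
        next
      }
      chrom <- calls$chrom[i]
      pos <- calls$pos[i]
      if (!chrom %in% names(genome)) {
        if (!chrom %in% warned_chroms) {
          warning("VCF chromosome '", chrom, "' absent from genome; ",
                  "its calls are skipped")
          warned_chroms <- c(warned_chroms, chrom)
        }
        cnt$skipped_ref_mismatch <- cnt$skipped_ref_mismatch + 1L
        next
      }
      if (pos > nchar(genome[[chrom]]) ||
          substr(genome[[chrom]], pos, pos) != ref) {
        cnt$skipped_ref_mismatch <- cnt$skipped_ref_mismatch + 1L
        next
      }
      cnt$retained <- cnt$retained + 1L
      keep_id <- c(keep_id, calls$id[i])
      keep_chrom <- c(keep_chrom, chrom)
      keep_pos <- c(keep_pos, pos)
      keep_a1 <- c(keep_a1, ref)
      keep_a2 <- c(keep_a2, alt)
    }
  }
  snps <- data.frame(id = keep_id, chrom = keep_chrom, pos = keep_pos,
                     allele1 = keep_a1, allele2 = keep_a2,
                     stringsAsFactors = FALSE)
  summary <- validate_filter_summary(new_filter_summary(cnt))
  list(snps = snps, summary = summary)
}

#' Substitute SNP positions in a genome
#'
#' In `n_mask` mode every SNP position is replaced by `N`; in
#' `full_sequence` mode it is replaced by the base of the requested allele.
#' Chromosome lengths never change. Positions whose current genome base
#' matches neither allele are substituted anyway but recorded in the
#' report's disagreement list.
#'
#' @param genome Genome map.
#' @param snps SNP data frame.
#' @param mode `"n_mask"` (default) or `"full_sequence"`.
#' @param which_allele 1 or 2; the allele written in `full_sequence` mode.
#' @return A list with `genome` (edited map) and `report`
#'   (a `mask_report`: per-chromosome counts, total, disagreements).
#' @export
apply_mask <- function(genome, snps, mode = c("n_mask", "full_sequence"),
                       which_allele = 2L) {
  mode <- match.arg(mode)
  snps <- validate_snps(snps)
  stopifnot(which_allele %in% c(1L, 2L))
  per_chrom <- integer(0)
  disagreements <- data.frame(chrom = character(0), pos = integer(0),
                              stringsAsFactors = FALSE)
  if (nrow(snps)) {
    bad_chrom <- !snps$chrom %in% names(genome)
    if (any(bad_chrom)) {
      stop("SNP chromosome absent from genome: ",
           snps$chrom[bad_chrom][1L])
    }
    for (chrom in unique(snps$chrom)) {
      sel <- snps[snps$chrom == chrom, ]
      raw <- charToRaw(genome[[chrom]])
      if (any(sel$pos > length(raw))) {
        stop("SNP position beyond end of chromosome ", chrom, ": ",
             max(sel$pos))
      }
      cur <- rawToChar(raw[sel$pos], multiple = TRUE)
      off <- cur != sel$allele1 & cur != sel$allele2
      if (any(off)) {
        disagreements <- rbind(disagreements,
                               data.frame(chrom = chrom, pos = sel$pos[off],
                                          stringsAsFactors = FALSE))
      }
      repl <- if (mode == "n_mask") rep("N", nrow(sel)) else
        if (which_allele == 1L) sel$allele1 else sel$allele2
      raw[sel$pos] <- charToRaw(paste0(repl, collapse = ""))
      genome[[chrom]] <- rawToChar(raw)
      per_chrom[chrom] <- nrow(sel)
    }
  }
  report <- structure(
    list(per_chromosome = per_chrom, total = sum(per_chrom),
         disagreements = disagreements),
    class = "mask_report"
  )
  list(genome = genome, report = report)
}

#' @export
print.mask_report <- function(x, ...) {
  cat("Masking report: ", x$total, " positions substituted\n", sep = "")
  for (chrom in names(x$per_chromosome)) {
    cat(sprintf("  %s: %d\n", chrom, x$per_chromosome[[chrom]]))
  }
  if (nrow(x$disagreements)) {
    cat("  genome/annotation base disagreements:", nrow(x$disagreements), "\n")
  }
  invisible(x)
}

#' Build the dual-hybrid SNP annotation
#'
#' Re-references two strains' SNP sets (both called against the common
#' reference) so that allele 1 is strain 1 and allele 2 is strain 2:
#' positions variant only in strain 1 become `(strain1 alt, reference)`;
#' positions variant only in strain 2 become `(reference, strain2 alt)`;
#' positions variant in both with different ALTs become
#' `(strain1 alt, strain2 alt)`; positions where both strains carry the
#' same ALT are no longer polymorphic between the hybrids and are excluded
#' (counted under `skipped_shared_identical`).
#'
#' @param snps1,snps2 SNP data frames for strain 1 and strain 2, both with
#'   `allele1` = reference base, `allele2` = strain ALT.
#' @param genome1 Full-sequence strain-1 genome (from [apply_mask()] in
#'   `full_sequence` mode); every output record's `allele1` must equal its
#'   base here, which is asserted.
#' @return A list with `snps` (the dual annotation) and `summary`.
#' @export
build_dual_hybrid_annotation <- function(snps1, snps2, genome1) {
  snps1 <- validate_snps(snps1)
  snps2 <- validate_snps(snps2)
  key1 <- paste(snps1$chrom, snps1$pos)
  key2 <- paste(snps2$chrom, snps2$pos)
  if (anyDuplicated(key1)) stop("duplicate positions in strain-1 SNPs")
  if (anyDuplicated(key2)) stop("duplicate positions in strain-2 SNPs")
  in2 <- match(key1, key2)
  shared <- !is.na(in2)
  same_alt <- shared & snps1$allele2 == snps2$allele2[in2]

  only1 <- snps1[!shared, , drop = FALSE]
  rec1 <- data.frame(id = only1$id, chrom = only1$chrom, pos = only1$pos,
                     allele1 = only1$allele2, allele2 = only1$allele1,
                     stringsAsFactors = FALSE)

  only2 <- snps2[!key2 %in% key1, , drop = FALSE]
  rec2 <- data.frame(id = only2$id, chrom = only2$chrom, pos = only2$pos,
                     allele1 = only2$allele1, allele2 = only2$allele2,
                     stringsAsFactors = FALSE)

  both <- shared & !same_alt
  rec12 <- data.frame(id = snps1$id[both], chrom = snps1$chrom[both],
                      pos = snps1$pos[both], allele1 = snps1$allele2[both],
                      allele2 = snps2$allele2[in2[both]],
                      stringsAsFactors = FALSE)

  snps <- rbind(rec1, rec2, rec12)
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL

  if (nrow(snps)) {
    g1_base <- vapply(seq_len(nrow(snps)), function(i) {
      substr(genome1[[snps$chrom[i]]], snps$pos[i], snps$pos[i])
    }, character(1L))
    if (any(g1_base != snps$allele1)) {
      stop("dual-hybrid annotation inconsistent with strain-1 genome at ",
           snps$chrom[g1_base != snps$allele1][1L], ":",
           snps$pos[g1_base != snps$allele1][1L])
    }
  }
  total <- length(union(key1, key2))
  summary <- validate_filter_summary(new_filter_summary(list(
    total_seen = total, retained = nrow(snps),
    skipped_shared_identical = sum(same_alt)
  )))
  list(snps = snps, summary = summary)
}

#' Prepare a single-hybrid genome
#'
#' Filters the VCF for one strain and writes an N-masked (and/or
#' full-sequence) genome in which allele 1 is the reference and allele 2
#' the strain, together with the SNP annotation file and a filtering
#' report.
#'
#' @param vcf Path to the strain VCF.
#' @param strain Strain (sample) name.
#' @param reference Genome map or path to the reference FASTA.
#' @param out_dir Output directory (created if needed).
#' @param n_masking Write the N-masked genome (default `TRUE`).
#' @param full_sequence Also write the personalised full-sequence genome.
#' @param accept_unflagged Passed to [filter_strain_snps()].
#' @param chromosomes Optional chromosome subset.
#' @return A list with `snps`, `summary`, `mask_report` and output `paths`.
#' @export
prepare_single_hybrid <- function(vcf, strain, reference, out_dir,
                                  n_masking = TRUE, full_sequence = FALSE,
                                  accept_unflagged = FALSE,
                                  chromosomes = NULL) {
  genome <- if (is.character(reference) && length(reference) == 1L &&
                file.exists(reference)) read_fasta(reference) else reference
  if (!is.null(chromosomes)) genome <- genome[chromosomes]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  calls <- parse_vcf(vcf, samples = strain)
  filt <- filter_strain_snps(calls, strain, genome,
                             accept_unflagged = accept_unflagged)
  if (nrow(filt$snps) == 0L) {
    print(filt$summary)
    stop("zero SNPs retained for strain ", strain)
  }
  paths <- list(
    snp_file = file.path(out_dir, paste0("all_SNPs_", strain, ".txt.gz")),
    report = file.path(out_dir, "SNP_filtering_report.txt")
  )
  write_snp_file(filt$snps, paths$snp_file)
  mask_report <- NULL
  if (n_masking) {
    masked <- apply_mask(genome, filt$snps, mode = "n_mask")
    paths$n_masked <- file.path(out_dir, paste0(strain, "_N-masked.fa"))
    write_fasta(masked$genome, paths$n_masked)
    mask_report <- masked$report
  }
  if (full_sequence) {
    full <- apply_mask(genome, filt$snps, mode = "full_sequence",
                       which_allele = 2L)
    paths$full_sequence <- file.path(out_dir,
                                     paste0(strain, "_full_sequence.fa"))
    write_fasta(full$genome, paths$full_sequence)
    if (is.null(mask_report)) mask_report <- full$report
  }
  render_report(filt$summary, paths$report)
  list(snps = filt$snps, summary = filt$summary, mask_report = mask_report,
       paths = paths)
}

#' Prepare a dual-hybrid genome
#'
#' Filters the VCF for both strains, builds the strain-1 full-sequence
#' genome, re-references the annotation to strain 1 versus strain 2, and
#' N-masks the strain-1 genome at the re-referenced SNP positions.
#'
#' @inheritParams prepare_single_hybrid
#' @param strain1,strain2 The two strain (sample) names; allele 1 of the
#'   output is `strain1`.
#' @return A list with `snps` (dual annotation), per-strain filter
#'   summaries, the dual `summary`, `mask_report` and output `paths`.
#' @export
prepare_dual_hybrid <- function(vcf, strain1, strain2, reference, out_dir,
                                n_masking = TRUE, full_sequence = FALSE,
                                accept_unflagged = FALSE,
                                chromosomes = NULL) {
  genome <- if (is.character(reference) && length(reference) == 1L &&
                file.exists(reference)) read_fasta(reference) else reference
  if (!is.null(chromosomes)) genome <- genome[chromosomes]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  calls <- parse_vcf(vcf, samples = c(strain1, strain2))
  f1 <- filter_strain_snps(calls, strain1, genome,
                           accept_unflagged = accept_unflagged)
  f2 <- filter_strain_snps(calls, strain2, genome,
                           accept_unflagged = accept_unflagged)
  genome1 <- apply_mask(genome, f1$snps, mode = "full_sequence",
                        which_allele = 2L)$genome
  dual <- build_dual_hybrid_annotation(f1$snps, f2$snps, genome1)
  if (nrow(dual$snps) == 0L) {
    print(dual$summary)
    stop("zero SNPs in dual-hybrid annotation for ", strain1, "/", strain2)
  }
  label <- paste0(strain1, "_", strain2)
  paths <- list(
    snp_file = file.path(out_dir, paste0("all_SNPs_", label, ".txt.gz")),
    report = file.path(out_dir, "SNP_filtering_report.txt")
  )
  write_snp_file(dual$snps, paths$snp_file)
  masked <- apply_mask(genome1, dual$snps, mode = "n_mask")
  mask_report <- masked$report
  if (n_masking) {
    paths$n_masked <- file.path(out_dir, paste0(label, "_N-masked.fa"))
    write_fasta(masked$genome, paths$n_masked)
  }
  if (full_sequence) {
    paths$full_sequence_strain1 <-
      file.path(out_dir, paste0(strain1, "_full_sequence.fa"))
    write_fasta(genome1, paths$full_sequence_strain1)
    genome2 <- apply_mask(genome, f2$snps, mode = "full_sequence",
                          which_allele = 2L)$genome
    paths$full_sequence_strain2 <-
      file.path(out_dir, paste0(strain2, "_full_sequence.fa"))
    write_fasta(genome2, paths$full_sequence_strain2)
  }
  render_report(dual$summary, paths$report)
  list(snps = dual$snps, summary1 = f1$summary, summary2 = f2$summary,
       summary = dual$summary, mask_report = mask_report, paths = paths)
}
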