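# Deterministic synthetic-data generator: a toy diploid system (reference,
# strain VCF, N-masked genome, reads of known allelic origin as SAM
# records) so the whole workflow is testable without external downloads.

#' Simulation configuration
#'
#' Defaults describe the validation conditions used throughout the
#' package: a 2 x 100 kb genome carrying roughly 500 SNPs
#' (density 0.0025/bp), 10,000 error-free 50 bp single-end reads drawn
#' alternately from the two alleles.
#'
#' @param seed Integer seed; the same seed yields byte-identical outputs.
#'   Separate sub-seeds are derived per file type, so e.g. adding read
#'   simulation does not perturb the genome.
#' @param n_chromosomes,chromosome_length Genome shape.
#' @param snp_density Expected SNPs per bp.
#' @param read_length,n_reads Read shape and count.
#' @param error_rate Per-base substitution error probability.
#' @param indel_rate Per-read probability of one 1-3 bp insertion or
#'   deletion.
#' @param splice_rate Per-read probability of one internal 50-500 bp
#'   splice (`N`) gap.
#' @param bisulfite Simulate bisulfite-converted reads (with `XG` tags).
#' @param methylation_rate Probability that a cytosine is methylated (and
#'   therefore protected from conversion).
#' @param paired,hic Emit name-adjacent read pairs (`hic` implies pairs
#'   with independently placed mates).
#' @param snp_coverage `"any"` (uniform placement), `"force"` (every read
#'   overlaps at least one SNP) or `"zero"` (no read span touches a SNP).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 2L,
                       chromosome_length = 100000L, snp_density = 0.0025,
                       read_length = 50L, n_reads = 10000L,
                       error_rate = 0, indel_rate = 0, splice_rate = 0,
                       bisulfite = FALSE, methylation_rate = 0,
                       paired = FALSE, hic = FALSE,
                       snp_coverage = c("any", "force", "zero")) {
  snp_coverage <- match.arg(snp_coverage)
  stopifnot(error_rate >= 0, error_rate <= 1, indel_rate >= 0,
            indel_rate <= 1, splice_rate >= 0, splice_rate <= 1,
            methylation_rate >= 0, methylation_rate <= 1,
            chromosome_length >= read_length)
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 chromosome_length = chromosome_length,
                 snp_density = snp_density, read_length = read_length,
                 n_reads = n_reads, error_rate = error_rate,
                 indel_rate = indel_rate, splice_rate = splice_rate,
                 bisulfite = bisulfite,
                 methylation_rate = methylation_rate, paired = paired,
                 hic = hic, snp_coverage = snp_coverage),
            class = "sim_config")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate a uniform random reference genome
#'
#' @param config A [sim_config()].
#' @return A genome map (named character vector `chr1`, `chr2`, ...).
#' @export
simulate_reference <- function(config) {
  with_seed(config$seed, {
    seqs <- vapply(seq_len(config$n_chromosomes), function(i) {
      paste(sample(BASES, config$chromosome_length, replace = TRUE),
            collapse = "")
    }, character(1L))
    stats::setNames(seqs, paste0("chr", seq_len(config$n_chromosomes)))
  })
}

random_alt <- function(ref) {
  vapply(ref, function(b) sample(setdiff(BASES, b), 1L), character(1L),
         USE.NAMES = FALSE)
}

#' Simulate a strain VCF with known-truth SNPs and deliberate negatives
#'
#' Emits homozygous-alternate pass-flag calls at sampled positions plus
#' deliberate negatives (heterozygous calls, fail-flag calls, indel ALTs
#' and, with two strains, shared-identical variants) so that VCF
#' filtering has known expected outcomes. The truth lists contain only
#' the calls [filter_strain_snps()] should retain for each strain.
#'
#' @param genome Reference genome map.
#' @param config A [sim_config()].
#' @param strains Character vector of one or two strain names.
#' @param path Optional output path for the VCF text (plain, v4.2-shaped).
#' @return A list with `vcf` (character lines), `truth` (named list of
#'   per-strain retainable SNP data frames) and, for two strains,
#'   `shared_identical` (positions both strains share with the same ALT).
#' @export
simulate_vcf <- function(genome, config, strains = "STRAIN1",
                         path = NULL) {
  stopifnot(length(strains) %in% c(1L, 2L))
  with_seed(config$seed + 1L, {
    rows <- list()
    truth <- stats::setNames(rep(list(NULL), length(strains)), strains)
    shared_identical <- data.frame(chrom = character(0), pos = integer(0))
    for (chrom in names(genome)) {
      len <- nchar(genome[[chrom]])
      n_snp <- max(1L, round(config$snp_density * len))
      n_extra <- max(2L, round(0.3 * n_snp))  # negatives
      pos <- sort(sample.int(len, n_snp + n_extra))
      ref <- substring(genome[[chrom]], pos, pos)
      kind <- rep("retain", length(pos))
      kind[sample.int(length(pos), n_extra)] <-
        sample(c("het", "fail", "indel", "homref"), n_extra, replace = TRUE)
      if (length(strains) == 2L) {
        # among retainable sites, allot strain-specific / shared fates
        idx <- which(kind == "retain")
        fate <- sample(c("s1", "s2", "shared_diff", "shared_same"),
                       length(idx), replace = TRUE,
                       prob = c(0.35, 0.35, 0.2, 0.1))
      }
      for (j in seq_along(pos)) {
        alt <- random_alt(ref[j])
        gt <- list()
        if (kind[j] == "retain") {
          if (length(strains) == 1L) {
            gt[[strains[1L]]] <- "1/1:1"
            truth[[1L]] <- rbind(truth[[1L]], data.frame(
              id = sprintf("sim_%s_%d", chrom, pos[j]), chrom = chrom,
              pos = pos[j], allele1 = ref[j], allele2 = alt,
              stringsAsFactors = FALSE))
          } else {
            f <- fate[match(j, idx)]
            if (f == "s1") {
              gt[[strains[1L]]] <- "1/1:1"; gt[[strains[2L]]] <- "0/0:1"
              truth[[1L]] <- rbind(truth[[1L]], data.frame(
                id = sprintf("sim_%s_%d", chrom, pos[j]), chrom = chrom,
                pos = pos[j], allele1 = ref[j], allele2 = alt,
                stringsAsFactors = FALSE))
            } else if (f == "s2") {
              gt[[strains[1L]]] <- "0/0:1"; gt[[strains[2L]]] <- "1/1:1"
              truth[[2L]] <- rbind(truth[[2L]], data.frame(
                id = sprintf("sim_%s_%d", chrom, pos[j]), chrom = chrom,
                pos = pos[j], allele1 = ref[j], allele2 = alt,
                stringsAsFactors = FALSE))
            } else if (f == "shared_diff") {
              alt2 <- sample(setdiff(BASES, c(ref[j], alt)), 1L)
              alt <- paste(alt, alt2, sep = ",")
              gt[[strains[1L]]] <- "1/1:1"; gt[[strains[2L]]] <- "2/2:1"
              truth[[1L]] <- rbind(truth[[1L]], data.frame(
                id = sprintf("sim_%s_%d", chrom, pos[j]), chrom = chrom,
                pos = pos[j], allele1 = ref[j],
                allele2 = sub(",.*", "", alt), stringsAsFactors = FALSE))
              truth[[2L]] <- rbind(truth[[2L]], data.frame(
                id = sprintf("sim_%s_%d", chrom, pos[j]), chrom = chrom,
                pos = pos[j], allele1 = ref[j], allele2 = alt2,
                stringsAsFactors = FALSE))
            } else {            # shared_same: both strains, same ALT
              gt[[strains[1L]]] <- "1/1:1"; gt[[strains[2L]]] <- "1/1:1"
              for (s in 1:2) {
                truth[[s]] <- rbind(truth[[s]], data.frame(
                  id = sprintf("sim_%s_%d", chrom, pos[j]), chrom = chrom,
                  pos = pos[j], allele1 = ref[j], allele2 = alt,
                  stringsAsFactors = FALSE))
              }
              shared_identical <- rbind(shared_identical, data.frame(
                chrom = chrom, pos = pos[j], stringsAsFactors = FALSE))
            }
          }
        } else if (kind[j] == "het") {
          for (s in strains) gt[[s]] <- "0/1:1"
        } else if (kind[j] == "fail") {
          for (s in strains) gt[[s]] <- "1/1:0"
        } else if (kind[j] == "indel") {
          alt <- paste0(ref[j], "A")
          for (s in strains) gt[[s]] <- "1/1:1"
        } else {                # homref
          for (s in strains) gt[[s]] <- "0/0:1"
        }
        rows[[length(rows) + 1L]] <- paste(
          chrom, pos[j], sprintf("sim_%s_%d", chrom, pos[j]), ref[j], alt,
          ".", "PASS", ".", "GT:FI",
          paste(unlist(gt[strains]), collapse = "\t"), sep = "\t")
      }
    }
    header <- c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste0("##FORMAT=<ID=FI,Number=1,Type=Integer,",
             "Description=\"High confidence (1) or low confidence (0)\">"),
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", strains), collapse = "\t")
    )
    vcf <- c(header, unlist(rows))
    if (!is.null(path)) writeLines(vcf, path)
    list(vcf = vcf, truth = truth, shared_identical = shared_identical)
  })
}

# Build the CIGAR run list for one simulated read: M runs with optional
# single indel and/or splice gap. Returns list(op=, len=) where query
# lengths sum to read_length.
sim_read_ops <- function(config) {
  L <- config$read_length
  op <- "M"; len <- L
  if (config$indel_rate > 0 && stats::runif(1L) < config$indel_rate) {
    ilen <- sample(1:3, 1L)
    if (stats::runif(1L) < 0.5) {      # insertion: M a, I ilen, M b
      a <- sample.int(L - ilen - 1L, 1L)
      op <- c("M", "I", "M"); len <- c(a, ilen, L - ilen - a)
    } else {                           # deletion: M a, D ilen, M b
      a <- sample.int(L - 1L, 1L)
      op <- c("M", "D", "M"); len <- c(a, ilen, L - a)
    }
  }
  if (config$splice_rate > 0 && stats::runif(1L) < config$splice_rate) {
    # split one M run with an N gap
    m_idx <- which(op == "M" & len >= 2L)
    k <- m_idx[sample.int(length(m_idx), 1L)]
    a <- sample.int(len[k] - 1L, 1L)
    gap <- sample(50:500, 1L)
    op <- append(op, c("N", "M"), after = k)
    len <- append(len, c(gap, len[k] - a), after = k)
    len[k] <- a
  }
  list(op = op, len = len)
}

# Genomic span (reference bases consumed) of an op list.
ops_ref_span <- function(ops) sum(ops$len[ops$op %in% c("M", "D", "N")])

# MD string of a read against the reference window, given the op list.
# Walks aligned columns (M: compare; D: ^-block; N: skipped).
md_from_alignment <- function(ops, ref_bases_by_run, read_bases_by_run) {
  md <- character(0)
  run <- 0L
  flush_mismatch <- function(refb) {
    md <<- c(md, as.character(run), refb)
    run <<- 0L
  }
  for (k in seq_along(ops$op)) {
    o <- ops$op[k]
    if (o == "M") {
      refs <- ref_bases_by_run[[k]]
      reads <- read_bases_by_run[[k]]
      for (j in seq_along(refs)) {
        if (refs[j] == reads[j]) run <- run + 1L else flush_mismatch(refs[j])
      }
    } else if (o == "D") {
      md <- c(md, as.character(run),
              paste0("^", paste(ref_bases_by_run[[k]], collapse = "")))
      run <- 0L
    }                                   # I and N: absent from MD
  }
  paste0(paste(md, collapse = ""), run)
}

#' Simulate reads of known allelic origin against the N-masked genome
#'
#' Reads are drawn alternately from the allele-1 and allele-2 full
#' sequences and written as SAM records against the N-masked reference:
#' POS/CIGAR/MD are computed against the masked genome, so masked SNP
#' sites appear as reference-`N` mismatches in MD exactly as an aligner
#' would report them. Optional per-read indels and splice gaps, per-base
#' errors, bisulfite conversion (with `XG` conversion-strand tags) and
#' paired/Hi-C name-adjacent mates are supported.
#'
#' @param reference Reference genome map (allele 1 for a single hybrid).
#' @param snps SNP data frame (`allele1` = reference-strain base).
#' @param config A [sim_config()].
#' @param path Optional output path for the SAM text.
#' @return A list with `sam` (character lines), `truth` (data frame:
#'   `name`, `allele`, `snps_covered`, `errors`), and the three derived
#'   genomes `masked`, `genome1`, `genome2`.
#' @export
simulate_reads <- function(reference, snps, config, path = NULL) {
  snps <- validate_snps(snps)
  masked <- apply_mask(reference, snps, mode = "n_mask")$genome
  genome1 <- apply_mask(reference, snps, mode = "full_sequence",
                        which_allele = 1L)$genome
  genome2 <- apply_mask(reference, snps, mode = "full_sequence",
                        which_allele = 2L)$genome
  snp_pos <- split(snps$pos, snps$chrom)
  with_seed(config$seed + 2L, {
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(masked),
                        nchar(masked)))
    n_units <- config$n_reads
    paired <- config$paired || config$hic
    records <- character(0)
    truth <- list()
    emit_one <- function(name, allele, flag, mate_of = NULL) {
      g <- if (allele == 1L) genome1 else genome2
      repeat {
        ops <- sim_read_ops(config)
        span <- ops_ref_span(ops)
        chrom <- sample(names(masked), 1L)
        len <- nchar(masked[[chrom]])
        if (span > len) next
        sp <- snp_pos[[chrom]]
        if (config$snp_coverage == "force" && length(sp)) {
          anchor <- sp[sample.int(length(sp), 1L)]
          lo <- max(1L, anchor - span + 1L)
          hi <- min(anchor, len - span + 1L)
          if (hi < lo) next
          start <- if (hi == lo) lo else sample(lo:hi, 1L)
        } else {
          start <- sample.int(len - span + 1L, 1L)
        }
        # aligned columns per run
        gposs <- list(); r <- start
        for (k in seq_along(ops$op)) {
          o <- ops$op[k]; L <- ops$len[k]
          if (o == "M") { gposs[[k]] <- r + seq_len(L) - 1L; r <- r + L }
          else if (o %in% c("D", "N")) { gposs[[k]] <- r + seq_len(L) - 1L
            r <- r + L }
          else gposs[[k]] <- integer(0)  # I
        }
        m_gpos <- unlist(gposs[ops$op == "M"])
        covered <- if (length(sp)) sum(sp %in% m_gpos) else 0L
        if (config$snp_coverage == "force" && covered == 0L) next
        if (config$snp_coverage == "zero" &&
            length(sp) && any(sp >= start & sp <= start + span - 1L)) next
        # read bases per run (true allele), insertions random
        read_runs <- vector("list", length(ops$op))
        for (k in seq_along(ops$op)) {
          o <- ops$op[k]; L <- ops$len[k]
          read_runs[[k]] <- if (o == "M") {
            strsplit(substr(g[[chrom]], gposs[[k]][1L],
                            gposs[[k]][L]), "")[[1]]
          } else if (o == "I") {
            sample(BASES, L, replace = TRUE)
          } else character(0)
        }
        # bisulfite conversion on the read, before errors
        xg <- NULL
        if (config$bisulfite) {
          strand <- if (bitwAnd(flag, 16L) > 0L) "GA" else "CT"
          xg <- strand
          for (k in which(ops$op %in% c("M", "I"))) {
            b <- read_runs[[k]]
            from <- if (strand == "CT") "C" else "G"
            to <- if (strand == "CT") "T" else "A"
            conv <- b == from &
              stats::runif(length(b)) >= config$methylation_rate
            b[conv] <- to
            read_runs[[k]] <- b
          }
        }
        n_err <- 0L
        if (config$error_rate > 0) {
          for (k in which(ops$op %in% c("M", "I"))) {
            b <- read_runs[[k]]
            err <- stats::runif(length(b)) < config$error_rate
            if (any(err)) {
              b[err] <- vapply(b[err], function(x)
                sample(setdiff(BASES, x), 1L), character(1L))
              n_err <- n_err + sum(err)
              read_runs[[k]] <- b
            }
          }
        }
        ref_runs <- lapply(seq_along(ops$op), function(k) {
          if (ops$op[k] %in% c("M", "D")) {
            strsplit(substr(masked[[chrom]], gposs[[k]][1L],
                            gposs[[k]][length(gposs[[k]])]), "")[[1]]
          } else character(0)
        })
        md <- md_from_alignment(ops, ref_runs, read_runs)
        seq <- paste(unlist(read_runs[ops$op %in% c("M", "I")]),
                     collapse = "")
        cigar <- paste0(ops$len, ops$op, collapse = "")
        qual <- strrep("I", nchar(seq))
        aux <- if (!is.null(xg)) paste0("\tXG:Z:", xg) else ""
        rec <- sprintf("%s\t%d\t%s\t%d\t42\t%s\t%s\t%d\t0\t%s\t%s\tMD:Z:%s%s",
                       name, flag, chrom, start, cigar,
                       if (paired) "=" else "*",
                       if (paired && !is.null(mate_of)) mate_of else 0L,
                       seq, qual, md, aux)
        return(list(rec = rec, covered = covered, errors = n_err))
      }
    }
    for (u in seq_len(n_units)) {
      allele <- if (u %% 2L == 1L) 1L else 2L
      name <- sprintf("read_%06d_a%d", u, allele)
      if (paired) {
        flag1 <- 1L + 64L
        flag2 <- 1L + 128L + if (config$bisulfite) 16L else 0L
        r1 <- emit_one(name, allele, flag1)
        r2 <- emit_one(name, allele, flag2)
        records <- c(records, r1$rec, r2$rec)
        truth[[length(truth) + 1L]] <- data.frame(
          name = name, allele = allele,
          snps_covered = r1$covered + r2$covered,
          errors = r1$errors + r2$errors, stringsAsFactors = FALSE)
      } else {
        flag <- if (config$bisulfite && u %% 4L %in% c(3L, 0L)) 16L else 0L
        r <- emit_one(name, allele, flag)
        records <- c(records, r$rec)
        truth[[length(truth) + 1L]] <- data.frame(
          name = name, allele = allele, snps_covered = r$covered,
          errors = r$errors, stringsAsFactors = FALSE)
      }
    }
    sam <- c(header, records)
    if (!is.null(path)) writeLines(sam, path)
    list(sam = sam, truth = do.call(rbind, truth), masked = masked,
         genome1 = genome1, genome2 = genome2)
  })
}

#' Simulate a complete toy dataset on disk
#'
#' Convenience orchestrator writing `ref.fa`, `strain.vcf`, `masked.fa`,
#' `reads.sam` and `truth.tsv` into a directory.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param strains Strain name(s) for the VCF.
#' @return Invisibly, a list of the file paths plus the in-memory pieces.
#' @export
simulate_dataset <- function(config, out_dir, strains = "STRAIN1") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(config)
  write_fasta(ref, file.path(out_dir, "ref.fa"))
  vcf <- simulate_vcf(ref, config, strains = strains,
                      path = file.path(out_dir, "strain.vcf"))
  snps <- vcf$truth[[1L]]
  reads <- simulate_reads(ref, snps, config,
                          path = file.path(out_dir, "reads.sam"))
  write_fasta(reads$masked, file.path(out_dir, "masked.fa"))
  utils::write.table(reads$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(
    paths = file.path(out_dir, c("ref.fa", "strain.vcf", "masked.fa",
                                 "reads.sam", "truth.tsv")),
    reference = ref, vcf = vcf, snps = snps, reads = reads
  ))
}
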