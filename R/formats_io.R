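# Readers/writers for FASTA, a minimal VCF subset, the SNP annotation file,
# and the SAM/BAM adapter used by the tagger and sorter.

#' Read a FASTA file into a genome map
#'
#' A genome map is a named character vector: chromosome name (the FASTA
#' header up to the first whitespace) mapped to its uppercase sequence.
#' Characters outside `{A,C,G,T,N}` are normalised to `N`.
#'
#' @param path Path to a FASTA file, optionally gzip-compressed.
#' @return Named character vector of chromosome sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to read FASTA '", path, "': ",
                             conditionMessage(e))
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(nm))) stop("empty chromosome name in FASTA: ", path)
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name in FASTA: ", nm[duplicated(nm)][1L])
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for chromosome: ", nm[!nzchar(seqs)][1L])
  }
  seqs <- gsub("[^ACGTN]", "N", seqs)
  names(seqs) <- nm
  seqs
}

#' Write a genome map to a FASTA file
#'
#' @param genome Named character vector (see [read_fasta()]).
#' @param path Output path; a `.gz` suffix selects gzip compression.
#' @param line_width Sequence line width, default 60.
#' @return The path, invisibly.
#' @export
write_fasta <- function(genome, path, line_width = 60L) {
  stopifnot(line_width >= 1L)
  if (length(genome) == 0L) {
    warning("writing empty FASTA: ", path)
    file.create(path)
    return(invisible(path))
  }
  set <- Biostrings::BStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = as.integer(line_width),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Parse a VCF file into a per-call table
#'
#' Reads a VCF (v4.x, plain or gzipped) and extracts, for each requested
#' sample, the genotype (`GT`) and a per-sample confidence flag (default
#' field `FI`, as used by large strain-variation resources: value 1 means
#' the call passed filtering). The flag is reported as a tri-state:
#' `"pass"`, `"fail"`, or `"absent"` when the field is missing.
#'
#' @param path Path to the VCF file.
#' @param samples Character vector of sample names; all must appear in the
#'   `#CHROM` header line.
#' @param confidence_field Name of the per-sample confidence FORMAT field.
#' @return A data frame with columns `chrom`, `pos`, `id`, `ref`, `alt`
#'   (comma-separated ALT alleles as printed), and per sample `gt_<sample>`
#'   and `fi_<sample>` columns.
#' @export
parse_vcf <- function(path, samples, confidence_field = "FI") {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  have <- colnames(v@gt)[-1L]
  missing <- setdiff(samples, have)
  if (length(missing)) {
    stop("sample(s) not present in VCF header: ",
         paste(missing, collapse = ", "))
  }
  fix <- v@fix
  out <- data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    id = as.character(fix[, "ID"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$pos) || any(out$pos < 1L)) {
    stop("malformed VCF position at data line ",
         which(is.na(out$pos) | out$pos < 1L)[1L])
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  fi <- suppressWarnings(vcfR::extract.gt(v, element = confidence_field))
  for (s in samples) {
    out[[paste0("gt_", s)]] <- as.character(gt[, s])
    flag <- if (is.null(fi)) rep(NA_character_, nrow(out)) else
      as.character(fi[, s])
    out[[paste0("fi_", s)]] <-
      ifelse(is.na(flag), "absent", ifelse(flag == "1", "pass", "fail"))
  }
  rownames(out) <- NULL
  out
}

#' Write and read the SNP annotation file
#'
#' The SNP file is the interchange format between genome preparation and
#' read tagging: gzip-compressed, tab-delimited, one SNP per line with
#' columns ID, chromosome, 1-based position, a strand placeholder `1`, and
#' the two alleles joined as `allele1/allele2`.
#'
#' @param snps Data frame with columns `id`, `chrom`, `pos`, `allele1`,
#'   `allele2`.
#' @param path Output (input) path; always written gzip-compressed, read
#'   back transparently whether compressed or not.
#' @return `write_snp_file()` returns the path invisibly;
#'   `read_snp_file()` returns the SNP data frame.
#' @export
write_snp_file <- function(snps, path) {
  snps <- validate_snps(snps)
  con <- gzfile(path, "wb")
  on.exit(close(con))
  if (nrow(snps)) {
    writeLines(sprintf("%s\t%s\t%d\t1\t%s/%s", snps$id, snps$chrom,
                       snps$pos, snps$allele1, snps$allele2), con)
  } else {
    writeLines(character(0), con)
  }
  invisible(path)
}

#' @rdname write_snp_file
#' @export
read_snp_file <- function(path) {
  if (!file.exists(path)) stop("SNP file not found: ", path)
  lines <- readLines(gzfile(path))
  if (!length(lines)) {
    return(data.frame(id = character(0), chrom = character(0),
                      pos = integer(0), allele1 = character(0),
                      allele2 = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 5L)) {
    stop("malformed SNP file line ", which(nfield != 5L)[1L],
         ": expected 5 tab-separated columns")
  }
  m <- matrix(unlist(parts), ncol = 5L, byrow = TRUE)
  ok <- grepl("^[ACGT]/[ACGT]$", m[, 5L])
  if (any(!ok)) {
    stop("malformed allele column at SNP file line ", which(!ok)[1L],
         ": '", m[!ok, 5L][1L], "'")
  }
  a1 <- substr(m[, 5L], 1L, 1L)
  a2 <- substr(m[, 5L], 3L, 3L)
  if (any(a1 == a2)) {
    stop("identical alleles at SNP file line ", which(a1 == a2)[1L])
  }
  pos <- as.integer(m[, 2L + 1L])
  if (anyNA(pos) || any(pos < 1L)) {
    stop("malformed position at SNP file line ",
         which(is.na(pos) | pos < 1L)[1L])
  }
  data.frame(id = m[, 1L], chrom = m[, 2L], pos = pos, allele1 = a1,
             allele2 = a2, stringsAsFactors = FALSE)
}

# Validate a SNP data frame against the SnpRecord invariants.
validate_snps <- function(snps) {
  need <- c("id", "chrom", "pos", "allele1", "allele2")
  if (!all(need %in% names(snps))) {
    stop("SNP table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(snps)) {
    if (any(!snps$allele1 %in% c("A", "C", "G", "T")) ||
        any(!snps$allele2 %in% c("A", "C", "G", "T"))) {
      stop("SNP alleles must be single bases in {A,C,G,T}")
    }
    if (any(snps$allele1 == snps$allele2)) {
      stop("SNP with identical alleles at row ",
           which(snps$allele1 == snps$allele2)[1L])
    }
    if (any(snps$pos < 1L)) stop("SNP position must be >= 1")
  }
  snps$pos <- as.integer(snps$pos)
  snps
}

# ---- SAM/BAM adapter --------------------------------------------------------

is_bam <- function(path) grepl("\\.bam$", path, ignore.case = TRUE)

samtools_available <- function() nzchar(Sys.which("samtools"))

#' Read a SAM or BAM file as header lines plus record lines
#'
#' BAM input is converted through `samtools view -h`; plain SAM needs no
#' external tool. Record order is preserved.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return A list with `header` (character vector of `@` lines) and
#'   `records` (character vector of alignment lines).
#' @export
sam_read <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (is_bam(path)) {
    if (!samtools_available()) {
      stop("BAM input requires samtools on the PATH; provide SAM instead")
    }
    lines <- system2("samtools", c("view", "-h", shQuote(path)),
                     stdout = TRUE, stderr = FALSE)
    if (!is.null(attr(lines, "status"))) {
      stop("samtools failed to read: ", path)
    }
  } else {
    lines <- readLines(path)
  }
  is_h <- startsWith(lines, "@")
  n_h <- sum(is_h)
  if (n_h == 0L) stop("missing SAM header in: ", path)
  if (!all(which(is_h) == seq_len(n_h))) {
    stop("corrupt SAM header (header lines after records) in: ", path)
  }
  list(header = lines[is_h], records = lines[!is_h])
}

#' Write header plus record lines as SAM or BAM
#'
#' @param header Character vector of header lines.
#' @param records Character vector of alignment lines.
#' @param path Output path; a `.bam` suffix converts through samtools.
#' @return The path, invisibly.
#' @export
sam_write <- function(header, records, path) {
  if (is_bam(path)) {
    if (!samtools_available()) {
      stop("BAM output requires samtools on the PATH; use a .sam path")
    }
    tmp <- tempfile(fileext = ".sam")
    on.exit(unlink(tmp))
    writeLines(c(header, records), tmp)
    status <- system2("samtools", c("view", "-b", "-o", shQuote(path),
                                    shQuote(tmp)))
    if (status != 0L) stop("samtools failed to write: ", path)
  } else {
    writeLines(c(header, records), path)
  }
  invisible(path)
}

# Extract the value of an aux tag (e.g. "MD", "Z") from SAM record lines.
# Returns NA where the tag is absent. Vectorised.
sam_tag_value <- function(lines, tag, type = "Z") {
  key <- paste0("\t", tag, ":", type, ":")
  has <- grepl(key, lines, fixed = TRUE)
  out <- rep(NA_character_, length(lines))
  if (any(has)) {
    out[has] <- sub(paste0(".*\t", tag, ":", type, ":([^\t]*).*"), "\\1",
                    lines[has])
  }
  out
}

# Split SAM record lines into the mandatory fields the tagger and sorter
# need, plus the MD and genome-conversion aux tags. Vectorised over lines.
parse_sam_records <- function(records, conversion_tag = "XG") {
  n <- length(records)
  if (n == 0L) {
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      cigar = character(0), seq = character(0),
                      md = character(0), xg = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(records, "\t", fixed = TRUE)
  short <- lengths(parts) < 11L
  if (any(short)) {
    stop("malformed SAM record at line ", which(short)[1L],
         " (fewer than 11 fields)")
  }
  field <- function(i) vapply(parts, `[[`, character(1L), i)
  flag <- as.integer(field(2L))
  pos <- as.integer(field(4L))
  if (anyNA(flag) || anyNA(pos)) {
    stop("malformed FLAG/POS in SAM record ",
         which(is.na(flag) | is.na(pos))[1L])
  }
  data.frame(
    qname = field(1L), flag = flag, rname = field(3L), pos = pos,
    cigar = field(6L), seq = field(10L),
    md = sam_tag_value(records, "MD"),
    xg = sam_tag_value(records, conversion_tag),
    stringsAsFactors = FALSE
  )
}

#' Build an alignment view from one SAM record line
#'
#' The view is the subset of a SAM record the tagger consumes: name, flag
#' booleans, position, CIGAR, sequence, MD string and the optional
#' bisulfite genome-conversion strand, plus the raw line for pass-through.
#'
#' @param record One SAM alignment line.
#' @param conversion_tag Aux tag holding the Bismark-style genome
#'   conversion (`CT`/`GA`), default `XG`.
#' @return A list of class `alignment_view`.
#' @export
alignment_view <- function(record, conversion_tag = "XG") {
  p <- parse_sam_records(record, conversion_tag = conversion_tag)
  view <- list(
    name = p$qname, flag = p$flag,
    is_paired = bitwAnd(p$flag, 1L) > 0L,
    is_first = bitwAnd(p$flag, 64L) > 0L,
    is_reverse = bitwAnd(p$flag, 16L) > 0L,
    is_unmapped = bitwAnd(p$flag, 4L) > 0L,
    chrom = p$rname, pos = p$pos, cigar = p$cigar, sequence = p$seq,
    md = p$md,
    conversion_strand = if (is.na(p$xg)) NA_character_ else p$xg,
    raw = record
  )
  class(view) <- "alignment_view"
  if (!view$is_unmapped) {
    qlen <- cigar_query_length(view$cigar)
    if (!is.na(qlen) && qlen != nchar(view$sequence)) {
      stop("CIGAR query length (", qlen, ") disagrees with sequence length (",
           nchar(view$sequence), ") for read ", view$name)
    }
  }
  view
}

#' Append an allele tag to a SAM record line
#'
#' Any pre-existing `XX:Z:` tag is removed first, so re-tagging replaces
#' rather than duplicates; all other fields pass through unchanged.
#'
#' @param record One SAM alignment line.
#' @param tag One of `"UA"`, `"G1"`, `"G2"`, `"CF"`.
#' @return The record line with exactly one `XX:Z:` tag.
#' @export
emit_tagged <- function(record, tag) {
  stopifnot(all(tag %in% c("UA", "G1", "G2", "CF")))
  record <- gsub("\tXX:Z:[^\t]*", "", record)
  paste0(record, "\tXX:Z:", tag)
}
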