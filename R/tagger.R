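# Stage I: determine each aligned read's allelic origin from its bases at
# known SNP positions and append the XX:Z: tag (UA/G1/G2/CF).
#
# The pipeline per read is:
#   MD string -> read offsets whose reference base is N (masked positions)
#   CIGAR     -> genomic position of each such offset
#   SNP index -> allele-1/allele-2 verdict per observed base
#   verdicts  -> one of UA / G1 / G2 / CF

BASES <- c("A", "C", "G", "T")

#' Build a SNP index for fast positional lookup
#'
#' @param snps SNP data frame (or path to a SNP annotation file).
#' @return An object of class `snp_index` supporting per-chromosome
#'   position lookup. Duplicate positions are fatal (annotation corruption).
#' @export
build_snp_index <- function(snps) {
  if (is.character(snps)) snps <- read_snp_file(snps)
  snps <- validate_snps(snps)
  if (anyDuplicated(paste(snps$chrom, snps$pos))) {
    stop("duplicate SNP at one position in annotation: ",
         paste(snps$chrom, snps$pos)[
           duplicated(paste(snps$chrom, snps$pos))][1L])
  }
  chroms <- lapply(split(snps, snps$chrom), function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    list(pos = d$pos, allele1 = d$allele1, allele2 = d$allele2)
  })
  structure(list(chroms = chroms, n = nrow(snps)), class = "snp_index")
}

#' @export
print.snp_index <- function(x, ...) {
  cat("SNP index:", x$n, "SNPs on", length(x$chroms), "chromosome(s)\n")
  invisible(x)
}

# Binary-search lookup: indices into the chromosome's SNP arrays for each
# query position, NA where no SNP is annotated.
snp_index_lookup <- function(index, chrom, positions) {
  tab <- index$chroms[[chrom]]
  if (is.null(tab) || !length(positions)) {
    return(rep(NA_integer_, length(positions)))
  }
  i <- findInterval(positions, tab$pos)
  hit <- i > 0L & tab$pos[pmax(i, 1L)] == positions
  ifelse(hit, i, NA_integer_)
}

parse_cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(NULL)
  m <- gregexpr("\\d+|[A-Z=]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  n <- length(toks)
  if (n < 2L || n %% 2L != 0L) stop("malformed CIGAR: ", cigar)
  list(op = toks[seq(2L, n, 2L)],
       len = as.integer(toks[seq(1L, n, 2L)]))
}

# Total query (read) length implied by a CIGAR; NA for "*".
cigar_query_length <- function(cigar) {
  ops <- parse_cigar_ops(cigar)
  if (is.null(ops)) return(NA_integer_)
  sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
}

cigar_is_supported <- function(cigar) {
  ops <- parse_cigar_ops(cigar)
  if (is.null(ops)) return(FALSE)
  all(ops$op %in% c("M", "I", "D", "N", "=", "X"))
}

#' Map aligned read bases to genomic positions
#'
#' Walks the CIGAR string: `M` (and its `=`/`X` refinements) consumes both
#' read and genome, `I` consumes read only, `D` and `N` consume genome
#' only. Soft/hard clips and padding (`S`, `H`, `P`) are unsupported; such
#' reads are rejected upstream and counted.
#'
#' @param view An `alignment_view` (or a list with `pos` and `cigar`).
#' @return A list with parallel vectors `offsets` (0-based read offsets of
#'   aligned bases) and `gpos` (their 1-based genomic positions), both
#'   strictly increasing, or `NULL` if the CIGAR is unsupported.
#' @export
cigar_map <- function(view) {
  ops <- parse_cigar_ops(view$cigar)
  if (is.null(ops)) return(NULL)
  op <- ops$op
  op[op %in% c("=", "X")] <- "M"
  if (!all(op %in% c("M", "I", "D", "N"))) return(NULL)
  len <- ops$len
  offsets <- vector("list", length(op))
  gpos <- vector("list", length(op))
  r <- 0L           # 0-based read offset of next read base
  g <- view$pos     # 1-based genomic position of next reference base
  for (k in seq_along(op)) {
    L <- len[k]
    if (op[k] == "M") {
      offsets[[k]] <- r + seq_len(L) - 1L
      gpos[[k]] <- g + seq_len(L) - 1L
      r <- r + L
      g <- g + L
    } else if (op[k] == "I") {
      r <- r + L
    } else {        # D or N
      g <- g + L
    }
  }
  list(offsets = unlist(offsets), gpos = unlist(gpos))
}

parse_md_tokens <- function(md) {
  m <- gregexpr("\\^[A-Za-z]+|[0-9]+|[A-Za-z]", md, perl = TRUE)[[1]]
  regmatches(md, list(m))[[1]]
}

#' Find read offsets whose reference base is N
#'
#' Parses the MD string (run lengths of matches, substituted reference
#' bases, `^`-prefixed deletions) against the CIGAR-derived offsets of
#' aligned bases. MD omits insertions, which the CIGAR declares, so the
#' returned offsets are already insertion-adjusted. An MD string whose
#' match/mismatch count disagrees with the CIGAR's aligned-base count is
#' reported as `NULL` (per-read rejection, counted by the caller).
#'
#' @param view An `alignment_view` with `md` present.
#' @param map Optional precomputed [cigar_map()] result.
#' @return Integer vector of 0-based read offsets overlapping reference
#'   Ns (possibly empty), or `NULL` if MD and CIGAR are inconsistent.
#' @export
masked_positions_from_md <- function(view, map = cigar_map(view)) {
  if (is.null(map)) return(NULL)
  if (is.null(view$md) || is.na(view$md)) {
    stop("MD field absent for read ", view$name,
         "; the aligner must emit MD:Z: tags")
  }
  moffs <- map$offsets
  toks <- parse_md_tokens(view$md)
  i <- 1L           # index of next aligned column in moffs
  res <- integer(0)
  for (tok in toks) {
    first <- substr(tok, 1L, 1L)
    if (first >= "0" && first <= "9") {
      i <- i + as.integer(tok)
    } else if (first == "^") {
      # deletion: reference-only columns, not present in moffs
    } else {
      if (i > length(moffs)) return(NULL)
      if (tok == "N" || tok == "n") res <- c(res, moffs[i])
      i <- i + 1L
    }
  }
  if (i != length(moffs) + 1L) return(NULL)
  res
}

#' Bisulfite usability and matching rules
#'
#' After bisulfite conversion, C/T differences on the forward
#' (C-to-T-converted) strand and G/A differences on the reverse
#' (G-to-A-converted) strand cannot be told apart from methylation state,
#' so such SNPs are unusable on that strand. At usable SNPs involving a C
#' (forward strand) both methylation states are accepted: read base C or T
#' matches an allele base C; symmetrically, read base G or A matches an
#' allele base G on the reverse strand. All other bases must match
#' exactly.
#'
#' @param allele1,allele2 The SNP's two allele bases.
#' @param strand `"forward"` (genome conversion CT) or `"reverse"` (GA).
#' @return `bisulfite_usable()`: logical. `bisulfite_match()`: logical.
#' @export
bisulfite_usable <- function(allele1, allele2, strand) {
  pair <- paste(sort(c(allele1, allele2)), collapse = "")
  !((strand == "forward" && pair == "CT") ||
      (strand == "reverse" && pair == "AG"))
}

#' @rdname bisulfite_usable
#' @param read_base Base observed in the read.
#' @param allele_base Allele base being tested.
#' @export
bisulfite_match <- function(read_base, allele_base, strand) {
  if (strand == "forward" && allele_base == "C") {
    return(read_base %in% c("C", "T"))
  }
  if (strand == "reverse" && allele_base == "G") {
    return(read_base %in% c("G", "A"))
  }
  read_base == allele_base
}

conversion_strand_of <- function(view) {
  cs <- view$conversion_strand
  if (is.null(cs) || is.na(cs)) {
    stop("bisulfite mode requires the genome-conversion tag (e.g. XG:Z:CT)",
         " on every read; missing for ", view$name)
  }
  switch(cs, CT = "forward", GA = "reverse",
         stop("unrecognised genome-conversion value '", cs, "' for read ",
              view$name))
}

#' Collect base observations for one read
#'
#' For every MD-derived masked offset, maps to the genomic position, looks
#' up the SNP index (positions not in the index are ignored: masked but
#' unknown) and assigns a verdict. In bisulfite mode the strand-dependent
#' usability filter and dual-state matching rules apply; a base matching
#' both alleles carries no information and is scored `neither`.
#'
#' @param view An `alignment_view`.
#' @param index A `snp_index`.
#' @param bisulfite Apply bisulfite rules?
#' @return A data frame with columns `gpos`, `base`, `allele1`, `allele2`,
#'   `verdict` (one of `allele1`, `allele2`, `neither`,
#'   `skipped_bisulfite`), or `NULL` for an unsupported/inconsistent read.
#' @export
observe <- function(view, index, bisulfite = FALSE) {
  map <- cigar_map(view)
  if (is.null(map)) return(NULL)
  offs <- masked_positions_from_md(view, map)
  if (is.null(offs)) return(NULL)
  empty <- data.frame(gpos = integer(0), base = character(0),
                      allele1 = character(0), allele2 = character(0),
                      verdict = character(0), stringsAsFactors = FALSE)
  if (!length(offs)) return(empty)
  gpos <- map$gpos[match(offs, map$offsets)]
  hit <- snp_index_lookup(index, view$chrom, gpos)
  keep <- !is.na(hit)
  if (!any(keep)) return(empty)
  offs <- offs[keep]; gpos <- gpos[keep]; hit <- hit[keep]
  tab <- index$chroms[[view$chrom]]
  a1 <- tab$allele1[hit]
  a2 <- tab$allele2[hit]
  base <- substring(view$sequence, offs + 1L, offs + 1L)
  strand <- if (bisulfite) conversion_strand_of(view) else NULL
  verdict <- character(length(offs))
  for (j in seq_along(offs)) {
    if (bisulfite) {
      if (!bisulfite_usable(a1[j], a2[j], strand)) {
        verdict[j] <- "skipped_bisulfite"
        next
      }
      m1 <- bisulfite_match(base[j], a1[j], strand)
      m2 <- bisulfite_match(base[j], a2[j], strand)
      verdict[j] <- if (m1 && m2) "neither" else if (m1) "allele1" else
        if (m2) "allele2" else "neither"
    } else {
      verdict[j] <- if (base[j] == a1[j]) "allele1" else
        if (base[j] == a2[j]) "allele2" else "neither"
    }
  }
  data.frame(gpos = gpos, base = base, allele1 = a1, allele2 = a2,
             verdict = verdict, stringsAsFactors = FALSE)
}

#' Classify a read from its base observations
#'
#' Evidence for both alleles in one read is conflicting; evidence for one
#' allele only assigns the read to that genome; anything else (no
#' observations, or only `neither`/`skipped_bisulfite`) is unassignable.
#'
#' @param verdicts Character vector of observation verdicts (or the data
#'   frame returned by [observe()]).
#' @return One of `"UA"`, `"G1"`, `"G2"`, `"CF"`.
#' @export
classify <- function(verdicts) {
  if (is.data.frame(verdicts)) verdicts <- verdicts$verdict
  a1 <- sum(verdicts == "allele1")
  a2 <- sum(verdicts == "allele2")
  if (a1 > 0L && a2 > 0L) "CF" else if (a1 > 0L) "G1" else
    if (a2 > 0L) "G2" else "UA"
}

new_tag_report <- function(cnt) structure(cnt, class = "tag_report")

validate_tag_report <- function(x) {
  total <- x$unassignable + x$genome1 + x$genome2 + x$conflicting +
    x$unmapped_skipped + x$cigar_unsupported
  if (x$reads_seen != total) {
    stop("tag report violates conservation: reads_seen != sum of categories")
  }
  invisible(x)
}

#' @export
print.tag_report <- function(x, ...) {
  cat("Allele tagging report\n")
  writeLines(paste0("  ", format_report_lines(x)))
  invisible(x)
}

#' Tag every read in an alignment file with its allelic origin
#'
#' Stage I of the workflow. Every record is re-emitted in input order with
#' exactly one `XX:Z:` tag. Unmapped reads and reads with unsupported
#' CIGAR operations (S/H/P) or MD/CIGAR inconsistencies are emitted as
#' `XX:Z:UA` but counted in dedicated report buckets, so the output is a
#' same-order superset suitable for downstream pairing. If the first
#' records carry a Bismark-style genome-conversion tag, bisulfite mode is
#' enabled automatically with a logged notice.
#'
#' @param input Path to a SAM/BAM file aligned against the N-masked
#'   genome, with MD:Z: fields.
#' @param snps A `snp_index`, SNP data frame, or path to a SNP file.
#' @param output Output path; default `<input>.allele_flagged.<ext>`.
#' @param bisulfite Force bisulfite rules (`NA` = auto-detect).
#' @param conversion_tag Aux tag carrying the genome conversion, default
#'   `"XG"`.
#' @param report_path Where to write the plain-text report (default next
#'   to the output); `NULL` suppresses the file.
#' @return Invisibly, a list with `output`, `report` (a `tag_report`) and
#'   `report_path`.
#' @export
tag_alignments <- function(input, snps, output = NULL, bisulfite = NA,
                           conversion_tag = "XG", report_path = NA) {
  index <- if (inherits(snps, "snp_index")) snps else build_snp_index(snps)
  if (index$n == 0L) stop("SNP index is empty")
  sam <- sam_read(input)
  if (is.null(output)) {
    ext <- if (is_bam(input)) ".bam" else ".sam"
    output <- file.path(dirname(input),
                        paste0(strip_sam_ext(basename(input)),
                               ".allele_flagged", ext))
  }
  recs <- parse_sam_records(sam$records, conversion_tag = conversion_tag)
  n <- nrow(recs)
  if (n == 0L) {
    warning("no alignment records in ", input)
  }
  # Bismark-style auto-detection on the first records
  if (is.na(bisulfite)) {
    probe <- recs$xg[seq_len(min(n, 100L))]
    bisulfite <- n > 0L && any(!is.na(probe))
    if (bisulfite) {
      message("genome-conversion tags detected; bisulfite mode enabled")
      if (any(bitwAnd(recs$flag[seq_len(min(n, 100L))], 1L) > 0L)) {
        message("paired-end records detected")
      }
    }
  }
  cnt <- list(reads_seen = n, unassignable = 0L, genome1 = 0L,
              genome2 = 0L, conflicting = 0L, unmapped_skipped = 0L,
              cigar_unsupported = 0L, snp_positions_examined = 0L,
              bisulfite_positions_skipped = 0L,
              neither_allele_basecalls = 0L)
  tags <- rep("UA", n)
  if (n) {
    unmapped <- bitwAnd(recs$flag, 4L) > 0L
    cnt$unmapped_skipped <- sum(unmapped)
    supported <- !unmapped &
      !grepl("[SHP]", recs$cigar) & recs$cigar != "*"
    cnt$cigar_unsupported <- sum(!unmapped & !supported)
    # Candidates whose MD proves they overlap no reference N stay UA
    # without a per-read walk.
    candidate <- which(supported & grepl("N", recs$md) & !is.na(recs$md))
    if (any(supported & is.na(recs$md))) {
      stop("MD field absent for mapped read ",
           recs$qname[supported & is.na(recs$md)][1L],
           "; the aligner must emit MD:Z: tags")
    }
    for (i in candidate) {
      view <- list(name = recs$qname[i], chrom = recs$rname[i],
                   pos = recs$pos[i], cigar = recs$cigar[i],
                   sequence = recs$seq[i], md = recs$md[i],
                   conversion_strand = recs$xg[i])
      obs <- observe(view, index, bisulfite = bisulfite)
      if (is.null(obs)) {      # MD/CIGAR inconsistency
        cnt$cigar_unsupported <- cnt$cigar_unsupported + 1L
        supported[i] <- FALSE
        next
      }
      cnt$snp_positions_examined <- cnt$snp_positions_examined + nrow(obs)
      cnt$bisulfite_positions_skipped <- cnt$bisulfite_positions_skipped +
        sum(obs$verdict == "skipped_bisulfite")
      cnt$neither_allele_basecalls <- cnt$neither_allele_basecalls +
        sum(obs$verdict == "neither")
      tags[i] <- classify(obs)
    }
    assignable <- supported & !unmapped
    cnt$genome1 <- sum(tags == "G1" & assignable)
    cnt$genome2 <- sum(tags == "G2" & assignable)
    cnt$conflicting <- sum(tags == "CF" & assignable)
    cnt$unassignable <- sum(tags == "UA" & assignable)
  }
  report <- validate_tag_report(new_tag_report(cnt))
  sam_write(sam$header, if (n) emit_tagged(sam$records, tags) else
    character(0), output)
  if (!is.null(report_path) && is.na(report_path)) {
    report_path <- file.path(dirname(output),
                             paste0(strip_sam_ext(basename(input)),
                                    ".tagging_report.txt"))
  }
  if (!is.null(report_path)) render_report(report, report_path)
  invisible(list(output = output, report = report,
                 report_path = report_path))
}

strip_sam_ext <- function(x) sub("\\.(sam|bam)$", "", x, ignore.case = TRUE)
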