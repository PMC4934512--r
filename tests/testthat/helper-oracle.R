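# Independent brute-force oracles used to validate the CIGAR/MD walkers
# and the simulator's MD construction. These reconstruct the padded
# alignment column by column from the genome sequence itself, never from
# the MD string, so they share no code path with the implementation.

# One row per alignment column: op, 0-based read offset (NA for D/N),
# 1-based genomic position (NA for I), reference base (NA for I), read
# base (NA for D/N).
padded_alignment <- function(genome, chrom, pos, cigar, seq) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDN=X]", cigar))[[1]]
  stopifnot(length(lens) == length(ops))
  rows <- list()
  r <- 0L; g <- pos
  for (k in seq_along(ops)) {
    op <- if (ops[k] %in% c("=", "X")) "M" else ops[k]
    for (j in seq_len(lens[k])) {
      if (op == "M") {
        rows[[length(rows) + 1L]] <- data.frame(
          op = "M", read_off = r, gpos = g,
          ref_base = substr(genome[[chrom]], g, g),
          read_base = substr(seq, r + 1L, r + 1L))
        r <- r + 1L; g <- g + 1L
      } else if (op == "I") {
        rows[[length(rows) + 1L]] <- data.frame(
          op = "I", read_off = r, gpos = NA_integer_,
          ref_base = NA_character_,
          read_base = substr(seq, r + 1L, r + 1L))
        r <- r + 1L
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          op = op, read_off = NA_integer_, gpos = g,
          ref_base = substr(genome[[chrom]], g, g),
          read_base = NA_character_)
        g <- g + 1L
      }
    }
  }
  do.call(rbind, rows)
}

# Expected (read offset, genomic position) pairs for aligned bases.
oracle_cigar_map <- function(genome, chrom, pos, cigar, seq) {
  pa <- padded_alignment(genome, chrom, pos, cigar, seq)
  m <- pa[pa$op == "M", , drop = FALSE]
  list(offsets = m$read_off, gpos = m$gpos)
}

# Expected read offsets overlapping reference Ns, by direct genome scan.
oracle_masked_offsets <- function(genome, chrom, pos, cigar, seq) {
  pa <- padded_alignment(genome, chrom, pos, cigar, seq)
  pa$read_off[pa$op == "M" & pa$ref_base == "N"]
}

# Expected MD string, built column-wise from the padded alignment.
oracle_md <- function(genome, chrom, pos, cigar, seq) {
  pa <- padded_alignment(genome, chrom, pos, cigar, seq)
  out <- ""
  run <- 0L
  in_del <- FALSE
  for (i in seq_len(nrow(pa))) {
    if (pa$op[i] == "M") {
      if (pa$ref_base[i] == pa$read_base[i]) {
        run <- run + 1L
        in_del <- FALSE
      } else {
        out <- paste0(out, run, pa$ref_base[i]); run <- 0L
        in_del <- FALSE
      }
    } else if (pa$op[i] == "D") {
      if (!in_del) {
        out <- paste0(out, run, "^"); run <- 0L; in_del <- TRUE
      }
      out <- paste0(out, pa$ref_base[i])
    }
    # I and N columns leave MD untouched
  }
  paste0(out, run)
}

# Minimal alignment view for unit-level tagger calls.
make_view <- function(pos, cigar, seq, md = NA, chrom = "chr1",
                      name = "r1", xg = NA) {
  list(name = name, chrom = chrom, pos = pos, cigar = cigar,
       sequence = seq, md = md, conversion_strand = xg)
}

# Minimal SAM file fixture: header + handwritten records.
write_sam <- function(records, path, chrom_lens = c(chr1 = 10000L)) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lens), chrom_lens))
  writeLines(c(header, records), path)
  path
}

sam_record <- function(name, flag, chrom, pos, cigar, seq, md = NULL,
                       extra = NULL) {
  rec <- sprintf("%s\t%d\t%s\t%d\t42\t%s\t*\t0\t0\t%s\t%s",
                 name, flag, chrom, pos, cigar, seq,
                 strrep("I", nchar(seq)))
  if (!is.null(md)) rec <- paste0(rec, "\tMD:Z:", md)
  if (!is.null(extra)) rec <- paste0(rec, "\t", extra)
  rec
}

read_names_of <- function(path) {
  recs <- allelesort::sam_read(path)$records
  if (!length(recs)) return(character(0))
  vapply(strsplit(recs, "\t", fixed = TRUE), `[[`, character(1), 1L)
}
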