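# Stage II: partition a tagged alignment file into allele-specific output
# files, with single-end, paired-end and Hi-C pair-category logic.

extract_allele_tag <- function(records) sam_tag_value(records, "XX")

#' Combine the allele tags of a read pair
#'
#' A conflicting mate, or opposing single-genome evidence on the two
#' mates, makes the pair conflicting; otherwise any single-genome evidence
#' assigns the pair to that genome; two unassignable mates leave the pair
#' unassignable. Symmetric in its arguments.
#'
#' @param tag1,tag2 Allele tags (`UA`, `G1`, `G2`, `CF`).
#' @return One of `"G1"`, `"G2"`, `"UA"`, `"conflicting"`.
#' @export
combine_pair_tags <- function(tag1, tag2) {
  t <- c(tag1, tag2)
  if (any(t == "CF") || all(c("G1", "G2") %in% t)) return("conflicting")
  if (any(t == "G1")) return("G1")
  if (any(t == "G2")) return("G2")
  "UA"
}

#' Classify a Hi-C read pair
#'
#' Maps the unordered pair of mate tags to one of the six Hi-C contact
#' categories; mixed-genome pairs are normalised to `G1-G2` (proximity
#' contacts have no directionality, so no reverse `G2-G1` group exists).
#' Any conflicting mate makes the pair `conflicting`.
#'
#' @param tag1,tag2 Allele tags.
#' @return One of `"G1-G1"`, `"G2-G2"`, `"G1-UA"`, `"G2-UA"`, `"G1-G2"`,
#'   `"UA-UA"`, `"conflicting"`.
#' @export
classify_hic_pair <- function(tag1, tag2) {
  if (tag1 == "CF" || tag2 == "CF") return("conflicting")
  t <- sort(c(tag1, tag2))   # G1 < G2 < UA alphabetically
  paste(t, collapse = "-")
}

new_sort_report <- function(cnt) structure(cnt, class = "sort_report")

#' @export
print.sort_report <- function(x, ...) {
  cat("Allele sorting report\n")
  writeLines(paste0("  ", format_report_lines(x)))
  invisible(x)
}

sort_output_paths <- function(input, out_dir, hic, conflicting) {
  base <- strip_sam_ext(basename(input))
  ext <- if (is_bam(input)) ".bam" else ".sam"
  cats <- if (hic) {
    c("G1-G1" = ".G1_G1", "G2-G2" = ".G2_G2", "G1-UA" = ".G1_UA",
      "G2-UA" = ".G2_UA", "G1-G2" = ".G1_G2", "UA-UA" = ".UA_UA")
  } else {
    c(G1 = ".genome1", G2 = ".genome2", UA = ".unassigned")
  }
  if (conflicting) cats <- c(cats, conflicting = ".conflicting")
  stats::setNames(file.path(out_dir, paste0(base, cats, ext)), names(cats))
}

# Route record lines into category files. `routes` maps each record index
# to a category name or NA (suppressed).
write_sorted <- function(header, records, routes, paths) {
  for (cat in names(paths)) {
    sam_write(header, records[!is.na(routes) & routes == cat], paths[[cat]])
  }
  invisible(paths)
}

#' Sort a tagged alignment file into allele-specific files
#'
#' Stage II of the workflow. Single-end records are routed by their own
#' `XX:Z:` tag; paired-end mates are combined with [combine_pair_tags()];
#' Hi-C pairs are routed to the six contact-category files via
#' [classify_hic_pair()]. Conflicting reads/pairs are suppressed unless
#' `conflicting = TRUE`. Running it again on the same tagged file (to try
#' different options) performs no re-tagging.
#'
#' @param input Path to a tagged SAM/BAM file (every record must carry
#'   `XX:Z:`; untagged input is fatal).
#' @param out_dir Output directory, default alongside the input.
#' @param paired Treat input as paired-end; mates are paired by name
#'   adjacency, with a stable name-sort first if mates are not adjacent.
#' @param hic Hi-C mode: input must be strictly name-adjacent pairs.
#' @param singletons In paired mode, write mate-less records to separate
#'   `.st` files instead of the main files.
#' @param conflicting Write conflicting reads/pairs to a `.conflicting`
#'   file instead of suppressing them.
#' @param report_path Plain-text report destination (`NULL` suppresses).
#' @return Invisibly, a list with `paths`, `report` and `report_path`.
#' @export
sort_alignments <- function(input, out_dir = dirname(input), paired = FALSE,
                            hic = FALSE, singletons = FALSE,
                            conflicting = FALSE, report_path = NA) {
  sam <- sam_read(input)
  records <- sam$records
  n <- length(records)
  tags <- extract_allele_tag(records)
  if (any(is.na(tags))) {
    stop("input is not tagged (record without XX:Z: tag): run tagging first")
  }
  if (n && !all(tags %in% c("UA", "G1", "G2", "CF"))) {
    stop("unrecognised XX:Z: tag value: ",
         tags[!tags %in% c("UA", "G1", "G2", "CF")][1L])
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- sort_output_paths(input, out_dir, hic = hic,
                             conflicting = conflicting)
  qnames <- if (n) vapply(strsplit(records, "\t", fixed = TRUE), `[[`,
                          character(1L), 1L) else character(0)

  if (hic) {
    if (n %% 2L != 0L ||
        (n > 0L && any(qnames[seq(1L, n, 2L)] != qnames[seq(2L, n, 2L)]))) {
      stop("Hi-C mode requires strictly name-adjacent read pairs")
    }
    routes <- rep(NA_character_, n)
    cat_count <- stats::setNames(integer(7),
                                 c("G1-G1", "G2-G2", "G1-UA", "G2-UA",
                                   "G1-G2", "UA-UA", "conflicting"))
    suppressed <- 0L
    if (n) {
      for (p in seq_len(n %/% 2L)) {
        i <- 2L * p - 1L
        cat <- classify_hic_pair(tags[i], tags[i + 1L])
        cat_count[[cat]] <- cat_count[[cat]] + 1L
        if (cat == "conflicting" && !conflicting) {
          suppressed <- suppressed + 1L
        } else {
          routes[c(i, i + 1L)] <- cat
        }
      }
    }
    write_sorted(sam$header, records, routes, paths)
    report <- new_sort_report(c(
      list(reads_seen = n, pairs_seen = n %/% 2L),
      as.list(cat_count),
      list(conflicting_suppressed = suppressed)
    ))
  } else if (paired) {
    # Pair mates by adjacency; if a name recurs non-adjacently, perform a
    # stable name-sort first (and note it).
    if (n && length(rle(qnames)$values) != length(unique(qnames))) {
      message("mates are not name-adjacent; applying stable name-sort")
      ord <- order(qnames, method = "radix")
      records <- records[ord]
      tags <- tags[ord]
      qnames <- qnames[ord]
    }
    routes <- rep(NA_character_, n)
    cat_count <- stats::setNames(integer(4), c("G1", "G2", "UA",
                                               "conflicting"))
    pairs_seen <- 0L; singles_seen <- 0L; suppressed <- 0L
    i <- 1L
    while (i <= n) {
      if (i < n && qnames[i] == qnames[i + 1L]) {
        pairs_seen <- pairs_seen + 1L
        cat <- combine_pair_tags(tags[i], tags[i + 1L])
        cat_count[[cat]] <- cat_count[[cat]] + 1L
        if (cat == "conflicting" && !conflicting) {
          suppressed <- suppressed + 1L
        } else {
          routes[c(i, i + 1L)] <- cat
        }
        i <- i + 2L
      } else {
        singles_seen <- singles_seen + 1L
        cat <- if (tags[i] == "CF") "conflicting" else tags[i]
        if (cat == "conflicting" && !conflicting) {
          suppressed <- suppressed + 1L
          routes[i] <- NA_character_
        } else {
          routes[i] <- if (singletons) paste0(cat, ".st") else cat
        }
        i <- i + 1L
      }
    }
    if (singletons) {
      st_cats <- paste0(names(paths), ".st")
      st_paths <- stats::setNames(
        sub("(\\.(sam|bam))$", ".st\\1", unname(paths)), st_cats)
      paths <- c(paths, st_paths)
    }
    write_sorted(sam$header, records, routes, paths)
    report <- new_sort_report(c(
      list(reads_seen = n, pairs_seen = pairs_seen,
           singletons_seen = singles_seen),
      as.list(stats::setNames(cat_count,
                              c("genome1", "genome2", "unassigned",
                                "conflicting"))),
      list(conflicting_suppressed = suppressed)
    ))
  } else {
    routes <- ifelse(tags == "CF", "conflicting",
                     c(G1 = "G1", G2 = "G2", UA = "UA")[tags])
    suppressed <- 0L
    if (!conflicting) {
      suppressed <- sum(routes == "conflicting", na.rm = TRUE)
      routes[routes == "conflicting"] <- NA_character_
    }
    write_sorted(sam$header, records, routes, paths)
    report <- new_sort_report(list(
      reads_seen = n,
      genome1 = sum(tags == "G1"), genome2 = sum(tags == "G2"),
      unassigned = sum(tags == "UA"), conflicting = sum(tags == "CF"),
      conflicting_suppressed = suppressed
    ))
  }
  if (!is.null(report_path) && is.na(report_path)) {
    report_path <- file.path(out_dir,
                             paste0(strip_sam_ext(basename(input)),
                                    ".sorting_report.txt"))
  }
  if (!is.null(report_path)) render_report(report, report_path)
  invisible(list(paths = paths, report = report,
                 report_path = report_path))
}

#' Re-sort a previously tagged file under different options
#'
#' Stand-alone sorting of an already tagged file, e.g. to materialise the
#' conflicting reads or separate singletons without re-tagging.
#'
#' @inheritParams sort_alignments
#' @export
resort <- function(input, out_dir = dirname(input), paired = FALSE,
                   hic = FALSE, singletons = FALSE, conflicting = FALSE,
                   report_path = NA) {
  sort_alignments(input, out_dir = out_dir, paired = paired, hic = hic,
                  singletons = singletons, conflicting = conflicting,
                  report_path = report_path)
}
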