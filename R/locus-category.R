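#' Read BLAST tabular homology output (12-column outfmt 6)
#'
#' Reads the standard 12-column tabular BLAST dialect: `qseqid`, `sseqid`,
#' `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#' `send`, `evalue`, `bitscore`. Query coordinates are 1-based inclusive.
#'
#' @param path Path to a tab-separated file without header.
#' @return A tibble with the 12 standard columns.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) {
    stop("homology file not found: ", path, call. = FALSE)
  }
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  out <- readr::read_tsv(path, col_names = cols, col_types = readr::cols(
    qseqid = readr::col_character(), sseqid = readr::col_character(),
    pident = readr::col_double(), length = readr::col_integer(),
    mismatch = readr::col_integer(), gapopen = readr::col_integer(),
    qstart = readr::col_integer(), qend = readr::col_integer(),
    sstart = readr::col_integer(), send = readr::col_integer(),
    evalue = readr::col_double(), bitscore = readr::col_double()
  ), comment = "#")
  if (any(is.na(out$qstart)) || any(is.na(out$qend))) {
    stop("malformed homology segments: missing query coordinates",
         call. = FALSE)
  }
  out
}

#' Read coding/feature intervals from BED
#'
#' @param path Path to a BED file (0-based half-open on disk).
#' @return A tibble with 1-based inclusive `start`/`end`, plus `chrom` and
#'   (when present) `name` and `strand`.
#' @export
read_bed_intervals <- function(path) {
  if (!file.exists(path)) {
    stop("BED file not found: ", path, call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Categorise a motif locus from homology segments
#'
#' Classifies the sequence fate of one motif-centred query window (the motif
#' plus flanks, typically 500 nt each side) in one subject genome, from the
#' query-coordinate homology segments of a BLAST comparison:
#'
#' * `no_homology` — no segments at all: the region is not found in the
#'   subject.
#' * `region_missing` — some stretch of the query longer than
#'   `missing_min` nt (default 300) has no homology coverage.
#' * `intergenic_change` — homology losses or sub-`high_identity` changes
#'   exist but are confined to the intergenic interval.
#' * `no_change` — the query is covered at high identity throughout (gaps
#'   shorter than `min_gap` nt are ignored).
#'
#' "Covered" means inside a segment with `pident >= cover_identity`
#' (default 90). For the two change categories the motif fate is
#' sub-classified: `tm_missing` when the motif interval is entirely
#' uncovered, `tm_mutated` when it is covered but below 100% identity, and —
#' optionally, for inverted-repeat loci — `palindrome_effect` when
#' `hairpin_check = TRUE`, a subject sequence is supplied, and the subject
#' still carries a hairpin ([find_hairpins()]) in the locus although part of
#' the motif was lost.
#'
#' @param segments Homology segments for one (locus, subject) pair: a tibble
#'   with `qstart`, `qend` (1-based inclusive query coordinates) and
#'   `pident` ([read_blast_tab()]). Zero rows mean no homology.
#' @param query_length Length of the query window in nt.
#' @param tm_start,tm_end Motif interval in query coordinates.
#' @param intergenic_start,intergenic_end Intergenic interval in query
#'   coordinates (e.g. from [read_bed_intervals()] of the coding intervals);
#'   when absent, `intergenic_change` cannot be assigned and such loci fall
#'   through to the remaining rules, with a warning.
#' @param subject_seq Optional subject-side locus sequence for the hairpin
#'   check.
#' @param hairpin_check Assess the palindrome effect (default `FALSE`).
#' @param missing_min Minimum uncovered stretch for `region_missing`
#'   (default 300 nt).
#' @param cover_identity Identity at or above which a segment counts as
#'   coverage (default 90).
#' @param high_identity Identity required for "no change" (default 99).
#' @param min_gap Uncovered stretches shorter than this are tolerated in
#'   `no_change` (default 10 nt).
#' @return A one-row tibble: `category`, `subcategory` (`"none"` outside the
#'   two change categories), `uncovered_nt`, `changed_nt`.
#' @export
categorize_locus <- function(segments, query_length, tm_start, tm_end,
                             intergenic_start = NULL, intergenic_end = NULL,
                             subject_seq = NULL, hairpin_check = FALSE,
                             missing_min = 300L, cover_identity = 90,
                             high_identity = 99, min_gap = 10L) {
  stopifnot(query_length >= 1L, tm_start >= 1L, tm_end <= query_length,
            tm_start <= tm_end)
  if (is.null(segments) || nrow(segments) == 0L) {
    return(locus_row("no_homology", "none", query_length, query_length))
  }
  stopifnot(all(c("qstart", "qend", "pident") %in% names(segments)))
  if (any(segments$qstart < 1L) || any(segments$qend > query_length) ||
      any(segments$qstart > segments$qend)) {
    stop("malformed homology segments: query coordinates outside the window",
         call. = FALSE)
  }
  covered <- merge_intervals(segments[segments$pident >= cover_identity, ,
                                      drop = FALSE])
  uncovered <- complement_intervals(covered, query_length)
  high <- merge_intervals(segments[segments$pident >= high_identity, ,
                                   drop = FALSE])
  changed <- complement_intervals(high, query_length)
  uncovered_nt <- sum_width(uncovered)
  changed_nt <- sum_width(changed)

  tm_cov <- overlap_width(covered, tm_start, tm_end)
  tm_len <- tm_end - tm_start + 1L
  tm_full_ident <- overlap_width(
    merge_intervals(segments[segments$pident >= 100, , drop = FALSE]),
    tm_start, tm_end) == tm_len
  sub <- if (tm_cov == 0L) {
    "tm_missing"
  } else if (!tm_full_ident) {
    "tm_mutated"
  } else {
    "none"
  }
  if (hairpin_check && !is.null(subject_seq) && sub != "none") {
    hp <- find_hairpins(tibble::tibble(id = "subject",
                                       seq = normalize_dna(subject_seq),
                                       circular = FALSE))
    if (nrow(hp) > 0L) sub <- "palindrome_effect"
  }

  if (nrow(uncovered) > 0L && any(width_of(uncovered) > missing_min)) {
    return(locus_row("region_missing", sub, uncovered_nt, changed_nt))
  }
  big_changes <- changed[width_of(changed) >= min_gap, , drop = FALSE]
  if (nrow(big_changes) > 0L) {
    if (is.null(intergenic_start) || is.null(intergenic_end)) {
      warning("no intergenic interval supplied; cannot assign ",
              "intergenic_change", call. = FALSE)
    } else if (all(big_changes$start >= intergenic_start &
                   big_changes$end <= intergenic_end)) {
      return(locus_row("intergenic_change", sub, uncovered_nt, changed_nt))
    }
  }
  locus_row("no_change", "none", uncovered_nt, changed_nt)
}

locus_row <- function(category, subcategory, uncovered_nt, changed_nt) {
  tibble::tibble(category = category, subcategory = subcategory,
                 uncovered_nt = as.integer(uncovered_nt),
                 changed_nt = as.integer(changed_nt))
}

# interval helpers on 1-based inclusive tibbles with start/end -------------

merge_intervals <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  s <- if ("qstart" %in% names(segments)) segments$qstart else segments$start
  e <- if ("qend" %in% names(segments)) segments$qend else segments$end
  ord <- order(s, e)
  s <- s[ord]; e <- e[ord]
  out_s <- s[1]; out_e <- e[1]
  res <- list()
  for (i in seq_along(s)[-1]) {
    if (s[i] <= out_e + 1L) {
      out_e <- max(out_e, e[i])
    } else {
      res[[length(res) + 1L]] <- c(out_s, out_e)
      out_s <- s[i]; out_e <- e[i]
    }
  }
  res[[length(res) + 1L]] <- c(out_s, out_e)
  m <- do.call(rbind, res)
  tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

complement_intervals <- function(merged, query_length) {
  if (nrow(merged) == 0L) {
    return(tibble::tibble(start = 1L, end = as.integer(query_length)))
  }
  starts <- c(1L, merged$end + 1L)
  ends <- c(merged$start - 1L, as.integer(query_length))
  keep <- starts <= ends
  tibble::tibble(start = starts[keep], end = ends[keep])
}

width_of <- function(iv) {
  if (nrow(iv) == 0L) return(integer())
  iv$end - iv$start + 1L
}

sum_width <- function(iv) sum(width_of(iv))

overlap_width <- function(iv, start, end) {
  if (nrow(iv) == 0L) return(0L)
  w <- pmin(iv$end, end) - pmax(iv$start, start) + 1L
  sum(pmax(w, 0L))
}
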