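#' The TM consensus motif
#'
#' The G/C-rich class II triplex motif abundant in *Escherichia coli* (TM)
#' follows the degenerate consensus
#'
#' ```
#' 5'-CCCTCNCCC N(3-6) GGGNGAGGG N(3) GGGNGAGGG [GTC-]-3'
#' ```
#'
#' a C-rich 9-nt stem, a 3-6 nt first loop, two G-rich 9-nt stems separated
#' by a 3-nt second loop, and an optional one-base tail (`G`, `T` or `C`).
#' Motifs are typed by the last base of the second loop: type A ends in `A`
#' (the `T-T-A` triad), type B ends in `G` (`C-C-G`); anything else is
#' `unassigned`.
#'
#' @name tmeco
#' @keywords internal
NULL

tmeco_pattern <- function() {
  paste0("CCCTC[ACGT]CCC",        # C-rich stem (stemA)
         "([ACGT]{3,6}?)",        # loop1, shortest per anchor
         "GGG[ACGT]GAGGG",        # first G-rich stem (stemB)
         "([ACGT]{3})",           # loop2 (types the motif)
         "GGG[ACGT]GAGGG",        # second G-rich stem (stemC)
         "([GTC]?)")              # optional tail
}

#' Find TM consensus motifs in genomes
#'
#' Scans both strands of each record for non-overlapping matches of the TM
#' consensus (see [tmeco]); per anchor the shortest first loop is taken.
#' Minus-strand matches are reported with forward-strand coordinates and
#' `strand = "-"`; circular records are scanned across the origin. Each hit
#' carries its parsed parts and classification ([classify_tmeco()]).
#'
#' @param genomes Genome tibble ([read_genome_fasta()], [gen_genome()]).
#' @return A tibble of class `tmeco_hits`: `record_id`, 1-based inclusive
#'   `start`/`end`, `strand`, `length`, the parts `stemA`, `loop1`, `stemB`,
#'   `loop2`, `stemC`, `tail`, then `tm_type`, `mismatches` and the combined
#'   `type_label` (type plus `" mm"` when mismatched).
#' @examples
#' ref <- tmeco_reference()
#' g <- tibble::tibble(id = "m1", seq = ref$sequence[1], circular = FALSE)
#' find_tmeco(g)
#' @export
find_tmeco <- function(genomes) {
  genomes <- as_genome_tbl(genomes)
  pat <- tmeco_pattern()
  hits <- purrr::map_dfr(seq_len(nrow(genomes)), function(i) {
    rec <- genomes[i, ]
    or <- orient_record(rec, 15L, 6L)
    purrr::map_dfr(c("+", "-"), function(strand) {
      s <- if (strand == "+") or$fwd else or$rev
      m <- gregexpr(pat, s, perl = TRUE)[[1]]
      if (m[1] == -1L) return(NULL)
      starts0 <- as.integer(m) - 1L
      lens <- attr(m, "match.length")
      seqs <- substring(s, starts0 + 1L, starts0 + lens)
      fstart0 <- if (strand == "+") starts0 else or$next_len - (starts0 + lens)
      keep <- fstart0 >= 0L & fstart0 < or$n
      if (!any(keep)) return(NULL)
      parts <- purrr::map_dfr(seqs[keep], parse_tmeco)
      dplyr::bind_cols(
        tibble::tibble(record_id = rec$id,
                       start = fstart0[keep] + 1L,
                       end = fstart0[keep] + lens[keep],
                       strand = strand,
                       length = lens[keep]),
        parts
      )
    })
  })
  if (nrow(hits) == 0L) {
    hits <- tibble::tibble(
      record_id = character(), start = integer(), end = integer(),
      strand = character(), length = integer(), stemA = character(),
      loop1 = character(), stemB = character(), loop2 = character(),
      stemC = character(), tail = character()
    )
  }
  hits <- classify_tmeco(hits)
  hits <- dplyr::arrange(hits, .data$record_id, .data$start)
  new_hits(hits, genomes, "tmeco_hits")
}

#' Parse one TM sequence into its parts
#'
#' Decomposes a string that is exactly one TM consensus match into the five
#' stem/loop parts plus tail. Ties between a longer first loop plus tail and
#' a shorter tail-less reading are broken toward the shortest first loop.
#'
#' @param seq A DNA string matching the TM consensus end to end.
#' @return A one-row tibble with columns `stemA`, `loop1`, `stemB`, `loop2`,
#'   `stemC`, `tail` (empty string when absent), whose concatenation is `seq`.
#' @export
parse_tmeco <- function(seq) {
  assert_dna(seq)
  m <- regmatches(seq, regexec(paste0("^", tmeco_pattern(), "$"), seq,
                               perl = TRUE))[[1]]
  if (length(m) == 0L) {
    stop("sequence does not match the TM consensus: ", seq, call. = FALSE)
  }
  loop1 <- m[2]; loop2 <- m[3]; tail <- m[4]
  l1 <- nchar(loop1)
  tibble::tibble(
    stemA = substr(seq, 1L, 9L),
    loop1 = loop1,
    stemB = substr(seq, 10L + l1, 18L + l1),
    loop2 = loop2,
    stemC = substr(seq, 22L + l1, 30L + l1),
    tail = tail
  )
}

#' Classify TM motifs: type and mismatch count
#'
#' Adds `tm_type`, `mismatches` and `type_label` to a tibble of parsed TM
#' parts. Type follows the last base of the second loop (`A` -> type A,
#' `G` -> type B, otherwise `unassigned`). A stack position `k` (0-8) carries
#' the triad `(stemA[k], stemB[8-k], stemC[k])`; it counts as a mismatch when
#' that triad is not a valid triad of *any* intrastrand triplex class
#' ([triplet_table()]). The canonical TM stack is all class II (`C-G-G`,
#' `T-A-A`, `T-A-T`), but a triad of another class (such as `T-T-A`, the very
#' triad that types a type A motif) is a formable triple and does not count
#' as mismatched; this rule reproduces the annotated types of all 23 E. coli
#' K-12 MG1655 motifs ([tmeco_reference()]).
#'
#' @param parts A tibble with columns `stemA`, `stemB`, `stemC`, `loop2`
#'   (e.g. from [parse_tmeco()] or [find_tmeco()]).
#' @return `parts` with `tm_type` (`"A"`, `"B"` or `"unassigned"`),
#'   `mismatches` (0-9) and `type_label` (e.g. `"A mm"`) appended.
#' @export
classify_tmeco <- function(parts) {
  stopifnot(is.data.frame(parts),
            all(c("stemA", "stemB", "stemC", "loop2") %in% names(parts)))
  n <- nrow(parts)
  if (n == 0L) {
    return(dplyr::mutate(parts, tm_type = character(), mismatches = integer(),
                         type_label = character()))
  }
  last2 <- substr(parts$loop2, 3L, 3L)
  tm_type <- dplyr::case_when(last2 == "A" ~ "A",
                              last2 == "G" ~ "B",
                              TRUE ~ "unassigned")
  mm <- vapply(seq_len(n), function(i) {
    tm_stack_mismatches(parts$stemA[i], parts$stemB[i], parts$stemC[i])
  }, integer(1))
  dplyr::mutate(parts, tm_type = tm_type, mismatches = mm,
                type_label = paste0(tm_type, ifelse(mm >= 1L, " mm", "")))
}

# number of stack positions whose triad is valid in no class
tm_stack_mismatches <- function(stemA, stemB, stemC) {
  a <- strsplit(stemA, "", fixed = TRUE)[[1]]
  b <- rev(strsplit(stemB, "", fixed = TRUE)[[1]])
  c_ <- strsplit(stemC, "", fixed = TRUE)[[1]]
  stopifnot(length(a) == 9L, length(b) == 9L, length(c_) == 9L)
  tab <- triplet_table()
  triads <- paste0(a, b, c_)
  sum(!(triads %in% paste0(tab$a, tab$b, tab$c)))
}

#' Pair inverted-repeat TM motifs
#'
#' Detects tandem TM motifs in inverted-repeat configuration: one motif on
#' the forward and one on the reverse strand, close together. Hits are taken
#' in genomic order and paired greedily left to right; two adjacent hits pair
#' when they lie on opposite strands of the same record and the gap between
#' the inner motif ends is at most `max_gap`. Each hit joins at most one pair.
#'
#' @param hits A `tmeco_hits` tibble (or any tibble with `record_id`,
#'   `start`, `end`, `strand`; an optional `no` column is used as the hit
#'   identifier, otherwise genomic rank is used).
#' @param max_gap Maximum number of nucleotides between the inner ends
#'   (default 200; the known E. coli pairs lie 16-59 nt apart).
#' @return A tibble with one row per pair: `record_id`, `no1`, `no2`,
#'   `start1`, `end1`, `strand1`, `start2`, `end2`, `strand2`, `gap`, and the
#'   two `tm_type`s when present.
#' @export
find_inverted_pairs <- function(hits, max_gap = 200L) {
  stopifnot(is.data.frame(hits),
            all(c("record_id", "start", "end", "strand") %in% names(hits)))
  hits <- dplyr::arrange(tibble::as_tibble(hits), .data$record_id, .data$start)
  ids <- if ("no" %in% names(hits)) hits$no else seq_len(nrow(hits))
  types <- if ("tm_type" %in% names(hits)) hits$tm_type else NA_character_
  types <- rep_len(types, nrow(hits))
  used <- logical(nrow(hits))
  rows <- list()
  i <- 1L
  while (i < nrow(hits)) {
    j <- i + 1L
    gap <- hits$start[j] - hits$end[i] - 1L
    if (!used[i] && !used[j] &&
        hits$record_id[i] == hits$record_id[j] &&
        hits$strand[i] != hits$strand[j] &&
        gap <= max_gap) {
      used[i] <- used[j] <- TRUE
      rows[[length(rows) + 1L]] <- tibble::tibble(
        record_id = hits$record_id[i],
        no1 = ids[i], no2 = ids[j],
        start1 = hits$start[i], end1 = hits$end[i], strand1 = hits$strand[i],
        start2 = hits$start[j], end2 = hits$end[j], strand2 = hits$strand[j],
        gap = gap,
        tm_type1 = types[i], tm_type2 = types[j]
      )
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      record_id = character(), no1 = integer(), no2 = integer(),
      start1 = integer(), end1 = integer(), strand1 = character(),
      start2 = integer(), end2 = integer(), strand2 = character(),
      gap = integer(), tm_type1 = character(), tm_type2 = character()
    ))
  }
  dplyr::bind_rows(rows)
}

#' The 23 annotated TM motifs of E. coli K-12 MG1655
#'
#' Returns the packaged reference set of the 23 TM motif occurrences in the
#' *E. coli* K-12 MG1655 chromosome: sequence, length, annotated type label
#' (`A`, `B`, with `" mm"` for mismatched stacks), genomic interval
#' (1-based, `start < end`), map position in minutes, and strand.
#'
#' @return A tibble with 23 rows and columns `no`, `sequence`, `length`,
#'   `type`, `start`, `end`, `minutes`, `strand`.
#' @export
tmeco_reference <- function() {
  path <- system.file("extdata", "tmeco_mg1655.tsv", package = "intriplex",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    no = readr::col_integer(),
    sequence = readr::col_character(),
    length = readr::col_integer(),
    type = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    minutes = readr::col_double(),
    strand = readr::col_character()
  ))
}

#' Write TM hits in the reference annotation layout
#'
#' @param hits A `tmeco_hits` tibble.
#' @param path Output path.
#' @param genome_length Optional genome length used to add the map position
#'   in minutes (`round(start / genome_length * 100 * 2) / 2`).
#' @return `path`, invisibly.
#' @export
write_tmeco_tsv <- function(hits, path, genome_length = NULL) {
  out <- tibble::tibble(
    no = seq_len(nrow(hits)),
    sequence = paste0(hits$stemA, hits$loop1, hits$stemB, hits$loop2,
                      hits$stemC, hits$tail),
    length = hits$length,
    type = hits$type_label,
    genome_localization = paste0(hits$start, "-", hits$end),
    strand = hits$strand
  )
  if (!is.null(genome_length)) {
    out$minutes <- round(hits$start / genome_length * 100 * 2) / 2
  }
  readr::write_tsv(out, path)
  invisible(path)
}
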