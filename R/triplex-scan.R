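#' Scan genomes for intrastrand triplex motifs
#'
#' Enumerates every candidate intrastrand triplex over the records of a genome
#' tibble: three stems of equal length `L` (`min_stem <= L <= max_stem`)
#' separated by two loops of `min_loop` to `max_loop` arbitrary nucleotides,
#' where at each stack position `k` the triad `(stemA[k], stemB[L-1-k],
#' stemC[k])` must belong to the triad set of the class ([triplet_table()]).
#' At most one stack position may violate the set when `L >= 7`
#' (`mismatch = TRUE`); stems of length 6 must be perfect. Both fold-backs are
#' antiparallel, so stemB is read 3'->5' against stemA and stemC.
#'
#' The reverse strand is scanned on the reverse complement and hits are mapped
#' back to forward-strand coordinates. Circular records are scanned on a
#' circularised sequence ([circular_extend()]); origin-spanning hits are
#' reported once, with `start <= length` and `end` possibly exceeding the
#' genome length.
#'
#' @param genomes Genome tibble ([read_genome_fasta()], [gen_genome()]).
#' @param min_stem,max_stem Stem length range (defaults 6 and 15).
#' @param min_loop,max_loop Loop length range (defaults 1 and 6).
#' @param classes Subset of `c("I","II","III","IV")`; default all four.
#' @param strands Subset of `c("+","-")`; default both.
#' @param mismatch Allow one mismatched stack position for stems of 7 nt or
#'   longer (default `TRUE`). `FALSE` requires perfect stems at all lengths.
#' @param collapse `"all"` (default) reports one row per qualifying
#'   `(anchor, stem, loop1, loop2)` tuple; `"leftmost_longest"` keeps one
#'   representative per cluster of overlapping same-class same-strand hits
#'   (see [collapse_hits()]).
#' @return A tibble of class `triplex_hits`, one row per hit, with 1-based
#'   inclusive forward-strand `start`/`end`, `strand`, `class`, `stem_len`,
#'   `loop1_len`, `loop2_len`, `mismatches`, the five motif-strand parts
#'   `stemA`, `loop1`, `stemB`, `loop2`, `stemC`, and `stem_gc` (G+C fraction
#'   over the 3L stem positions).
#' @examples
#' g <- gen_genome(600, gc = 0.6, seed = 1)
#' find_triplexes(g, classes = "II")
#' @export
find_triplexes <- function(genomes,
                           min_stem = 6L, max_stem = 15L,
                           min_loop = 1L, max_loop = 6L,
                           classes = c("I", "II", "III", "IV"),
                           strands = c("+", "-"),
                           mismatch = TRUE,
                           collapse = c("all", "leftmost_longest")) {
  collapse <- match.arg(collapse)
  classes <- match_classes(classes)
  strands <- match.arg(strands, c("+", "-"), several.ok = TRUE)
  check_scan_params(min_stem, max_stem, min_loop, max_loop)
  genomes <- as_genome_tbl(genomes)

  valid <- triad_lookup()
  hits <- purrr::map_dfr(seq_len(nrow(genomes)), function(i) {
    rec <- genomes[i, ]
    or <- orient_record(rec, max_stem, max_loop)
    purrr::map_dfr(strands, function(strand) {
      s <- if (strand == "+") or$fwd else or$rev
      codes <- encode_dna(s)
      limit <- if (strand == "+") or$limit else nchar(s)
      purrr::map_dfr(classes, function(cl) {
        raw <- scan_triplexes_cpp(codes, valid, match(cl, TRIPLEX_CLASSES),
                                  as.integer(min_stem), as.integer(max_stem),
                                  as.integer(min_loop), as.integer(max_loop),
                                  isTRUE(mismatch), as.integer(limit))
        triplex_rows(raw, s, strand, cl, rec$id, or)
      })
    })
  })
  hits <- finish_hits(hits, triplex_hit_cols())
  hits <- dplyr::arrange(hits, .data$record_id, .data$start, .data$class,
                         .data$strand, .data$stem_len)
  hits <- new_hits(hits, genomes, "triplex_hits")
  if (collapse == "leftmost_longest") hits <- collapse_hits(hits, collapse)
  hits
}

#' Scan genomes for hairpins (inverted repeats)
#'
#' Finds stem-loop structures whose two arms are reverse-complementary at all
#' but at most `max_mismatch` stem positions. The defaults (9-15 nt stem,
#' 1-6 nt loop, one mismatch) match the triplex motif geometry, so the hairpin
#' scan serves as the Watson-Crick-only control for the triplex scan: a locus
#' effect specific to triplexes should not reproduce at plain hairpins.
#' Hairpins are strand-symmetric, so only the forward strand is scanned.
#'
#' @inheritParams find_triplexes
#' @param max_mismatch Maximum number of non-pairing stem positions
#'   (default 1).
#' @return A tibble of class `hairpin_hits` with 1-based inclusive
#'   `start`/`end`, `stem_len`, `loop_len`, `mismatches` and the parts `arm1`,
#'   `loop`, `arm2`.
#' @export
find_hairpins <- function(genomes,
                          min_stem = 9L, max_stem = 15L,
                          min_loop = 1L, max_loop = 6L,
                          max_mismatch = 1L,
                          collapse = c("all", "leftmost_longest")) {
  collapse <- match.arg(collapse)
  stopifnot(min_stem >= 2L, min_stem <= max_stem,
            min_loop >= 1L, min_loop <= max_loop, max_mismatch >= 0L)
  genomes <- as_genome_tbl(genomes)
  hits <- purrr::map_dfr(seq_len(nrow(genomes)), function(i) {
    rec <- genomes[i, ]
    or <- orient_record(rec, max_stem, max_loop)
    raw <- scan_hairpins_cpp(encode_dna(or$fwd), as.integer(min_stem),
                             as.integer(max_stem), as.integer(min_loop),
                             as.integer(max_loop), as.integer(max_mismatch),
                             as.integer(or$limit))
    if (nrow(raw) == 0L) return(NULL)
    width <- 2L * raw$stem_len + raw$loop_len
    tibble::tibble(
      record_id = rec$id,
      start = raw$start0 + 1L,
      end = raw$start0 + width,
      stem_len = raw$stem_len,
      loop_len = raw$loop_len,
      mismatches = raw$mismatches,
      arm1 = substring(or$fwd, start, start + raw$stem_len - 1L),
      loop = substring(or$fwd, start + raw$stem_len, start + raw$stem_len +
                         raw$loop_len - 1L),
      arm2 = substring(or$fwd, end - raw$stem_len + 1L, end)
    )
  })
  hits <- finish_hits(hits, hairpin_hit_cols())
  hits <- dplyr::arrange(hits, .data$record_id, .data$start, .data$stem_len)
  hits <- new_hits(hits, genomes, "hairpin_hits")
  if (collapse == "leftmost_longest") hits <- collapse_hits(hits, collapse)
  hits
}

#' Collapse overlapping hits to one representative
#'
#' Clusters mutually overlapping hits of the same record, class (for triplex
#' hits) and strand, and keeps one representative per cluster: smallest
#' `start`, then largest `stem_len`, then smallest `loop1_len`, then smallest
#' `loop2_len`. For circular records, overlap across the origin joins
#' clusters, so the collapsed hit count does not depend on where the sequence
#' was linearised. `policy = "all"` returns the input unchanged.
#'
#' @param hits A `triplex_hits` or `hairpin_hits` tibble.
#' @param policy `"all"` or `"leftmost_longest"`.
#' @return A tibble of the same class, sorted by `(record_id, start)`.
#' @export
collapse_hits <- function(hits, policy = c("leftmost_longest", "all")) {
  policy <- match.arg(policy)
  if (policy == "all" || nrow(hits) == 0L) return(hits)
  genomes <- attr(hits, "genomes")
  keys <- intersect(c("record_id", "class", "strand"), names(hits))
  groups <- dplyr::group_split(dplyr::group_by(hits,
                                               dplyr::across(dplyr::all_of(keys))))
  out <- purrr::map_dfr(groups, function(g) {
    rec <- g$record_id[1]
    glen <- NULL
    if (!is.null(genomes)) {
      j <- match(rec, genomes$id)
      if (!is.na(j) && isTRUE(genomes$circular[j])) glen <- genomes$length[j]
    }
    comp <- overlap_components(g$start, g$end, glen)
    reps <- dplyr::group_by(dplyr::mutate(g, .comp = comp), .data$.comp)
    if ("loop1_len" %in% names(g)) {
      reps <- dplyr::arrange(reps, .data$start, dplyr::desc(.data$stem_len),
                             .data$loop1_len, .data$loop2_len, .by_group = TRUE)
    } else {
      reps <- dplyr::arrange(reps, .data$start, dplyr::desc(.data$stem_len),
                             .data$loop_len, .by_group = TRUE)
    }
    dplyr::select(dplyr::ungroup(dplyr::slice_head(reps, n = 1L)), -".comp")
  })
  out <- dplyr::arrange(out, .data$record_id, .data$start)
  cls <- class(hits)
  attrs <- attributes(hits)
  out <- tibble::new_tibble(out, class = setdiff(cls, class(tibble::tibble())))
  attr(out, "genomes") <- genomes
  out
}

# Connected components of the interval overlap graph (1-based inclusive
# intervals, pre-sorted or not). If glen is given the intervals live on a
# circle of that length: ends beyond glen wrap and may join the components
# near the start.
overlap_components <- function(start, end, glen = NULL) {
  ord <- order(start, end)
  comp <- integer(length(start))
  cur <- 0L
  max_end <- -Inf
  for (i in ord) {
    if (start[i] > max_end) cur <- cur + 1L
    comp[i] <- cur
    max_end <- max(max_end, end[i])
  }
  if (!is.null(glen)) {
    # union components joined by wrap-around overlap
    parent <- seq_len(cur)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    wraps <- which(end > glen)
    for (i in wraps) {
      tail_end <- end[i] - glen
      touching <- which(start <= tail_end & seq_along(start) != i)
      for (j in touching) {
        a <- find(comp[i]); b <- find(comp[j])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
    comp <- vapply(comp, find, integer(1))
  }
  match(comp, unique(comp[ord]))
}

# -- internal helpers ---------------------------------------------------------

check_scan_params <- function(min_stem, max_stem, min_loop, max_loop) {
  if (!(min_stem >= 6L && min_stem <= max_stem)) {
    stop("stem range must satisfy 6 <= min_stem <= max_stem", call. = FALSE)
  }
  if (!(min_loop >= 1L && min_loop <= max_loop)) {
    stop("loop range must satisfy 1 <= min_loop <= max_loop", call. = FALSE)
  }
  invisible(TRUE)
}

as_genome_tbl <- function(genomes) {
  if (is.character(genomes) && length(genomes) == 1L && file.exists(genomes)) {
    genomes <- read_genome_fasta(genomes)
  }
  stopifnot(is.data.frame(genomes), all(c("id", "seq") %in% names(genomes)))
  if (!"circular" %in% names(genomes)) genomes$circular <- FALSE
  if (!"length" %in% names(genomes)) genomes$length <- nchar(genomes$seq)
  tibble::as_tibble(genomes)
}

# Prepare the scanning strings for one record: the (possibly circularised)
# forward string, its reverse complement, and the anchor limit that makes the
# forward scan report each circular motif exactly once.
orient_record <- function(rec, max_stem, max_loop) {
  n <- nchar(rec$seq)
  pad <- 3L * as.integer(max_stem) + 2L * as.integer(max_loop)
  if (isTRUE(rec$circular) && n >= pad) {
    fwd <- circular_extend(rec$seq, max_stem, max_loop)
    limit <- n
  } else {
    if (isTRUE(rec$circular) && n < pad) {
      warning("record ", rec$id, " is shorter than the circular padding (",
              pad, " nt); scanning as linear", call. = FALSE)
    }
    fwd <- rec$seq
    limit <- n
  }
  list(fwd = fwd, rev = reverse_complement(fwd), n = n,
       next_len = nchar(fwd), limit = limit)
}

# Turn the raw per-class scan table into user-facing rows on one strand.
triplex_rows <- function(raw, s, strand, cl, record_id, or) {
  if (nrow(raw) == 0L) return(NULL)
  L <- raw$stem_len
  l1 <- raw$loop1_len
  l2 <- raw$loop2_len
  width <- 3L * L + l1 + l2
  p <- raw$start0 + 1L                     # 1-based in the scanned string
  stemA <- substring(s, p, p + L - 1L)
  loop1 <- substring(s, p + L, p + L + l1 - 1L)
  stemB <- substring(s, p + L + l1, p + 2L * L + l1 - 1L)
  loop2 <- substring(s, p + 2L * L + l1, p + 2L * L + l1 + l2 - 1L)
  stemC <- substring(s, p + 2L * L + l1 + l2, p + width - 1L)
  stems <- paste0(stemA, stemB, stemC)
  gc <- (nchar(stems) - nchar(gsub("[GC]", "", stems))) / nchar(stems)
  if (strand == "+") {
    fstart0 <- raw$start0
  } else {
    fstart0 <- or$next_len - (raw$start0 + width)
  }
  keep <- fstart0 < or$n & fstart0 >= 0L
  tibble::tibble(
    record_id = record_id,
    start = fstart0 + 1L,
    end = fstart0 + width,
    strand = strand,
    class = cl,
    stem_len = L,
    loop1_len = l1,
    loop2_len = l2,
    mismatches = raw$mismatches,
    stemA = stemA, loop1 = loop1, stemB = stemB, loop2 = loop2, stemC = stemC,
    stem_gc = gc
  )[keep, ]
}

triplex_hit_cols <- function() {
  c(record_id = "character", start = "integer", end = "integer",
    strand = "character", class = "character", stem_len = "integer",
    loop1_len = "integer", loop2_len = "integer", mismatches = "integer",
    stemA = "character", loop1 = "character", stemB = "character",
    loop2 = "character", stemC = "character", stem_gc = "double")
}

hairpin_hit_cols <- function() {
  c(record_id = "character", start = "integer", end = "integer",
    stem_len = "integer", loop_len = "integer", mismatches = "integer",
    arm1 = "character", loop = "character", arm2 = "character")
}

finish_hits <- function(hits, cols) {
  if (is.null(hits) || nrow(hits) == 0L) {
    hits <- tibble::as_tibble(lapply(cols, function(t) vector(t, 0L)))
  }
  hits
}

new_hits <- function(hits, genomes, subclass) {
  out <- tibble::new_tibble(tibble::as_tibble(hits), class = subclass)
  attr(out, "genomes") <- genomes[, c("id", "length", "circular")]
  out
}

#' Write triplex hits as TSV
#'
#' One row per hit with the fields of the scan report: 1-based location,
#' type (class), stem size, the two loop sizes, strand, the five motif parts
#' and the mismatch count.
#'
#' @param hits A `triplex_hits` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- tibble::tibble(
    record = hits$record_id,
    location = hits$start,
    type = hits$class,
    stem_size = hits$stem_len,
    loop1_size = hits$loop1_len,
    loop2_size = hits$loop2_len,
    strand = hits$strand,
    stemA = hits$stemA, loop1 = hits$loop1, stemB = hits$stemB,
    loop2 = hits$loop2, stemC = hits$stemC,
    mismatches = hits$mismatches
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write hits as BED6
#'
#' 0-based half-open intervals; `name` is the triplex class, `score` the stem
#' length.
#'
#' @inheritParams write_hits_tsv
#' @export
write_hits_bed <- function(hits, path) {
  strand <- if ("strand" %in% names(hits)) hits$strand else "+"
  name <- if ("class" %in% names(hits)) hits$class else "hairpin"
  out <- tibble::tibble(
    chrom = hits$record_id,
    chromStart = hits$start - 1L,
    chromEnd = hits$end,
    name = name,
    score = hits$stem_len,
    strand = strand
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
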