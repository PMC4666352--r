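#' Read genome or plasmid sequences from FASTA
#'
#' Reads a (multi-record) FASTA file into a tibble of genome records, the unit
#' every scan in this package operates on. Sequences are uppercased and any
#' character outside `A`, `C`, `G`, `T` is mapped to `N`; `N` never takes part
#' in a base pair or triplet, so ambiguity codes cannot create spurious motifs.
#' `U` is rejected rather than converted: the scanners are DNA-motif tools and
#' purine-motif triplexes do not form in RNA.
#'
#' @param path Path to a FASTA file.
#' @param circular Logical, recycled over records. Bacterial chromosomes and
#'   plasmids are circular; scans on circular records run on a circularised
#'   sequence (see [circular_extend()]).
#' @return A tibble with one row per record and columns `id` (first header
#'   token), `description` (full header line), `seq` (uppercase DNA over
#'   `ACGTN`), `length`, and `circular`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr demo", "acgtACGT"), fa)
#' read_genome_fasta(fa)
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("FASTA record with empty header in ", path, call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("FASTA record with empty sequence: ",
         paste(ids[empty], collapse = ", "), call. = FALSE)
  }
  if (any(grepl("U", seqs, fixed = TRUE))) {
    stop("RNA input (U) is not supported; supply DNA sequences", call. = FALSE)
  }
  seqs <- unname(normalize_dna(seqs))
  tibble::tibble(
    id = unname(ids),
    description = unname(headers),
    seq = unname(seqs),
    length = nchar(seqs),
    circular = rep_len(circular, length(seqs))
  )
}

#' Write genome records to FASTA
#'
#' Writes the `seq` column of a genome tibble as 60-column-wrapped FASTA,
#' using `id` as the header.
#'
#' @param genomes A tibble as returned by [read_genome_fasta()] or
#'   [gen_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  stopifnot(is.data.frame(genomes), all(c("id", "seq") %in% names(genomes)))
  set <- Biostrings::DNAStringSet(genomes$seq)
  names(set) <- genomes$id
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# uppercase + collapse every non-ACGT character to N
normalize_dna <- function(seqs) {
  gsub("[^ACGT]", "N", toupper(seqs))
}

assert_dna <- function(seq, what = "seq") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single DNA string", call. = FALSE)
  }
  if (grepl("[^ACGTN]", seq)) {
    stop(what, " contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  invisible(seq)
}

#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick complement (with `N` mapping to `N`) followed by
#' reversal. Used to scan the reverse strand of a genome.
#'
#' @param seq A DNA string over `ACGTN`.
#' @return The reverse-complemented string, same length.
#' @examples
#' reverse_complement("AAAC") # "GTTT"
#' @export
reverse_complement <- function(seq) {
  assert_dna(seq)
  if (!nzchar(seq)) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Circularise a sequence for origin-spanning motif search
#'
#' Appends the first `3 * max_stem + 2 * max_loop` characters of the sequence
#' to its end, so that a scan over the result sees every motif that spans the
#' replication origin of a circular genome exactly once. The padding length is
#' the largest extent a single motif can have (three stems plus two loops).
#'
#' @param seq A DNA string.
#' @param max_stem Maximum stem length of the intended scan (default 15).
#' @param max_loop Maximum loop length of the intended scan (default 6).
#' @return The extended string of length `nchar(seq) + 3 * max_stem +
#'   2 * max_loop`. Sequences shorter than the padding cannot be circularised
#'   (wrapping more than once is not meaningful) and raise an error; scan them
#'   as linear instead.
#' @export
circular_extend <- function(seq, max_stem = 15L, max_loop = 6L) {
  assert_dna(seq)
  stopifnot(max_stem >= 6L, max_loop >= 1L)
  pad <- 3L * as.integer(max_stem) + 2L * as.integer(max_loop)
  if (nchar(seq) < pad) {
    stop("sequence shorter than circular padding (", pad,
         " nt); scan it as linear", call. = FALSE)
  }
  paste0(seq, substr(seq, 1L, pad))
}

#' Mononucleotide scramble of a sequence
#'
#' Returns a uniform random permutation of the characters of `seq`
#' (Fisher-Yates via `sample.int`), preserving length and the exact count of
#' each letter. Scrambled genomes are the null model for motif enrichment:
#' they keep the mononucleotide composition of the original while destroying
#' all higher-order sequence structure.
#'
#' @param seq A DNA string.
#' @param seed Integer seed; the permutation is deterministic per seed.
#' @return The scrambled string.
#' @export
scramble_sequence <- function(seq, seed = 1L) {
  assert_dna(seq)
  if (!nzchar(seq)) stop("cannot scramble an empty sequence", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  paste(chars[sample.int(length(chars))], collapse = "")
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
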