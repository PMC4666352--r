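#' Generate a synthetic genome with implanted motifs
#'
#' Draws an i.i.d. (order-0) background sequence with the given G+C fraction
#' — the same null model as mononucleotide scrambling — and overwrites it
#' with the requested implants. Minus-strand implants are inserted as their
#' reverse complement, so a scan recovers them on the reverse strand.
#'
#' @param length Genome length in nt.
#' @param gc Background G+C fraction; `P(G) = P(C) = gc/2`,
#'   `P(A) = P(T) = (1 - gc)/2`.
#' @param seed Integer seed; the genome is a pure function of the arguments.
#' @param implants Optional tibble/data frame with columns `motif` (DNA
#'   string), `position` (1-based start) and optionally `strand`
#'   (`"+"`/`"-"`, default `"+"`). Implants must fit and must not overlap.
#' @param id Record id (default `"synthetic"`).
#' @param circular Circularity flag for the record (default `FALSE`).
#' @return A one-row genome tibble (`id`, `description`, `seq`, `length`,
#'   `circular`).
#' @examples
#' ref <- tmeco_reference()
#' g <- gen_genome(1000, gc = 0.5, seed = 7,
#'                 implants = data.frame(motif = ref$sequence[1],
#'                                       position = 401))
#' find_tmeco(g)
#' @export
gen_genome <- function(length, gc = 0.5, seed = 1L, implants = NULL,
                       id = "synthetic", circular = FALSE) {
  stopifnot(length >= 1L, gc >= 0, gc <= 1)
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  if (!is.null(implants) && nrow(implants) > 0L) {
    implants <- tibble::as_tibble(implants)
    if (!"strand" %in% names(implants)) implants$strand <- "+"
    ends <- implants$position + nchar(implants$motif) - 1L
    if (any(implants$position < 1L) || any(ends > length)) {
      stop("implant outside the genome", call. = FALSE)
    }
    ord <- order(implants$position)
    if (any(implants$position[ord][-1] <= ends[ord][-nrow(implants)])) {
      stop("implants overlap", call. = FALSE)
    }
    for (i in seq_len(nrow(implants))) {
      motif <- normalize_dna(implants$motif[i])
      if (implants$strand[i] == "-") motif <- reverse_complement(motif)
      idx <- seq(implants$position[i], ends[i])
      chars[idx] <- strsplit(motif, "", fixed = TRUE)[[1]]
    }
  }
  tibble::tibble(
    id = id,
    description = id,
    seq = paste(chars, collapse = ""),
    length = as.integer(length),
    circular = circular
  )
}

#' Generate a TM consensus sequence of a given type and mismatch count
#'
#' Builds a random sequence matching the TM consensus ([tmeco]) whose
#' classification ([classify_tmeco()]) is exactly the requested type and
#' mismatch count. Loop nucleotides and the degenerate stem positions are
#' randomised per seed; candidates whose random loops would re-parse
#' differently are rejected and redrawn, so the round trip through
#' [parse_tmeco()] is exact by construction.
#'
#' @param tm_type `"A"` or `"B"`.
#' @param mismatches 0 or 1 mismatched stack positions.
#' @param seed Integer seed.
#' @return A DNA string (33-37 nt).
#' @export
gen_tmeco_sequence <- function(tm_type = c("A", "B"), mismatches = 0L,
                               seed = 1L) {
  tm_type <- match.arg(tm_type)
  stopifnot(mismatches %in% c(0L, 1L))
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  for (try in 1:100) {
    # canonical stack: stemA N = T, stemB N = A, stemC N in {A, T}
    xa <- if (mismatches == 1L) "G" else "T"
    xb <- sample(c("A", "T"), 1L)   # T-A-(A/T) at stack 4 stays valid
    xc <- sample(c("A", "T"), 1L)
    stemA <- paste0("CCCTC", xa, "CCC")
    stemB <- paste0("GGG", xb, "GAGGG")
    stemC <- paste0("GGG", xc, "GAGGG")
    loop1 <- paste(sample(c("A", "C", "G", "T"), sample(3:6, 1L),
                          replace = TRUE), collapse = "")
    loop2 <- paste0(paste(sample(c("A", "C", "G", "T"), 2L, replace = TRUE),
                          collapse = ""),
                    if (tm_type == "A") "A" else "G")
    tail <- sample(c("", "G", "T", "C"), 1L)
    seq <- paste0(stemA, loop1, stemB, loop2, stemC, tail)
    got <- tryCatch(classify_tmeco(parse_tmeco(seq)), error = function(e) NULL)
    if (!is.null(got) && got$tm_type == tm_type &&
        got$mismatches == mismatches &&
        got$stemA == stemA && got$loop1 == loop1) {
      return(seq)
    }
  }
  stop("failed to generate a TM sequence after 100 draws", call. = FALSE)
}

#' Generate a synthetic multiple alignment with controlled column diversity
#'
#' Emulates a realigned block of closely related genomes: outside the given
#' blocks all rows are identical; inside a block every column realises
#' exactly `states` distinct symbols (drawn from `A`, `C`, `G`, `T` and the
#' gap `-`), so the per-column state count and the windowed variability
#' statistic are known by construction.
#'
#' @param n_rows Number of aligned sequences (>= 2).
#' @param length Alignment length in columns.
#' @param blocks Optional tibble/data frame with columns `start`, `end`
#'   (1-based inclusive column interval) and `states`
#'   (`2 <= states <= min(5, n_rows)`).
#' @param seed Integer seed.
#' @return An alignment tibble with columns `id` and `seq` (equal-length
#'   strings over `ACGT-`).
#' @export
gen_alignment <- function(n_rows, length, blocks = NULL, seed = 1L) {
  stopifnot(n_rows >= 2L, length >= 1L)
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  base <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  mat <- matrix(rep(base, each = n_rows), nrow = n_rows)
  if (!is.null(blocks) && nrow(blocks) > 0L) {
    blocks <- tibble::as_tibble(blocks)
    stopifnot(all(blocks$start >= 1L), all(blocks$end <= length),
              all(blocks$start <= blocks$end))
    if (any(blocks$states > min(5L, n_rows)) || any(blocks$states < 1L)) {
      stop("states must be between 1 and min(5, n_rows)", call. = FALSE)
    }
    for (b in seq_len(nrow(blocks))) {
      s <- blocks$states[b]
      for (j in seq(blocks$start[b], blocks$end[b])) {
        symbols <- sample(c("A", "C", "G", "T", "-"), s)
        col <- c(symbols, sample(symbols, n_rows - s, replace = TRUE))
        mat[, j] <- sample(col)   # every symbol appears at least once
      }
    }
  }
  tibble::tibble(
    id = sprintf("strain_%02d", seq_len(n_rows)),
    seq = apply(mat, 1L, paste, collapse = "")
  )
}
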