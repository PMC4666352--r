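#' Read a gapped (aligned) FASTA file
#'
#' Reads a multiple alignment in aligned FASTA (gaps as `-`) into a tibble.
#' Characters outside `A`, `C`, `G`, `T`, `-` are mapped to `N` (excluded
#' from the column state count).
#'
#' @param path Path to an aligned FASTA file.
#' @return An alignment tibble with columns `id` and `seq`; at least two
#'   rows, all of equal length.
#' @export
read_alignment_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("alignment file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2L) {
    stop("an alignment needs at least two sequences", call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("[^ACGT-]", "N", seqs)
  aln <- tibble::tibble(
    id = vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L),
    seq = unname(seqs)
  )
  check_alignment(aln)
  aln
}

check_alignment <- function(alignment) {
  stopifnot(is.data.frame(alignment),
            all(c("id", "seq") %in% names(alignment)))
  if (nrow(alignment) < 2L) {
    stop("an alignment needs at least two rows", call. = FALSE)
  }
  if (length(unique(nchar(alignment$seq))) != 1L) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  invisible(alignment)
}

#' Per-column state counts of an alignment
#'
#' For each alignment column, counts the number of distinct symbols among
#' `A`, `C`, `G`, `T` and the gap `-` observed across the rows. `N`
#' (ambiguous) is excluded; a column of only `N` counts 1 by convention. A
#' fully conserved column scores 1, a maximally diverse one 5.
#'
#' @param alignment An alignment tibble (`id`, `seq`), rows of equal length.
#' @return An integer vector of length `nchar(seq)`, values in 1..5.
#' @export
column_states <- function(alignment) {
  check_alignment(alignment)
  mat <- do.call(rbind, strsplit(alignment$seq, "", fixed = TRUE))
  counts <- rowSums(matrix(vapply(c("A", "C", "G", "T", "-"), function(sym) {
    colSums(mat == sym) > 0L
  }, logical(ncol(mat))), ncol = 5L))
  pmax(as.integer(counts), 1L)
}

#' Windowed column-variability statistic
#'
#' The variability of aligned site `j` is the mean of `n_i - 1` over the
#' centred window of `l` columns, where `n_i` is the per-column state count
#' ([column_states()]):
#'
#' \deqn{v_j = \frac{1}{l} \sum_{i = j-(l-1)/2}^{j+(l-1)/2} (n_i - 1)}
#'
#' A fully conserved window scores 0; a window of maximally diverse columns
#' scores 4. Edge columns without a full window are undefined (`NA`).
#'
#' @param n Integer vector of per-column state counts, or an alignment tibble
#'   (in which case [column_states()] is applied first).
#' @param l Window length in columns; odd, >= 3 (default 11).
#' @return A tibble of class `variability_profile` with columns `column`
#'   (1-based), `n` and `v`.
#' @export
variability_profile <- function(n, l = 11L) {
  if (is.data.frame(n)) n <- column_states(n)
  stopifnot(is.numeric(n), all(n >= 1), all(n <= 5))
  l <- as.integer(l)
  if (l %% 2L == 0L || l < 3L) {
    stop("window length l must be odd and >= 3", call. = FALSE)
  }
  if (length(n) < l) {
    stop("alignment shorter than the window (", l, " columns)", call. = FALSE)
  }
  v <- as.numeric(stats::filter(n - 1, rep(1 / l, l), sides = 2))
  tibble::new_tibble(
    tibble::tibble(column = seq_along(n), n = as.integer(n), v = v),
    class = "variability_profile", window = l
  )
}

#' Call variable regions from a variability profile
#'
#' State machine over the defined `v` values: a region opens at the first
#' column of the first run of at least `run_length` consecutive columns with
#' `v > start_threshold`; it closes at the column preceding the first
#' subsequent run of at least `run_length` consecutive columns with
#' `v < end_threshold` (the closing low run lies outside the region), or at
#' the last defined column. Regions are returned in order and do not overlap.
#'
#' @param profile A `variability_profile` tibble (or any tibble with
#'   `column` and `v`).
#' @param start_threshold Opening threshold on `v` (default 0.9).
#' @param end_threshold Closing threshold on `v` (default 0.5).
#' @param run_length Required run length in columns (default 10).
#' @return A tibble with one row per region: `start`, `end` (1-based
#'   inclusive columns) and `length`.
#' @export
detect_variable_regions <- function(profile, start_threshold = 0.9,
                                    end_threshold = 0.5, run_length = 10L) {
  stopifnot(is.data.frame(profile), all(c("column", "v") %in% names(profile)))
  run_length <- as.integer(run_length)
  stopifnot(run_length >= 1L)
  def <- which(!is.na(profile$v))
  regions <- list()
  if (length(def) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          length = integer()))
  }
  v <- profile$v
  cols <- profile$column
  i <- def[1]
  last_def <- def[length(def)]
  open_at <- NA_integer_
  while (i <= last_def) {
    if (is.na(v[i])) { i <- i + 1L; next }
    if (is.na(open_at)) {
      if (v[i] > start_threshold && run_holds(v, i, run_length, last_def,
                                              function(x) x > start_threshold)) {
        open_at <- i
        i <- i + 1L
      } else {
        i <- i + 1L
      }
    } else {
      if (v[i] < end_threshold && run_holds(v, i, run_length, last_def,
                                            function(x) x < end_threshold)) {
        regions[[length(regions) + 1L]] <- c(open_at, i - 1L)
        open_at <- NA_integer_
        i <- i + run_length
      } else {
        i <- i + 1L
      }
    }
  }
  if (!is.na(open_at)) {
    regions[[length(regions) + 1L]] <- c(open_at, last_def)
  }
  if (length(regions) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          length = integer()))
  }
  out <- do.call(rbind, regions)
  tibble::tibble(start = cols[out[, 1]], end = cols[out[, 2]],
                 length = cols[out[, 2]] - cols[out[, 1]] + 1L)
}

# TRUE iff v satisfies pred at run_length consecutive defined columns
# starting at i (no NA inside the run, and the run fits before last_def + 1)
run_holds <- function(v, i, run_length, last_def, pred) {
  j <- i + run_length - 1L
  if (j > last_def) return(FALSE)
  seg <- v[i:j]
  !anyNA(seg) && all(pred(seg))
}

#' Variable length containing a focal position
#'
#' Returns, for each focal column, the length of the variable region
#' containing it (0 when the position lies in no region). Tandem motifs that
#' share one variable region naturally report the same length.
#'
#' @param regions Region tibble from [detect_variable_regions()].
#' @param positions Integer vector of focal columns.
#' @return An integer vector parallel to `positions`.
#' @export
variable_length_at <- function(regions, positions) {
  vapply(positions, function(p) {
    inside <- regions$start <= p & regions$end >= p
    if (any(inside)) regions$length[which(inside)[1]] else 0L
  }, integer(1))
}
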