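# Independent brute-force enumerations used as oracles for the compiled
# scanners. They enumerate every (stem length, loop1, loop2, stack position)
# stripe over all anchors with direct array lookups and no prefiltering --
# a different decomposition of the search space than the scanner's
# anchor-major loop.

oracle_code <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

oracle_triplexes <- function(seq, min_stem = 6L, max_stem = 15L,
                             min_loop = 1L, max_loop = 6L,
                             classes = c("I", "II", "III", "IV"),
                             strands = c("+", "-"), mismatch = TRUE) {
  tab <- triplet_table()
  res <- list()
  for (strand in strands) {
    s <- if (strand == "+") seq else reverse_complement(seq)
    x <- oracle_code[strsplit(s, "", fixed = TRUE)[[1]]]
    n <- length(x)
    for (cl in classes) {
      V <- array(FALSE, dim = c(5L, 5L, 5L))
      t2 <- tab[tab$class == cl, ]
      V[cbind(oracle_code[t2$a], oracle_code[t2$b], oracle_code[t2$c])] <- TRUE
      for (L in min_stem:max_stem) {
        allow <- if (mismatch && L >= 7L) 1L else 0L
        for (l1 in min_loop:max_loop) {
          for (l2 in min_loop:max_loop) {
            w <- 3L * L + l1 + l2
            np <- n - w + 1L
            if (np < 1L) next
            mm <- integer(np)
            p <- seq_len(np)
            for (k in 0:(L - 1L)) {
              ia <- p + k
              ib <- p + L + l1 + (L - 1L - k)
              ic <- p + 2L * L + l1 + l2 + k
              mm <- mm + !V[cbind(x[ia], x[ib], x[ic])]
            }
            keep <- which(mm <= allow)
            if (length(keep)) {
              fstart <- if (strand == "+") keep else n - (keep - 1L + w) + 1L
              res[[length(res) + 1L]] <- tibble::tibble(
                start = fstart, strand = strand, class = cl, stem_len = L,
                loop1_len = l1, loop2_len = l2, mismatches = mm[keep]
              )
            }
          }
        }
      }
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble::tibble(start = integer(), strand = character(),
                          class = character(), stem_len = integer(),
                          loop1_len = integer(), loop2_len = integer(),
                          mismatches = integer()))
  }
  dplyr::arrange(out, start, class, strand, stem_len, loop1_len, loop2_len)
}

oracle_hairpins <- function(seq, min_stem = 9L, max_stem = 15L,
                            min_loop = 1L, max_loop = 6L, max_mismatch = 1L) {
  comp <- c(A = 4L, C = 3L, G = 2L, T = 1L, N = 0L)  # code of the WC partner
  x <- oracle_code[strsplit(seq, "", fixed = TRUE)[[1]]]
  n <- length(x)
  res <- list()
  for (L in min_stem:max_stem) {
    for (l in min_loop:max_loop) {
      w <- 2L * L + l
      np <- n - w + 1L
      if (np < 1L) next
      mm <- integer(np)
      p <- seq_len(np)
      for (k in 0:(L - 1L)) {
        ia <- p + k
        ib <- p + L + l + (L - 1L - k)
        partner <- comp[names(oracle_code)[x[ia]]]
        mm <- mm + (x[ib] != partner | x[ia] == 5L)
      }
      keep <- which(mm <= max_mismatch)
      if (length(keep)) {
        res[[length(res) + 1L]] <- tibble::tibble(
          start = keep, stem_len = L, loop_len = l, mismatches = mm[keep]
        )
      }
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble::tibble(start = integer(), stem_len = integer(),
                          loop_len = integer(), mismatches = integer()))
  }
  dplyr::arrange(out, start, stem_len, loop_len)
}

# hit tables reduced to the comparable tuple columns, in canonical order
hit_tuples <- function(hits) {
  cols <- intersect(c("start", "strand", "class", "stem_len", "loop1_len",
                      "loop2_len", "loop_len", "mismatches"), names(hits))
  out <- tibble::as_tibble(as.data.frame(hits)[cols])
  dplyr::arrange(out, dplyr::across(dplyr::all_of(cols)))
}

random_dna <- function(n, gc = 0.5, seed = 1L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
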