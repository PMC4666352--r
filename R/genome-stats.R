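#' Summarise a triplex scan over one genome
#'
#' Pools the hits of one genome into the standard accounting: total count,
#' per-class counts, a stem-size histogram over the scanned range, and the
#' G/C bins — `gc50` counts hits whose stems are more than 50% G+C, `at50`
#' the rest (a stem G+C of exactly 50% bins as A/T-rich, since the G/C-rich
#' bin is defined strictly as > 50%).
#'
#' @param hits A `triplex_hits` tibble from one genome.
#' @param genome Optional one-row genome tibble; supplies `genome_id`,
#'   `genome_length` and `genome_gc` (G+C fraction over A/C/G/T positions
#'   only).
#' @return A one-row tibble: `genome_id`, `genome_length`, `genome_gc`,
#'   `total`, `class_I` .. `class_IV`, `gc50`, `at50`, and a nested
#'   `stem_hist` tibble (`stem_len`, `n`).
#' @export
summarize_hits <- function(hits, genome = NULL) {
  stopifnot(is.data.frame(hits))
  genome_id <- NA_character_
  genome_length <- NA_integer_
  genome_gc <- NA_real_
  if (!is.null(genome)) {
    stopifnot(nrow(genome) == 1L)
    genome_id <- genome$id
    genome_length <- nchar(genome$seq)
    acgt <- nchar(gsub("N", "", genome$seq, fixed = TRUE))
    gcn <- nchar(gsub("[^GC]", "", genome$seq))
    genome_gc <- if (acgt > 0L) gcn / acgt else NA_real_
    if (nrow(hits) > 0L && !all(hits$record_id == genome$id)) {
      stop("hits do not all belong to the supplied genome", call. = FALSE)
    }
  }
  cls <- vapply(TRIPLEX_CLASSES, function(cl) sum(hits$class == cl),
                integer(1))
  stems <- sort(unique(c(6:15, hits$stem_len)))
  hist <- tibble::tibble(
    stem_len = stems,
    n = vapply(stems, function(L) sum(hits$stem_len == L), integer(1))
  )
  tibble::tibble(
    genome_id = genome_id,
    genome_length = genome_length,
    genome_gc = genome_gc,
    total = nrow(hits),
    class_I = cls[["I"]], class_II = cls[["II"]],
    class_III = cls[["III"]], class_IV = cls[["IV"]],
    gc50 = sum(hits$stem_gc > 0.5),
    at50 = sum(hits$stem_gc <= 0.5),
    stem_hist = list(hist)
  )
}

#' Compare a genome scan against its mononucleotide-scrambled control
#'
#' Scans the genome and a scrambled copy ([scramble_sequence()]) with
#' identical parameters, and reports both summaries plus the
#' scrambled-to-wild-type ratios. The excess of hits in the genuine genome
#' over its scramble — especially at long stem sizes, which essentially never
#' arise by chance — is the enrichment evidence that the motifs are
#' non-random.
#'
#' @param genome A one-row genome tibble.
#' @param seed Seed for the scramble (one scramble per report).
#' @param ... Scan parameters passed to [find_triplexes()].
#' @return An object of class `triplex_comparison`: a list with elements
#'   `wt` and `scrambled` (summaries from [summarize_hits()]), `ratio_total`
#'   (scrambled total / wt total, `NA` when wt is 0), `stem_ratios` (tibble
#'   `stem_len`, `n_wt`, `n_scrambled`, `ratio`) and `class_fractions`
#'   (tibble `class`, `frac_wt`, `frac_scrambled`). Use [generics::tidy()] /
#'   [generics::glance()] or [ggplot2::autoplot()] on it.
#' @export
compare_wt_scrambled <- function(genome, seed = 1L, ...) {
  stopifnot(is.data.frame(genome), nrow(genome) == 1L)
  scr <- genome
  scr$id <- paste0(genome$id, "_scrambled")
  scr$seq <- scramble_sequence(genome$seq, seed = seed)
  wt_hits <- find_triplexes(genome, ...)
  scr_hits <- find_triplexes(scr, ...)
  wt <- summarize_hits(wt_hits, genome)
  sc <- summarize_hits(scr_hits, scr)
  stem <- dplyr::full_join(
    dplyr::rename(wt$stem_hist[[1]], n_wt = "n"),
    dplyr::rename(sc$stem_hist[[1]], n_scrambled = "n"),
    by = "stem_len"
  )
  stem$ratio <- ifelse(stem$n_wt > 0, stem$n_scrambled / stem$n_wt, NA_real_)
  fr <- tibble::tibble(
    class = TRIPLEX_CLASSES,
    frac_wt = if (wt$total > 0) {
      unlist(wt[paste0("class_", TRIPLEX_CLASSES)]) / wt$total
    } else rep(NA_real_, 4L),
    frac_scrambled = if (sc$total > 0) {
      unlist(sc[paste0("class_", TRIPLEX_CLASSES)]) / sc$total
    } else rep(NA_real_, 4L)
  )
  structure(
    list(
      wt = wt,
      scrambled = sc,
      ratio_total = if (wt$total > 0) sc$total / wt$total else NA_real_,
      stem_ratios = stem,
      class_fractions = fr,
      seed = as.integer(seed)
    ),
    class = "triplex_comparison"
  )
}

#' @export
print.triplex_comparison <- function(x, ...) {
  cat("Triplex scan: wild type vs mononucleotide scramble\n")
  cat(sprintf("  genome: %s (%d nt, G+C %.3f)\n", x$wt$genome_id,
              x$wt$genome_length, x$wt$genome_gc))
  cat(sprintf("  wild-type hits: %d   scrambled hits: %d   ratio: %s\n",
              x$wt$total, x$scrambled$total,
              ifelse(is.na(x$ratio_total), "NA",
                     sprintf("%.3f", x$ratio_total))))
  long <- x$stem_ratios[x$stem_ratios$n_wt > 0 | x$stem_ratios$n_scrambled > 0, ]
  if (nrow(long) > 0L) {
    cat("  stem-size histogram (wt / scrambled):\n")
    for (i in seq_len(nrow(long))) {
      cat(sprintf("    %2d nt: %d / %d\n", long$stem_len[i], long$n_wt[i],
                  long$n_scrambled[i]))
    }
  }
  invisible(x)
}

#' Tidy a wild-type vs scrambled comparison
#'
#' @param x A `triplex_comparison` object.
#' @param ... Unused.
#' @return A long tibble with one row per (stem size, sequence) combination:
#'   `stem_len`, `sequence` (`"wt"`/`"scrambled"`), `n`.
#' @export
tidy.triplex_comparison <- function(x, ...) {
  tidyr::pivot_longer(
    x$stem_ratios[, c("stem_len", "n_wt", "n_scrambled")],
    cols = c("n_wt", "n_scrambled"),
    names_to = "sequence", names_prefix = "n_", values_to = "n"
  )
}

#' One-row summary of a wild-type vs scrambled comparison
#'
#' @inheritParams tidy.triplex_comparison
#' @return A one-row tibble: `genome_id`, `total_wt`, `total_scrambled`,
#'   `ratio_total`, `gc50_wt`, `gc50_scrambled`, `seed`.
#' @export
glance.triplex_comparison <- function(x, ...) {
  tibble::tibble(
    genome_id = x$wt$genome_id,
    total_wt = x$wt$total,
    total_scrambled = x$scrambled$total,
    ratio_total = x$ratio_total,
    gc50_wt = x$wt$gc50,
    gc50_scrambled = x$scrambled$gc50,
    seed = x$seed
  )
}

#' Stem-size enrichment sign test over replicate scrambles
#'
#' Repeats [compare_wt_scrambled()] over several scramble seeds and tests,
#' with a one-sided sign test, whether the scrambled control carries fewer
#' hits at or above a stem-size threshold than the wild-type genome. Long
#' stems essentially never survive scrambling, so genuine long-stem motifs
#' show up as a consistent wt excess.
#'
#' @param genome A one-row genome tibble.
#' @param seeds Integer vector of scramble seeds.
#' @param min_stem_len Stem-size threshold (default 9).
#' @param ... Scan parameters passed to [find_triplexes()].
#' @return A list: `per_seed` tibble (`seed`, `n_wt`, `n_scrambled`),
#'   `successes` (seeds with scrambled < wt), `p_value` (one-sided binomial).
#' @export
scramble_sign_test <- function(genome, seeds = 1:20, min_stem_len = 9L, ...) {
  wt_hits <- find_triplexes(genome, ...)
  n_wt <- sum(wt_hits$stem_len >= min_stem_len)
  per <- purrr::map_dfr(seeds, function(s) {
    scr <- genome
    scr$id <- paste0(genome$id, "_scrambled")
    scr$seq <- scramble_sequence(genome$seq, seed = s)
    sh <- find_triplexes(scr, ...)
    tibble::tibble(seed = as.integer(s), n_wt = n_wt,
                   n_scrambled = sum(sh$stem_len >= min_stem_len))
  })
  succ <- sum(per$n_scrambled < per$n_wt)
  p <- stats::binom.test(succ, nrow(per), p = 0.5,
                         alternative = "greater")$p.value
  list(per_seed = per, successes = succ, p_value = p)
}
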