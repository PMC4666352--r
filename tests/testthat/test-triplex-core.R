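test_that("triplet tables carry the four class triad sets", {
  tab <- triplet_table()
  expect_equal(nrow(tab), 10L)
  expect_true(triplet_valid("I", "G", "G", "C"))
  expect_true(triplet_valid("II", "C", "G", "G"))
  expect_false(triplet_valid("I", "G", "G", "T"))
  expect_false(triplet_valid("II", "N", "G", "G"))
  expect_error(triplet_valid("V", "A", "A", "T"), "unknown")
  # per-class stemA alphabet is the projection of the triad set
  proj <- function(cl) sort(unique(triplet_table(cl)$a))
  expect_equal(proj("I"), c("A", "G", "T"))
  expect_equal(proj("II"), c("C", "T"))
  expect_equal(proj("III"), c("A", "G"))
  expect_equal(proj("IV"), c("C", "T"))
})

test_that("the known class II motif decomposes exactly", {
  seq <- tmeco_reference()$sequence[1]
  g <- tibble::tibble(id = "t", seq = seq, circular = FALSE)
  h <- find_triplexes(g, min_stem = 9, max_stem = 9, min_loop = 3,
                      max_loop = 3, classes = "II", strands = "+")
  expect_equal(nrow(h), 1L)
  expect_equal(h$stemA, "CCCTCTCCC")
  expect_equal(h$loop1, "TGT")
  expect_equal(h$stemB, "GGGAGAGGG")
  expect_equal(h$loop2, "CCG")
  expect_equal(h$stemC, "GGGTGAGGG")
  expect_equal(h$mismatches, 0L)
  expect_equal(h$start, 1L)
  expect_equal(h$end, 33L)
})

test_that("homopolymers yield no triplexes and no hairpins", {
  g <- tibble::tibble(id = "a", seq = strrep("A", 60), circular = FALSE)
  expect_equal(nrow(find_triplexes(g)), 0L)
  g40 <- tibble::tibble(id = "a", seq = strrep("A", 40), circular = FALSE)
  expect_equal(nrow(find_hairpins(g40)), 0L)
})

test_that("every hit reconstructs its substring and satisfies the geometry", {
  g <- gen_genome(500, gc = 0.1, seed = 21)
  h <- find_triplexes(g)
  expect_gt(nrow(h), 0L)
  expect_equal(h$end - h$start + 1L,
               3L * h$stem_len + h$loop1_len + h$loop2_len)
  motif <- paste0(h$stemA, h$loop1, h$stemB, h$loop2, h$stemC)
  fwd <- substring(g$seq, h$start, h$end)
  shown <- ifelse(h$strand == "+", fwd,
                  vapply(fwd, reverse_complement, character(1)))
  expect_equal(motif, unname(shown))
  expect_true(all(h$mismatches <= ifelse(h$stem_len >= 7, 1L, 0L)))
  stems <- paste0(h$stemA, h$stemB, h$stemC)
  expect_equal(h$stem_gc,
               unname(vapply(stems, function(s) {
                 mean(strsplit(s, "")[[1]] %in% c("G", "C"))
               }, numeric(1))))
})

test_that("scanner matches the brute-force oracle on seeded sequences", {
  ref <- tmeco_reference()
  for (seed in 1:4) {
    gc <- c(0, 0.95, 0.1, 0.5)[seed]
    s <- random_dna(450, gc = gc, seed = seed)
    motif <- ref$sequence[seed]
    substr(s, 101, 100 + nchar(motif)) <- motif
    g <- tibble::tibble(id = "r", seq = s, circular = FALSE)
    expect_identical(hit_tuples(find_triplexes(g)),
                     hit_tuples(oracle_triplexes(s)))
    expect_identical(hit_tuples(find_hairpins(g)),
                     hit_tuples(oracle_hairpins(s)))
  }
})

test_that("reverse-strand hits map back to forward coordinates", {
  motif <- make_class2_motif(stem_len = 9L)
  g <- gen_genome(300, gc = 0.2, seed = 3,
                  implants = data.frame(motif = motif, position = 101,
                                        strand = "-"))
  h <- find_triplexes(g, classes = "II", strands = "-")
  expect_true(all(h$strand == "-"))
  # the implanted decomposition itself is among the reported tuples
  exact <- h[h$start == 101 & h$end == 100 + nchar(motif) &
             h$loop1_len == 2L & h$loop2_len == 3L &
             h$stemA == substr(motif, 1, 9), ]
  expect_equal(nrow(exact), 1L)
})

test_that("tightening parameters never increases the hit count", {
  g <- gen_genome(600, gc = 0.05, seed = 9)
  full <- nrow(find_triplexes(g))
  expect_lte(nrow(find_triplexes(g, min_stem = 7, max_stem = 12)), full)
  expect_lte(nrow(find_triplexes(g, classes = c("I", "II"))), full)
  expect_lte(nrow(find_triplexes(g, mismatch = FALSE)), full)
  expect_lte(nrow(find_triplexes(g, strands = "+")), full)
  expect_lte(nrow(find_triplexes(g, max_loop = 3)), full)
})

test_that("collapse_hits keeps one representative per overlap cluster", {
  expect_equal(nrow(collapse_hits(find_triplexes(
    tibble::tibble(id = "e", seq = strrep("A", 80), circular = FALSE)))), 0L)
  # two identical-span hits differing only in the loop split
  base <- tibble::tibble(
    record_id = "x", strand = "+", class = "II",
    start = c(10L, 10L), end = c(40L, 40L), stem_len = c(8L, 8L),
    loop1_len = c(3L, 2L), loop2_len = c(4L, 5L), mismatches = 0L
  )
  kept <- collapse_hits(base, "leftmost_longest")
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$loop1_len, 2L)
  # three mutually overlapping hits plus one isolated hit -> two survivors
  four <- tibble::tibble(
    record_id = "x", strand = "+", class = "I",
    start = c(5L, 12L, 20L, 200L), end = c(30L, 38L, 45L, 230L),
    stem_len = c(7L, 8L, 6L, 9L), loop1_len = 1L, loop2_len = 1L,
    mismatches = 0L
  )
  kept4 <- collapse_hits(four, "leftmost_longest")
  expect_equal(nrow(kept4), 2L)
  expect_equal(kept4$start, c(5L, 200L))
})

test_that("mismatch-free class II hits mirror as class IV on the other strand", {
  m1 <- make_class2_motif(stem_len = 8L, taa_at = c(3L, 6L))
  m2 <- make_class2_motif(stem_len = 10L)
  g <- gen_genome(700, gc = 0.8, seed = 5,
                  implants = data.frame(motif = c(m1, m2),
                                        position = c(100, 300),
                                        strand = c("+", "-")))
  h <- find_triplexes(g)
  h2 <- h[h$class == "II" & h$mismatches == 0L, ]
  expect_gt(nrow(h2), 0L)
  n_checked <- 0L
  for (i in seq_len(nrow(h2))) {
    a <- strsplit(h2$stemA[i], "")[[1]]
    cc <- strsplit(h2$stemC[i], "")[[1]]
    if (any(a == "T" & cc == "T")) next  # T-A-T triads are exempt
    mirror <- h[h$class == "IV" & h$strand != h2$strand[i] &
                h$start == h2$start[i] & h$end == h2$end[i] &
                h$loop1_len == h2$loop2_len[i] &
                h$loop2_len == h2$loop1_len[i], ]
    expect_gte(nrow(mirror), 1L)
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 0L)
  # class I <-> class III analogue on an A/T-rich fixture (A-A-T triads)
  a <- rep("A", 8); a[4] <- "G"
  m3 <- paste0(paste(a, collapse = ""), "CC",
               paste(rev(ifelse(a == "G", "G", "A")), collapse = ""), "C",
               paste(ifelse(a == "G", "C", "T"), collapse = ""))
  g3 <- gen_genome(400, gc = 0.9, seed = 8,
                   implants = data.frame(motif = m3, position = 150))
  h3 <- find_triplexes(g3)
  h1 <- h3[h3$class == "I" & h3$mismatches == 0L, ]
  expect_gt(nrow(h1), 0L)
  for (i in seq_len(nrow(h1))) {
    a1 <- strsplit(h1$stemA[i], "")[[1]]
    c1 <- strsplit(h1$stemC[i], "")[[1]]
    if (any(a1 == "T" & c1 == "T")) next
    mirror <- h3[h3$class == "III" & h3$strand != h1$strand[i] &
                 h3$start == h1$start[i] & h3$end == h1$end[i] &
                 h3$loop1_len == h1$loop2_len[i] &
                 h3$loop2_len == h1$loop1_len[i], ]
    expect_gte(nrow(mirror), 1L)
  }
})

test_that("hairpin scan finds perfect inverted repeats and obeys the oracle", {
  g <- tibble::tibble(id = "h", seq = paste0(strrep("G", 10), "AAA",
                                             strrep("C", 10)),
                      circular = FALSE)
  h <- find_hairpins(g)
  ten <- h[h$stem_len == 10 & h$loop_len == 3, ]
  expect_equal(nrow(ten), 1L)
  expect_equal(ten$mismatches, 0L)
  expect_equal(ten$start, 1L)
  expect_equal(ten$end, 23L)
})

test_that("circular scans are invariant under sequence rotation", {
  ref <- tmeco_reference()
  base <- gen_genome(900, gc = 0.6, seed = 7)$seq
  s <- paste0(substr(base, 1, 860), ref$sequence[3],
              substr(base, 897, 900))
  expect_equal(nchar(s), 900L)
  counts <- vapply(c(0L, 123L, 456L, 880L, 899L), function(k) {
    sr <- paste0(substr(s, k + 1, 900), substr(s, 1, k))
    gr <- tibble::tibble(id = "r", seq = sr, circular = TRUE)
    c(nrow(find_triplexes(gr)),
      nrow(find_triplexes(gr, collapse = "leftmost_longest")),
      nrow(find_hairpins(gr)))
  }, integer(3))
  expect_gt(counts[1, 1], 0L)
  expect_true(all(counts == counts[, 1]))
})
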