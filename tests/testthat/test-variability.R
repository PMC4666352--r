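test_that("column_states counts distinct symbols per column", {
  aln <- tibble::tibble(id = c("a", "b", "c", "d"),
                        seq = rep("ACGTACGT", 4))
  expect_equal(column_states(aln), rep(1L, 8))
  aln5 <- tibble::tibble(id = letters[1:5],
                         seq = c("AA", "CA", "GA", "TA", "-A"))
  expect_equal(column_states(aln5), c(5L, 1L))
  # N is excluded; an all-N column counts 1 by convention
  alnN <- tibble::tibble(id = c("a", "b"), seq = c("NA", "NC"))
  expect_equal(column_states(alnN), c(1L, 2L))
  expect_error(column_states(tibble::tibble(id = c("a", "b"),
                                            seq = c("ACG", "AC"))), "unequal")
  # independent per-column recount on a random alignment
  aln_r <- gen_alignment(6, 80, blocks = data.frame(start = 21, end = 50,
                                                    states = 3), seed = 4)
  mat <- do.call(rbind, strsplit(aln_r$seq, ""))
  hand <- apply(mat, 2, function(col) {
    max(1L, length(setdiff(unique(col), "N")))
  })
  expect_equal(column_states(aln_r), unname(hand))
})

test_that("variability_profile matches the closed form", {
  # fully conserved -> 0 everywhere defined
  p0 <- variability_profile(rep(1L, 30), l = 11)
  expect_true(all(p0$v[6:25] == 0))
  expect_true(all(is.na(p0$v[c(1:5, 26:30)])))
  # single maximally diverse column -> 4/11 at the 11 covering windows
  n <- rep(1L, 31); n[16] <- 5L
  p1 <- variability_profile(n, l = 11)
  expect_equal(p1$v[11:21], rep(4 / 11, 11))
  expect_true(all(p1$v[setdiff(6:26, 11:21)] == 0))
  # maximal diversity -> upper bound 4
  p4 <- variability_profile(rep(5L, 20), l = 11)
  expect_equal(p4$v[6:15], rep(4, 10))
  expect_error(variability_profile(rep(1L, 30), l = 10), "odd")
  expect_error(variability_profile(rep(1L, 5), l = 11), "shorter")
})

test_that("variable-region state machine follows the run rules", {
  prof <- function(v) tibble::tibble(column = seq_along(v), v = v)
  expect_equal(nrow(detect_variable_regions(prof(rep(0, 50)))), 0L)
  # 30 high columns then 30 low: one region over the high block
  r <- detect_variable_regions(prof(c(rep(1, 30), rep(0, 30))))
  expect_equal(r$start, 1L)
  expect_equal(r$end, 30L)
  expect_equal(r$length, 30L)
  # alternating values never sustain a run of 10
  expect_equal(nrow(detect_variable_regions(prof(rep(c(1, 0), 30)))), 0L)
  # the closing low run is excluded; a region without a closing run extends
  # to the last defined column
  v <- c(rep(0.95, 15), rep(0.7, 10), rep(0.2, 12), rep(0.95, 14))
  r2 <- detect_variable_regions(prof(v))
  expect_equal(r2$start, c(1L, 38L))
  expect_equal(r2$end, c(25L, 51L))
  # shifting all columns shifts the regions by the same offset
  shifted <- tibble::tibble(column = seq_along(v) + 100L, v = v)
  r3 <- detect_variable_regions(shifted)
  expect_equal(r3$start, r2$start + 100L)
  expect_equal(r3$end, r2$end + 100L)
})

test_that("duplicating a row changes neither states nor regions", {
  aln <- gen_alignment(5, 200, blocks = data.frame(start = 61, end = 140,
                                                   states = 4), seed = 9)
  aln2 <- dplyr::bind_rows(aln, aln[1, ])
  expect_equal(column_states(aln2), column_states(aln))
  p1 <- variability_profile(aln)
  p2 <- variability_profile(aln2)
  expect_equal(p2$v, p1$v)
  expect_equal(detect_variable_regions(p2), detect_variable_regions(p1))
})

test_that("variable length is larger at diverse blocks than conserved flanks", {
  aln <- gen_alignment(8, 300, blocks = data.frame(start = 101, end = 180,
                                                   states = 3), seed = 12)
  prof <- variability_profile(aln)
  regions <- detect_variable_regions(prof)
  expect_gte(nrow(regions), 1L)
  at_motif <- variable_length_at(regions, 140L)
  at_flank <- variable_length_at(regions, 30L)
  expect_gt(at_motif, 0L)
  expect_equal(at_flank, 0L)
})

test_that("locus categorisation follows the coverage rules", {
  seg <- function(qstart, qend, pident) {
    tibble::tibble(qstart = qstart, qend = qend, pident = pident)
  }
  # full high-identity coverage
  expect_equal(categorize_locus(seg(1, 1000, 100), 1000, 480, 515)$category,
               "no_change")
  # no segments at all
  none <- categorize_locus(seg(1, 1, 100)[0, ], 1000, 480, 515)
  expect_equal(none$category, "no_homology")
  # central 400-nt gap spanning the motif
  rm <- categorize_locus(seg(c(1, 701), c(300, 1000), c(100, 100)),
                         1000, 480, 515)
  expect_equal(rm$category, "region_missing")
  expect_equal(rm$subcategory, "tm_missing")
  # covered motif below 100% identity, losses confined to the intergenic
  ic <- categorize_locus(seg(c(1, 450, 601), c(449, 560, 1000),
                             c(100, 95, 100)),
                         1000, 480, 515,
                         intergenic_start = 400, intergenic_end = 620)
  expect_equal(ic$category, "intergenic_change")
  expect_equal(ic$subcategory, "tm_mutated")
  # without the intergenic interval the same locus cannot be assigned there
  expect_warning(
    fallback <- categorize_locus(seg(c(1, 450, 601), c(449, 560, 1000),
                                     c(100, 95, 100)), 1000, 480, 515),
    "intergenic"
  )
  expect_equal(fallback$category, "no_change")
})

test_that("removing homology segments only moves loci toward no_homology", {
  rank <- c(no_change = 1, intergenic_change = 2, region_missing = 3,
            no_homology = 4)
  segs <- tibble::tibble(qstart = c(1, 350, 800), qend = c(340, 790, 1000),
                         pident = c(100, 98, 100))
  subsets <- list(segs, segs[-2, ], segs[-c(2, 3), ], segs[0, ])
  cats <- vapply(subsets, function(s) {
    categorize_locus(s, 1000, 500, 535, intergenic_start = 300,
                     intergenic_end = 850)$category
  }, character(1))
  expect_true(all(diff(rank[cats]) >= 0))
})

test_that("alignment, BLAST tabular and BED readers honour the contracts", {
  afa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGT-ACGT", ">s2", "ACGTTACGT"), afa)
  aln <- read_alignment_fasta(afa)
  expect_equal(nrow(aln), 2L)
  expect_equal(column_states(aln), c(1L, 1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L))

  bl <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("q1", "s1", "98.5", "500", "6", "1", "11", "510",
                     "1001", "1500", "1e-50", "900"), collapse = "\t"), bl)
  seg <- read_blast_tab(bl)
  expect_equal(seg$qstart, 11L)
  expect_equal(seg$qend, 510L)
  expect_equal(seg$pident, 98.5)
  expect_equal(ncol(seg), 12L)

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tgeneA\t0\t+", "chr1\t500\t900\tgeneB\t0\t-"),
             bed)
  iv <- read_bed_intervals(bed)
  expect_equal(iv$start, c(1L, 501L))   # 1-based inclusive
  expect_equal(iv$end, c(100L, 900L))
  expect_equal(iv$name, c("geneA", "geneB"))
})
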