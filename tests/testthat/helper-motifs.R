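# Construct class II motifs triad by triad, so tests know the exact stack
# composition. `taa_at` gives the stack positions carrying the T-A-A triad;
# all others are C-G-G. Loops are fixed non-pairing spacers.
make_class2_motif <- function(stem_len = 8L, taa_at = integer(),
                              loop1 = "AC", loop2 = "TGA") {
  a <- rep("C", stem_len); b <- rep("G", stem_len); c_ <- rep("G", stem_len)
  a[taa_at] <- "T"; b[taa_at] <- "A"; c_[taa_at] <- "A"
  paste0(paste(a, collapse = ""), loop1,
         paste(rev(b), collapse = ""), loop2,
         paste(c_, collapse = ""))
}
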