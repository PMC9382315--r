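# Shared helpers: tiny alignments written to temp files, and an
# independently coded brute-force evaluation of the information-content
# equations used as an oracle against the vectorized implementation.

write_temp_fasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

temp_fasta_from_seqs <- function(seqs, ids = paste0("s", seq_along(seqs))) {
  write_temp_fasta(as.vector(rbind(paste0(">", ids), seqs)))
}

# Literal, loop-based evaluation of H, Rseq and the heights for one
# probability row; deliberately independent of the package's code path.
oracle_row <- function(p, smax) {
  H <- 0
  for (x in p) if (x > 0) H <- H - x * log2(x)
  rseq <- smax - H
  heights <- numeric(length(p))
  for (i in seq_along(p)) heights[i] <- p[i] * rseq
  list(H = H, Rseq = rseq, heights = heights)
}

# An alignment with one fully conserved position, one 3:1 split and one
# 50/50 split; 4 sequences.
small_alignment <- function() {
  codon_alignment(c("ATGAAATTT",
                    "ATGAAATTT",
                    "ATGAAAGGG",
                    "ATGAATGGG"),
                  ids = c("a", "b", "c", "d"))
}
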