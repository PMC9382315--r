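# Position x codon matrices and their information-content transform.
#
# The model is the classic sequence-logo one, applied to triplets instead of
# single residues: at codon position l the observed entropy is
#   H(l) = -sum_n f(n,l) log2 f(n,l)
# and the information content (stack height) is
#   Rseq(l) = Smax - H(l),   Smax = log2(N)
# with N the number of symbols the alphabet could show (64 plain codons, or
# 15^3 = 3375 once IUPAC-ambiguous codons are admitted).  A codon's glyph
# height is Height(n,l) = f(n,l) * Rseq(l).

AMBIG_REGEX <- "[RYSWKMBDHVN]"

#' Split a sequence into frame-0 codons
#'
#' Non-overlapping triplets starting at the first nucleotide. Triplets that
#' contain a gap character are returned as `NA` and are excluded from codon
#' counting downstream.
#'
#' @param sequence a single sequence string whose length is a multiple of 3.
#' @return character vector of codons, with `NA` for gap-containing triplets;
#'   `character(0)` for the empty string.
#' @examples
#' tokenize_codons("ATGAAATGA")
#' tokenize_codons("ATG---AAA")
#' @export
tokenize_codons <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (n %% 3L != 0L)
    cl_stop(sprintf("sequence length %d is not a multiple of 3", n), "frame")
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(sequence, starts, starts + 2L)
  codons[grepl("-", codons, fixed = TRUE)] <- NA_character_
  codons
}

#' Count codons per alignment position
#'
#' Builds the positions x codons integer count matrix. Columns are all codons
#' observed anywhere in the alignment, in lexicographic order; gap-containing
#' triplets are not counted, so per-position depth can be below the number of
#' sequences.
#'
#' @param aln a `codon_alignment`.
#' @return a `codon_count_matrix`: integer matrix with one row per codon
#'   position (rownames are 1-based positions) and attribute `depth`, the
#'   number of counted (gap-free) codons at each position.
#' @export
count_codons <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  toks <- lapply(aln$seqs, tokenize_codons)
  n_pos <- aln$length %/% 3L
  # sequences x positions character matrix of codons (NA = gap codon)
  m <- matrix(unlist(toks), nrow = length(toks), ncol = n_pos, byrow = TRUE)
  codons <- sort(unique(as.vector(m[!is.na(m)])))
  counts <- matrix(0L, nrow = n_pos, ncol = length(codons),
                   dimnames = list(position = as.character(seq_len(n_pos)),
                                   codon = codons))
  for (l in seq_len(n_pos)) {
    tab <- table(factor(m[, l], levels = codons))
    counts[l, ] <- as.integer(tab)
  }
  structure(counts, depth = rowSums(counts),
            class = c("codon_count_matrix", class(counts)))
}

#' Convert codon counts to per-position probabilities
#'
#' Each row is divided by its depth (number of counted codons at that
#' position), so rows sum to 1. Positions where every sequence had a
#' gap-containing triplet have depth 0 and no defined distribution: by
#' default this is an error; with `drop_empty = TRUE` such rows are removed.
#'
#' @param counts a `codon_count_matrix`.
#' @param drop_empty drop zero-depth positions instead of failing.
#' @return a `codon_prob_matrix` with the same geometry (minus any dropped
#'   rows) and attribute `depth`.
#' @export
to_probability <- function(counts, drop_empty = FALSE) {
  stopifnot(inherits(counts, "codon_count_matrix"))
  depth <- attr(counts, "depth")
  if (any(depth == 0L)) {
    if (drop_empty) {
      keep <- depth > 0L
      counts <- structure(counts[keep, , drop = FALSE],
                          depth = depth[keep],
                          class = class(counts))
      depth <- depth[keep]
      if (nrow(counts) == 0L)
        cl_stop("all positions are gap-only", "degenerate_column")
    } else {
      cl_stop(sprintf(
        "position %s has no counted codons (all sequences have gaps there); use drop_empty to discard such positions",
        paste(rownames(counts)[depth == 0L], collapse = ", ")),
        "degenerate_column")
    }
  }
  prob <- unclass(counts) / depth
  structure(prob, depth = depth,
            class = c("codon_prob_matrix", "matrix", "array"))
}

#' Shannon entropy of one position's codon distribution
#'
#' `H = -sum(f * log2(f))` in bits, with `0 * log2(0)` defined as 0.
#'
#' @param prob_row numeric vector of probabilities summing to 1.
#' @return entropy in bits.
#' @examples
#' position_entropy(rep(1 / 64, 64))  # 6
#' position_entropy(c(0.75, 0.25))    # 0.8112781
#' @export
position_entropy <- function(prob_row) {
  p <- as.numeric(prob_row)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    cl_stop("probabilities must lie in [0, 1]", "contract")
  if (abs(sum(p) - 1) > 1e-6)
    cl_stop(sprintf("probabilities sum to %.9g, not 1", sum(p)), "contract")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Maximum possible entropy for an alphabet
#'
#' `Smax = log2(N)` bits for an alphabet of `N` symbols: 2 bits for the 4
#' nucleotides, about 4.32 bits for the 20 amino acids, 6 bits for the 64
#' codons, and log2(3375) ~ 11.72 bits when all 15^3 IUPAC-ambiguous triplets
#' are admitted as symbols.
#'
#' @param n_symbols number of distinct symbols (>= 2).
#' @return Smax in bits.
#' @examples
#' compute_smax(64)  # 6
#' @export
compute_smax <- function(n_symbols) {
  if (!is.numeric(n_symbols) || length(n_symbols) != 1L ||
      is.na(n_symbols) || n_symbols < 2)
    cl_stop("n_symbols must be a single number >= 2", "domain")
  log2(n_symbols)
}

#' Pick the default codon alphabet size for a matrix
#'
#' 64 when only unambiguous codons occur among the matrix columns; 3375
#' (15^3, every IUPAC triplet) as soon as any counted codon contains an
#' ambiguity code, since admitting ambiguous symbols enlarges the alphabet
#' and therefore Smax.
#'
#' @param m a `codon_count_matrix` or `codon_prob_matrix`.
#' @return the symbol count (64 or 3375).
#' @export
default_n_symbols <- function(m) {
  if (any(grepl(AMBIG_REGEX, colnames(m)))) 3375L else 64L
}

#' Transform a probability matrix into an information (bit) matrix
#'
#' For each position `l`, `Rseq(l) = smax - H(l)` and every codon's height is
#' `f(n,l) * Rseq(l)`; a row therefore sums to `Rseq(l)` and a fully
#' conserved position shows a single glyph of height `smax`.
#'
#' @param prob a `codon_prob_matrix`.
#' @param smax maximum entropy in bits; defaults to `log2(64)` or
#'   `log2(3375)` depending on whether ambiguous codons are present (see
#'   [default_n_symbols()]).
#' @return a `codon_bit_matrix` with attributes `H`, `Rseq` (per-position
#'   bits) and `smax`.
#' @export
to_bits <- function(prob, smax = compute_smax(default_n_symbols(prob))) {
  stopifnot(inherits(prob, "codon_prob_matrix"))
  H <- apply(unclass(prob), 1L, position_entropy)
  if (any(H > smax + 1e-9))
    cl_stop(sprintf(
      "observed entropy %.6f bits exceeds Smax = %.6f bits; the alphabet (n_symbols) is too small for the observed codons",
      max(H), smax), "alphabet_mismatch")
  rseq <- pmax(smax - H, 0)
  bits <- unclass(prob) * rseq
  structure(bits, depth = attr(prob, "depth"), H = H, Rseq = rseq,
            smax = smax, class = c("codon_bit_matrix", "matrix", "array"))
}

#' Write a codon matrix as CSV
#'
#' First column `position` (1-based codon index), then one column per codon
#' in the matrix's (lexicographic) column order. Values are written at full
#' double precision so the file re-reads losslessly.
#'
#' @param m a `codon_prob_matrix`, `codon_bit_matrix` or
#'   `codon_count_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m))
  header <- paste(c("position", colnames(m)), collapse = ",")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = ",")
  }, character(1))
  con <- tryCatch(file(path, "w"),
                  error = function(e) cl_stop(
                    sprintf("cannot write matrix to '%s'", path), "io"))
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read back a codon matrix CSV
#'
#' Inverse of [write_matrix()] (values only; `depth`/`H`/`Rseq` metadata are
#' not stored in the CSV).
#'
#' @param path a CSV written by [write_matrix()].
#' @return numeric matrix with positions as rownames and codons as colnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path))
    cl_stop(sprintf("cannot read matrix file '%s'", path), "io")
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  names(dimnames(m)) <- c("position", "codon")
  m
}
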