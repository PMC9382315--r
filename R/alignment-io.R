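# Reading, validating and filtering aligned protein-coding nucleotide
# sequences.  An alignment here is a strictly rectangular set of sequences
# over the IUPAC nucleotide alphabet (plus '-') whose common length is a
# multiple of three, so that codons can be taken in frame 0.

NUC_UNAMBIGUOUS <- c("A", "C", "G", "T")
NUC_AMBIGUOUS   <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
NUC_GAP         <- "-"
NUC_ALLOWED     <- c(NUC_UNAMBIGUOUS, NUC_AMBIGUOUS, NUC_GAP)

#' Signal a classed codonlogo error
#'
#' All package errors carry a subclass of `codonlogo_error` so callers (and
#' the CLI) can react to the failure kind rather than match message text.
#'
#' @param msg error message.
#' @param class error subclass, e.g. `"frame"` becomes
#'   `codonlogo_frame_error`.
#' @noRd
cl_stop <- function(msg, class) {
  stop(structure(
    class = c(paste0("codonlogo_", class, "_error"), "codonlogo_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

new_codon_alignment <- function(ids, seqs) {
  structure(
    list(ids = as.character(ids), seqs = as.character(seqs),
         length = if (length(seqs)) nchar(seqs[[1]]) else 0L),
    class = "codon_alignment"
  )
}

#' Construct a codon alignment from sequences in memory
#'
#' Validates and normalizes a set of aligned nucleotide sequences: uppercases,
#' maps RNA `U` to `T`, and enforces the rectangular / in-frame / alphabet
#' invariants used throughout the package.
#'
#' @param seqs character vector of aligned sequences (equal length, multiple
#'   of 3, IUPAC nucleotide codes and `-`).
#' @param ids character vector of identifiers; defaults to `seq1..seqN`.
#' @return a `codon_alignment` object: list with elements `ids`, `seqs` and
#'   `length` (alignment width in nucleotides).
#' @examples
#' aln <- codon_alignment(c("ATGAAA", "ATGAAG"))
#' aln$length
#' @export
codon_alignment <- function(seqs, ids = paste0("seq", seq_along(seqs))) {
  if (length(seqs) == 0L)
    cl_stop("alignment has no sequences", "empty_input")
  if (length(ids) != length(seqs))
    cl_stop("ids and seqs must have the same length", "contract")
  seqs <- chartr("u", "U", toupper(as.character(seqs)))
  seqs <- chartr("U", "T", seqs)
  bad <- gsub(sprintf("[%s]", paste(NUC_ALLOWED, collapse = "")), "", seqs)
  offender <- which(nchar(bad) > 0L)
  if (length(offender)) {
    cl_stop(sprintf(
      "record '%s' contains disallowed character '%s' (allowed: IUPAC nucleotide codes and '-')",
      ids[offender[1]], substr(bad[offender[1]], 1, 1)), "alphabet")
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    cl_stop(sprintf("sequences have unequal lengths (%s)",
                    paste(unique(widths), collapse = ", ")), "alignment")
  if (widths[1] == 0L)
    cl_stop("sequences are empty", "empty_input")
  if (widths[1] %% 3L != 0L)
    cl_stop(sprintf("alignment length %d is not a multiple of 3", widths[1]),
            "frame")
  new_codon_alignment(ids, seqs)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d sequences x %d nt (%d codons)\n",
              length(x$seqs), x$length, x$length %/% 3L))
  invisible(x)
}

#' Number of sequences in an alignment
#' @param aln a `codon_alignment`.
#' @return integer count of records.
#' @export
n_sequences <- function(aln) length(aln$seqs)

#' Read an aligned nucleotide FASTA file
#'
#' Parses a multi-record FASTA file (wrapped or unwrapped lines), keeps the
#' first whitespace-delimited token of each header as the identifier, and
#' normalizes sequences (uppercase, `U` mapped to `T`). The file must contain
#' at least one record; all records must share one length which is a multiple
#' of three, and may only use IUPAC nucleotide codes or `-`.
#'
#' @param path path to a FASTA file.
#' @return a `codon_alignment`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ATGAAA", ">b", "ATGAAG"), f)
#' read_fasta_alignment(f)
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path))
    cl_stop(sprintf("cannot read FASTA file '%s'", path), "io")
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) cl_stop(
                    sprintf("failed to parse '%s' as FASTA: %s",
                            path, conditionMessage(e)), "io"))
  if (length(set) == 0L)
    cl_stop(sprintf("FASTA file '%s' contains no records", path),
            "empty_input")
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  codon_alignment(as.character(set), ids = ids)
}

#' Write an alignment to FASTA
#'
#' Writes standard FASTA at 60 characters per line. Round-trips through
#' [read_fasta_alignment()] without loss.
#'
#' @param aln a `codon_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (length(aln$seqs) == 0L)
    cl_stop("refusing to write an empty alignment", "empty_input")
  set <- Biostrings::BStringSet(stats::setNames(aln$seqs, aln$ids))
  tryCatch(Biostrings::writeXStringSet(set, filepath = path, width = 60L),
           error = function(e) cl_stop(
             sprintf("cannot write FASTA to '%s': %s",
                     path, conditionMessage(e)), "io"))
  invisible(path)
}

#' Percentage of ambiguous nucleotides in a sequence
#'
#' The fraction (as a percentage in `[0, 100]`) of IUPAC ambiguity codes
#' (`R Y S W K M B D H V N`) among the non-gap characters of a sequence.
#' Gaps are neither ambiguous nor part of the denominator.
#'
#' @param sequence a single normalized sequence string.
#' @return numeric percentage.
#' @examples
#' ambiguity_fraction("ATGATGATGNNN")  # 25
#' @export
ambiguity_fraction <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "")[[1]]
  non_gap <- sum(chars != NUC_GAP)
  if (non_gap == 0L)
    cl_stop("ambiguity fraction undefined for an all-gap sequence",
            "undefined_fraction")
  100 * sum(chars %in% NUC_AMBIGUOUS) / non_gap
}

new_filter_report <- function(aln, keep, rule) {
  list(n_input = length(aln$seqs),
       n_removed = sum(!keep),
       removed_ids = aln$ids[!keep],
       rule = rule)
}

#' Remove sequences exceeding an ambiguity threshold
#'
#' Drops every record whose [ambiguity_fraction()] is strictly greater than
#' `threshold` percent; survivors keep their input order. The strict
#' inequality means e.g. that at threshold 30 a 12-nt sequence is excluded
#' from 4 ambiguous nucleotides upward (4/12 = 33.3%) while 3 (25%) is kept.
#'
#' @param aln a `codon_alignment`.
#' @param threshold percentage in `[0, 100]`; 100 disables the filter.
#' @return list with elements `alignment` (the filtered `codon_alignment`)
#'   and `report` (counts and ids of removed records).
#' @export
filter_by_uncertainty <- function(aln, threshold) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 100)
    cl_stop("threshold must be a single number in [0, 100]", "validation")
  frac <- vapply(aln$seqs, ambiguity_fraction, numeric(1), USE.NAMES = FALSE)
  keep <- frac <= threshold
  report <- new_filter_report(aln, keep, "uncertainty")
  if (!any(keep))
    cl_stop(sprintf(
      "no sequences remain after ambiguity filtering at threshold %g%%",
      threshold), "empty_after_filter")
  list(alignment = new_codon_alignment(aln$ids[keep], aln$seqs[keep]),
       report = report)
}

#' Remove exact duplicate sequences
#'
#' Among records whose normalized sequences are byte-identical, only the
#' first occurrence is kept (headers are ignored for identity). Idempotent.
#'
#' @param aln a `codon_alignment`.
#' @return list with elements `alignment` and `report`, as for
#'   [filter_by_uncertainty()].
#' @export
deduplicate <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  keep <- !duplicated(aln$seqs)
  list(alignment = new_codon_alignment(aln$ids[keep], aln$seqs[keep]),
       report = new_filter_report(aln, keep, "duplicate"))
}

#' Warn when an alignment is small
#'
#' Plug-in (maximum-likelihood) entropy is biased downward in small samples,
#' which inflates apparent information content; at least 40 sequences are
#' recommended. Emits a warning below that size.
#'
#' @param aln a `codon_alignment`.
#' @return `aln`, invisibly.
#' @export
check_alignment_size <- function(aln) {
  if (length(aln$seqs) < 40L)
    warning(sprintf(
      "alignment has only %d sequences; at least 40 are recommended to avoid entropy underestimation",
      length(aln$seqs)), call. = FALSE)
  invisible(aln)
}
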