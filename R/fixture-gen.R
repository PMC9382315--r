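# Seeded synthetic codon alignments with controlled conservation, ambiguity
# and duplication, so the whole pipeline is testable without external data.

# Run `expr` under a private RNG stream: the caller's .Random.seed is left
# untouched, and identical seeds give identical draws.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify a synthetic codon-alignment profile
#'
#' Describes the generative world for [generate_alignment()]: per-position
#' codon distributions, an independent per-nucleotide ambiguity ('N')
#' substitution rate, a fraction of records replaced by copies of earlier
#' records, and a seed.
#'
#' The default profile follows common practice for testing logo pipelines:
#' 40 sequences (the minimum recommended to keep plug-in entropy bias small),
#' 10 codon positions, and at each position one modal codon at probability
#' 0.7 with three minor codons at 0.1 — a moderately conserved coding
#' profile — with no ambiguity and no duplicates.
#'
#' @param n_sequences number of records (>= 1).
#' @param n_codons number of codon positions (>= 1).
#' @param distributions list of named numeric vectors (codon -> probability,
#'   each summing to 1), one per position, or a single-element list recycled
#'   across positions; `NULL` selects the default profile above.
#' @param ambiguity_rate per-nucleotide probability of replacement by 'N'
#'   (or by a uniformly drawn IUPAC ambiguity code, see `iupac_full`).
#' @param duplicate_fraction proportion of records (after the first)
#'   replaced by copies of earlier records, in `[0, 1]`.
#' @param iupac_full inject the full IUPAC ambiguity set uniformly instead
#'   of only 'N'.
#' @param seed integer RNG seed.
#' @return a `codon_profile` list.
#' @export
codon_profile <- function(n_sequences = 40L, n_codons = 10L,
                          distributions = NULL, ambiguity_rate = 0,
                          duplicate_fraction = 0, iupac_full = FALSE,
                          seed = 1L) {
  if (n_sequences < 1L || n_codons < 1L)
    cl_stop("n_sequences and n_codons must be >= 1", "validation")
  if (ambiguity_rate < 0 || ambiguity_rate > 1 ||
      duplicate_fraction < 0 || duplicate_fraction > 1)
    cl_stop("rates must lie in [0, 1]", "validation")
  if (is.null(distributions)) {
    base <- c("ATG", "GAA", "TGC", "CAT")
    distributions <- replicate(n_codons, {
      stats::setNames(c(0.7, 0.1, 0.1, 0.1), base)
    }, simplify = FALSE)
    # rotate the modal codon so positions differ
    for (l in seq_len(n_codons))
      names(distributions[[l]]) <- base[((seq_len(4) + l - 2) %% 4) + 1]
  }
  if (length(distributions) == 1L)
    distributions <- rep(distributions, n_codons)
  if (length(distributions) != n_codons)
    cl_stop("need one codon distribution per position", "validation")
  for (l in seq_along(distributions)) {
    d <- distributions[[l]]
    if (is.null(names(d)) || any(nchar(names(d)) != 3L) ||
        any(d < 0) || abs(sum(d) - 1) > 1e-9)
      cl_stop(sprintf(
        "distribution for position %d must be named codon probabilities summing to 1", l),
        "validation")
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 n_codons = as.integer(n_codons),
                 distributions = distributions,
                 ambiguity_rate = ambiguity_rate,
                 duplicate_fraction = duplicate_fraction,
                 iupac_full = isTRUE(iupac_full),
                 seed = as.integer(seed)),
            class = "codon_profile")
}

#' Generate a synthetic codon alignment
#'
#' Draws each record's codon at position `l` independently from the
#' profile's distribution `l`; then replaces `duplicate_fraction` of records
#' (never the first) with copies of earlier records; then substitutes each
#' nucleotide independently by an ambiguity code with probability
#' `ambiguity_rate`. Fully reproducible from the profile's seed.
#'
#' @param profile a `codon_profile`.
#' @return a `codon_alignment` with ids `seq0001`, `seq0002`, ...
#' @examples
#' aln <- generate_alignment(codon_profile(n_sequences = 5, n_codons = 3))
#' aln$length
#' @export
generate_alignment <- function(profile) {
  stopifnot(inherits(profile, "codon_profile"))
  with_local_seed(profile$seed, {
    n <- profile$n_sequences
    cod <- matrix("", nrow = n, ncol = profile$n_codons)
    for (l in seq_len(profile$n_codons)) {
      d <- profile$distributions[[l]]
      cod[, l] <- sample(names(d), n, replace = TRUE, prob = d)
    }
    seqs <- apply(cod, 1L, paste, collapse = "")
    n_dup <- floor(profile$duplicate_fraction * n)
    if (n_dup > 0 && n > 1) {
      targets <- sample(2:n, min(n_dup, n - 1L))
      for (i in targets)
        seqs[i] <- seqs[sample.int(i - 1L, 1L)]
    }
    if (profile$ambiguity_rate > 0) {
      codes <- if (profile$iupac_full) NUC_AMBIGUOUS else "N"
      chars <- strsplit(seqs, "")
      width <- profile$n_codons * 3L
      for (i in seq_len(n)) {
        hit <- stats::runif(width) < profile$ambiguity_rate
        if (any(hit))
          chars[[i]][hit] <- sample(codes, sum(hit), replace = TRUE)
      }
      seqs <- vapply(chars, paste, character(1), collapse = "")
    }
    codon_alignment(seqs, ids = sprintf("seq%04d", seq_len(n)))
  })
}

#' Measure how well the pipeline recovers a specified profile
#'
#' Generates an alignment of `n_sequences` records from `profile` (ambiguity
#' and duplication left as specified), runs the codon-count and probability
#' steps, and summarizes the deviation of the empirical distribution from
#' the specified one: the maximum over positions/codons of
#' `|empirical f - specified f|` and of `|empirical H - theoretical H|`.
#'
#' @param profile a `codon_profile`.
#' @param n_sequences number of records to draw; defaults to the profile's.
#' @param seed seed for this draw; defaults to the profile's.
#' @return list with `max_freq_dev`, `max_entropy_dev`, and `positions`, a
#'   data.frame of per-position empirical and theoretical entropies.
#' @export
empirical_recovery <- function(profile, n_sequences = profile$n_sequences,
                               seed = profile$seed) {
  stopifnot(inherits(profile, "codon_profile"))
  p2 <- profile
  p2$n_sequences <- as.integer(n_sequences)
  p2$seed <- as.integer(seed)
  aln <- generate_alignment(p2)
  prob <- to_probability(count_codons(aln))
  freq_dev <- 0
  emp_H <- apply(unclass(prob), 1L, position_entropy)
  theo_H <- vapply(p2$distributions, function(d) position_entropy(d),
                   numeric(1))
  for (l in seq_len(p2$n_codons)) {
    d <- p2$distributions[[l]]
    emp <- rep(0, length(d))
    names(emp) <- names(d)
    seen <- intersect(names(d), colnames(prob))
    emp[seen] <- prob[l, seen]
    freq_dev <- max(freq_dev, abs(emp - d))
  }
  list(max_freq_dev = freq_dev,
       max_entropy_dev = max(abs(emp_H - theo_H)),
       positions = data.frame(position = seq_len(p2$n_codons),
                              empirical_H = unname(emp_H),
                              theoretical_H = theo_H))
}
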