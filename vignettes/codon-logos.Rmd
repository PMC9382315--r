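---
title: "Codon-level sequence logos: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-level sequence logos: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonlogo)
```

## Why codon logos

A sequence logo summarizes a multiple sequence alignment as per-position
stacks of symbols whose total height reflects conservation and whose
individual heights reflect frequency. For protein-coding DNA the usual
per-nucleotide logo can mislead: three nucleotides can each be individually
common at the three positions of a codon while the triplet they spell never
occurs together in any sequence. Working at the codon level keeps synonymous
and non-synonymous variation visible and rules out such phantom codons — a
triplet that never occurs at a position has height exactly zero, whatever
the marginal nucleotide frequencies suggest.

## The model

For codon position $l$ over an alphabet of $N$ symbols, with $f(n,l)$ the
observed frequency of codon $n$:

$$H(l) = -\sum_{n=1}^{N} f(n,l)\,\log_2 f(n,l), \qquad
R_{seq}(l) = S_{max} - H(l) = \log_2 N - H(l), \qquad
\mathrm{Height}(n,l) = f(n,l)\, R_{seq}(l).$$

$S_{max}$ is the maximum possible entropy: 2 bits for 4 nucleotides,
$\approx 4.32$ bits for 20 amino acids, 6 bits for the 64 codons. The
convention $0 \cdot \log_2 0 = 0$ applies. A fully conserved position shows
one glyph of height $S_{max}$; a position uniform over all 64 codons has
$R_{seq} = 0$ and an empty stack.

The estimator of $H$ is the plug-in (maximum-likelihood) one, which is
biased downward in small samples and therefore *overstates* conservation;
no small-sample correction is applied. Instead the package warns below 40
sequences, and the fixture module's `empirical_recovery()` demonstrates the
bias direction by simulation (`test-fixture_gen.R`).

## Parameters that matter

- **`degree_of_uncertainty`** (percent, default 100 = off): a sequence is
  excluded when its percentage of IUPAC-ambiguous nucleotides among non-gap
  characters is *strictly greater* than the threshold. The strict
  inequality is fixed by the worked example that a 30% threshold on 12-nt
  sequences excludes 4 ambiguous nucleotides (33.3%) but keeps 3 (25%).
- **`dataset_type`** (`redundant` default): `nonredundant` removes exact
  duplicate sequences (byte identity after normalization, headers ignored,
  first occurrence kept), which makes rarer codons visible in the logo.
- **`smax_symbols`** (default automatic): 64 when only plain codons were
  counted; as soon as any counted codon contains an ambiguity code the
  alphabet conceptually becomes all $15^3 = 3375$ IUPAC triplets and
  $S_{max} = \log_2 3375 \approx 11.72$ bits. Ambiguous codons are counted
  as their own symbols, never expanded fractionally over the codons they
  could be — expansion would fabricate observations. An explicit override
  is available for interoperability.
- **`matrix_logo_type`**: `bit` (default) or `probability`; the y axis runs
  to $S_{max}$ or to 1 accordingly.
- **`alpha_color`**: palette mapping each codon to the class of its encoded
  amino acid (standard genetic code). An ambiguous codon whose expansions
  all encode one amino acid (e.g. GCN → Ala) is coloured as that amino
  acid; otherwise it gets the dedicated ambiguous colour.

## Numerical and degenerate-input choices

- Input is uppercased and RNA `U` is mapped to `T` at parse time; DNA and
  RNA inputs are thereby unified.
- Gaps (`-`) are accepted; they are not ambiguity codes and are excluded
  from the ambiguity denominator. A triplet containing any gap is not a
  codon and is excluded from counting, and the remaining codons at that
  position are renormalized. A position where *every* sequence has a gap
  triplet has no defined distribution: an error by default,
  `drop_empty_positions` discards such positions instead.
- Probability rows must sum to 1 within $10^{-6}$ on input to the entropy
  routine; stack-conservation identities are tested at $10^{-9}$; the
  entropy implementation is checked against a brute-force oracle at
  $10^{-12}$.
- Matrix CSVs are written with `%.17g` so they re-read losslessly.
- Stacking order is ascending by height (largest glyph on top), the common
  logo convention; ties fall back to the sort's stable order on the
  lexicographic column order.
- Palette hues: the four palette *names* follow WebLogo conventions but no
  authoritative hex values exist for them, so the classes and colours are
  fixed here (see `logo_palette()`) and treated as part of this package's
  contract.

## The synthetic-data generator

`codon_profile()` / `generate_alignment()` state a simple generative world:
each record's codon at position $l$ is drawn i.i.d. from a specified
per-position distribution; then a stated fraction of records is replaced by
copies of earlier records (exercising duplicate removal); then each
nucleotide is independently replaced by `N` (or a uniform IUPAC code) at a
stated rate (exercising the ambiguity filter and the $S_{max}$ switch).
Defaults: 40 sequences (the recommended minimum), 10 codons, one modal
codon at 0.7 with three minors at 0.1 per position — a moderately conserved
coding profile; ambiguity and duplication off.

What it does *not* emulate: phylogenetic correlation between sequences,
indel structure, or codon-usage bias linked across positions. A green test
therefore establishes the information-theoretic and plumbing contracts —
frequency recovery, entropy identities, filter semantics, file formats —
not realism of evolutionary structure. Columns are i.i.d., so convergence
diagnostics (`empirical_recovery()`) obey binomial sampling error;
tolerances in the tests (0.02 at $n = 10^4$) come from that, not from
tuning.

## Known limitations

- No reading-frame inference, frameshift handling, or partial 5′ codons:
  the input must be a codon-aligned alignment starting in frame.
- No entropy bias correction; small alignments overstate conservation.
- No clustering-based redundancy reduction (only exact duplicates); large
  datasets should be reduced with external tools first.
- Rendering draws codons as scaled text, not stretched letter outlines;
  geometry (box extents) is the tested contract, typography is not.
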