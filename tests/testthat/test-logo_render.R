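test_that("translate_codon follows table 1 and resolves ambiguity", {
  expect_equal(translate_codon("ATG"), "M")
  expect_equal(translate_codon("TAA"), "*")
  expect_equal(translate_codon("TGA"), "*")
  # 4-fold degenerate boxes resolve through a third-position N
  expect_equal(translate_codon("GCN"), "A")
  expect_equal(translate_codon("CGN"), "R")
  # YTR = {CTA, CTG, TTA, TTG}, all leucine
  expect_equal(translate_codon("YTR"), "L")
  # RAT = {AAT (N), GAT (D)} does not resolve
  expect_equal(translate_codon("RAT"), "X")
  expect_equal(translate_codon("NNN"), "X")
  expect_error(translate_codon("AT-"), class = "codonlogo_alphabet_error")
  expect_error(translate_codon("AT"), class = "codonlogo_alphabet_error")
})

test_that("palettes cover all 20 amino acids plus stop and ambiguous", {
  for (name in c("weblogo_protein", "charge", "chemistry", "hydrophobicity")) {
    pal <- logo_palette(name)
    expect_setequal(names(pal$mapping),
                    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    expect_true(all(nzchar(pal$mapping)))
    expect_false(is.null(pal$stop_color))
    expect_false(is.null(pal$ambiguous_color))
  }
})

test_that("assign_color maps codons through amino-acid classes", {
  charge <- logo_palette("charge")
  # lysine positive, aspartate negative, alanine neutral
  expect_equal(assign_color("AAA", charge), unname(charge$mapping["K"]))
  expect_equal(assign_color("GAT", charge), unname(charge$mapping["D"]))
  expect_equal(assign_color("AAA", charge), assign_color("AAG", charge))
  expect_false(assign_color("AAA", charge) == assign_color("GAT", charge))
  for (name in c("weblogo_protein", "charge", "chemistry", "hydrophobicity")) {
    pal <- logo_palette(name)
    expect_equal(assign_color("TGA", pal), pal$stop_color)
    expect_equal(assign_color("RAT", pal), pal$ambiguous_color)
  }
})

test_that("layout_logo stacks ascending with contiguous disjoint boxes", {
  prob <- to_probability(count_codons(small_alignment()))
  bits <- to_bits(prob, smax = 6)
  layout <- layout_logo(bits)
  expect_s3_class(layout, "logo_layout")
  expect_equal(layout$y_axis_max, 6)
  expect_equal(layout$y_label, "bits")

  # position 2: AAT (smaller) below, AAA (larger) on top
  p2 <- layout$boxes[layout$boxes$position == 2, ]
  expect_equal(p2$codon, c("AAT", "AAA"))
  expect_equal(p2$y_bottom[1], 0)
  expect_equal(p2$y_top[1], p2$y_bottom[2])
  expect_equal(p2$y_top[2], unname(attr(bits, "Rseq")[["2"]]),
               tolerance = 1e-9)

  # fully conserved position: one box spanning [0, smax]
  p1 <- layout$boxes[layout$boxes$position == 1, ]
  expect_equal(nrow(p1), 1L)
  expect_equal(c(p1$y_bottom, p1$y_top), c(0, 6))

  # probability mode: axis max 1, stacks sum to 1
  playout <- layout_logo(prob)
  expect_equal(playout$y_axis_max, 1)
  expect_equal(playout$y_label, "probability")
  totals <- tapply(playout$boxes$y_top - playout$boxes$y_bottom,
                   playout$boxes$position, sum)
  expect_equal(as.vector(totals), rep(1, 3), tolerance = 1e-9)

  # zero rows produce no boxes
  uniform <- to_probability(count_codons(
    codon_alignment(c("AAA", "AAC", "AAG", "AAT"))))
  zlayout <- layout_logo(to_bits(uniform, smax = 2))
  expect_equal(nrow(zlayout$boxes), 0L)
})

test_that("stack totals equal Rseq for generated alignments", {
  for (seed in c(5, 6)) {
    aln <- generate_alignment(codon_profile(n_sequences = 40, n_codons = 8,
                                            seed = seed))
    bits <- to_bits(to_probability(count_codons(aln)))
    layout <- layout_logo(bits)
    totals <- tapply(layout$boxes$y_top - layout$boxes$y_bottom,
                     layout$boxes$position, sum)
    expect_equal(as.vector(totals),
                 unname(attr(bits, "Rseq")[names(totals)]),
                 tolerance = 1e-9)
  }
})

test_that("identical inputs give identical layouts and JSON", {
  bits <- to_bits(to_probability(count_codons(small_alignment())), 6)
  l1 <- layout_logo(bits, logo_palette("chemistry"))
  l2 <- layout_logo(bits, logo_palette("chemistry"))
  expect_identical(l1, l2)
  expect_identical(as.character(layout_to_json(l1)),
                   as.character(layout_to_json(l2)))
  f <- withr::local_tempfile(fileext = ".json")
  layout_to_json(l1, f)
  parsed <- jsonlite::fromJSON(f)
  expect_equal(nrow(parsed$boxes), nrow(l1$boxes))
  expect_equal(parsed$y_axis_max, 6)
})

test_that("render writes decodable PNG and parseable PDF files", {
  layout <- layout_logo(to_bits(to_probability(count_codons(
    small_alignment())), 6))

  png_path <- withr::local_tempfile(fileext = ".png")
  render_logo(layout, png_path, format = "png", dpi = 150, title = "demo")
  expect_true(file.exists(png_path))
  magic <- readBin(png_path, "raw", 8)
  expect_equal(magic, as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)))
  expect_gt(file.size(png_path), 1000)

  pdf_path <- withr::local_tempfile(fileext = ".pdf")
  render_logo(layout, pdf_path, format = "pdf", title = "demo")
  first <- readLines(pdf_path, n = 1, warn = FALSE)
  expect_match(first, "^%PDF")

  expect_error(render_logo(layout, png_path, format = "png", dpi = 10),
               class = "codonlogo_config_error")

  # empty layout (all-zero matrix) renders axes without glyphs
  uniform <- to_bits(to_probability(count_codons(
    codon_alignment(c("AAA", "AAC", "AAG", "AAT")))), smax = 2)
  empty <- layout_logo(uniform)
  out <- withr::local_tempfile(fileext = ".png")
  expect_no_error(render_logo(empty, out, format = "png", dpi = 100))
  expect_true(file.size(out) > 0)
})

test_that("per-codon logo suppresses codons absent despite nucleotide consensus", {
  # At codon position 4 (nucleotides 10-12) G, A and T are each modal, yet
  # the codon GAT never occurs there; a per-nucleotide view would suggest
  # GAT, the per-codon view must give it zero height.
  pos4 <- c("GAA", "GAC", "GAG", "TAT", "AAT", "CAT")
  seqs <- paste0("ATGCATCCA", pos4)
  aln <- codon_alignment(seqs)
  nt10 <- substr(seqs, 10, 10); nt11 <- substr(seqs, 11, 11)
  nt12 <- substr(seqs, 12, 12)
  expect_gte(mean(nt10 == "G"), 0.5)
  expect_gte(mean(nt11 == "A"), 0.5)
  expect_gte(mean(nt12 == "T"), 0.5)

  bits <- to_bits(to_probability(count_codons(aln)))
  expect_false("GAT" %in% colnames(bits)[bits[4, ] > 0])
  layout <- layout_logo(bits)
  gat <- layout$boxes[layout$boxes$position == 4 &
                        layout$boxes$codon == "GAT", ]
  expect_equal(nrow(gat), 0L)
})
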