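# Palette assignment, stack layout and figure rendering.
#
# Codons are coloured by the physico-chemical class of the amino acid they
# encode under the standard genetic code (translation table 1).  Ambiguous
# codons are translated by expanding their IUPAC characters: if every
# expansion encodes the same amino acid the codon gets that colour (e.g. GCN
# is still alanine), otherwise it is drawn in the "ambiguous" colour.

#' Translate a codon under the standard genetic code
#'
#' Accepts IUPAC-ambiguous codons: the codon is expanded to all compatible
#' unambiguous triplets and translated with translation table 1. If all
#' expansions agree the common one-letter amino acid (or `"*"` for stop) is
#' returned; otherwise `"X"` marks an unresolvable codon.
#'
#' @param codon a 3-character string over IUPAC nucleotide codes (no gaps).
#' @return one-letter amino acid code, `"*"` (stop) or `"X"` (ambiguous).
#' @examples
#' translate_codon("ATG")  # "M"
#' translate_codon("GCN")  # "A": every GC* codon is alanine
#' translate_codon("TAA")  # "*"
#' @export
translate_codon <- function(codon) {
  stopifnot(is.character(codon), length(codon) == 1L)
  codon <- toupper(codon)
  chars <- strsplit(codon, "")[[1]]
  if (length(chars) != 3L || !all(chars %in% c(NUC_UNAMBIGUOUS, NUC_AMBIGUOUS)))
    cl_stop(sprintf("'%s' is not a gap-free IUPAC codon", codon), "alphabet")
  expansions <- strsplit(Biostrings::IUPAC_CODE_MAP[chars], "")
  combos <- expand.grid(expansions, stringsAsFactors = FALSE)
  triplets <- do.call(paste0, combos)
  aas <- unique(unname(Biostrings::GENETIC_CODE[triplets]))
  if (length(aas) == 1L) aas else "X"
}

# Amino-acid class memberships follow the WebLogo colour-scheme conventions.
PALETTE_CLASSES <- list(
  weblogo_protein = list(
    polar       = list(aa = c("G", "S", "T", "Y", "C", "Q", "N"), color = "#109648"),
    basic       = list(aa = c("K", "R", "H"),                     color = "#255C99"),
    acidic      = list(aa = c("D", "E"),                          color = "#D62839"),
    hydrophobic = list(aa = c("A", "V", "L", "I", "P", "W", "F", "M"), color = "#221E22")
  ),
  chemistry = list(
    polar       = list(aa = c("G", "S", "T", "Y", "C"),           color = "#109648"),
    neutral     = list(aa = c("Q", "N"),                          color = "#7B2D8B"),
    basic       = list(aa = c("K", "R", "H"),                     color = "#255C99"),
    acidic      = list(aa = c("D", "E"),                          color = "#D62839"),
    hydrophobic = list(aa = c("A", "V", "L", "I", "P", "W", "F", "M"), color = "#221E22")
  ),
  hydrophobicity = list(
    hydrophilic = list(aa = c("R", "K", "D", "E", "N", "Q"),      color = "#255C99"),
    neutral     = list(aa = c("S", "G", "H", "T", "A", "P"),      color = "#109648"),
    hydrophobic = list(aa = c("Y", "V", "M", "C", "L", "F", "I", "W"), color = "#221E22")
  ),
  charge = list(
    positive = list(aa = c("K", "R", "H"),                        color = "#255C99"),
    negative = list(aa = c("D", "E"),                             color = "#D62839"),
    neutral  = list(aa = c("A", "C", "F", "G", "I", "L", "M", "N",
                           "P", "Q", "S", "T", "V", "W", "Y"),    color = "#808080")
  )
)

#' Construct a codon colour palette
#'
#' Four palettes colour codons by properties of the encoded amino acid:
#' `weblogo_protein` (default; polar green, basic blue, acidic red,
#' hydrophobic black), `chemistry` (as before but with neutral Q/N in
#' purple), `hydrophobicity` (hydrophilic blue, neutral green, hydrophobic
#' black) and `charge` (positive blue, negative red, neutral gray). Stop
#' codons are dark red and unresolvable ambiguous codons gray in every
#' palette.
#'
#' @param name palette name.
#' @return a `logo_palette`: list with `name`, `mapping` (named colour vector
#'   over the 20 amino acids), `stop_color` and `ambiguous_color`.
#' @export
logo_palette <- function(name = c("weblogo_protein", "charge", "chemistry",
                                  "hydrophobicity")) {
  name <- match.arg(name)
  classes <- PALETTE_CLASSES[[name]]
  mapping <- character(0)
  for (cls in classes)
    mapping[cls$aa] <- cls$color
  stopifnot(length(mapping) == 20L)
  structure(list(name = name, mapping = mapping,
                 stop_color = "#8B0000", ambiguous_color = "#9A9A9A"),
            class = "logo_palette")
}

#' Colour for a codon under a palette
#'
#' @param codon 3-character IUPAC codon.
#' @param palette a `logo_palette`.
#' @return a colour string.
#' @examples
#' assign_color("AAA", logo_palette("charge"))  # lysine: positive-charge blue
#' @export
assign_color <- function(codon, palette) {
  stopifnot(inherits(palette, "logo_palette"))
  aa <- translate_codon(codon)
  if (aa == "*") return(palette$stop_color)
  if (aa == "X") return(palette$ambiguous_color)
  unname(palette$mapping[aa])
}

#' Compute the stacked-glyph layout of a logo
#'
#' At each position, codons with positive value are stacked bottom-up in
#' ascending value order, so the most frequent codon sits on top; box
#' extents are cumulative sums, making the stack total equal the matrix row
#' sum (`Rseq(l)` for a bit matrix, 1 for a probability matrix).
#'
#' @param m a `codon_bit_matrix` or `codon_prob_matrix`.
#' @param palette a `logo_palette`.
#' @return a `logo_layout`: list with `boxes` (data.frame of `position`,
#'   `codon`, `y_bottom`, `y_top`, `color`), `y_axis_max` (`smax` in bit
#'   mode, 1 in probability mode), `y_label` and `x_positions`.
#' @export
layout_logo <- function(m, palette = logo_palette()) {
  stopifnot(is.matrix(m), inherits(palette, "logo_palette"))
  bit_mode <- inherits(m, "codon_bit_matrix")
  if (!bit_mode && !inherits(m, "codon_prob_matrix"))
    cl_stop("layout requires a codon_bit_matrix or codon_prob_matrix",
            "contract")
  colors <- vapply(colnames(m), assign_color, character(1), palette = palette)
  boxes <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    v <- v[v > 0]
    if (length(v) == 0L) next
    v <- sort(v)  # ascending: largest glyph ends up on top
    tops <- cumsum(v)
    boxes[[i]] <- data.frame(
      position = as.integer(rownames(m)[i]),
      codon = names(v),
      y_bottom = tops - v,
      y_top = tops,
      color = unname(colors[names(v)]),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  boxes <- do.call(rbind, boxes)
  if (is.null(boxes))
    boxes <- data.frame(position = integer(0), codon = character(0),
                        y_bottom = numeric(0), y_top = numeric(0),
                        color = character(0), stringsAsFactors = FALSE)
  structure(list(
    boxes = boxes,
    y_axis_max = if (bit_mode) attr(m, "smax") else 1,
    y_label = if (bit_mode) "bits" else "probability",
    x_positions = as.integer(rownames(m))
  ), class = "logo_layout")
}

#' Export a logo layout as JSON
#'
#' Serializes the glyph boxes and axis metadata, so layouts can be compared
#' or consumed without image comparison.
#'
#' @param layout a `logo_layout`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
layout_to_json <- function(layout, path = NULL) {
  stopifnot(inherits(layout, "logo_layout"))
  js <- jsonlite::toJSON(unclass(layout), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Render a logo layout to PNG or PDF
#'
#' Draws each glyph as its 3-letter codon text scaled to fill its box, over
#' a light box fill; the x axis is labelled with codon positions and the y
#' axis with bits or probability. An empty layout (all-zero matrix) renders
#' axes without glyphs.
#'
#' @param layout a `logo_layout`.
#' @param path output file path.
#' @param format `"png"` or `"pdf"`.
#' @param dpi raster resolution for PNG (>= 72).
#' @param title plot title.
#' @return `path`, invisibly.
#' @export
render_logo <- function(layout, path, format = c("png", "pdf"), dpi = 300,
                        title = "") {
  stopifnot(inherits(layout, "logo_layout"))
  format <- match.arg(format)
  if (format == "png" && (!is.numeric(dpi) || dpi < 72))
    cl_stop("dpi must be >= 72", "config")
  n_pos <- max(1L, length(layout$x_positions))
  width_in <- max(4, 0.5 * n_pos + 1.5)
  height_in <- 3.5
  opened <- tryCatch({
    if (format == "png")
      grDevices::png(path, width = width_in, height = height_in,
                     units = "in", res = dpi)
    else
      grDevices::pdf(path, width = width_in, height = height_in)
    TRUE
  }, error = function(e) cl_stop(
    sprintf("cannot open '%s' for %s output: %s", path, format,
            conditionMessage(e)), "io"))
  on.exit(grDevices::dev.off(), add = TRUE)
  old_par <- graphics::par(mar = c(4, 4, 3, 1))
  # restore par while the device is still open, then close it
  on.exit(graphics::par(old_par), add = TRUE, after = FALSE)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0.5, n_pos + 0.5),
                        ylim = c(0, layout$y_axis_max), xaxs = "i", yaxs = "i")
  graphics::axis(1, at = layout$x_positions, labels = layout$x_positions)
  graphics::axis(2, las = 1)
  graphics::title(main = title, xlab = "codon position",
                  ylab = layout$y_label)
  boxes <- layout$boxes
  if (nrow(boxes)) {
    half_w <- 0.45
    graphics::rect(boxes$position - half_w, boxes$y_bottom,
                   boxes$position + half_w, boxes$y_top,
                   col = grDevices::adjustcolor(boxes$color, alpha.f = 0.15),
                   border = NA)
    for (i in seq_len(nrow(boxes))) {
      h <- boxes$y_top[i] - boxes$y_bottom[i]
      cex <- min(2 * half_w * 0.95 / graphics::strwidth(boxes$codon[i]),
                 h * 0.95 / graphics::strheight(boxes$codon[i]))
      graphics::text(boxes$position[i], (boxes$y_bottom[i] + boxes$y_top[i]) / 2,
                     labels = boxes$codon[i], col = boxes$color[i],
                     cex = cex, font = 2)
    }
  }
  graphics::box()
  invisible(path)
}
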