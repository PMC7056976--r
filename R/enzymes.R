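# Bundled restriction enzymes used throughout the dual-reporter vector
# series. cut_top / cut_bottom are offsets from the recognition start on the
# top strand (top cut after cut_top bases, bottom cut opposite cut_bottom).
# Offsets cross-checked against the REBASE catalog; regression-tested on the
# known overhang chemistries.
ENZYME_TABLE <- data.frame(
  name = c("EcoRI", "AscI", "AgeI", "StuI", "BamHI", "BglII", "XhoI",
           "SbfI", "SacII", "NheI", "SpeI", "FseI", "NotI"),
  recognition = c("GAATTC", "GGCGCGCC", "ACCGGT", "AGGCCT", "GGATCC",
                  "AGATCT", "CTCGAG", "CCTGCAGG", "CCGCGG", "GCTAGC",
                  "ACTAGT", "GGCCGGCC", "GCGGCCGC"),
  cut_top    = c(1L, 2L, 1L, 3L, 1L, 1L, 1L, 6L, 4L, 1L, 1L, 6L, 2L),
  cut_bottom = c(5L, 6L, 5L, 3L, 5L, 5L, 5L, 2L, 2L, 5L, 5L, 2L, 6L),
  stringsAsFactors = FALSE
)

#' Bundled restriction enzyme catalog
#'
#' @return `data.frame` with recognition sequences, cut offsets, and the
#'   derived overhang kind (`cut_top < cut_bottom` leaves a 5' overhang,
#'   `>` a 3' overhang, `=` a blunt end).
#' @export
enzyme_table <- function() {
  tab <- ENZYME_TABLE
  tab$overhang <- ifelse(tab$cut_top < tab$cut_bottom, "5p",
                  ifelse(tab$cut_top > tab$cut_bottom, "3p", "blunt"))
  tab
}

#' Look up a restriction enzyme by name
#'
#' @param name Enzyme name (e.g. `"EcoRI"`).
#' @return An object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name) {
  i <- match(name, ENZYME_TABLE$name)
  if (is.na(i)) stop("unknown enzyme '", name, "'", call. = FALSE)
  row <- enzyme_table()[i, ]
  structure(list(name = row$name, recognition = row$recognition,
                 cut_top = row$cut_top, cut_bottom = row$cut_bottom,
                 overhang = row$overhang),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<enzyme> %s %s (%d/%d, %s)\n", x$name, x$recognition,
              x$cut_top, x$cut_bottom, x$overhang))
  invisible(x)
}

#' Cloning primers for the bundled enhancers
#'
#' The published primer pairs used to amplify pupal enhancers for cloning
#' into the AscI and SbfI sites of the 8 kb-spacer dual-reporter vector.
#' Lowercase in the originals marks the restriction-site tails (AscI
#' ggcgcgcc forward, SbfI cctgcagg reverse); degenerate IUPAC bases (S, K,
#' R, M) occur in the expanded dimorphic element pair.
#'
#' @return `data.frame`: enhancer, approximate product size (bp), primer
#'   name, direction, sequence.
#' @export
enhancer_primers <- function() {
  data.frame(
    enhancer = rep(c("yBE0.6", "t_MSE2", "DEcore", "LAE", "expandedDE"),
                   each = 2L),
    approx_bp = rep(c(600L, 350L, 690L, 1400L, 1580L), each = 2L),
    primer = c("BE2.5 Fwd", "BE3.5 Rvs", "tan_MSE-mid-F", "tan_MSE-mid-R",
               "DE core Fwd", "DE core Rvs", "bab TRE Fwd", "bab TRE Rvs",
               "sub1orthoF1", "dimorphic Rvs1"),
    direction = rep(c("fwd", "rev"), 5L),
    sequence = c(
      "TTCCGGGCGCGCCCTGTGGGTGCAATGATTTAGAATG",
      "TTGCCCCTGCAGGGTTATTGGCAGGTGATTTTGAGC",
      "TTCCGGGCGCGCCTGAAATAATAATAAATAATCAGAAT",
      "TTGCCCCTGCAGGTGTTTCAACTCAATCCTAGCAGTTGG",
      "TTCCGGGCGCGCCTCGCCTCCGCGGCTCTTTCTCTTTGCCATTTTAAC",
      "TTGCCCCTGCAGGCCCTTGGCTAGCGTGTGTGAACCAATTTGTTGTGC",
      "TTCCGGGCGCGCCGTGAGGGGCAAATTATGGAGAG",
      "TTGCCCCTGCAGGGTGCGCCTAACTAGCCAACAATTAG",
      "TTCCGGGCGCGCCCACATAAAAATCAGCAACAAASTTGC",
      "TTGCCCCTGCAGGCAAAACKGCRCATAAAAMSAAATTACA"),
    stringsAsFactors = FALSE
  )
}
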