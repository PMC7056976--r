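#' @importFrom methods is
#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

# IUPAC degenerate nucleotide alphabet: code -> set of concrete bases.
IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' DNA sequence with topology
#'
#' The universal substrate of the package: a concrete (A/C/G/T only) DNA
#' sequence with an identifier and a topology. Circular sequences have their
#' origin at position 1; every position reported anywhere in the package is
#' 1-based inclusive relative to that origin.
#'
#' @param bases Character scalar over A/C/G/T (lowercase is normalized to
#'   uppercase; any other character is an error). Ambiguity codes are legal
#'   only in patterns and primers, never here: designed sequences are concrete.
#' @param id Identifier label.
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `nuc_seq`.
#' @examples
#' s <- nuc_seq("acgtACGT", id = "demo")
#' seq_chars(s)
#' @export
nuc_seq <- function(bases, id = "seq", topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(bases), length(bases) == 1L, !is.na(bases))
  bases <- toupper(bases)
  if (nzchar(bases) && grepl("[^ACGT]", bases)) {
    bad <- regmatches(bases, regexpr("[^ACGT]", bases))
    stop("nuc_seq bases must be A/C/G/T only; found '", bad, "'", call. = FALSE)
  }
  structure(list(id = as.character(id), bases = bases, topology = topology),
            class = "nuc_seq")
}

#' @export
print.nuc_seq <- function(x, ...) {
  n <- seq_length(x)
  preview <- if (n > 60) paste0(substr(x$bases, 1, 57), "...") else x$bases
  cat(sprintf("<nuc_seq> %s [%s, %d bp]\n  %s\n", x$id, x$topology, n, preview))
  invisible(x)
}

#' @export
as.character.nuc_seq <- function(x, ...) x$bases

#' Sequence length in bp
#' @param s A `nuc_seq`.
#' @export
seq_length <- function(s) nchar(as_nuc_seq(s)$bases)

#' Sequence as a character vector of single bases
#' @param s A `nuc_seq` (or plain character scalar).
#' @export
seq_chars <- function(s) {
  if (is(s, "nuc_seq")) s <- s$bases
  if (!nzchar(s)) return(character(0))
  strsplit(s, "", fixed = TRUE)[[1]]
}

as_nuc_seq <- function(s, id = "seq", topology = "linear") {
  if (is(s, "nuc_seq")) s else nuc_seq(s, id = id, topology = topology)
}

#' Reverse complement
#'
#' Standard Watson-Crick reverse complement; topology and id are preserved.
#' For plain character input, IUPAC ambiguity codes are complemented per the
#' degenerate alphabet (useful for patterns and primers).
#'
#' @param s A `nuc_seq` or a character scalar (IUPAC codes allowed).
#' @return Same type as the input.
#' @export
reverse_complement <- function(s) {
  if (is(s, "nuc_seq")) {
    rc <- revcomp_chr(s$bases)
    out <- s
    out$bases <- rc
    return(out)
  }
  revcomp_chr(toupper(s))
}

# chartr is C-level; IUPAC codes complement to their complementary sets
revcomp_chr <- function(x) {
  if (!nzchar(x)) return(x)
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Test a concrete base against an IUPAC code
#'
#' `TRUE` iff `base` belongs to the expansion of `code` in the degenerate
#' nucleotide alphabet (S = G or C, K = G or T, R = A or G, M = A or C, ...).
#' Case-insensitive; vectorized over both arguments.
#'
#' @param base Concrete base(s), each one of A/C/G/T.
#' @param code IUPAC code(s).
#' @export
iupac_match <- function(base, code) {
  base <- toupper(base); code <- toupper(code)
  if (any(!base %in% c("A", "C", "G", "T")))
    stop("base must be a concrete A/C/G/T", call. = FALSE)
  if (any(!code %in% names(IUPAC_EXPANSION)))
    stop("invalid IUPAC code: ",
         paste(setdiff(code, names(IUPAC_EXPANSION)), collapse = ","),
         call. = FALSE)
  mapply(function(b, k) b %in% IUPAC_EXPANSION[[k]], base, code,
         USE.NAMES = FALSE)
}

#' Expansion set of an IUPAC pattern
#'
#' All concrete sequences matching a degenerate pattern. The set size is the
#' product of per-position degeneracies; guarded against combinatorial blowup.
#'
#' @param code IUPAC character string.
#' @param max_size Refuse to enumerate more than this many sequences.
#' @export
iupac_expand <- function(code, max_size = 10000L) {
  ch <- seq_chars(toupper(code))
  if (any(!ch %in% names(IUPAC_EXPANSION)))
    stop("invalid IUPAC code in pattern", call. = FALSE)
  sets <- IUPAC_EXPANSION[ch]
  n <- prod(lengths(sets))
  if (n > max_size) stop("expansion set too large (", n, ")", call. = FALSE)
  if (length(sets) == 0L) return(character(0))
  apply(do.call(expand.grid,
                c(rev(sets), list(stringsAsFactors = FALSE))), 1L,
        function(r) paste(rev(r), collapse = ""))
}

#' IUPAC-coded motif with a label
#'
#' @param code Character string over the 15 IUPAC codes.
#' @param label Text label (e.g. `"Hox-like"`, `"AbdB"`).
#' @return An object of class `degenerate_pattern`.
#' @examples
#' degenerate_pattern("YTAATKV", "Hox-like")
#' @export
degenerate_pattern <- function(code, label = code) {
  code <- toupper(code)
  ch <- seq_chars(code)
  if (length(ch) == 0L || any(!ch %in% names(IUPAC_EXPANSION)))
    stop("pattern must be a non-empty IUPAC string", call. = FALSE)
  structure(list(code = code, label = as.character(label)),
            class = "degenerate_pattern")
}

#' @export
print.degenerate_pattern <- function(x, ...) {
  cat(sprintf("<pattern> %s (%s)\n", x$code, x$label))
  invisible(x)
}

as_pattern <- function(p) {
  if (is(p, "degenerate_pattern")) p else degenerate_pattern(p)
}

FEATURE_KINDS <- c("promoter", "CDS", "UTR_polyA", "enhancer", "spacer",
                   "site", "misc")

#' Annotated feature table constructor
#'
#' Features live on 1-based inclusive coordinates; a feature spanning the
#' origin of a circular map is represented with `end < start` and rendered as
#' a `join(...)` location in GenBank output.
#'
#' @param label,kind,start,end,strand Vectors of equal length; `kind` one of
#'   promoter, CDS, UTR_polyA, enhancer, spacer, site, misc; `strand` `"+"` or
#'   `"-"`.
#' @return A `data.frame` with one row per feature.
#' @export
features <- function(label = character(), kind = character(),
                     start = integer(), end = integer(),
                     strand = character()) {
  stopifnot(all(kind %in% FEATURE_KINDS), all(strand %in% c("+", "-")))
  data.frame(label = as.character(label), kind = as.character(kind),
             start = as.integer(start), end = as.integer(end),
             strand = as.character(strand), stringsAsFactors = FALSE)
}

#' Assembled vector map: sequence plus ordered features
#'
#' @param seq A `nuc_seq`.
#' @param feat A feature table from [features()]; all features must lie within
#'   the sequence and have nonzero length (origin-spanning features on circular
#'   maps have `end < start`).
#' @return An object of class `construct_map`.
#' @export
construct_map <- function(seq, feat = features()) {
  seq <- as_nuc_seq(seq)
  n <- seq_length(seq)
  if (nrow(feat)) {
    ok <- feat$start >= 1L & feat$end >= 1L & feat$start <= n & feat$end <= n
    if (!all(ok))
      stop("feature out of range: ", paste(feat$label[!ok], collapse = ","),
           call. = FALSE)
    wraps <- feat$end < feat$start
    if (any(wraps) && seq$topology != "circular")
      stop("origin-spanning feature on a linear sequence", call. = FALSE)
  }
  structure(list(seq = seq, features = feat), class = "construct_map")
}

#' @export
print.construct_map <- function(x, ...) {
  cat(sprintf("<construct_map> %s [%s, %d bp] %d features\n",
              x$seq$id, x$seq$topology, seq_length(x$seq),
              nrow(x$features)))
  if (nrow(x$features)) print(x$features, row.names = FALSE)
  invisible(x)
}

feature_length <- function(feat, n) {
  ifelse(feat$end >= feat$start, feat$end - feat$start + 1L,
         n - feat$start + 1L + feat$end)
}

# Extract bases start..end (1-based inclusive) honoring circular wrap.
subseq_chr <- function(bases, start, end, circular = FALSE) {
  n <- nchar(bases)
  if (!circular || end >= start) return(substr(bases, start, end))
  paste0(substr(bases, start, n), substr(bases, 1, end))
}
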