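# Mutation operators used to build regulatory-neutral spacers and scanning
# mutant series. The elementary move is the non-complementary transversion:
# each base has two transversion (purine<->pyrimidine) partners, one of which
# is its Watson-Crick complement; excluding the complement forces a unique
# map A->C, C->A, G->T, T->G, which is its own inverse.

NC_TRANSVERSION <- c(A = "C", C = "A", G = "T", T = "G")
TRANSITION      <- c(A = "G", G = "A", C = "T", T = "C")
COMPLEMENT      <- c(A = "T", T = "A", C = "G", G = "C")

#' Non-complementary transversion of a base
#'
#' The unique purine/pyrimidine swap of `b` that is not its Watson-Crick
#' complement: A->C, C->A, G->T, T->G. An involution. Vectorized.
#'
#' @param b Concrete base(s) in A/C/G/T.
#' @export
nc_transversion <- function(b) {
  b <- toupper(b)
  if (any(!b %in% names(NC_TRANSVERSION)))
    stop("nc_transversion requires A/C/G/T input", call. = FALSE)
  unname(NC_TRANSVERSION[b])
}

#' Mutation pattern specification
#'
#' @param mode `"all"`, `"odd"`, `"even"` (parity of 1-based positions), or
#'   `"block"` (a contiguous 1-based interval).
#' @param block_start,block_len Interval, block mode only.
#' @export
mutation_spec <- function(mode = c("all", "odd", "even", "block"),
                          block_start = NULL, block_len = NULL) {
  mode <- match.arg(mode)
  if (mode == "block") {
    stopifnot(is.numeric(block_start), is.numeric(block_len),
              block_start >= 1, block_len >= 1)
  }
  structure(list(mode = mode,
                 block_start = if (!is.null(block_start)) as.integer(block_start),
                 block_len = if (!is.null(block_len)) as.integer(block_len)),
            class = "mutation_spec")
}

#' Apply a transversion pattern to selected positions
#'
#' Positions selected by the spec (all; 1-based odd; 1-based even; or a block
#' interval) are replaced by their non-complementary transversion; all other
#' positions are untouched. Length is always preserved, and applying the same
#' spec twice returns the original sequence.
#'
#' @param s A `nuc_seq` or character scalar.
#' @param spec A [mutation_spec()] (or its mode as a string).
#' @return Same type as `s`.
#' @export
apply_mutation_pattern <- function(s, spec) {
  if (is.character(spec)) spec <- mutation_spec(spec)
  seqobj <- as_nuc_seq(s)
  ch <- seq_chars(seqobj)
  n <- length(ch)
  idx <- switch(spec$mode,
    all  = seq_len(n),
    odd  = seq(1L, n, by = 2L),
    even = if (n >= 2L) seq(2L, n, by = 2L) else integer(0),
    block = {
      if (spec$block_start + spec$block_len - 1L > n)
        stop("block extends past end of sequence", call. = FALSE)
      seq.int(spec$block_start, length.out = spec$block_len)
    })
  ch[idx] <- nc_transversion(ch[idx])
  out <- paste(ch, collapse = "")
  if (is(s, "nuc_seq")) { s$bases <- out; s } else out
}

#' Tandem-duplicate spacer from a unit sequence
#'
#' Concatenates two copies of the unit, the first altered at every odd base
#' pair and the second at every even base pair by non-complementary
#' transversions. The two copies therefore differ from each other at every
#' position, and each copy differs from the unit at exactly half of them,
#' giving a doubled-length spacer with no perfect internal repeat.
#'
#' @param unit A linear `nuc_seq` (or character scalar).
#' @return A `nuc_seq` of twice the unit length.
#' @export
build_tandem_spacer <- function(unit) {
  u <- as_nuc_seq(unit)
  if (u$topology != "linear")
    stop("tandem spacer unit must be linear", call. = FALSE)
  if (seq_length(u) == 0L) stop("empty unit", call. = FALSE)
  odd  <- apply_mutation_pattern(u$bases, "odd")
  even <- apply_mutation_pattern(u$bases, "even")
  nuc_seq(paste0(odd, even), id = paste0(u$id, "_tandem2x"))
}

#' Deterministically scramble nucleotide composition
#'
#' A uniformly random permutation of the bases driven by an explicit integer
#' seed; the base multiset is preserved exactly and the same (sequence, seed)
#' pair always yields the same output.
#'
#' @param s A linear `nuc_seq` or character scalar.
#' @param seed Integer seed.
#' @return Same type as `s`.
#' @export
scramble_composition <- function(s, seed) {
  seqobj <- as_nuc_seq(s)
  ch <- seq_chars(seqobj)
  out <- withr::with_seed(as.integer(seed),
                          paste(sample(ch), collapse = ""))
  if (is(s, "nuc_seq")) { s$bases <- out; s } else out
}

#' Scanning-block mutant series
#'
#' Tiles the parent 5' to 3' with non-overlapping blocks of `block_len` bp
#' (the final block may be shorter) and emits one mutant per block in which
#' that block - and nothing else - is altered by non-complementary
#' transversions. Because the transversion map changes every base, each
#' mutant differs from the parent at exactly the positions of its block.
#'
#' @param enh Parent `nuc_seq` (typically an enhancer).
#' @param block_len Block size in bp, `1 <= block_len <= length(enh)`.
#' @return An object of class `scan_series`: the parent, block length, a
#'   manifest `data.frame` (mutant id, interval), and the list of mutants.
#' @export
scanning_series <- function(enh, block_len) {
  enh <- as_nuc_seq(enh)
  n <- seq_length(enh)
  block_len <- as.integer(block_len)
  if (block_len < 1L || block_len > n)
    stop("block_len must be in 1..length(enh)", call. = FALSE)
  starts <- seq(1L, n, by = block_len)
  ends <- pmin(starts + block_len - 1L, n)
  mutants <- lapply(seq_along(starts), function(i) {
    m <- apply_mutation_pattern(
      enh, mutation_spec("block", starts[i], ends[i] - starts[i] + 1L))
    m$id <- sprintf("%s_scan%02d_%d-%d", enh$id, i, starts[i], ends[i])
    m
  })
  structure(list(parent = enh, block_len = block_len,
                 manifest = data.frame(
                   mutant = vapply(mutants, function(m) m$id, character(1)),
                   start = starts, end = ends,
                   parent = enh$id, stringsAsFactors = FALSE),
                 mutants = mutants),
            class = "scan_series")
}

#' @export
print.scan_series <- function(x, ...) {
  cat(sprintf("<scan_series> %s: %d mutants, %d bp blocks\n",
              x$parent$id, length(x$mutants), x$block_len))
  print(x$manifest, row.names = FALSE)
  invisible(x)
}
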