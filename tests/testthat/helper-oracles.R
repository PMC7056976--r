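# Independent oracles, deliberately implemented on different machinery than
# the package: degenerate-motif scanning via the PCRE regex engine
# (zero-width lookahead for overlapping matches) and its own complement
# table; translation via seqinr when cross-checking coding scrubs.

ORACLE_IUPAC_REGEX <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")

ORACLE_COMP <- c(A = "T", T = "A", C = "G", G = "C", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

oracle_revcomp <- function(x) {
  paste(rev(ORACLE_COMP[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

oracle_regex <- function(code) {
  paste(ORACLE_IUPAC_REGEX[strsplit(toupper(code), "")[[1]]], collapse = "")
}

# All (overlapping) match start positions of an IUPAC pattern, regex route.
oracle_scan <- function(bases, code, strand_policy = "both",
                        circular = FALSE) {
  m <- nchar(code); n <- nchar(bases)
  subject <- if (circular && m > 1L) paste0(bases, substr(bases, 1L, m - 1L))
             else bases
  one <- function(cd) {
    hits <- gregexpr(paste0("(?=", oracle_regex(cd), ")"), subject,
                     perl = TRUE)[[1]]
    p <- as.integer(hits)
    p <- p[p > 0L]
    p[p <= n]
  }
  out <- data.frame(position = one(code),
                    strand = rep("+", length(one(code))),
                    stringsAsFactors = FALSE)
  if (strand_policy == "both") {
    mn <- one(oracle_revcomp(code))
    out <- rbind(out, data.frame(position = mn,
                                 strand = rep("-", length(mn)),
                                 stringsAsFactors = FALSE))
  }
  out[order(out$position, out$strand), , drop = FALSE]
}

oracle_clean <- function(bases, codes, circular = FALSE) {
  all(vapply(codes, function(cd)
    nrow(oracle_scan(bases, cd, "both", circular)) == 0L, logical(1)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random open reading frame: ATG then non-stop codons (no terminal stop).
random_orf_chr <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                  c("A","C","G","T")), 1, paste,
                      collapse = "")
  pool <- setdiff(all_codons, stops)
  paste0("ATG", paste(sample(pool, n_codons - 1L, replace = TRUE),
                      collapse = ""))
}

# Top-strand sequence of a labelled, plus-strand, non-wrapping feature.
feature_seq_of <- function(map, label) {
  f <- map$features[which(map$features$label == label)[1], ]
  substr(as.character(map$seq), f$start, f$end)
}

# Rotation equivalence of two circular sequences.
same_circle <- function(a, b) {
  nchar(a) == nchar(b) && (nchar(a) == 0L || grepl(b, paste0(a, a),
                                                   fixed = TRUE))
}
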