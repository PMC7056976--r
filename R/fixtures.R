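# Deterministic synthetic-fixture generator: random background DNA of a
# given GC fraction with planted motif instances, restriction sites and
# reading-frame-annotated CDS segments, plus a manifest and an audit of
# chance background matches so plant-then-scrub tests account for every
# occurrence.

#' Specification of a synthetic DNA fixture
#'
#' @param seed Integer; one RNG stream per spec, so identical specs always
#'   produce identical fixtures.
#' @param length Total length in bp.
#' @param gc_fraction Background GC content in 0..1 (default 0.5).
#' @param planted List of plants, each `list(pattern=, count=, strand=)`
#'   where `pattern` is an IUPAC string or [degenerate_pattern()], and
#'   `strand` is `"+"`, `"-"`, or `"random"`.
#' @param cds_segments List of `list(start=, length=)` open reading frames
#'   (ATG start, no internal stops, `length` a multiple of 3) written over
#'   the background; plants never overlap them.
#' @export
fixture_spec <- function(seed, length, gc_fraction = 0.5,
                         planted = list(), cds_segments = list()) {
  stopifnot(length >= 1L, gc_fraction >= 0, gc_fraction <= 1)
  planted <- lapply(planted, function(p) {
    p$pattern <- as_pattern(p$pattern)
    p$count <- as.integer(p$count %||% 1L)
    p$strand <- p$strand %||% "random"
    stopifnot(p$count >= 1L, p$strand %in% c("+", "-", "random"))
    p
  })
  cds_segments <- lapply(cds_segments, function(cs) {
    stopifnot(cs$length %% 3L == 0L, cs$start >= 1L,
              cs$start + cs$length - 1L <= length)
    cs
  })
  structure(list(seed = as.integer(seed), length = as.integer(length),
                 gc_fraction = gc_fraction, planted = planted,
                 cds_segments = cds_segments),
            class = "fixture_spec")
}

random_orf <- function(len) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- setdiff(names(codon_table()), stops)
  k <- len %/% 3L
  paste0("ATG", paste(sample(codons, k - 1L, replace = TRUE), collapse = ""))
}

#' Generate a synthetic DNA fixture
#'
#' Deterministic for a given spec. Planted instances (degenerate patterns are
#' concretized by uniform per-position choice) are written verbatim into
#' non-overlapping windows that also avoid CDS segments; the manifest lists
#' each one with position and strand, and the audit lists chance background
#' matches of every planted pattern so downstream scrub tests can account
#' for all occurrences.
#'
#' @param spec A [fixture_spec()].
#' @param id Sequence id.
#' @param topology Topology of the fixture.
#' @return List: `seq` (`nuc_seq`), `manifest` and `audit` (`data.frame`s).
#' @export
generate_fixture <- function(spec, id = "fixture", topology = "linear") {
  stopifnot(is(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    gc <- spec$gc_fraction
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    ch <- sample(names(probs), spec$length, replace = TRUE, prob = probs)
    occupied <- logical(spec$length)
    for (cs in spec$cds_segments) {
      idx <- seq.int(cs$start, length.out = cs$length)
      ch[idx] <- seq_chars(random_orf(cs$length))
      occupied[idx] <- TRUE
    }
    manifest <- data.frame(what = character(), position = integer(),
                           strand = character(), sequence = character(),
                           stringsAsFactors = FALSE)
    for (p in spec$planted) {
      m <- nchar(p$pattern$code)
      for (k in seq_len(p$count)) {
        placed <- FALSE
        for (try in seq_len(2000L)) {
          pos <- sample.int(spec$length - m + 1L, 1L)
          idx <- seq.int(pos, length.out = m)
          if (any(occupied[idx])) next
          strand <- if (p$strand == "random") sample(c("+", "-"), 1L)
                    else p$strand
          inst <- paste(vapply(seq_chars(p$pattern$code), function(code)
            sample(IUPAC_EXPANSION[[code]], 1L), character(1)),
            collapse = "")
          top <- if (strand == "+") inst else revcomp_chr(inst)
          ch[idx] <- seq_chars(top)
          occupied[idx] <- TRUE
          manifest <- rbind(manifest, data.frame(
            what = p$pattern$label, position = pos, strand = strand,
            sequence = top, stringsAsFactors = FALSE))
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place plant '", p$pattern$label,
               "' (infeasible spec?)", call. = FALSE)
      }
    }
    s <- nuc_seq(paste(ch, collapse = ""), id = id, topology = topology)
    audit <- data.frame(what = character(), position = integer(),
                        strand = character(), stringsAsFactors = FALSE)
    for (p in unique(lapply(spec$planted, `[[`, "pattern"))) {
      hits <- find_matches(s, p, "both")
      if (!nrow(hits)) next
      planted_here <- manifest$position[manifest$what == p$label]
      bg <- hits[!(hits$position %in% planted_here), , drop = FALSE]
      if (nrow(bg))
        audit <- rbind(audit, data.frame(what = p$label,
                                         position = bg$position,
                                         strand = bg$strand,
                                         stringsAsFactors = FALSE))
    }
    list(seq = s, manifest = manifest, audit = audit)
  })
}
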