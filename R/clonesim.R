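# In silico molecular cloning: restriction digestion with overhang
# chemistry, ligation with junction-scar tracking, PCR with tailed and
# degenerate primers, and homology-arm (seamless) assembly.
#
# Fragment convention: the body is the top-strand span between consecutive
# top-strand cuts, so bodies partition the substrate's top strand and
# concatenating them in original order reproduces it exactly. End chemistry
# records the protruding single strand read 5' to 3'; two sticky ends are
# ligatable iff they have the same polarity and their protruding strands are
# reverse complements (blunt joins blunt).

seq_fragment <- function(body, left_end, right_end, warning = NULL) {
  structure(list(body = body, left_end = left_end, right_end = right_end,
                 warning = warning),
            class = "seq_fragment")
}

frag_end <- function(overhang, polarity) {
  stopifnot(polarity %in% c("5p", "3p", "blunt"),
            nchar(overhang) <= 8L,
            polarity != "blunt" || overhang == "")
  list(overhang = overhang, polarity = polarity)
}

blunt_end <- function() frag_end("", "blunt")

#' @export
print.seq_fragment <- function(x, ...) {
  fe <- function(e) if (e$polarity == "blunt") "blunt"
                    else sprintf("%s %s", e$polarity, e$overhang)
  cat(sprintf("<fragment> %s [%d bp] left: %s | right: %s\n",
              x$body$id, seq_length(x$body), fe(x$left_end),
              fe(x$right_end)))
  invisible(x)
}

#' Fragment length (top strand)
#' @param f A `seq_fragment`.
#' @export
fragment_length <- function(f) seq_length(f$body)

# All cut events of the given enzymes on a substrate: one event per
# recognition window (palindromic windows occur once), with top/bottom cut
# gap coordinates (gap g = cut after base g of the top strand).
cut_events <- function(seqobj, enzymes) {
  n <- seq_length(seqobj)
  ev <- data.frame(g_top = integer(), g_bot = integer(),
                   enzyme = character(), site_pos = integer(),
                   stringsAsFactors = FALSE)
  for (e in enzymes) {
    L <- nchar(e$recognition)
    hits <- find_matches(seqobj, degenerate_pattern(e$recognition, e$name),
                         "both")
    if (!nrow(hits)) next
    for (i in seq_len(nrow(hits))) {
      p <- hits$position[i]
      if (hits$strand[i] == "+") {
        g_top <- p - 1L + e$cut_top
        g_bot <- p - 1L + e$cut_bottom
      } else {                      # recognition on the bottom strand
        g_top <- p - 1L + (L - e$cut_bottom)
        g_bot <- p - 1L + (L - e$cut_top)
      }
      # wrap the top cut into 1..n; keep the bottom cut as an offset from
      # it so the overhang window stays local even across the origin
      gt <- ((g_top - 1L) %% n) + 1L
      ev <- rbind(ev, data.frame(g_top = gt, g_bot = gt + (g_bot - g_top),
                                 enzyme = e$name, site_pos = p,
                                 stringsAsFactors = FALSE))
    }
  }
  ev <- unique(ev[, c("g_top", "g_bot", "enzyme", "site_pos")])
  ev[order(ev$g_top), , drop = FALSE]
}

event_ends <- function(seqobj, g_top, g_bot) {
  n <- seq_length(seqobj)
  circ <- seqobj$topology == "circular"
  if (g_top == g_bot)
    return(list(left_right = blunt_end(), right_left = blunt_end()))
  lo <- min(g_top, g_bot); hi <- max(g_top, g_bot)
  ov <- subseq_chr(seqobj$bases, ((lo) %% n) + 1L, ((hi - 1L) %% n) + 1L,
                   circular = circ)
  if (g_top < g_bot) {
    # 5' overhang: upstream fragment's bottom strand protrudes, downstream
    # fragment's top strand protrudes
    list(left_right = frag_end(revcomp_chr(ov), "5p"),
         right_left = frag_end(ov, "5p"))
  } else {
    list(left_right = frag_end(ov, "3p"),
         right_left = frag_end(revcomp_chr(ov), "3p"))
  }
}

#' Digest a construct with restriction enzymes
#'
#' Every recognition occurrence on either strand (circular seam included) is
#' cut at the enzyme's offsets. Fragments are returned in top-strand order
#' with correct end chemistry; a circular substrate with k cuts yields k
#' fragments, a linear one k+1. Top-strand nucleotides are conserved: bodies
#' partition the substrate, each overhang counted once.
#'
#' @param x A [construct_map()] or `nuc_seq`.
#' @param enzymes Character vector of enzyme names or list of
#'   `restriction_enzyme` objects.
#' @return List of `seq_fragment`s. If no enzyme cuts, the substrate is
#'   returned as a single fragment whose `warning` field is set.
#' @export
digest <- function(x, enzymes) {
  seqobj <- if (is(x, "construct_map")) x$seq else as_nuc_seq(x)
  if (is.character(enzymes)) enzymes <- lapply(enzymes, restriction_enzyme)
  ev <- cut_events(seqobj, enzymes)
  n <- seq_length(seqobj)
  circ <- seqobj$topology == "circular"
  if (nrow(ev) == 0L) {
    f <- seq_fragment(seqobj, blunt_end(), blunt_end(),
                      warning = "no recognition site; substrate uncut")
    return(list(f))
  }
  ends <- lapply(seq_len(nrow(ev)),
                 function(i) event_ends(seqobj, ev$g_top[i], ev$g_bot[i]))
  frags <- list()
  if (circ) {
    k <- nrow(ev)
    for (i in seq_len(k)) {
      nxt <- if (i == k) 1L else i + 1L
      a <- ev$g_top[i]; b <- ev$g_top[nxt]
      body <- subseq_chr(seqobj$bases, (a %% n) + 1L,
                         ((b - 1L) %% n) + 1L, circular = TRUE)
      frags[[i]] <- seq_fragment(
        nuc_seq(body, id = sprintf("%s_frag%d", seqobj$id, i)),
        left_end = ends[[i]]$right_left,
        right_end = ends[[nxt]]$left_right)
    }
  } else {
    k <- nrow(ev)
    bounds <- c(0L, ev$g_top, n)
    for (i in seq_len(k + 1L)) {
      body <- substr(seqobj$bases, bounds[i] + 1L, bounds[i + 1L])
      left <- if (i == 1L) blunt_end() else ends[[i - 1L]]$right_left
      right <- if (i == k + 1L) blunt_end() else ends[[i]]$left_right
      frags[[i]] <- seq_fragment(
        nuc_seq(body, id = sprintf("%s_frag%d", seqobj$id, i)),
        left_end = left, right_end = right)
    }
  }
  frags
}

ends_compatible <- function(a, b) {
  if (a$polarity == "blunt" && b$polarity == "blunt") return(TRUE)
  a$polarity == b$polarity && a$overhang == revcomp_chr(b$overhang)
}

#' Ligate fragments in order
#'
#' Adjacent ends join iff compatible: both blunt, or same overhang polarity
#' with protruding strands that are reverse complements. For each junction
#' the merged scar is re-scanned against the supplied enzymes to report
#' whether a cuttable site is (re)generated - e.g. a BamHI end ligated to a
#' BglII end leaves the scar GGATCT, cut by neither parent enzyme.
#'
#' @param fragments Ordered list of `seq_fragment`s.
#' @param circularize Join the last fragment's right end to the first
#'   fragment's left end, producing a circular map.
#' @param enzymes Enzymes to test each junction scar against (names or
#'   objects); defaults to the whole bundled catalog.
#' @param id Identifier for the ligation product.
#' @return List: `map` (a [construct_map()] with junction `site` features)
#'   and `junctions` (`data.frame`: position of the last base contributed by
#'   the upstream fragment, fragment ids, and `recut_by`, a comma-separated
#'   list of enzymes that cut within the scar window).
#' @export
ligate <- function(fragments, circularize = FALSE, enzymes = NULL,
                   id = "ligation") {
  stopifnot(length(fragments) >= 1L)
  if (is.null(enzymes)) enzymes <- enzyme_table()$name
  if (is.character(enzymes)) enzymes <- lapply(enzymes, restriction_enzyme)
  k <- length(fragments)
  pairs <- if (k > 1L) seq_len(k - 1L) else integer(0)
  for (i in pairs) {
    if (!ends_compatible(fragments[[i]]$right_end,
                         fragments[[i + 1L]]$left_end))
      stop("incompatible ends at junction ", i, " (",
           fragments[[i]]$body$id, " | ", fragments[[i + 1L]]$body$id, ")",
           call. = FALSE)
  }
  if (circularize &&
      !ends_compatible(fragments[[k]]$right_end, fragments[[1L]]$left_end))
    stop("incompatible ends at the circularizing junction (",
         fragments[[k]]$body$id, " | ", fragments[[1L]]$body$id, ")",
         call. = FALSE)
  bodies <- vapply(fragments, function(f) f$body$bases, character(1))
  bases <- paste(bodies, collapse = "")
  out <- nuc_seq(bases, id = id,
                 topology = if (circularize) "circular" else "linear")
  jpos <- cumsum(nchar(bodies))
  jpos <- if (circularize) jpos else head(jpos, -1L)
  junctions <- data.frame(position = integer(), upstream = character(),
                          downstream = character(), recut_by = character(),
                          stringsAsFactors = FALSE)
  ft <- features()
  maxrec <- max(vapply(enzymes, function(e) nchar(e$recognition), integer(1)))
  n <- nchar(bases)
  for (j in seq_along(jpos)) {
    g <- jpos[j]                 # junction between base g and g+1 (mod n)
    dn <- if (g == n && circularize) 1L else j + 1L
    dn_id <- fragments[[if (j == k) 1L else j + 1L]]$body$id
    recut <- character(0)
    for (e in enzymes) {
      L <- nchar(e$recognition)
      lo <- g - L + 2L; hi <- g + L - 1L
      if (!circularize) { lo <- max(lo, 1L); hi <- min(hi, n) }
      if (hi - lo + 1L < L) next
      win <- subseq_chr(bases, ((lo - 1L) %% n) + 1L, ((hi - 1L) %% n) + 1L,
                        circular = circularize)
      hits <- find_matches(nuc_seq(win), e$recognition, "both")
      if (nrow(hits)) recut <- c(recut, e$name)
    }
    junctions <- rbind(junctions, data.frame(
      position = g, upstream = fragments[[j]]$body$id, downstream = dn_id,
      recut_by = paste(unique(recut), collapse = ","),
      stringsAsFactors = FALSE))
    ft <- rbind(ft, features(sprintf("junction_%d", j), "site",
                             g, ((g) %% n) + 1L, "+"))
  }
  keep <- ft$end >= ft$start | out$topology == "circular"
  list(map = construct_map(out, ft[keep, , drop = FALSE]),
       junctions = junctions)
}

#' PCR primer with an optional 5' tail
#'
#' The 3'-terminal `min_anneal` bases define annealing (IUPAC-aware exact
#' match); the 5' remainder is the tail carried into the product.
#'
#' @param full Full primer sequence, IUPAC codes allowed.
#' @param name Primer name.
#' @param min_anneal Annealing length in bp (default 15).
#' @export
primer <- function(full, name = "primer", min_anneal = 15L) {
  full <- toupper(full)
  ch <- seq_chars(full)
  if (length(ch) == 0L || any(!ch %in% names(IUPAC_EXPANSION)))
    stop("primer must be a non-empty IUPAC string", call. = FALSE)
  min_anneal <- as.integer(min_anneal)
  if (min_anneal < 1L || min_anneal > length(ch))
    stop("min_anneal must be in 1..nchar(full)", call. = FALSE)
  structure(list(name = name, full = full, min_anneal = min_anneal),
            class = "primer")
}

pcr_error <- function(msg) {
  stop(structure(class = c("rlgl_pcr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Resolve IUPAC codes in a primer region: degenerate positions become the
# lexicographically smallest base of their expansion (documented choice for
# unannealed tails).
resolve_lex <- function(x) {
  ch <- seq_chars(x)
  paste(vapply(ch, function(k) IUPAC_EXPANSION[[k]][1], character(1)),
        collapse = "")
}

#' Simulate PCR with tailed, possibly degenerate primers
#'
#' The forward primer's 3'-terminal annealing window must match the top
#' strand exactly once (IUPAC-aware: a degenerate primer base anneals to any
#' compatible template base) and the reverse primer's window must match the
#' bottom strand exactly once, downstream of the forward footprint. The
#' product is the forward primer's full sequence, the template between the
#' footprints, and the reverse complement of the reverse primer's full
#' sequence; degenerate primer positions resolve to the template base inside
#' footprints and to the lexicographically smallest expansion base in tails.
#' Ends are blunt.
#'
#' @param template A `nuc_seq` or character scalar.
#' @param fwd,rev [primer()] objects (or character sequences).
#' @return A `seq_fragment` (blunt amplicon).
#' @export
simulate_pcr <- function(template, fwd, rev) {
  tpl <- as_nuc_seq(template)
  if (is.character(fwd)) fwd <- primer(fwd, "fwd")
  if (is.character(rev)) rev <- primer(rev, "rev")
  n <- seq_length(tpl)
  circ <- tpl$topology == "circular"
  anneal <- function(p) substr(p$full, nchar(p$full) - p$min_anneal + 1L,
                               nchar(p$full))
  fa <- anneal(fwd); ra <- anneal(rev)
  fhits <- find_matches(tpl, degenerate_pattern(fa, fwd$name), "given")
  rhits <- find_matches(tpl, degenerate_pattern(revcomp_chr(ra), rev$name),
                        "given")
  for (h in list(list(fwd$name, fhits), list(rev$name, rhits))) {
    if (nrow(h[[2]]) == 0L)
      pcr_error(sprintf("no amplicon: primer %s does not anneal", h[[1]]))
    if (nrow(h[[2]]) > 1L)
      pcr_error(sprintf("ambiguous amplicon: primer %s anneals at %d sites",
                        h[[1]], nrow(h[[2]])))
  }
  fpos <- fhits$position[1]; rpos <- rhits$position[1]
  fend <- fpos + fwd$min_anneal - 1L
  rend <- rpos + rev$min_anneal - 1L
  if (!circ && !(fend < rpos))
    pcr_error("no amplicon: reverse footprint is not downstream of forward")
  f_tail <- substr(fwd$full, 1L, nchar(fwd$full) - fwd$min_anneal)
  r_tail <- substr(rev$full, 1L, nchar(rev$full) - rev$min_anneal)
  f_foot <- subseq_chr(tpl$bases, fpos, ((fend - 1L) %% n) + 1L, circ)
  r_foot <- subseq_chr(tpl$bases, rpos, ((rend - 1L) %% n) + 1L, circ)
  mid <- if (((fend) %% n) + 1L == rpos) ""
         else subseq_chr(tpl$bases, (fend %% n) + 1L,
                         ((rpos - 2L) %% n) + 1L, circ)
  top <- paste0(resolve_lex(f_tail), f_foot, mid, r_foot,
                revcomp_chr(resolve_lex(r_tail)))
  seq_fragment(nuc_seq(top, id = sprintf("amplicon_%s_%s",
                                         fwd$name, rev$name)),
               blunt_end(), blunt_end())
}

#' Homology-arm (seamless) assembly of an insert into a linear vector
#'
#' The insert's first `arm_len` bases must equal the vector's last
#' `arm_len` bases and the insert's last `arm_len` bases must equal the
#' vector's first `arm_len` bases (exact match). The joint is seamless: each
#' homologous region appears once, the assembled circle has length
#' `vector + insert - 2*arm_len`.
#'
#' @param linear_vector,insert `seq_fragment`s or `nuc_seq`/character.
#' @param arm_len Homology arm length in bp (default 15).
#' @param id Identifier for the assembly.
#' @return A circular [construct_map()] with vector and insert features.
#' @export
infusion_assemble <- function(linear_vector, insert, arm_len = 15L, id = "assembly") {
  getb <- function(x) if (is(x, "seq_fragment")) x$body$bases
                      else as_nuc_seq(x)$bases
  v <- getb(linear_vector); ins <- getb(insert)
  a <- as.integer(arm_len)
  nv <- nchar(v); ni <- nchar(ins)
  stopifnot(a >= 1L, ni > 2L * a, nv >= a)
  if (substr(ins, 1L, a) != substr(v, nv - a + 1L, nv))
    stop("homology-arm mismatch at the insert 5' end", call. = FALSE)
  if (substr(ins, ni - a + 1L, ni) != substr(v, 1L, a))
    stop("homology-arm mismatch at the insert 3' end", call. = FALSE)
  core <- substr(ins, a + 1L, ni - a)
  s <- nuc_seq(paste0(v, core), id = id, topology = "circular")
  ft <- features(c("vector", "insert"), c("misc", "misc"),
                 c(1L, nv - a + 1L), c(nv, nv + nchar(core)),
                 c("+", "+"))
  construct_map(s, ft)
}
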