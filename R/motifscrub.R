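# Forbidden-motif detection and elimination. Spacer and reporter sequences
# must end up free of Hox-like binding motifs (YTAATKV, TTTAT) and of
# restriction sites reserved as single cutters; coding sequences may only be
# edited synonymously. Scrubbing iterates scan-and-fix to a certified
# zero-residual state and returns an auditable report of every edit.
#
# Matching engine: a vectorized positional scan (per pattern offset j, a
# single membership test of all windows' j-th bases against the IUPAC
# expansion). The scrub loop never rescans the whole sequence after an edit:
# a same-length edit can only create or destroy matches whose windows
# overlap the edited bases, so the match set is updated from a local rescan
# of that neighbourhood.

#' Forbidden-sequence rule
#'
#' @param pattern A [degenerate_pattern()] or IUPAC string.
#' @param strand_policy `"both"` (default; binding sites and restriction sites
#'   are strand-agnostic) or `"given"` (scan the top strand only).
#' @param action `"substitute_min"` (minimal deterministic base substitutions)
#'   or `"fixed_replacement"` (replace the whole matched window with
#'   `replacement`, which must have the same length).
#' @param replacement Replacement text for `fixed_replacement`.
#' @export
forbidden_rule <- function(pattern, strand_policy = c("both", "given"),
                           action = c("substitute_min", "fixed_replacement"),
                           replacement = NULL) {
  pattern <- as_pattern(pattern)
  strand_policy <- match.arg(strand_policy)
  action <- match.arg(action)
  if (action == "fixed_replacement") {
    stopifnot(is.character(replacement), length(replacement) == 1L)
    replacement <- toupper(replacement)
    if (nchar(replacement) != nchar(pattern$code))
      stop("replacement must have the same length as the pattern",
           call. = FALSE)
    if (grepl("[^ACGT]", replacement))
      stop("replacement must be concrete A/C/G/T", call. = FALSE)
  }
  codes <- list(`+` = seq_chars(pattern$code))
  if (strand_policy == "both")
    codes$`-` <- seq_chars(revcomp_chr(pattern$code))
  structure(list(pattern = pattern, strand_policy = strand_policy,
                 action = action, replacement = replacement, codes = codes),
            class = "forbidden_rule")
}

#' Default forbidden-motif rules for spacer design
#'
#' The Abd-B-type TTTAT motif carries its fixed replacement TTGGG; the
#' Hox-like YTAATKV motif and any restriction sites are scrubbed by minimal
#' substitution. All are scanned on both strands.
#'
#' @param single_cutters Enzyme names whose recognition sites must also be
#'   absent (so they stay unique elsewhere in the vector).
#' @return A list of [forbidden_rule()]s.
#' @export
spacer_rules <- function(single_cutters = character()) {
  rules <- list(
    forbidden_rule(degenerate_pattern("TTTAT", "AbdB"),
                   action = "fixed_replacement", replacement = "TTGGG"),
    forbidden_rule(degenerate_pattern("YTAATKV", "Hox-like")))
  for (nm in single_cutters) {
    enz <- restriction_enzyme(nm)
    rules <- c(rules, list(
      forbidden_rule(degenerate_pattern(enz$recognition, nm))))
  }
  rules
}

empty_matches <- function() {
  data.frame(position = integer(), strand = character(),
             match = character(), stringsAsFactors = FALSE)
}

# Vectorized positional scan: all 1-based window starts where every window
# base is in the IUPAC expansion of the corresponding pattern code. Circular
# subjects are scanned across the origin seam.
scan_positional <- function(chars, codes, circular) {
  n <- length(chars); m <- length(codes)
  if (n == 0L || (!circular && m > n)) return(integer(0))
  ext <- if (circular && m > 1L) c(chars, chars[seq_len(min(m - 1L, n))])
         else chars
  np <- length(ext) - m + 1L
  if (np < 1L) return(integer(0))
  ok <- rep(TRUE, np)
  for (j in seq_len(m)) {
    ok <- ok & ext[seq_len(np) + (j - 1L)] %in% IUPAC_EXPANSION[[codes[j]]]
    if (!any(ok)) return(integer(0))
  }
  pos <- which(ok)
  pos[pos <= n]
}

# Per-rule pattern code characters on each scanned strand (a minus-strand
# match is a top-strand occurrence of the reverse-complemented pattern);
# precomputed at rule construction.
rule_strand_codes <- function(rule) rule$codes

scan_rules_chars <- function(chars, rules, circular) {
  pos <- integer(); strand <- character(); rule_i <- integer()
  for (i in seq_along(rules)) {
    for (sd in names(rule_strand_codes(rules[[i]]))) {
      p <- scan_positional(chars, rule_strand_codes(rules[[i]])[[sd]],
                           circular)
      pos <- c(pos, p)
      strand <- c(strand, rep(sd, length(p)))
      rule_i <- c(rule_i, rep(i, length(p)))
    }
  }
  df <- data.frame(position = pos, strand = strand, rule = rule_i,
                   label = vapply(rule_i, function(i)
                     rules[[i]]$pattern$label, character(1)),
                   stringsAsFactors = FALSE)
  df[order(df$position, df$strand, df$rule), , drop = FALSE]
}

# Does the window of length m starting at p (wrapping if circular) satisfy
# the codes?
window_matches <- function(chars, p, codes, circular) {
  n <- length(chars); m <- length(codes)
  if (!circular && (p + m - 1L) > n) return(FALSE)
  idx <- ((p - 1L + seq_len(m) - 1L) %% n) + 1L
  for (j in seq_len(m)) {
    if (!(chars[idx[j]] %in% IUPAC_EXPANSION[[codes[j]]])) return(FALSE)
  }
  TRUE
}

# Matches of the rules whose windows overlap the edited interval
# [estart, estart+elen-1] (top-strand coordinates, wrap allowed).
local_matches <- function(chars, rules, circular, estart, elen) {
  n <- length(chars)
  pos <- integer(); strand <- character(); rule_i <- integer()
  for (i in seq_along(rules)) {
    codes_by_strand <- rule_strand_codes(rules[[i]])
    for (sd in names(codes_by_strand)) {
      codes <- codes_by_strand[[sd]]
      m <- length(codes)
      cand <- (estart - m + 1L):(estart + elen - 1L)
      cand <- if (circular) unique(((cand - 1L) %% n) + 1L)
              else cand[cand >= 1L & cand + m - 1L <= n]
      hit <- cand[vapply(cand, function(p)
        window_matches(chars, p, codes, circular), logical(1))]
      pos <- c(pos, hit)
      strand <- c(strand, rep(sd, length(hit)))
      rule_i <- c(rule_i, rep(i, length(hit)))
    }
  }
  data.frame(position = pos, strand = strand, rule = rule_i,
             stringsAsFactors = FALSE)
}

overlaps_edit <- function(position, m, estart, elen, n, circular) {
  # window [position, position+m-1] vs edit [estart, estart+elen-1], mod n
  if (!circular) {
    position <= estart + elen - 1L & position + m - 1L >= estart
  } else {
    # circular: offset of edit start from window start
    off <- ((estart - position) %% n)
    off < m | ((position - estart) %% n) < elen
  }
}

#' Find all matches of a degenerate pattern
#'
#' Reports every window (overlaps included) whose bases all satisfy the
#' pattern's IUPAC codes, at the 1-based top-strand coordinate of the window.
#' With `strand_policy = "both"` the reverse complement of the pattern is also
#' scanned, reported with strand `"-"` at the same top-strand coordinate; a
#' palindromic window is reported once per strand. Circular sequences are
#' scanned across the origin.
#'
#' @param s A `nuc_seq` or character scalar.
#' @param p A [degenerate_pattern()] or IUPAC string.
#' @param strand_policy `"given"` or `"both"`.
#' @return `data.frame` with columns position, strand, match (top-strand
#'   window sequence).
#' @export
find_matches <- function(s, p, strand_policy = c("both", "given")) {
  strand_policy <- match.arg(strand_policy)
  seqobj <- as_nuc_seq(s)
  p <- as_pattern(p)
  circ <- seqobj$topology == "circular"
  chars <- seq_chars(seqobj)
  m <- nchar(p$code)
  n <- length(chars)
  plus <- scan_positional(chars, seq_chars(p$code), circ)
  out <- data.frame(position = plus, strand = rep("+", length(plus)),
                    stringsAsFactors = FALSE)
  if (strand_policy == "both") {
    minus <- scan_positional(chars, seq_chars(revcomp_chr(p$code)), circ)
    out <- rbind(out, data.frame(position = minus,
                                 strand = rep("-", length(minus)),
                                 stringsAsFactors = FALSE))
  }
  out <- out[order(out$position, out$strand), , drop = FALSE]
  out$match <- vapply(out$position, function(i)
    subseq_chr(seqobj$bases, i, ((i + m - 2L) %% max(n, 1L)) + 1L,
               circular = circ), character(1))
  rownames(out) <- NULL
  out
}

scan_rules <- function(seqobj, rules) {
  scan_rules_chars(seq_chars(seqobj), rules,
                   seqobj$topology == "circular")
}

new_scrub_report <- function(edits, residual, iterations, converged) {
  structure(list(edits = edits, residual = residual,
                 iterations = iterations, converged = converged),
            class = "scrub_report")
}

empty_edits <- function() {
  data.frame(position = integer(), from = character(), to = character(),
             rule = character(), stringsAsFactors = FALSE)
}

#' @export
print.scrub_report <- function(x, ...) {
  cat(sprintf("<scrub_report> %d edits, %d iterations, %s\n",
              nrow(x$edits), x$iterations,
              if (x$converged) "converged (zero residual)"
              else sprintf("NOT converged (%d residual)", nrow(x$residual))))
  if (nrow(x$edits)) print(utils::head(x$edits, 20L), row.names = FALSE)
  invisible(x)
}

scrub_error <- function(msg, report) {
  stop(structure(class = c("rlgl_scrub_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), report = report)))
}

match_keys <- function(df) {
  if (nrow(df)) paste(df$rule, df$position, df$strand) else character(0)
}

# Deterministic substitute_min fix for one match. Candidate positions inside
# the window: non-degenerate pattern positions left to right, then degenerate
# ones; candidate bases at each: the non-complementary transversion, the
# transition, then the complement of the current base. The first candidate
# that (a) no longer satisfies the pattern code at its position and (b) does
# not create any match absent from the pre-edit set is taken. Returns the
# accepted single-base edit or NULL.
fix_substitute_min <- function(chars, match_row, rules, circular,
                               before_keys) {
  r <- rules[[match_row$rule]]
  codes <- rule_strand_codes(r)[[match_row$strand]]
  m <- length(codes)
  n <- length(chars)
  win_pos <- ((match_row$position - 1L + seq_len(m) - 1L) %% n) + 1L
  degeneracy <- lengths(IUPAC_EXPANSION[codes])
  cand_order <- c(which(degeneracy == 1L), which(degeneracy > 1L))
  for (j in cand_order) {
    pos <- win_pos[j]
    cur <- chars[pos]
    for (b in c(NC_TRANSVERSION[[cur]], TRANSITION[[cur]],
                COMPLEMENT[[cur]])) {
      if (iupac_match(b, codes[j])) next      # would still satisfy the code
      trial <- chars
      trial[pos] <- b
      after <- local_matches(trial, rules, circular, pos, 1L)
      if (all(match_keys(after) %in% before_keys))
        return(list(chars = trial, estart = pos, elen = 1L,
                    edit = data.frame(position = pos, from = cur, to = b,
                                      rule = r$pattern$label,
                                      stringsAsFactors = FALSE)))
    }
  }
  NULL
}

#' Scrub forbidden motifs from a noncoding sequence
#'
#' Iterates scan-and-fix until no rule matches anywhere on its declared
#' strands. Fixed-replacement rules substitute the whole matched window with
#' the stated replacement (reverse-complemented for minus-strand matches) and
#' are applied before substitute_min rules; substitute_min edits single bases
#' per a deterministic left-most policy built on the non-complementary
#' transversion. Length is preserved; the report records every edit.
#'
#' @param s A `nuc_seq` or character scalar.
#' @param rules Non-empty list of [forbidden_rule()]s.
#' @param max_iter Iteration cap; defaults to 10x the sequence length.
#'   Non-convergence raises an `rlgl_scrub_error` carrying the report.
#' @return List with elements `seq` (scrubbed `nuc_seq`) and `report`
#'   (a `scrub_report`).
#' @export
scrub_noncoding <- function(s, rules, max_iter = NULL) {
  seqobj <- as_nuc_seq(s)
  stopifnot(length(rules) >= 1L)
  circ <- seqobj$topology == "circular"
  if (is.null(max_iter)) max_iter <- 10L * max(seq_length(seqobj), 1L)
  chars <- seq_chars(seqobj)
  n <- length(chars)
  hits <- scan_rules_chars(chars, rules, circ)
  is_fixed <- vapply(rules, function(r) r$action == "fixed_replacement",
                     logical(1))
  edits <- list()
  it <- 0L
  finish <- function(converged, residual) {
    seqobj$bases <- paste(chars, collapse = "")
    rep <- new_scrub_report(
      if (length(edits)) do.call(rbind, edits) else empty_edits(),
      residual, it, converged)
    if (!converged) scrub_error("scrub did not converge", rep)
    list(seq = seqobj, report = rep)
  }
  repeat {
    if (nrow(hits) == 0L) return(finish(TRUE, empty_matches()))
    if (it >= max_iter) return(finish(FALSE, hits))
    it <- it + 1L
    fixed_sel <- is_fixed[hits$rule]
    pool <- if (any(fixed_sel)) hits[fixed_sel, , drop = FALSE] else hits
    target <- pool[order(pool$position, pool$strand), , drop = FALSE][1L, ]
    r <- rules[[target$rule]]
    if (r$action == "fixed_replacement") {
      m <- nchar(r$pattern$code)
      text <- if (target$strand == "+") r$replacement
              else revcomp_chr(r$replacement)
      idx <- ((target$position - 1L + seq_len(m) - 1L) %% n) + 1L
      old <- paste(chars[idx], collapse = "")
      chars[idx] <- seq_chars(text)
      edits[[length(edits) + 1L]] <- data.frame(
        position = target$position, from = old, to = text,
        rule = r$pattern$label, stringsAsFactors = FALSE)
      estart <- target$position; elen <- m
    } else {
      fix <- fix_substitute_min(chars, target, rules, circ,
                                match_keys(hits))
      if (is.null(fix)) {
        it <- max_iter  # force the explicit non-convergence failure path
        seqobj$bases <- paste(chars, collapse = "")
        scrub_error(sprintf(
          "no safe substitution destroys %s match at %d",
          r$pattern$label, target$position),
          new_scrub_report(
            if (length(edits)) do.call(rbind, edits) else empty_edits(),
            hits, it, FALSE))
      }
      chars <- fix$chars
      edits[[length(edits) + 1L]] <- fix$edit
      estart <- fix$estart; elen <- fix$elen
    }
    # incremental update: only windows overlapping the edit can have changed
    mlen <- vapply(hits$rule, function(i) nchar(rules[[i]]$pattern$code),
                   integer(1))
    touched <- overlaps_edit(hits$position, mlen, estart, elen, n, circ)
    kept <- hits[!touched, , drop = FALSE]
    fresh <- local_matches(chars, rules, circ, estart, elen)
    if (nrow(fresh)) {
      fm <- vapply(fresh$rule, function(i) nchar(rules[[i]]$pattern$code),
                   integer(1))
      fresh <- fresh[overlaps_edit(fresh$position, fm, estart, elen, n,
                                   circ), , drop = FALSE]
    }
    hits <- rbind(kept[, c("position", "strand", "rule")],
                  fresh[, c("position", "strand", "rule")])
    hits <- hits[order(hits$position, hits$strand, hits$rule), ,
                 drop = FALSE]
  }
}

#' Certify a sequence free of forbidden matches
#'
#' A full independent re-scan (no scrub bookkeeping reused) of every rule on
#' its declared strands.
#'
#' @param s A `nuc_seq` or character scalar.
#' @param rules List of [forbidden_rule()]s.
#' @return List: `clean` (logical) and `matches` (residual match table).
#' @export
verify_clean <- function(s, rules) {
  seqobj <- as_nuc_seq(s)
  hits <- do.call(rbind, lapply(rules, function(r) {
    df <- find_matches(seqobj, r$pattern, r$strand_policy)
    df$label <- rep(r$pattern$label, nrow(df))
    df
  }))
  list(clean = nrow(hits) == 0L, matches = hits)
}

codon_table <- function() Biostrings::GENETIC_CODE

#' Translate a coding sequence (standard genetic code)
#'
#' @param cds A `nuc_seq` or character scalar; length must be a multiple of 3.
#' @return Amino-acid string (stop = `*`).
#' @export
translate_cds <- function(cds) {
  b <- as_nuc_seq(cds)$bases
  if (nchar(b) %% 3L != 0L)
    stop("CDS length is not a multiple of 3", call. = FALSE)
  if (!nzchar(b)) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(b),
                                     no.init.codon = TRUE))
}

synonymous_codons <- function(codon) {
  tab <- codon_table()
  names(tab)[tab == tab[[codon]]]
}

#' Remove a restriction site from a CDS by synonymous substitution
#'
#' Destroys every occurrence of `site` (both strands by default) within the
#' coding region while conserving the translated protein exactly, preferring
#' a single base change. Among qualifying edits the tie-break is minimal
#' Hamming distance, then left-most codon, then lexicographically smallest
#' replacement codon. Fails with an `rlgl_scrub_error` when no synonymous
#' edit can destroy a site (e.g. a site spanning only Met/Trp codons).
#'
#' @param cds A `nuc_seq` or character scalar.
#' @param site The recognition pattern to remove.
#' @param frame_start 1-based position of the first codon's first base;
#'   the in-frame region from there must cover the site in whole codons.
#' @param strand_policy Strands to scan for the site.
#' @return List with `seq` (edited `nuc_seq`) and `report` (`scrub_report`
#'   whose from/to columns are codons).
#' @export
scrub_coding_synonymous <- function(cds, site, frame_start = 1L,
                                    strand_policy = c("both", "given")) {
  strand_policy <- match.arg(strand_policy)
  seqobj <- as_nuc_seq(cds)
  site <- as_pattern(site)
  n <- seq_length(seqobj)
  frame_start <- as.integer(frame_start)
  n_codons <- (n - frame_start + 1L) %/% 3L
  if (n_codons < 1L) stop("no complete codon in frame", call. = FALSE)
  codon_start <- function(k) frame_start + 3L * (k - 1L)
  get_codon <- function(bases, k)
    substr(bases, codon_start(k), codon_start(k) + 2L)
  site_count <- function(bases)
    nrow(find_matches(nuc_seq(bases, topology = seqobj$topology),
                      site, strand_policy))
  edits <- empty_edits()
  it <- 0L
  repeat {
    hits <- find_matches(seqobj, site, strand_policy)
    if (nrow(hits) == 0L)
      return(list(seq = seqobj,
                  report = new_scrub_report(edits, empty_matches(), it, TRUE)))
    it <- it + 1L
    target <- hits[1L, ]
    m <- nchar(site$code)
    win <- seq.int(target$position, length.out = m)
    win <- win[win >= frame_start]
    k_set <- unique((win - frame_start) %/% 3L + 1L)
    k_set <- k_set[k_set >= 1L & k_set <= n_codons]
    base_count <- site_count(seqobj$bases)
    best <- NULL
    for (k in sort(k_set)) {
      cur <- get_codon(seqobj$bases, k)
      for (alt in sort(setdiff(synonymous_codons(cur), cur))) {
        d <- sum(seq_chars(alt) != seq_chars(cur))
        trial <- replace_window(seqobj$bases, codon_start(k), 3L, alt, FALSE)
        cnt <- site_count(trial)
        if (cnt >= base_count) next          # site not destroyed / new one made
        cand <- list(k = k, from = cur, to = alt, d = d, bases = trial)
        if (is.null(best) || d < best$d ||
            (d == best$d && (k < best$k || (k == best$k && alt < best$to))))
          best <- cand
      }
    }
    if (is.null(best))
      scrub_error(sprintf(
        "no synonymous edit destroys %s site at %d",
        site$label, target$position),
        new_scrub_report(edits, hits, it, FALSE))
    seqobj$bases <- best$bases
    edits <- rbind(edits, data.frame(position = codon_start(best$k),
                                     from = best$from, to = best$to,
                                     rule = site$label,
                                     stringsAsFactors = FALSE))
  }
}

# Replace the window [start, start+len-1] (wrapping if circular) with text.
replace_window <- function(bases, start, len, text, circular) {
  n <- nchar(bases)
  end <- start + len - 1L
  if (end <= n) {
    paste0(substr(bases, 1L, start - 1L), text, substr(bases, end + 1L, n))
  } else {
    stopifnot(circular)
    over <- end - n
    paste0(substr(text, len - over + 1L, len),
           substr(bases, over + 1L, start - 1L),
           substr(text, 1L, len - over))
  }
}
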