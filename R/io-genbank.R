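# Minimal GenBank flat-file dialect: LOCUS / FEATURES / ORIGIN records with
# 1-based inclusive locations, complement() for minus-strand features and
# join() for features spanning the origin of a circular map. Feature kinds
# promoter and CDS use their native keys; everything else is a misc_feature
# carrying /label and a kind note so maps round-trip losslessly.

GB_NATIVE_KEYS <- c(promoter = "promoter", CDS = "CDS")

#' Write a construct map as a GenBank flat file
#'
#' @param map A [construct_map()].
#' @param path Output file.
#' @export
write_genbank <- function(map, path) {
  stopifnot(is(map, "construct_map"))
  s <- map$seq
  n <- seq_length(s)
  lines <- sprintf("LOCUS       %-16s %d bp    DNA     %-8s UNA %s",
                   s$id, n, s$topology,
                   toupper(format(Sys.Date(), "%d-%b-%Y")))
  lines <- c(lines, "FEATURES             Location/Qualifiers")
  ft <- map$features
  if (nrow(ft)) for (i in seq_len(nrow(ft))) {
    kind <- ft$kind[i]
    key <- if (kind %in% names(GB_NATIVE_KEYS)) GB_NATIVE_KEYS[[kind]]
           else "misc_feature"
    loc <- if (ft$end[i] >= ft$start[i]) {
      sprintf("%d..%d", ft$start[i], ft$end[i])
    } else {                       # wraps the origin of a circular map
      sprintf("join(%d..%d,1..%d)", ft$start[i], n, ft$end[i])
    }
    if (ft$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    lines <- c(lines,
               sprintf("     %-15s %s", key, loc),
               sprintf("                     /label=\"%s\"", ft$label[i]))
    if (key == "misc_feature")
      lines <- c(lines,
                 sprintf("                     /note=\"kind: %s\"", kind))
  }
  lines <- c(lines, "ORIGIN")
  ch <- tolower(s$bases)
  pos <- seq(1L, max(n, 1L), by = 60L)
  if (n > 0L) for (p in pos) {
    chunk <- substr(ch, p, min(p + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p, paste(tens, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GenBank flat file written by [write_genbank()]
#'
#' @param path GenBank file.
#' @return A [construct_map()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) != 1L)
    stop("malformed GenBank: expected one LOCUS line in ", path, call. = FALSE)
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  id <- toks[2]
  topology <- if (any(tolower(toks) == "circular")) "circular" else "linear"
  io <- grep("^ORIGIN", lines)
  if (length(io) != 1L)
    stop("malformed GenBank: missing ORIGIN in ", path, call. = FALSE)
  seq_lines <- lines[(io + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  bases <- toupper(gsub("[ 0-9]", "", paste(seq_lines, collapse = "")))
  s <- nuc_seq(bases, id = id, topology = topology)

  ifeat <- grep("^FEATURES", lines)
  ft <- features()
  if (length(ifeat) == 1L && io > ifeat + 1L) {
    body <- lines[(ifeat + 1L):(io - 1L)]
    starts <- grep("^     \\S", body)
    for (k in seq_along(starts)) {
      i0 <- starts[k]
      i1 <- if (k < length(starts)) starts[k + 1L] - 1L else length(body)
      head_toks <- strsplit(trimws(body[i0]), "\\s+")[[1]]
      key <- head_toks[1]; loc <- head_toks[2]
      quals <- body[seq.int(i0, i1)][-1]
      lab <- sub('.*/label="([^"]*)".*', "\\1",
                 grep("/label=", quals, value = TRUE)[1])
      note <- grep("/note=\"kind:", quals, value = TRUE)
      strand <- "+"
      if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
      }
      if (grepl("^join\\(", loc)) {
        parts <- strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",")[[1]]
        a <- as.integer(strsplit(parts[1], "\\.\\.")[[1]])
        b <- as.integer(strsplit(parts[2], "\\.\\.")[[1]])
        if (b[1] != 1L || a[2] != seq_length(s))
          stop("unsupported join() location '", loc, "' in ", path,
               call. = FALSE)
        start <- a[1]; end <- b[2]
      } else {
        se <- as.integer(strsplit(loc, "\\.\\.")[[1]])
        if (length(se) == 1L) se <- c(se, se)
        start <- se[1]; end <- se[2]
      }
      kind <- if (key %in% GB_NATIVE_KEYS) key
              else if (length(note)) sub('.*kind: ([a-zA-Z_]+)".*', "\\1",
                                         note[1])
              else "misc"
      ft <- rbind(ft, features(lab, kind, start, end, strand))
    }
  }
  construct_map(s, ft)
}
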