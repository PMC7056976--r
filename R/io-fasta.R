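#' Read a multi-record FASTA file
#'
#' Lowercase bases are normalized to uppercase; any non-ACGT character is an
#' error naming the offending record. Topology is not encoded in FASTA and
#' defaults to linear.
#'
#' @param path FASTA file.
#' @param topology Topology assigned to every record.
#' @return A list of [nuc_seq()] objects, named by record id.
#' @export
read_fasta <- function(path, topology = "linear") {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set), function(i) {
    b <- toupper(as.character(set[[i]]))
    if (grepl("[^ACGT]", b))
      stop("non-ACGT base in FASTA record '", ids[i], "' of ", path,
           call. = FALSE)
    nuc_seq(b, id = ids[i], topology = topology)
  })
  setNames(out, ids)
}

#' Write sequences as FASTA (60-column wrap)
#'
#' @param seqs A `nuc_seq` or list of them.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is(seqs, "nuc_seq")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, as.character, character(1)))
  names(set) <- vapply(seqs, function(s) s$id, character(1))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
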