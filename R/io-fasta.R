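#' Read a reference genome from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] with the pipeline's
#' conventions applied: headers are truncated at the first whitespace,
#' sequence is upper-cased, duplicate or empty records are errors.
#'
#' @param path FASTA file.
#' @return Named character vector, one uppercase sequence per chromosome.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(Biostrings::width(seqs) == 0L)) {
    stop("empty FASTA record: ", paste(ids[Biostrings::width(seqs) == 0L],
                                       collapse = ", "), call. = FALSE)
  }
  setNames(toupper(as.character(seqs)), ids)
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}
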