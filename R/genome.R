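#' Load a genome from FASTA
#'
#' Reads a (optionally gzipped) FASTA file into a `DNAStringSet`. Sequence
#' names are truncated at the first whitespace, case is normalized to upper
#' case, and names are required to be unique and non-empty.
#'
#' @param path path to a FASTA or FASTA.gz file.
#' @param include_pattern optional regular expression; only sequences whose
#'   name matches are kept (e.g. `"^chr[0-9XY]+$"` to drop decoys/contigs).
#' @return a named `DNAStringSet`.
#' @export
read_genome <- function(path, include_pattern = NULL) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (!is.null(include_pattern)) {
    genome <- genome[grepl(include_pattern, names(genome))]
    if (!length(genome)) stop("include_pattern removed every sequence")
  }
  check_genome(genome)
  genome
}

# Accept a named character vector or DNAStringSet; return a DNAStringSet.
as_genome <- function(genome) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  check_genome(genome)
  genome
}

check_genome <- function(genome) {
  nm <- names(genome)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("genome sequences must all be named")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  invisible(genome)
}

genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}
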