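# Internal helpers shared across modules.

# IUPAC nucleotide codes -> set of concrete bases each code stands for.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

is_iupac <- function(x) {
  all(strsplit(toupper(x), "")[[1]] %in% names(IUPAC_SETS))
}

#' Reverse complement of a DNA string (IUPAC-aware)
#'
#' @param x character scalar or vector of DNA sequences (IUPAC codes allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length strings. N is a literal
# character here; callers decide how N is scored (see assign_barcode).
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  if (length(ra) != length(rb)) stop("hamming(): sequences differ in length")
  sum(ra != rb)
}

# Coerce a 0-based half-open interval data frame and validate columns.
as_intervals <- function(x, require_class = FALSE) {
  x <- as.data.frame(x)
  need <- c("chrom", "start", "end")
  if (require_class) need <- c(need, "class")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("interval table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(x) && any(x$start < 0 | x$end < x$start)) {
    stop("intervals must satisfy 0 <= start <= end")
  }
  x
}

# Convert 0-based half-open intervals to GRanges (1-based closed).
intervals_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# Convert 0-based point positions to width-1 GRanges.
points_to_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pos + 1L, width = 1L)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
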