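#' Nuclear barcode set
#'
#' A set of inline (nuclear) barcodes of common length. The minimum pairwise
#' Hamming distance is computed at construction; duplicate sequences or ids
#' and unequal lengths are errors.
#'
#' @param ids character vector of unique barcode ids, or a two-column data
#'   frame (`id`, `sequence`) when `sequences` is missing.
#' @param sequences DNA sequences over A/C/G/T, all the same length.
#' @return an object of class `barcode_set`: data frame (`id`, `sequence`)
#'   with attributes `bc_length` and `min_distance`.
#' @export
barcode_set <- function(ids, sequences) {
  if (missing(sequences)) {
    df <- as.data.frame(ids)
    if (!all(c("id", "sequence") %in% names(df))) {
      stop("expected columns 'id' and 'sequence'")
    }
    ids <- df$id; sequences <- df$sequence
  }
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (!length(ids) || length(ids) != length(sequences)) {
    stop("ids and sequences must be non-empty and of equal length")
  }
  if (anyDuplicated(ids)) stop("barcode ids must be unique")
  if (any(!nzchar(sequences))) stop("barcode sequences must be non-empty")
  if (any(grepl("[^ACGT]", sequences))) {
    stop("barcode sequences must be over A,C,G,T only")
  }
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("all barcodes must have the same length")
  if (anyDuplicated(sequences)) stop("duplicate barcode sequences")
  out <- data.frame(id = ids, sequence = sequences)
  class(out) <- c("barcode_set", "data.frame")
  attr(out, "bc_length") <- L
  attr(out, "min_distance") <-
    if (length(sequences) >= 2L) min_pairwise_distance_chr(sequences) else NA_integer_
  out
}

#' @export
print.barcode_set <- function(x, ...) {
  cat("Barcode set: ", nrow(x), " barcodes of length ", attr(x, "bc_length"),
      ", min pairwise Hamming distance ", attr(x, "min_distance"), "\n",
      sep = "")
  invisible(x)
}

#' Read a barcode table
#'
#' Tab-separated `id<TAB>sequence`, no header, `#` comments.
#'
#' @param path path to the TSV file.
#' @return a [barcode_set()].
#' @export
read_barcodes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#",
                          col.names = c("id", "sequence"),
                          colClasses = "character")
  barcode_set(df$id, df$sequence)
}

#' Write a barcode table
#' @param set a `barcode_set`.
#' @param path output TSV path.
#' @export
write_barcodes <- function(set, path) {
  utils::write.table(set[, c("id", "sequence")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Minimum pairwise Hamming distance of a barcode set
#'
#' @param set a `barcode_set` (or character vector of equal-length
#'   sequences) with at least two members.
#' @return integer minimum over all unordered pairs.
#' @export
min_pairwise_distance <- function(set) {
  seqs <- if (inherits(set, "barcode_set")) set$sequence else as.character(set)
  if (length(seqs) < 2L) stop("need at least 2 barcodes")
  if (length(unique(nchar(seqs))) != 1L) stop("unequal barcode lengths")
  min_pairwise_distance_chr(seqs)
}

min_pairwise_distance_chr <- function(seqs) {
  raws <- lapply(seqs, charToRaw)
  n <- length(raws)
  m <- Inf
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- sum(raws[[i]] != raws[[j]])
      if (d < m) m <- d
    }
  }
  as.integer(m)
}

#' Validate a barcode set for unambiguous decoding
#'
#' Decoding with up to `max_mismatch` substitutions per read is guaranteed
#' unambiguous iff the minimum pairwise Hamming distance is at least
#' `2 * max_mismatch + 1`. Homopolymer runs of 4 or more and GC content
#' outside 25--75% are flagged as warnings (synthesis/sequencing
#' robustness), not failures.
#'
#' @param set a `barcode_set`.
#' @param max_mismatch per-mate substitution budget (default 1).
#' @return an object of class `barcode_validation`: `pass`, `min_distance`,
#'   `required_distance`, `violating_pairs` (data frame), `warnings`
#'   (data frame with `id`, `issue`).
#' @export
validate_barcode_set <- function(set, max_mismatch = 1L) {
  stopifnot(inherits(set, "barcode_set"))
  max_mismatch <- as.integer(max_mismatch)
  if (max_mismatch < 0L) stop("max_mismatch must be >= 0")
  required <- 2L * max_mismatch + 1L

  seqs <- set$sequence
  viol <- list()
  md <- Inf
  if (length(seqs) >= 2L) {
    raws <- lapply(seqs, charToRaw)
    for (i in seq_len(length(seqs) - 1L)) {
      for (j in (i + 1L):length(seqs)) {
        d <- sum(raws[[i]] != raws[[j]])
        md <- min(md, d)
        if (d < required) {
          viol[[length(viol) + 1L]] <-
            data.frame(id1 = set$id[i], id2 = set$id[j], distance = d)
        }
      }
    }
  }
  violating_pairs <- if (length(viol)) do.call(rbind, viol) else
    data.frame(id1 = character(0), id2 = character(0), distance = integer(0))

  warn <- list()
  gc <- gc_content(seqs)
  homo <- grepl("A{4,}|C{4,}|G{4,}|T{4,}", seqs)
  for (k in seq_along(seqs)) {
    if (homo[k]) {
      warn[[length(warn) + 1L]] <-
        data.frame(id = set$id[k], issue = "homopolymer_run")
    }
    if (gc[k] < 0.25 || gc[k] > 0.75) {
      warn[[length(warn) + 1L]] <-
        data.frame(id = set$id[k], issue = "gc_out_of_range")
    }
  }
  warnings <- if (length(warn)) do.call(rbind, warn) else
    data.frame(id = character(0), issue = character(0))

  structure(
    list(
      pass = nrow(violating_pairs) == 0L,
      min_distance = if (is.finite(md)) as.integer(md) else NA_integer_,
      required_distance = required,
      max_mismatch = max_mismatch,
      violating_pairs = violating_pairs,
      warnings = warnings
    ),
    class = "barcode_validation"
  )
}

#' @export
print.barcode_validation <- function(x, ...) {
  cat("Barcode validation: ", if (x$pass) "PASS" else "FAIL",
      " (min distance ", x$min_distance, ", required ", x$required_distance,
      " for max_mismatch = ", x$max_mismatch, ")\n", sep = "")
  if (nrow(x$violating_pairs)) {
    cat("Violating pairs:\n")
    print(x$violating_pairs, row.names = FALSE)
  }
  if (nrow(x$warnings)) {
    cat(nrow(x$warnings), "composition warning(s)\n")
  }
  invisible(x)
}

gc_content <- function(seqs) {
  vapply(seqs, function(s) {
    r <- charToRaw(s)
    mean(r == charToRaw("G") | r == charToRaw("C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Generate a random decodable barcode set
#'
#' Greedy rejection sampling: random A/C/G/T sequences are accepted when
#' they keep the minimum pairwise distance at or above `min_distance` and
#' (optionally) avoid homopolymer runs >= 4 and extreme GC.
#'
#' @param n number of barcodes.
#' @param length barcode length in bp (default 8).
#' @param min_distance minimum pairwise Hamming distance (default 3, i.e.
#'   unambiguous decoding at one mismatch).
#' @param seed optional RNG seed for reproducibility.
#' @param clean_composition also enforce the composition warnings.
#' @param max_tries sampling attempts before giving up.
#' @return a [barcode_set()].
#' @export
generate_barcodes <- function(n, length = 8L, min_distance = 3L, seed = NULL,
                              clean_composition = TRUE, max_tries = 100000L) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  accepted <- character(0)
  tries <- 0L
  while (length(accepted) < n && tries < max_tries) {
    tries <- tries + 1L
    cand <- paste(sample(bases, length, replace = TRUE), collapse = "")
    if (clean_composition) {
      if (grepl("A{4,}|C{4,}|G{4,}|T{4,}", cand)) next
      gc <- gc_content(cand)
      if (gc < 0.25 || gc > 0.75) next
    }
    if (length(accepted)) {
      rc <- charToRaw(cand)
      ok <- all(vapply(accepted, function(a) {
        sum(charToRaw(a) != rc) >= min_distance
      }, logical(1)))
      if (!ok) next
    }
    accepted <- c(accepted, cand)
  }
  if (length(accepted) < n) {
    stop("could not generate ", n, " barcodes at min_distance ",
         min_distance, " within ", max_tries, " tries")
  }
  barcode_set(sprintf("bc%02d", seq_len(n)), accepted)
}

#' Hairpin adapter template
#'
#' Schematic single-strand hairpin: a stem arm, a loop carrying a cleavable
#' base placeholder (`U`), the barcode slot (`[BC]`), the reverse-complement
#' stem arm, and an optional 3' T overhang for ligation to A-tailed
#' fragments. The exact commercial oligo architecture is proprietary; the
#' template is fully configurable.
#'
#' @param name template name.
#' @param stem 5' stem arm (the 3' arm is its reverse complement).
#' @param loop loop sequence; may contain `U` as the cleavable-base
#'   placeholder.
#' @param barcode_length expected barcode slot length.
#' @param overhang logical; append the 3' T overhang.
#' @return an object of class `hairpin_template`.
#' @export
hairpin_template <- function(name = "schematic",
                             stem = "GACGTGTGCT",
                             loop = "CCUCC",
                             barcode_length = 8L,
                             overhang = TRUE) {
  structure(
    list(
      name = name,
      stem = toupper(stem),
      loop = toupper(loop),
      barcode_length = as.integer(barcode_length),
      overhang = isTRUE(overhang),
      sequence = paste0(toupper(stem), toupper(loop), "[BC]",
                        revcomp(toupper(stem)), if (overhang) "T" else "")
    ),
    class = "hairpin_template"
  )
}

#' Build a hairpin adapter for one barcode
#'
#' Deterministically substitutes the barcode into the template's single
#' `[BC]` slot.
#'
#' @param barcode barcode sequence (character) or a one-row slice of a
#'   `barcode_set`.
#' @param template a [hairpin_template()].
#' @param id optional barcode id for labeling.
#' @return an object of class `hairpin_adapter`: `id`, `barcode`,
#'   `full_sequence`, `template_name`, `overhang`.
#' @export
build_hairpin <- function(barcode, template = hairpin_template(), id = NULL) {
  if (is.data.frame(barcode)) {
    id <- id %||% barcode$id[1]
    barcode <- barcode$sequence[1]
  }
  barcode <- toupper(barcode)
  if (lengths(regmatches(template$sequence,
                         gregexpr("[BC]", template$sequence, fixed = TRUE))) != 1L) {
    stop("template must contain exactly one [BC] slot")
  }
  if (nchar(barcode) != template$barcode_length) {
    stop("barcode length ", nchar(barcode), " does not match template slot (",
         template$barcode_length, ")")
  }
  structure(
    list(
      id = id %||% barcode,
      barcode = barcode,
      full_sequence = sub("[BC]", barcode, template$sequence, fixed = TRUE),
      template_name = template$name,
      overhang = template$overhang
    ),
    class = "hairpin_adapter"
  )
}

#' Expected read prefix for a barcode
#'
#' After adapter opening and A-tailing chemistry, each mate is expected to
#' start with the barcode followed by a fixed junction base (a T from the
#' A-tail) before the genomic insert.
#'
#' @param barcode barcode sequence.
#' @param junction_bases number of fixed junction bases after the barcode
#'   (default 1).
#' @param junction_base the junction base character (default `"T"`).
#' @return the expected 5' read prefix.
#' @export
expected_read_prefix <- function(barcode, junction_bases = 1L,
                                 junction_base = "T") {
  paste0(toupper(barcode), strrep(junction_base, junction_bases))
}
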