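#' Demultiplexing options
#'
#' @param max_mismatch per-mate substitution budget for barcode matching
#'   (default 1: reads with more than one mismatch against every barcode on
#'   a mate are discarded).
#' @param junction_bases fixed bases between barcode and insert, trimmed
#'   together with the barcode (default 1).
#' @param require_mate_agreement if `TRUE` (default) a pair is assigned only
#'   when both mates decode to the same barcode; if `FALSE`, assignment is
#'   by mate 1 alone.
#' @param count_N_as_mismatch score read N bases as mismatches (default
#'   `TRUE`, conservative).
#' @return a list of class `demux_options`.
#' @export
demux_options <- function(max_mismatch = 1L, junction_bases = 1L,
                          require_mate_agreement = TRUE,
                          count_N_as_mismatch = TRUE) {
  max_mismatch <- as.integer(max_mismatch)
  junction_bases <- as.integer(junction_bases)
  if (max_mismatch < 0L) stop("max_mismatch must be >= 0")
  if (junction_bases < 0L) stop("junction_bases must be >= 0")
  structure(
    list(max_mismatch = max_mismatch, junction_bases = junction_bases,
         require_mate_agreement = isTRUE(require_mate_agreement),
         count_N_as_mismatch = isTRUE(count_N_as_mismatch)),
    class = "demux_options"
  )
}

#' Assign read prefixes to barcodes by Hamming distance
#'
#' Compares the first `L` bases of each prefix against every barcode and
#' returns the unique barcode with minimal distance at most `max_mismatch`.
#' Ties at the minimal distance give `ambiguous`; distances just over
#' budget give `mismatch_exceeded`; prefixes far from every barcode give
#' `no_match` (farther than `max_mismatch + 2` from the closest); prefixes
#' shorter than the barcode give `too_short`.
#'
#' @param prefix character vector of read 5' sequences (at least the
#'   barcode length; longer prefixes are fine, only the first `L` bases are
#'   compared).
#' @param set a [barcode_set()].
#' @param max_mismatch substitution budget.
#' @param count_N_as_mismatch score N in the read as a mismatch (default
#'   `TRUE`); if `FALSE`, N matches any barcode base.
#' @return data frame with one row per prefix: `barcode` (id or `NA`),
#'   `mismatches` (to the assigned barcode, `NA` if unassigned), `reason`
#'   (`NA` when assigned, else one of `no_match`, `mismatch_exceeded`,
#'   `ambiguous`, `too_short`).
#' @export
assign_barcode <- function(prefix, set, max_mismatch = 1L,
                           count_N_as_mismatch = TRUE) {
  stopifnot(inherits(set, "barcode_set"))
  if (!nrow(set)) stop("empty barcode set")
  L <- attr(set, "bc_length")
  n <- length(prefix)

  barcode <- rep(NA_character_, n)
  mismatches <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)

  too_short <- nchar(prefix) < L
  reason[too_short] <- "too_short"
  ok <- which(!too_short)
  if (length(ok)) {
    pr <- substr(prefix[ok], 1L, L)
    praw <- matrix(charToRaw(paste(pr, collapse = "")), nrow = L)
    n_mask <- if (!count_N_as_mismatch) praw == charToRaw("N") else NULL

    dist <- matrix(0L, nrow = length(ok), ncol = nrow(set))
    for (b in seq_len(nrow(set))) {
      braw <- charToRaw(set$sequence[b])
      neq <- praw != braw
      if (!is.null(n_mask)) neq <- neq & !n_mask
      dist[, b] <- .colSums(neq, L, length(ok))
    }
    dmin <- do.call(pmin, as.data.frame(dist))
    n_at_min <- .rowSums(dist == dmin, length(ok), nrow(set))

    assigned <- dmin <= max_mismatch & n_at_min == 1L
    ambig <- dmin <= max_mismatch & n_at_min > 1L
    over <- dmin > max_mismatch

    if (any(assigned)) {
      best <- max.col(-dist[assigned, , drop = FALSE], ties.method = "first")
      barcode[ok[assigned]] <- set$id[best]
      mismatches[ok[assigned]] <- dmin[assigned]
    }
    reason[ok[ambig]] <- "ambiguous"
    reason[ok[over]] <- ifelse(dmin[over] <= max_mismatch + 2L,
                               "mismatch_exceeded", "no_match")
  }
  data.frame(barcode = barcode, mismatches = mismatches, reason = reason)
}

#' Paired-end read container
#'
#' @param read_id character vector of unique pair ids.
#' @param seq1,seq2 mate sequences.
#' @param qual1,qual2 optional per-base quality strings (same lengths as the
#'   sequences).
#' @return a data frame of class `read_pairs`.
#' @export
read_pairs <- function(read_id, seq1, seq2, qual1 = NULL, qual2 = NULL) {
  n <- length(read_id)
  qual1 <- qual1 %||% strrep("I", nchar(seq1))
  qual2 <- qual2 %||% strrep("I", nchar(seq2))
  stopifnot(length(seq1) == n, length(seq2) == n,
            all(nchar(qual1) == nchar(seq1)),
            all(nchar(qual2) == nchar(seq2)))
  if (anyDuplicated(read_id)) stop("read ids must be unique")
  out <- data.frame(read_id = as.character(read_id),
                    seq1 = toupper(seq1), qual1 = qual1,
                    seq2 = toupper(seq2), qual2 = qual2)
  class(out) <- c("read_pairs", "data.frame")
  out
}

#' Demultiplex paired-end reads by inline nuclear barcode
#'
#' Decodes both mates independently against the barcode set. With
#' `require_mate_agreement` a pair is assigned only when both mates decode
#' to the same barcode; otherwise it is discarded as `mate_disagreement`
#' (or with the reason of the failing mate). Assigned pairs have
#' barcode + junction bases trimmed from the 5' end of both mates
#' (sequence and quality); mates stay synchronized.
#'
#' @param pairs a [read_pairs()] data frame.
#' @param set a [barcode_set()]; a decodability warning is issued (not an
#'   error) if the set fails [validate_barcode_set()] at `max_mismatch`.
#' @param opts a [demux_options()].
#' @return an object of class `demux_result`: `assignments` (per pair:
#'   `read_id`, `barcode`, `mm1`, `mm2`, `reason`), `reads` (trimmed
#'   `read_pairs` for assigned pairs, with a `barcode` column), and
#'   `stats` (totals, per-barcode counts, discard counts by reason).
#' @export
demux_pairs <- function(pairs, set, opts = demux_options()) {
  stopifnot(inherits(set, "barcode_set"), inherits(opts, "demux_options"))
  if (!nrow(set)) stop("empty barcode set")
  val <- validate_barcode_set(set, opts$max_mismatch)
  if (!val$pass) {
    warning("barcode set is not guaranteed decodable at max_mismatch = ",
            opts$max_mismatch, " (min distance ", val$min_distance, ")")
  }
  n <- nrow(pairs)
  L <- attr(set, "bc_length")
  trim <- L + opts$junction_bases

  a1 <- assign_barcode(pairs$seq1, set, opts$max_mismatch,
                       opts$count_N_as_mismatch)
  if (opts$require_mate_agreement) {
    a2 <- assign_barcode(pairs$seq2, set, opts$max_mismatch,
                         opts$count_N_as_mismatch)
    both <- !is.na(a1$barcode) & !is.na(a2$barcode)
    agree <- both & a1$barcode == a2$barcode
    barcode <- ifelse(agree, a1$barcode, NA_character_)
    reason <- rep(NA_character_, n)
    reason[both & !agree] <- "mate_disagreement"
    fail1 <- is.na(a1$barcode)
    reason[fail1] <- a1$reason[fail1]
    fail2 <- !fail1 & is.na(a2$barcode)
    reason[fail2] <- a2$reason[fail2]
    mm2 <- a2$mismatches
  } else {
    barcode <- a1$barcode
    reason <- a1$reason
    mm2 <- rep(NA_integer_, n)
  }

  assignments <- data.frame(read_id = pairs$read_id, barcode = barcode,
                            mm1 = a1$mismatches, mm2 = mm2, reason = reason)

  keep <- !is.na(barcode)
  too_short_out <- nchar(pairs$seq1[keep]) < trim | nchar(pairs$seq2[keep]) < trim
  if (any(too_short_out)) {
    # mates shorter than barcode + junction after assignment cannot be
    # trimmed to a usable insert
    idx <- which(keep)[too_short_out]
    assignments$barcode[idx] <- NA_character_
    assignments$reason[idx] <- "too_short"
    keep <- !is.na(assignments$barcode)
  }

  reads <- pairs[keep, , drop = FALSE]
  if (nrow(reads)) {
    reads$seq1 <- substring(reads$seq1, trim + 1L)
    reads$qual1 <- substring(reads$qual1, trim + 1L)
    reads$seq2 <- substring(reads$seq2, trim + 1L)
    reads$qual2 <- substring(reads$qual2, trim + 1L)
    reads$barcode <- assignments$barcode[keep]
  } else {
    reads$barcode <- character(0)
  }
  rownames(reads) <- NULL

  per_barcode <- table(factor(assignments$barcode, levels = set$id))
  discards <- table(factor(
    assignments$reason[is.na(assignments$barcode)],
    levels = c("no_match", "mismatch_exceeded", "ambiguous",
               "mate_disagreement", "too_short")
  ))
  stats <- list(
    total = n,
    assigned = sum(keep),
    per_barcode = as.integer(per_barcode),
    per_barcode_ids = set$id,
    discards = as.integer(discards),
    discard_reasons = names(discards)
  )
  stopifnot(stats$total == stats$assigned + sum(stats$discards))

  structure(list(assignments = assignments, reads = reads, stats = stats,
                 options = opts),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  s <- x$stats
  cat("Demultiplexing: ", s$assigned, "/", s$total, " pairs assigned (",
      sprintf("%.2f%%", if (s$total) 100 * s$assigned / s$total else 0),
      ")\n", sep = "")
  tab <- data.frame(barcode = s$per_barcode_ids, pairs = s$per_barcode)
  print(tab, row.names = FALSE)
  if (sum(s$discards)) {
    cat("Discards:\n")
    print(data.frame(reason = s$discard_reasons, pairs = s$discards)[
      s$discards > 0, ], row.names = FALSE)
  }
  invisible(x)
}

#' Cross-barcode contamination matrix
#'
#' Tabulates truth barcode (rows) against assigned barcode (columns) for
#' all assigned pairs. The off-diagonal sum divided by total assigned pairs
#' is the contamination (misassignment) rate.
#'
#' @param assignments the `assignments` data frame of a [demux_pairs()]
#'   result (or a `demux_result`).
#' @param truth a truth manifest data frame with columns `read_id` and
#'   `barcode` (as produced by the simulator).
#' @return a square integer matrix (truth x assigned) over the union of
#'   barcode ids, with attribute `contamination_rate`.
#' @export
contamination_matrix <- function(assignments, truth) {
  if (inherits(assignments, "demux_result")) {
    assignments <- assignments$assignments
  }
  asg <- assignments[!is.na(assignments$barcode), ]
  idx <- match(asg$read_id, truth$read_id)
  if (anyNA(idx)) {
    stop("read id(s) missing from truth manifest: ",
         paste(utils::head(asg$read_id[is.na(idx)], 5), collapse = ", "))
  }
  ids <- sort(unique(c(truth$barcode, asg$barcode)))
  m <- table(factor(truth$barcode[idx], levels = ids),
             factor(asg$barcode, levels = ids))
  m <- unclass(m)
  names(dimnames(m)) <- c("truth", "assigned")
  total <- sum(m)
  attr(m, "contamination_rate") <-
    if (total) (total - sum(diag(m))) / total else 0
  m
}

#' Demultiplex paired FASTQ files
#'
#' File-based wrapper around [demux_pairs()]: reads synchronized paired
#' FASTQ(.gz), demultiplexes, and writes one trimmed FASTQ pair per
#' barcode plus an `undetermined` pair, a stats TSV/JSON, and (when a truth
#' manifest is given) a contamination matrix TSV.
#'
#' @param r1,r2 paths to mate FASTQ(.gz) files with matching record order.
#' @param set a [barcode_set()] or path to a barcode TSV.
#' @param outdir output directory (created if needed).
#' @param opts a [demux_options()].
#' @param truth optional truth manifest data frame or JSON path.
#' @param compress write gzipped FASTQ output (default `TRUE`).
#' @return the `demux_result`, invisibly.
#' @export
demux_fastq <- function(r1, r2, set, outdir, opts = demux_options(),
                        truth = NULL, compress = TRUE) {
  if (is.character(set)) set <- read_barcodes(set)
  f1 <- read_fastq(r1)
  f2 <- read_fastq(r2)
  if (length(f1$id) != length(f2$id)) {
    stop("mate files have different record counts")
  }
  id1 <- sub("/[12]$| .*$", "", f1$id)
  id2 <- sub("/[12]$| .*$", "", f2$id)
  bad <- which(id1 != id2)
  if (length(bad)) {
    stop("desynchronized mate files at record ", bad[1], ": '",
         id1[bad[1]], "' vs '", id2[bad[1]], "'")
  }
  pairs <- read_pairs(id1, f1$seq, f2$seq, f1$qual, f2$qual)
  res <- demux_pairs(pairs, set, opts)

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (compress) ".fastq.gz" else ".fastq"
  for (b in set$id) {
    sub_reads <- res$reads[res$reads$barcode == b, , drop = FALSE]
    write_fastq(sub_reads$read_id, sub_reads$seq1, sub_reads$qual1,
                file.path(outdir, paste0(b, "_R1", ext)))
    write_fastq(sub_reads$read_id, sub_reads$seq2, sub_reads$qual2,
                file.path(outdir, paste0(b, "_R2", ext)))
  }
  und <- is.na(res$assignments$barcode)
  write_fastq(pairs$read_id[und], pairs$seq1[und], pairs$qual1[und],
              file.path(outdir, paste0("undetermined_R1", ext)))
  write_fastq(pairs$read_id[und], pairs$seq2[und], pairs$qual2[und],
              file.path(outdir, paste0("undetermined_R2", ext)))

  s <- res$stats
  stats_df <- data.frame(
    category = c(paste0("assigned:", s$per_barcode_ids),
                 paste0("discarded:", s$discard_reasons)),
    pairs = c(s$per_barcode, s$discards)
  )
  utils::write.table(stats_df, file.path(outdir, "demux_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(total = s$total, assigned = s$assigned,
         per_barcode = stats::setNames(as.list(s$per_barcode),
                                       s$per_barcode_ids),
         discards = stats::setNames(as.list(s$discards), s$discard_reasons)),
    file.path(outdir, "demux_stats.json"), auto_unbox = TRUE, pretty = TRUE
  )

  if (!is.null(truth)) {
    if (is.character(truth)) truth <- read_manifest(truth)
    cm <- contamination_matrix(res, truth)
    utils::write.table(as.data.frame.matrix(cm),
                       file.path(outdir, "contamination_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(res)
}

# FASTQ I/O through Biostrings.
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(id = names(x),
       seq = as.character(x),
       qual = as.character(S4Vectors::mcols(x)$qualities))
}

write_fastq <- function(id, seq, qual, path) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}
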