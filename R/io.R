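# Plain-text interval and summary I/O. All coordinates are 0-based
# half-open, matching BED.

#' Read a BED file
#'
#' @param path BED(.gz) path; at least 3 columns. Column 4, when present,
#'   is read as the class/name label.
#' @param merge_classes merge overlapping intervals within each class.
#' @return data frame `chrom`, `start`, `end` (+ `class` when column 4
#'   exists).
#' @export
read_bed <- function(path, merge_classes = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  has_class <- ncol(df) >= 4L
  if (has_class) names(df)[4] <- "class"
  df <- df[, seq_len(if (has_class) 4L else 3L), drop = FALSE]
  df <- as_intervals(df, require_class = has_class)
  if (merge_classes && has_class) {
    merged <- lapply(split(df, df$class), function(cls) {
      gr <- GenomicRanges::reduce(intervals_to_gr(cls))
      data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr),
                 class = cls$class[1])
    })
    df <- do.call(rbind, merged)
    rownames(df) <- NULL
  }
  df
}

#' Write intervals as BED
#'
#' @param x interval data frame (`chrom`, `start`, `end`, optionally more).
#' @param path output path.
#' @param extra_cols extra columns to append after the first three.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, extra_cols = character(0)) {
  cols <- c("chrom", "start", "end", extra_cols)
  utils::write.table(x[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write restriction cut positions as BED3
#'
#' Cut positions are zero-width points; each is encoded as the 1 bp
#' interval `[p, p+1)` (a cut position `p` at the chromosome end is encoded
#' `[p-1, p)` to stay in range).
#'
#' @param sites a `site_index`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  stopifnot(inherits(sites, "site_index"))
  dfs <- lapply(names(sites$sites), function(chr) {
    p <- sites$sites[[chr]]
    L <- sites$seqlengths[[chr]]
    p <- ifelse(p >= L, L - 1L, p)
    data.frame(chrom = chr, start = p, end = p + 1L)
  })
  write_bed(do.call(rbind, dfs), path)
}

#' Read cut positions from a sites BED3
#'
#' Inverse of [write_sites_bed()]: the interval start is the cut position.
#'
#' @param path sites BED path.
#' @param seqlengths named chromosome lengths (bp).
#' @param motif the motif to record in the index.
#' @return a `site_index`.
#' @export
read_sites_bed <- function(path, seqlengths, motif = degenerate_motif()) {
  df <- read_bed(path)
  sites <- lapply(split(df$start, factor(df$chrom, levels = names(seqlengths))),
                  function(p) sort(unique(as.integer(p))))
  structure(
    list(motif = motif, sites = sites, seqlengths = seqlengths,
         total_sites = sum(lengths(sites))),
    class = "site_index"
  )
}

#' Write a digest summary as JSON
#'
#' @param sites a `site_index`.
#' @param gaps a `gap_report` (optional).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_digest_summary <- function(sites, gaps = NULL, path) {
  x <- list(motif = sites$motif$pattern,
            cut_offset = sites$motif$cut_offset,
            total_sites = sites$total_sites,
            genome_bases = sum(as.numeric(sites$seqlengths)))
  if (!is.null(gaps)) {
    x$gap_threshold <- gaps$threshold
    x$n_gaps <- gaps$n_gaps
    x$gap_bases <- gaps$gap_bases
    x$blind_fraction <- gaps$blind_fraction
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
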