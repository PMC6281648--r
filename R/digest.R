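#' Degenerate restriction motif
#'
#' Describes a restriction recognition site as an IUPAC pattern plus the
#' cut offset. The default is the blunt cutter CviKI-1 with the degenerate
#' palindromic site RG|CY (R = A/G, Y = C/T), cutting between the G and C.
#'
#' @param pattern IUPAC pattern, length >= 1.
#' @param cut_offset cut position in bp from the pattern start,
#'   `0 <= cut_offset <= nchar(pattern)`. The recorded cut position is the
#'   0-based position of the first base 3' of the (blunt) cut.
#' @param blunt logical; blunt-ended cut. Informational only.
#' @return an object of class `degenerate_motif`.
#' @export
degenerate_motif <- function(pattern = "RGCY", cut_offset = 2L, blunt = TRUE) {
  pattern <- toupper(pattern)
  if (nchar(pattern) < 1L) stop("pattern must have length >= 1")
  if (!is_iupac(pattern)) {
    stop("invalid IUPAC character in pattern '", pattern, "'")
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(pattern)) {
    stop("cut_offset must be in [0, pattern length]")
  }
  structure(
    list(pattern = pattern, cut_offset = cut_offset, blunt = isTRUE(blunt)),
    class = "degenerate_motif"
  )
}

#' @export
print.degenerate_motif <- function(x, ...) {
  cut <- paste0(substr(x$pattern, 1, x$cut_offset), "|",
                substr(x$pattern, x$cut_offset + 1, nchar(x$pattern)))
  cat("Degenerate motif ", cut, if (x$blunt) " (blunt)" else "", "\n", sep = "")
  invisible(x)
}

#' Scan a genome for degenerate restriction sites
#'
#' Finds every occurrence of an IUPAC motif and records the cut positions
#' (0-based, the first base after the cut). A genome base matches a pattern
#' code only if it is a concrete A/C/G/T contained in that code's set; N in
#' the genome never matches, so windows containing N are never reported.
#' Overlapping matches are all reported.
#'
#' RGCY is its own reverse complement as a degenerate pattern, so
#' forward-strand scanning is complete for the default motif. For
#' non-palindromic motifs set `both_strands = TRUE` to also scan the minus
#' strand; cut positions from both strands are merged and deduplicated.
#'
#' @param genome a `DNAStringSet` or named character vector of chromosomes.
#' @param motif a [degenerate_motif()].
#' @param both_strands also scan the reverse complement of the motif.
#' @return an object of class `site_index` with elements `motif`,
#'   `sites` (chromosome -> strictly increasing 0-based cut positions),
#'   `seqlengths`, and `total_sites`.
#' @export
scan_sites <- function(genome, motif = degenerate_motif(),
                       both_strands = FALSE) {
  if (!inherits(motif, "degenerate_motif")) {
    stop("motif must be a degenerate_motif object")
  }
  genome <- as_genome(genome)
  plen <- nchar(motif$pattern)

  fwd <- match_starts0(genome, motif$pattern)
  sites <- lapply(fwd, function(s) s + motif$cut_offset)

  if (both_strands) {
    # A minus-strand recognition at forward window [s, s+plen) cuts so that
    # the first base 3' of the cut on the forward strand is at
    # s + (plen - cut_offset).
    rc <- match_starts0(genome, revcomp(motif$pattern))
    rev_cut <- lapply(rc, function(s) s + (plen - motif$cut_offset))
    sites <- Map(function(a, b) sort(unique(c(a, b))), sites, rev_cut)
  }

  structure(
    list(
      motif = motif,
      sites = sites,
      seqlengths = genome_lengths(genome),
      total_sites = sum(lengths(sites))
    ),
    class = "site_index"
  )
}

# 0-based match start positions of an IUPAC pattern, per chromosome.
# Biostrings with fixed = "subject" interprets ambiguity codes in the
# pattern only, and a literal subject base matches iff it is contained in
# the pattern code's base set -- exactly the conservative rule we want.
# The one exception is a pattern N, which would match a subject N under
# bit-subset semantics; windows containing N are filtered out explicitly
# when the pattern itself contains N.
match_starts0 <- function(genome, pattern) {
  hits <- Biostrings::vmatchPattern(pattern, genome, fixed = "subject")
  starts <- lapply(Biostrings::startIndex(hits), function(s) {
    if (is.null(s)) integer(0) else sort(as.integer(s)) - 1L
  })
  names(starts) <- names(genome)
  if (grepl("N", pattern, fixed = TRUE)) {
    plen <- nchar(pattern)
    starts <- lapply(names(genome), function(chr) {
      s <- starts[[chr]]
      if (!length(s)) return(s)
      win <- Biostrings::extractAt(
        genome[[chr]], IRanges::IRanges(start = s + 1L, width = plen)
      )
      keep <- Biostrings::vcountPattern("N", win, fixed = TRUE) == 0L
      s[keep]
    })
    names(starts) <- names(genome)
  }
  starts
}

#' @export
print.site_index <- function(x, ...) {
  cat("Restriction site index: ", x$motif$pattern, ", ",
      format(x$total_sites, big.mark = ","), " sites on ",
      length(x$sites), " sequence(s)\n", sep = "")
  invisible(x)
}

#' Build restriction fragments from a site index
#'
#' Consecutive cut positions define half-open fragments `[site_i, site_i+1)`.
#' With `include_terminal = TRUE` the segments before the first and after the
#' last cut are appended (and flagged), so fragments tile `[0, chrom length)`
#' exactly; zero-length segments are dropped.
#'
#' @param sites a `site_index` from [scan_sites()].
#' @param genome optional genome for consistency checking: every chromosome
#'   in `sites` must be present with a matching length.
#' @param include_terminal include chromosome-terminal segments.
#' @return an object of class `fragment_map`: a list with `fragments`
#'   (data frame `chrom`, `start`, `end`, `terminal`; 0-based half-open),
#'   `terminal_included` and `seqlengths`.
#' @export
build_fragments <- function(sites, genome = NULL, include_terminal = FALSE) {
  stopifnot(inherits(sites, "site_index"))
  if (!is.null(genome)) {
    genome <- as_genome(genome)
    missing_chr <- setdiff(names(sites$sites), names(genome))
    if (length(missing_chr)) {
      stop("chromosome(s) in site index absent from genome: ",
           paste(missing_chr, collapse = ", "))
    }
  }
  frag_list <- lapply(names(sites$sites), function(chr) {
    s <- sites$sites[[chr]]
    L <- sites$seqlengths[[chr]]
    inner <- if (length(s) >= 2L) {
      data.frame(chrom = chr, start = s[-length(s)], end = s[-1],
                 terminal = FALSE)
    } else {
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 terminal = logical(0))
    }
    if (include_terminal) {
      if (length(s)) {
        term <- data.frame(
          chrom = chr,
          start = c(0L, s[length(s)]),
          end = c(s[1], L),
          terminal = TRUE
        )
        inner <- rbind(term[1, ], inner, term[2, ])
      } else {
        inner <- data.frame(chrom = chr, start = 0L, end = L, terminal = TRUE)
      }
    }
    inner[inner$end > inner$start, , drop = FALSE]
  })
  fragments <- do.call(rbind, frag_list)
  rownames(fragments) <- NULL
  structure(
    list(fragments = fragments, terminal_included = isTRUE(include_terminal),
         seqlengths = sites$seqlengths),
    class = "fragment_map"
  )
}

#' @export
print.fragment_map <- function(x, ...) {
  cat("Fragment map: ", nrow(x$fragments), " fragments",
      if (x$terminal_included) " (terminal segments included)", "\n", sep = "")
  invisible(x)
}

#' Restriction gap ("blind region") report
#'
#' Gaps are inter-site intervals strictly longer than `threshold`. Fragments
#' from such gaps cannot be sequenced as single short-read inserts, so the
#' assay is blind there. By default chromosome-terminal segments are not
#' considered; set `include_terminal = TRUE` to include them.
#'
#' @param sites a `site_index`.
#' @param threshold minimum gap length in bp (strictly greater than).
#' @param include_terminal treat terminal segments as potential gaps.
#' @return an object of class `gap_report`: `threshold`, `gaps` (BED-like
#'   data frame in genome order), `n_gaps`, `gap_bases`, and
#'   `blind_fraction` = gap_bases / total genome length.
#' @export
gap_report <- function(sites, threshold = 1000, include_terminal = FALSE) {
  stopifnot(inherits(sites, "site_index"))
  if (threshold <= 0) stop("threshold must be > 0")
  fm <- build_fragments(sites, include_terminal = include_terminal)
  fr <- fm$fragments
  gaps <- fr[fr$end - fr$start > threshold,
             c("chrom", "start", "end"), drop = FALSE]
  rownames(gaps) <- NULL
  gap_bases <- sum(as.numeric(gaps$end - gaps$start))
  total_bp <- sum(as.numeric(sites$seqlengths))
  structure(
    list(
      threshold = threshold,
      gaps = gaps,
      n_gaps = nrow(gaps),
      gap_bases = gap_bases,
      blind_fraction = gap_bases / total_bp,
      genome_bases = total_bp,
      include_terminal = isTRUE(include_terminal)
    ),
    class = "gap_report"
  )
}

#' @export
print.gap_report <- function(x, ...) {
  cat("Gap report (> ", x$threshold, " bp): ", x$n_gaps, " gaps, ",
      format(x$gap_bases, big.mark = ","), " bp blind (",
      sprintf("%.3f%%", 100 * x$blind_fraction), " of genome)\n", sep = "")
  invisible(x)
}

#' Restriction site density per region class ("cutability")
#'
#' Counts cut positions falling inside the intervals of each class and
#' divides by the class length in kbp. Classes with zero total length are
#' omitted with a warning.
#'
#' @param sites a `site_index`.
#' @param states 0-based half-open intervals with columns `chrom`, `start`,
#'   `end`, `class`.
#' @param merge merge overlapping intervals within a class before measuring
#'   class length (a site in two merged intervals is counted once).
#' @return data frame with columns `class`, `site_count`, `class_kbp`,
#'   `sites_per_kbp`.
#' @export
site_density_by_class <- function(sites, states, merge = TRUE) {
  stopifnot(inherits(sites, "site_index"))
  states <- as_intervals(states, require_class = TRUE)
  if (!nrow(states)) stop("states must be non-empty")

  chroms <- rep(names(sites$sites), lengths(sites$sites))
  pos <- unlist(sites$sites, use.names = FALSE)
  site_gr <- points_to_gr(chroms, pos)

  res <- lapply(split(states, states$class), function(cls) {
    gr <- intervals_to_gr(cls)
    if (merge) gr <- GenomicRanges::reduce(gr)
    bp <- sum(as.numeric(GenomicRanges::width(gr)))
    if (bp == 0) return(NULL)
    hits <- sum(IRanges::overlapsAny(site_gr, gr))
    data.frame(class = cls$class[1], site_count = hits,
               class_kbp = bp / 1000, sites_per_kbp = hits / (bp / 1000))
  })
  dropped <- names(res)[vapply(res, is.null, logical(1))]
  if (length(dropped)) {
    warning("class(es) with zero total length omitted: ",
            paste(dropped, collapse = ", "))
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "omitted_classes") <- dropped
  out
}

#' Restriction site usage per region class ("accessibility")
#'
#' Given observed fragments whose boundaries should coincide with cut
#' positions, computes per class the mean number of observed fragment ends
#' per restriction site. Ends not located at any cut position are tallied
#' as violations and excluded from usage. The genome-wide mean is attached
#' so classes can be compared as relative usage.
#'
#' @param sites a `site_index`.
#' @param observed data frame of observed fragments (`chrom`, `start`,
#'   `end`; 0-based half-open).
#' @param states class intervals as in [site_density_by_class()].
#' @return data frame with columns `class`, `n_sites`,
#'   `observed_fragment_ends`, `ends_per_site`, `relative_usage`;
#'   attributes `genome_wide_mean` and `n_violations`.
#' @export
cut_usage <- function(sites, observed, states) {
  stopifnot(inherits(sites, "site_index"))
  observed <- as_intervals(observed)
  if (!nrow(observed)) stop("empty observation set")
  states <- as_intervals(states, require_class = TRUE)

  site_key <- unlist(lapply(names(sites$sites), function(chr) {
    paste0(chr, ":", sites$sites[[chr]])
  }), use.names = FALSE)

  end_chrom <- rep(observed$chrom, 2L)
  end_pos <- c(observed$start, observed$end)
  end_key <- paste0(end_chrom, ":", end_pos)
  valid <- end_key %in% site_key
  n_violations <- sum(!valid)

  # Multiplicity of observed ends at each cut position.
  end_tab <- table(end_key[valid])

  chroms <- rep(names(sites$sites), lengths(sites$sites))
  pos <- unlist(sites$sites, use.names = FALSE)
  ends_at_site <- as.integer(end_tab[match(paste0(chroms, ":", pos),
                                           names(end_tab))])
  ends_at_site[is.na(ends_at_site)] <- 0L

  site_gr <- points_to_gr(chroms, pos)
  total_sites <- length(pos)
  gw_mean <- sum(ends_at_site) / total_sites

  res <- lapply(split(states, states$class), function(cls) {
    gr <- GenomicRanges::reduce(intervals_to_gr(cls))
    in_class <- IRanges::overlapsAny(site_gr, gr)
    n_sites <- sum(in_class)
    ends <- sum(ends_at_site[in_class])
    data.frame(
      class = cls$class[1],
      n_sites = n_sites,
      observed_fragment_ends = ends,
      ends_per_site = if (n_sites > 0) ends / n_sites else NA_real_
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$relative_usage <- out$ends_per_site / gw_mean
  attr(out, "genome_wide_mean") <- gw_mean
  attr(out, "n_violations") <- n_violations
  out
}
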