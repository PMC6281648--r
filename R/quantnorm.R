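#' Tile a genome into fixed-size bins
#'
#' @param seqlengths named vector of chromosome lengths (bp).
#' @param bin_size bin width in bp (default 10 kb); the last bin of each
#'   chromosome is truncated.
#' @return data frame `chrom`, `start`, `end` (0-based half-open) in genome
#'   order.
#' @export
genome_bins <- function(seqlengths, bin_size = 10000L) {
  if (bin_size <= 0) stop("bin_size must be > 0")
  out <- lapply(names(seqlengths), function(chr) {
    L <- seqlengths[[chr]]
    starts <- seq.int(0L, max(L - 1L, 0L), by = bin_size)
    data.frame(chrom = chr, start = starts, end = pmin(starts + bin_size, L))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Bin fragment counts by midpoint
#'
#' Each fragment increments the bin containing its midpoint. Fragments
#' whose midpoint falls inside a blacklist interval are excluded, and bins
#' fully contained in blacklist regions are masked.
#'
#' @param fragments a named list of per-sample fragment data frames
#'   (`chrom`, `start`, `end`; 0-based half-open), or a single data frame
#'   with a `sample` column.
#' @param seqlengths named chromosome lengths.
#' @param bin_size bin width in bp (default 10 kb).
#' @param blacklist optional interval data frame of regions to exclude.
#' @return an object of class `binned_counts`: `bins` (data frame),
#'   `counts` (bins x samples integer matrix), `masked` (logical per bin),
#'   `bin_size`, `blacklist_filtered`.
#' @export
bin_counts <- function(fragments, seqlengths, bin_size = 10000L,
                       blacklist = NULL) {
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (is.data.frame(fragments)) {
    if (!"sample" %in% names(fragments)) {
      fragments <- list(sample1 = fragments)
    } else {
      fragments <- split(fragments, fragments$sample)
    }
  }
  bins <- genome_bins(seqlengths, bin_size)
  bin_gr <- intervals_to_gr(bins)
  nb <- nrow(bins)

  masked <- rep(FALSE, nb)
  bl_gr <- NULL
  if (!is.null(blacklist) && nrow(blacklist)) {
    bl_gr <- GenomicRanges::reduce(intervals_to_gr(as_intervals(blacklist)))
    masked <- IRanges::overlapsAny(bin_gr, bl_gr, type = "within")
  }

  # global bin index: offset per chromosome + local bin
  offs <- c(0L, cumsum(tapply(rep(1L, nb), factor(bins$chrom, levels = unique(bins$chrom)), sum)))
  names(offs) <- c(unique(bins$chrom), "")

  counts <- matrix(0L, nrow = nb, ncol = length(fragments),
                   dimnames = list(NULL, names(fragments)))
  for (s in seq_along(fragments)) {
    fr <- as_intervals(fragments[[s]])
    if (!nrow(fr)) next
    mid <- fr$start + (fr$end - fr$start) %/% 2L
    if (!is.null(bl_gr)) {
      drop <- IRanges::overlapsAny(points_to_gr(fr$chrom, mid), bl_gr)
      fr <- fr[!drop, , drop = FALSE]
      mid <- mid[!drop]
    }
    if (!nrow(fr)) next
    gidx <- offs[fr$chrom] + mid %/% bin_size + 1L
    tab <- tabulate(gidx, nbins = nb)
    counts[, s] <- counts[, s] + tab
  }
  structure(
    list(bins = bins, counts = counts, masked = masked, bin_size = bin_size,
         blacklist_filtered = !is.null(bl_gr)),
    class = "binned_counts"
  )
}

#' Input-based scaling factors for multiplexed samples
#'
#' Estimates one multiplicative scaling factor per sample from genome-wide
#' binned input counts, normalized so the factors have geometric mean 1.
#' `median_ratio` (default) takes, per sample, the median over informative
#' bins of the count divided by that bin's geometric mean across samples;
#' informative bins are non-zero in every sample (and unmasked). When fewer
#' than `min_informative` such bins exist, the estimator falls back to
#' `total_count` (library-size ratios) with a warning.
#'
#' @param inputs a [bin_counts()] result or a bins x samples count matrix.
#' @param method `"median_ratio"` or `"total_count"`.
#' @param min_informative minimum shared non-zero bins for `median_ratio`
#'   (default 50).
#' @return named numeric vector of class `scaling_factor_set` with
#'   attribute `method`; geometric mean 1.
#' @export
input_scaling_factors <- function(inputs,
                                  method = c("median_ratio", "total_count"),
                                  min_informative = 50L) {
  method <- match.arg(method)
  counts <- if (inherits(inputs, "binned_counts")) inputs$counts else
    as.matrix(inputs)
  masked <- if (inherits(inputs, "binned_counts")) inputs$masked else
    rep(FALSE, nrow(counts))
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  }

  if (method == "median_ratio") {
    informative <- !masked & rowSums(counts == 0) == 0L
    if (sum(informative) < min_informative) {
      warning("only ", sum(informative), " bins non-zero in all samples; ",
              "falling back to total_count")
      method <- "total_count"
    } else {
      m <- counts[informative, , drop = FALSE]
      log_gm <- rowMeans(log(m))
      f <- apply(exp(log(m) - log_gm), 2, stats::median)
    }
  }
  if (method == "total_count") {
    f <- colSums(counts[!masked, , drop = FALSE])
  }
  f <- f / exp(mean(log(f)))
  structure(f, method = method, class = "scaling_factor_set")
}

#' @export
print.scaling_factor_set <- function(x, ...) {
  cat("Scaling factors (", attr(x, "method"), ", geometric mean 1):\n",
      sep = "")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Merged peak set with genome fraction
#'
#' @param peaks interval data frame (`chrom`, `start`, `end`).
#' @param genome_bases total genome length in bp.
#' @return an object of class `peak_set`: merged `intervals`,
#'   `total_peak_bases`, `genome_fraction`.
#' @export
peak_set <- function(peaks, genome_bases) {
  peaks <- as_intervals(peaks)
  if (!nrow(peaks)) stop("peak set is empty")
  gr <- GenomicRanges::reduce(intervals_to_gr(peaks))
  merged <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  total <- sum(as.numeric(merged$end - merged$start))
  gf <- total / sum(as.numeric(genome_bases))
  if (gf <= 0 || gf > 1) stop("genome_fraction must be in (0, 1]")
  structure(list(intervals = merged, total_peak_bases = total,
                 genome_fraction = gf),
            class = "peak_set")
}

#' Fraction of fragments in peaks (FRiP)
#'
#' Fraction of fragments overlapping any peak by at least 1 bp.
#'
#' @param fragments fragment data frame (`chrom`, `start`, `end`).
#' @param peaks a [peak_set()] or raw interval data frame (merged
#'   internally; genome fraction not needed for FRiP itself).
#' @return fraction in `[0, 1]`.
#' @export
frip <- function(fragments, peaks) {
  fragments <- as_intervals(fragments)
  if (!nrow(fragments)) stop("zero fragments")
  pk <- if (inherits(peaks, "peak_set")) peaks$intervals else
    as_intervals(peaks)
  pk_gr <- GenomicRanges::reduce(intervals_to_gr(pk))
  mean(IRanges::overlapsAny(intervals_to_gr(fragments), pk_gr))
}

#' Convert FRiP to an RPKM-scaled enrichment
#'
#' The FRiP score is divided by the fraction of the genome falling into
#' peaks and multiplied by 1e6, giving an enrichment on an RPKM scale that
#' is comparable across peak sets of different total size. A FRiP equal to
#' the genome fraction (no enrichment) maps to 1e6.
#'
#' @param frip FRiP score in `[0, 1]`.
#' @param peaks a [peak_set()] (for its `genome_fraction`) or the genome
#'   fraction itself.
#' @return `(frip / genome_fraction) * 1e6`.
#' @export
frip_rpkm <- function(frip, peaks) {
  gf <- if (inherits(peaks, "peak_set")) peaks$genome_fraction else
    as.numeric(peaks)
  if (gf <= 0) stop("genome_fraction must be > 0")
  (frip / gf) * 1e6
}

#' Input-normalized log2 ratio per bin
#'
#' Computes `log2((chip/f + pseudocount) / (input/f' + pseudocount))` per
#' bin for each chip sample and its matched input, after dividing by the
#' respective scaling factors. Masked bins are emitted as `NA`.
#'
#' @param chip,input [bin_counts()] results sharing the same bin axis.
#' @param chip_factors,input_factors optional [input_scaling_factors()]
#'   sets (default: all 1). Names must cover the sample names.
#' @param pairs named character vector mapping chip sample -> input sample;
#'   by default samples are matched by name (or positionally when both
#'   objects have the same number of samples).
#' @param pseudocount added to scaled counts (default 1).
#' @return list of class `log2_ratio_table`: `bins`, `ratio` (bins x chip
#'   samples matrix).
#' @export
normalize_chip <- function(chip, input, chip_factors = NULL,
                           input_factors = NULL, pairs = NULL,
                           pseudocount = 1) {
  stopifnot(inherits(chip, "binned_counts"), inherits(input, "binned_counts"))
  if (!identical(dim(chip$counts)[1], dim(input$counts)[1]) ||
      !identical(chip$bins, input$bins)) {
    stop("chip and input must share the same bin axis")
  }
  cn <- colnames(chip$counts)
  if (is.null(pairs)) {
    if (all(cn %in% colnames(input$counts))) {
      pairs <- stats::setNames(cn, cn)
    } else if (ncol(chip$counts) == ncol(input$counts)) {
      pairs <- stats::setNames(colnames(input$counts), cn)
    } else {
      stop("cannot match chip samples to input samples; supply `pairs`")
    }
  }
  missing_pair <- setdiff(cn, names(pairs))
  if (length(missing_pair)) {
    stop("unmatched chip sample(s): ", paste(missing_pair, collapse = ", "))
  }
  missing_input <- setdiff(unname(pairs[cn]), colnames(input$counts))
  if (length(missing_input)) {
    stop("input sample(s) not present: ",
         paste(missing_input, collapse = ", "))
  }
  fc <- get_factors(chip_factors, cn)
  fi <- get_factors(input_factors, unname(pairs[cn]))

  masked <- chip$masked | input$masked
  ratio <- sapply(cn, function(s) {
    num <- chip$counts[, s] / fc[[s]] + pseudocount
    den <- input$counts[, pairs[[s]]] / fi[[pairs[[s]]]] + pseudocount
    r <- log2(num / den)
    r[masked] <- NA_real_
    r
  })
  ratio <- matrix(ratio, nrow = nrow(chip$bins), dimnames = list(NULL, cn))
  structure(list(bins = chip$bins, ratio = ratio),
            class = "log2_ratio_table")
}

get_factors <- function(factors, samples) {
  if (is.null(factors)) {
    return(stats::setNames(rep(1, length(samples)), samples))
  }
  f <- unclass(factors)
  missing_f <- setdiff(samples, names(f))
  if (length(missing_f)) {
    stop("no scaling factor for sample(s): ",
         paste(missing_f, collapse = ", "))
  }
  f[samples]
}
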