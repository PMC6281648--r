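# Independent brute-force oracles and fixture generators. These stay
# deliberately naive (O(n*m) loops, character-by-character comparison) so
# they cannot share a defect with the vectorized implementation.

iupac_oracle <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Sliding-window IUPAC scan: returns 0-based cut positions. A window
# matches iff every genome base is a concrete A/C/G/T inside the pattern
# code's set (so N in the genome never matches).
oracle_scan <- function(seq, pattern = "RGCY", cut_offset = 2L) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  k <- length(p)
  hits <- integer(0)
  if (length(s) < k) return(hits)
  for (i in seq_len(length(s) - k + 1L)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      base <- s[i + j - 1L]
      if (!(base %in% c("A", "C", "G", "T")) ||
          !(base %in% iupac_oracle[[p[j]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, i - 1L + cut_offset)
  }
  hits
}

oracle_hamming <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  sum(va != vb)
}

oracle_min_distance <- function(seqs) {
  m <- Inf
  for (i in seq_len(length(seqs) - 1L)) {
    for (j in (i + 1L):length(seqs)) {
      m <- min(m, oracle_hamming(seqs[i], seqs[j]))
    }
  }
  m
}

# Per-site membership count: sites per class / class kbp.
oracle_density <- function(chrom, pos, states) {
  chrom <- rep(chrom, length.out = length(pos))
  out <- list()
  for (cl in unique(states$class)) {
    st <- states[states$class == cl, ]
    cnt <- 0L
    for (k in seq_along(pos)) {
      inside <- FALSE
      for (r in seq_len(nrow(st))) {
        if (chrom[k] == st$chrom[r] && pos[k] >= st$start[r] &&
            pos[k] < st$end[r]) {
          inside <- TRUE
        }
      }
      if (inside) cnt <- cnt + 1L
    }
    out[[cl]] <- cnt
  }
  out
}

oracle_bin <- function(fr, chrom_len, bin_size) {
  nb <- ceiling(chrom_len / bin_size)
  counts <- integer(nb)
  for (k in seq_len(nrow(fr))) {
    mid <- fr$start[k] + (fr$end[k] - fr$start[k]) %/% 2
    counts[mid %/% bin_size + 1L] <- counts[mid %/% bin_size + 1L] + 1L
  }
  counts
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# A site_index around hand-picked positions, bypassing scanning, for
# fragment/gap arithmetic tests.
fake_sites <- function(positions, chrom_len, chrom = "chr1") {
  structure(
    list(motif = degenerate_motif(),
         sites = stats::setNames(list(as.integer(positions)), chrom),
         seqlengths = stats::setNames(as.integer(chrom_len), chrom),
         total_sites = length(positions)),
    class = "site_index"
  )
}
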