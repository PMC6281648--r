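#' Simulation configuration
#'
#' Parameters of the synthetic multiplexed ChIP-seq experiment: a random
#' genome carved into labeled region classes, restriction digestion with the
#' configured motif, accessibility-weighted fragment sampling, inline
#' barcoding of both mates, and substitution sequencing errors.
#'
#' @param seed integer RNG seed; every stochastic step is reproducible
#'   under it.
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param gc genome GC fraction.
#' @param classes data frame with columns `class`, `fraction` (genome
#'   share), `weight` (accessibility weight for fragment sampling) and
#'   `enrichment` (extra multiplier applied when simulating a ChIP rather
#'   than an input). Defaults to an open/closed chromatin caricature:
#'   open 25% of the genome with 4-fold accessibility and 4-fold ChIP
#'   enrichment.
#' @param class_block block size in bp for assigning classes along the
#'   chromosome.
#' @param motif the restriction motif ([degenerate_motif()]).
#' @param fragment_window `(min, max)` fragment length window in bp
#'   retained after digestion (default 30--1000, a typical short-insert
#'   library cleanup window).
#' @param read_length sequenced read length (default 75).
#' @param junction_bases fixed bases between barcode and insert (default 1,
#'   a T from A-tailing).
#' @param error_rate per-base substitution error rate, `0 <= rate < 0.25`.
#' @param duplicate_rate fraction of emitted fragments that are re-emissions
#'   of already-sampled fragments (flat PCR-duplicate model).
#' @param chimera_rate fraction of pairs whose mate 2 carries the barcode of
#'   a different sample (exercises mate-disagreement discards).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 1L, chrom_length = 1e6,
                       gc = 0.5,
                       classes = data.frame(
                         class = c("open", "closed"),
                         fraction = c(0.25, 0.75),
                         weight = c(4, 1),
                         enrichment = c(4, 1)
                       ),
                       class_block = 5000L,
                       motif = degenerate_motif(),
                       fragment_window = c(30L, 1000L),
                       read_length = 75L,
                       junction_bases = 1L,
                       error_rate = 0,
                       duplicate_rate = 0,
                       chimera_rate = 0) {
  stopifnot(all(c("class", "fraction", "weight", "enrichment") %in%
                  names(classes)))
  if (any(classes$weight <= 0)) stop("class weights must be > 0")
  if (error_rate < 0 || error_rate >= 0.25) {
    stop("error_rate must be in [0, 0.25)")
  }
  if (fragment_window[1] >= fragment_window[2]) {
    stop("fragment_window must satisfy min < max")
  }
  classes$fraction <- classes$fraction / sum(classes$fraction)
  structure(
    list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
         chrom_length = as.integer(chrom_length), gc = gc,
         classes = classes, class_block = as.integer(class_block),
         motif = motif,
         fragment_window = as.integer(fragment_window),
         read_length = as.integer(read_length),
         junction_bases = as.integer(junction_bases),
         error_rate = error_rate, duplicate_rate = duplicate_rate,
         chimera_rate = chimera_rate),
    class = "sim_config"
  )
}

#' Simulate a random genome with labeled region classes
#'
#' Draws i.i.d. bases at the configured GC fraction and assigns region
#' classes in blocks of `class_block` bp with probabilities equal to the
#' class fractions; adjacent blocks of the same class are merged. Class
#' intervals partition each chromosome exactly.
#'
#' @param cfg a [sim_config()]. The RNG is seeded from `cfg$seed`.
#' @return list with `genome` (`DNAStringSet`) and `classes` (0-based
#'   half-open data frame `chrom`, `start`, `end`, `class`).
#' @export
make_genome <- function(cfg) {
  set.seed(cfg$seed)
  bases <- c("A", "C", "G", "T")
  p <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
  seqs <- vapply(seq_len(cfg$n_chroms), function(i) {
    paste(bases[sample.int(4L, cfg$chrom_length, replace = TRUE, prob = p)],
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(cfg$n_chroms))
  genome <- Biostrings::DNAStringSet(seqs)

  cls <- lapply(names(seqs), function(chr) {
    L <- cfg$chrom_length
    nb <- ceiling(L / cfg$class_block)
    lab <- sample(cfg$classes$class, nb, replace = TRUE,
                  prob = cfg$classes$fraction)
    r <- rle(lab)
    ends <- pmin(cumsum(r$lengths) * cfg$class_block, L)
    starts <- c(0L, utils::head(ends, -1L))
    data.frame(chrom = chr, start = starts, end = ends, class = r$values)
  })
  classes <- do.call(rbind, cls)
  rownames(classes) <- NULL
  list(genome = genome, classes = classes)
}

#' Candidate restriction fragments within the length window
#'
#' Inter-site intervals (terminal segments excluded) whose length falls in
#' the configured window, labeled with the region class of their midpoint.
#'
#' @param sites a `site_index` from [scan_sites()].
#' @param classes region-class intervals (from [make_genome()]).
#' @param cfg a [sim_config()].
#' @return data frame `chrom`, `start`, `end`, `class`.
#' @export
candidate_fragments <- function(sites, classes, cfg) {
  fr <- build_fragments(sites, include_terminal = FALSE)$fragments
  len <- fr$end - fr$start
  fr <- fr[len >= cfg$fragment_window[1] & len <= cfg$fragment_window[2], ,
           drop = FALSE]
  if (!nrow(fr)) {
    stop("no candidate fragments in window [", cfg$fragment_window[1], ", ",
         cfg$fragment_window[2], "] bp; digest yielded ",
         sum(lengths(sites$sites)), " sites")
  }
  mid <- fr$start + (fr$end - fr$start) %/% 2L
  hit <- GenomicRanges::findOverlaps(
    points_to_gr(fr$chrom, mid),
    intervals_to_gr(as_intervals(classes, require_class = TRUE)),
    select = "first"
  )
  fr$class <- classes$class[hit]
  fr$terminal <- NULL
  rownames(fr) <- NULL
  fr
}

#' Sample fragments with accessibility weights
#'
#' Draws fragments from the candidate pool with probability proportional to
#' the accessibility weight of each fragment's class (times the ChIP
#' enrichment multiplier when `chip = TRUE`). A configurable fraction of
#' the output re-emits already-sampled fragments, flagged as duplicates.
#'
#' @param candidates candidate pool from [candidate_fragments()] (or
#'   `sites` + `classes` to build it on the fly via those arguments).
#' @param cfg a [sim_config()].
#' @param n number of fragments to emit.
#' @param sample_id sample label attached to the fragments.
#' @param chip simulate a ChIP (apply enrichment multipliers) rather than
#'   an input.
#' @return data frame `chrom`, `start`, `end`, `class`, `is_duplicate`,
#'   `sample`.
#' @export
sample_fragments <- function(candidates, cfg, n, sample_id = "s1",
                             chip = FALSE) {
  w_class <- cfg$classes$weight *
    (if (chip) cfg$classes$enrichment else rep(1, nrow(cfg$classes)))
  w <- w_class[match(candidates$class, cfg$classes$class)]
  n <- as.integer(n)
  n_dup <- as.integer(round(n * cfg$duplicate_rate))
  n_primary <- n - n_dup
  idx <- sample.int(nrow(candidates), n_primary, replace = TRUE, prob = w)
  dup_idx <- if (n_dup > 0) sample(idx, n_dup, replace = TRUE) else integer(0)
  out <- candidates[c(idx, dup_idx), , drop = FALSE]
  out$is_duplicate <- rep(c(FALSE, TRUE), c(n_primary, n_dup))
  out$sample <- sample_id
  rownames(out) <- NULL
  out
}

#' Emit barcoded paired-end reads with a truth manifest
#'
#' Mate 1 is the sample's barcode, the junction base(s), then the fragment
#' 5' prefix; mate 2 is the barcode, junction, then the reverse complement
#' of the fragment 3' end. Reads are truncated at the fragment end when the
#' insert is shorter than the read allows (recorded implicitly by the read
#' length). Substitution errors are injected i.i.d. per base, uniformly
#' over the three alternatives; the number of errors landing in each mate's
#' barcode region is recorded in the manifest.
#'
#' @param fragments sampled fragments with a `sample` column
#'   (from [sample_fragments()]).
#' @param genome the simulated genome (`DNAStringSet`).
#' @param set a [barcode_set()].
#' @param cfg a [sim_config()].
#' @param sample_to_barcode named character vector sample -> barcode id;
#'   defaults to the identity when sample labels are barcode ids.
#' @param id_prefix read id prefix.
#' @return list with `reads` (a [read_pairs()] data frame) and `manifest`
#'   (data frame: `read_id`, `sample`, `barcode`, `chrom`, `start`, `end`,
#'   `is_duplicate`, `chimera`, `bc_errors1`, `bc_errors2`).
#' @export
emit_reads <- function(fragments, genome, set, cfg,
                       sample_to_barcode = NULL, id_prefix = "rp") {
  genome <- as_genome(genome)
  if (is.null(sample_to_barcode)) {
    sample_to_barcode <- stats::setNames(set$id, set$id)
  }
  bad <- setdiff(unique(fragments$sample), names(sample_to_barcode))
  if (length(bad)) {
    stop("no barcode mapping for sample(s): ", paste(bad, collapse = ", "))
  }
  L <- attr(set, "bc_length")
  if (cfg$read_length < L + cfg$junction_bases + 1L) {
    stop("read_length must be >= barcode length + junction_bases + 1")
  }
  n <- nrow(fragments)
  bc_id <- unname(sample_to_barcode[fragments$sample])
  bc_seq <- set$sequence[match(bc_id, set$id)]

  # chimeras: mate 2 carries another sample's barcode
  chimera <- rep(FALSE, n)
  bc_seq2 <- bc_seq
  if (cfg$chimera_rate > 0 && nrow(set) > 1L) {
    n_chi <- as.integer(round(n * cfg$chimera_rate))
    if (n_chi > 0) {
      ci <- sample.int(n, n_chi)
      chimera[ci] <- TRUE
      shift <- sample.int(nrow(set) - 1L, n_chi, replace = TRUE)
      pos <- match(bc_id[ci], set$id)
      bc_seq2[ci] <- set$sequence[((pos - 1L + shift) %% nrow(set)) + 1L]
    }
  }

  chrom_seq <- as.character(genome)
  insert_len <- cfg$read_length - L - cfg$junction_bases
  subj <- chrom_seq[fragments$chrom]
  ins1 <- substring(subj, fragments$start + 1L,
                    pmin(fragments$start + insert_len, fragments$end))
  ins2_fwd <- substring(subj, pmax(fragments$end - insert_len,
                                   fragments$start) + 1L,
                        fragments$end)
  ins2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(ins2_fwd)))
  junction <- strrep("T", cfg$junction_bases)
  seq1 <- paste0(bc_seq, junction, ins1)
  seq2 <- paste0(bc_seq2, junction, ins2)

  e1 <- inject_errors(seq1, cfg$error_rate, L)
  e2 <- inject_errors(seq2, cfg$error_rate, L)

  read_id <- sprintf("%s%08d", id_prefix, seq_len(n))
  reads <- read_pairs(read_id, e1$seqs, e2$seqs)
  manifest <- data.frame(
    read_id = read_id,
    sample = fragments$sample,
    barcode = bc_id,
    chrom = fragments$chrom,
    start = fragments$start,
    end = fragments$end,
    is_duplicate = fragments$is_duplicate %||% rep(FALSE, n),
    chimera = chimera,
    bc_errors1 = e1$bc_errors,
    bc_errors2 = e2$bc_errors
  )
  list(reads = reads, manifest = manifest)
}

# Inject i.i.d. substitution errors into a character vector of reads.
# Vectorized through one concatenated raw buffer; returns the mutated
# sequences and the per-read error count within the first bc_len bases.
inject_errors <- function(seqs, rate, bc_len) {
  n <- length(seqs)
  if (rate <= 0 || n == 0L) {
    return(list(seqs = seqs, bc_errors = integer(n)))
  }
  lens <- nchar(seqs)
  k <- stats::rbinom(n, lens, rate)
  idx <- rep.int(seq_len(n), k)
  if (!length(idx)) {
    return(list(seqs = seqs, bc_errors = integer(n)))
  }
  pos <- 1L + as.integer(floor(stats::runif(length(idx)) * lens[idx]))
  # i.i.d. per-position errors never hit the same position twice
  dup <- duplicated(idx * (max(lens) + 1) + pos)
  idx <- idx[!dup]; pos <- pos[!dup]

  off <- cumsum(c(0, as.numeric(lens)))
  gpos <- off[idx] + pos
  raw <- charToRaw(paste(seqs, collapse = ""))
  base_raw <- charToRaw("ACGT")
  cur <- match(raw[gpos], base_raw)
  ok <- !is.na(cur)
  new_base <- (cur[ok] - 1L +
                 sample.int(3L, sum(ok), replace = TRUE)) %% 4L + 1L
  raw[gpos[ok]] <- base_raw[new_base]
  big <- rawToChar(raw)
  out <- substring(big, off[seq_len(n)] + 1, off[seq_len(n)] + lens)
  in_bc <- ok & pos <= bc_len
  list(seqs = out, bc_errors = tabulate(idx[in_bc], nbins = n))
}

#' Run a complete synthetic multiplexed experiment
#'
#' Seeds the RNG, simulates the genome and region classes, digests it with
#' the configured motif, samples per-sample fragment pools, emits barcoded
#' error-injected read pairs, and returns everything together with the
#' ground-truth manifest. Optionally writes the standard file set.
#'
#' @param cfg a [sim_config()].
#' @param set a [barcode_set()]; default: 8 generated barcodes of length 8
#'   at min distance 3.
#' @param n_pairs read pairs per sample (scalar or named per-sample vector).
#' @param samples sample labels; default the barcode ids.
#' @param chip simulate ChIP samples (class enrichment on) instead of
#'   inputs.
#' @param outdir optional output directory; writes `sim_R1.fastq.gz`,
#'   `sim_R2.fastq.gz`, `genome.fa`, `classes.bed`,
#'   `truth.manifest.json` and `sim.config.json`.
#' @return list of class `relacs_sim`: `genome`, `classes`, `sites`,
#'   `candidates`, `fragments`, `reads`, `manifest`, `set`, `cfg`.
#' @export
simulate_relacs <- function(cfg = sim_config(), set = NULL, n_pairs = 1000L,
                            samples = NULL, chip = FALSE, outdir = NULL) {
  gen <- make_genome(cfg)   # seeds the RNG from cfg$seed
  if (is.null(set)) {
    set <- generate_barcodes(8L, length = 8L, min_distance = 3L)
  }
  samples <- samples %||% set$id
  if (length(n_pairs) == 1L) {
    n_pairs <- stats::setNames(rep(n_pairs, length(samples)), samples)
  }
  sites <- scan_sites(gen$genome, cfg$motif)
  cand <- candidate_fragments(sites, gen$classes, cfg)
  frags <- do.call(rbind, lapply(samples, function(s) {
    sample_fragments(cand, cfg, n_pairs[[s]], sample_id = s, chip = chip)
  }))
  map <- stats::setNames(set$id[seq_along(samples)], samples)
  em <- emit_reads(frags, gen$genome, set, cfg, sample_to_barcode = map)

  out <- structure(
    list(genome = gen$genome, classes = gen$classes, sites = sites,
         candidates = cand, fragments = frags, reads = em$reads,
         manifest = em$manifest, set = set, cfg = cfg),
    class = "relacs_sim"
  )
  if (!is.null(outdir)) write_simulation(out, outdir)
  out
}

#' @export
print.relacs_sim <- function(x, ...) {
  cat("Synthetic multiplexed experiment: ", nrow(x$reads), " read pairs, ",
      nrow(x$set), " barcodes, genome ",
      format(sum(x$sites$seqlengths), big.mark = ","), " bp with ",
      format(x$sites$total_sites, big.mark = ","), " restriction sites\n",
      sep = "")
  invisible(x)
}

#' Write simulation outputs
#'
#' @param sim a `relacs_sim` object.
#' @param outdir output directory.
#' @param compress gzip the FASTQ files.
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir, compress = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (compress) ".fastq.gz" else ".fastq"
  Biostrings::writeXStringSet(sim$genome, file.path(outdir, "genome.fa"))
  write_bed(sim$classes, file.path(outdir, "classes.bed"),
            extra_cols = "class")
  write_fastq(sim$reads$read_id, sim$reads$seq1, sim$reads$qual1,
              file.path(outdir, paste0("sim_R1", ext)))
  write_fastq(sim$reads$read_id, sim$reads$seq2, sim$reads$qual2,
              file.path(outdir, paste0("sim_R2", ext)))
  write_manifest(sim$manifest, file.path(outdir, "truth.manifest.json"),
                 seed = sim$cfg$seed)
  cfg <- unclass(sim$cfg)
  cfg$motif <- unclass(cfg$motif)[c("pattern", "cut_offset", "blunt")]
  jsonlite::write_json(cfg, file.path(outdir, "sim.config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' Write / read a truth manifest
#'
#' @param manifest the manifest data frame.
#' @param path JSON path.
#' @param seed the seed recorded in the header.
#' @return `path` (write) or the manifest data frame (read).
#' @export
write_manifest <- function(manifest, path, seed = NA_integer_) {
  jsonlite::write_json(
    list(schema = "relacs-truth-manifest/1", seed = seed,
         n_pairs = nrow(manifest), pairs = manifest),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "relacs-truth-manifest/1")) {
    stop("unrecognized manifest schema: ", x$schema %||% "<none>")
  }
  x$pairs
}
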