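test_that("genome simulation is reproducible and classes partition the genome", {
  cfg <- sim_config(seed = 501, chrom_length = 1e5, n_chroms = 2)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$classes, g2$classes)

  by_chr <- tapply(g1$classes$end - g1$classes$start, g1$classes$chrom, sum)
  expect_true(all(by_chr == 1e5))
  # intervals abut in order
  for (chr in unique(g1$classes$chrom)) {
    cl <- g1$classes[g1$classes$chrom == chr, ]
    expect_equal(cl$start, c(0, head(cl$end, -1)))
  }
})

test_that("site counts on the simulated genome match the binomial expectation", {
  cfg <- sim_config(seed = 502, chrom_length = 1e6, gc = 0.5)
  g <- make_genome(cfg)
  n <- scan_sites(g$genome)$total_sites
  windows <- 1e6 - 3
  expected <- windows / 64
  expect_lt(abs(n - expected), 5 * sqrt(windows * (1 / 64) * (63 / 64)))
})

test_that("sampled fragments respect the length window and duplicate flagging", {
  cfg <- sim_config(seed = 503, chrom_length = 5e5, duplicate_rate = 0.1)
  g <- make_genome(cfg)
  sites <- scan_sites(g$genome)
  cand <- candidate_fragments(sites, g$classes, cfg)
  len <- cand$end - cand$start
  expect_true(all(len >= 30 & len <= 1000))

  fr <- sample_fragments(cand, cfg, 5000, sample_id = "s1")
  expect_equal(nrow(fr), 5000)
  expect_equal(sum(fr$is_duplicate), 500)
  # every duplicate re-emits an already-sampled fragment
  key <- paste(fr$chrom, fr$start, fr$end)
  expect_true(all(key[fr$is_duplicate] %in% key[!fr$is_duplicate]))
  # fragment boundaries coincide with cut positions
  expect_true(all(fr$start %in% sites$sites$chr1) &&
                all(fr$end %in% sites$sites$chr1))

  cfg_bad <- sim_config(seed = 503, chrom_length = 5e5,
                        fragment_window = c(2000L, 2001L))
  expect_error(candidate_fragments(sites, g$classes, cfg_bad),
               "no candidate fragments")
})

test_that("accessibility weights drive class sampling and are recovered by cut_usage", {
  cfg <- sim_config(seed = 504, chrom_length = 2e6)
  g <- make_genome(cfg)
  sites <- scan_sites(g$genome)
  cand <- candidate_fragments(sites, g$classes, cfg)
  fr <- sample_fragments(cand, cfg, 40000, sample_id = "s1")

  # empirical class frequencies proportional to candidate counts x weight
  n_cand <- table(cand$class)[c("open", "closed")]
  expected_ratio <- (4 * n_cand[["open"]]) / (1 * n_cand[["closed"]])
  obs <- table(fr$class)[c("open", "closed")]
  expect_lt(abs(obs[["open"]] / obs[["closed"]] / expected_ratio - 1), 0.1)

  # relative usage per site recovers the 4:1 accessibility ratio
  usage <- cut_usage(sites, fr, g$classes)
  ratio <- usage$ends_per_site[usage$class == "open"] /
    usage$ends_per_site[usage$class == "closed"]
  expect_lt(abs(ratio / 4 - 1), 0.15)

  # with equal weights, class frequencies follow candidate counts
  cfg_eq <- sim_config(seed = 505, chrom_length = 2e6,
                       classes = data.frame(
                         class = c("open", "closed"),
                         fraction = c(0.25, 0.75),
                         weight = c(1, 1), enrichment = c(1, 1)))
  g2 <- make_genome(cfg_eq)
  sites2 <- scan_sites(g2$genome)
  cand2 <- candidate_fragments(sites2, g2$classes, cfg_eq)
  fr2 <- sample_fragments(cand2, cfg_eq, 40000)
  p_cand <- as.numeric(table(cand2$class)) / nrow(cand2)
  chisq <- suppressWarnings(
    stats::chisq.test(table(fr2$class), p = p_cand))
  expect_gt(chisq$p.value, 1e-4)
})

test_that("error-free reads start with the expected barcode prefix and truncate at fragment ends", {
  set <- generate_barcodes(4, 8, 3, seed = 506)
  cfg <- sim_config(seed = 507, chrom_length = 2e5, error_rate = 0)
  sim <- simulate_relacs(cfg, set = set, n_pairs = 300)

  bc <- set$sequence[match(sim$manifest$barcode, set$id)]
  expect_true(all(startsWith(sim$reads$seq1, expected_read_prefix(bc, 1))))
  expect_true(all(startsWith(sim$reads$seq2, expected_read_prefix(bc, 1))))
  expect_true(all(sim$manifest$bc_errors1 == 0))

  # read length: full 75 when the insert allows, else truncated at the
  # fragment end
  frag_len <- sim$manifest$end - sim$manifest$start
  exp_len <- pmin(75, 8 + 1 + frag_len)
  expect_equal(nchar(sim$reads$seq1), exp_len)
  expect_equal(nchar(sim$reads$seq2), exp_len)

  # mate 2 is the reverse complement of the fragment 3' end
  i <- which(frag_len >= 66)[1]
  chrom <- as.character(sim$genome[[sim$manifest$chrom[i]]])
  frag_3p <- substr(chrom, sim$manifest$end[i] - 66 + 1, sim$manifest$end[i])
  expect_equal(substr(sim$reads$seq2[i], 10, 75), revcomp(frag_3p))

  # same seed gives byte-identical reads
  sim2 <- simulate_relacs(cfg, set = set, n_pairs = 300)
  expect_identical(sim$reads, sim2$reads)
})

test_that("injected substitution errors hit at about the configured rate", {
  set <- generate_barcodes(4, 8, 3, seed = 508)
  cfg0 <- sim_config(seed = 509, chrom_length = 3e5, error_rate = 0)
  clean <- simulate_relacs(cfg0, set = set, n_pairs = 2000)
  cfg2 <- sim_config(seed = 509, chrom_length = 3e5, error_rate = 0.02)
  noisy <- simulate_relacs(cfg2, set = set, n_pairs = 2000)

  # same seed, same fragments; only the bases differ
  expect_identical(clean$manifest[, c("chrom", "start", "end")],
                   noisy$manifest[, c("chrom", "start", "end")])
  mm <- sum(mapply(function(a, b) sum(charToRaw(a) != charToRaw(b)),
                   clean$reads$seq1, noisy$reads$seq1))
  bases <- sum(nchar(clean$reads$seq1))
  expect_lt(abs(mm / bases - 0.02), 5 * sqrt(0.02 * 0.98 / bases))
  # manifest barcode-region error counts match the observed prefix damage
  pre_mm <- mapply(function(a, b) sum(charToRaw(substr(a, 1, 8)) !=
                                        charToRaw(substr(b, 1, 8))),
                   clean$reads$seq1, noisy$reads$seq1)
  expect_equal(unname(pre_mm), noisy$manifest$bc_errors1)
})

test_that("end-to-end demultiplexing recovers per-sample counts from the manifest", {
  set <- generate_barcodes(8, 8, 3, seed = 510)
  cfg <- sim_config(seed = 511, chrom_length = 3e5, error_rate = 0)
  sim <- simulate_relacs(cfg, set = set, n_pairs = 400)
  res <- demux_pairs(sim$reads, set)
  truth_counts <- table(sim$manifest$barcode)
  got <- stats::setNames(res$stats$per_barcode, res$stats$per_barcode_ids)
  expect_equal(as.numeric(got[names(truth_counts)]),
               as.numeric(truth_counts))
})

test_that("simulated depth differences are recovered as scaling factors", {
  cfg <- sim_config(seed = 512, chrom_length = 2e6)
  g <- make_genome(cfg)
  sites <- scan_sites(g$genome)
  cand <- candidate_fragments(sites, g$classes, cfg)
  fr <- rbind(sample_fragments(cand, cfg, 30000, sample_id = "a"),
              sample_fragments(cand, cfg, 60000, sample_id = "b"))
  bc <- bin_counts(fr, c(chr1 = 2e6), 10000)
  f <- input_scaling_factors(bc)
  expect_lt(abs(f[["b"]] / f[["a"]] / 2 - 1), 0.05)
})

test_that("simulation outputs round-trip through the written file set", {
  tmp <- withr::local_tempdir()
  set <- generate_barcodes(4, 8, 3, seed = 513)
  cfg <- sim_config(seed = 514, chrom_length = 1e5, error_rate = 0.01)
  sim <- simulate_relacs(cfg, set = set, n_pairs = 100, outdir = tmp)

  expect_true(all(file.exists(file.path(
    tmp, c("genome.fa", "classes.bed", "sim_R1.fastq.gz", "sim_R2.fastq.gz",
           "truth.manifest.json", "sim.config.json")))))
  g <- read_genome(file.path(tmp, "genome.fa"))
  expect_identical(as.character(g), as.character(sim$genome))
  man <- read_manifest(file.path(tmp, "truth.manifest.json"))
  expect_equal(man$read_id, sim$manifest$read_id)
  expect_equal(man$start, sim$manifest$start)
  cls <- read_bed(file.path(tmp, "classes.bed"))
  expect_equal(nrow(cls), nrow(sim$classes))
  r1 <- Biostrings::readDNAStringSet(file.path(tmp, "sim_R1.fastq.gz"),
                                     format = "fastq")
  expect_equal(as.character(unname(r1)), sim$reads$seq1)
})
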