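test_that("scan_sites finds degenerate RGCY sites with the documented conventions", {
  # A is in R, T is in Y: cut between G and C
  si <- scan_sites(c(chr1 = "AGCT"))
  expect_identical(si$sites$chr1, 2L)
  expect_identical(si$total_sites, 1L)

  expect_identical(scan_sites(c(chr1 = "TTTT"))$total_sites, 0L)
  expect_identical(scan_sites(c(chr1 = "GGCCGGCC"))$sites$chr1, c(2L, 6L))

  # overlapping matches are all reported: AGCCGCT has RGCY at 0 and ?; use
  # a construct with two overlapping windows
  expect_identical(scan_sites(c(chr1 = "GGCGCT"))$sites$chr1,
                   oracle_scan("GGCGCT") + 0L)

  # N never matches, even inside an otherwise valid window
  expect_identical(scan_sites(c(chr1 = "ANCT"))$total_sites, 0L)
  expect_identical(scan_sites(c(chr1 = "AGNT"))$total_sites, 0L)

  # chromosome shorter than the pattern: zero sites, no error
  expect_identical(scan_sites(c(chr1 = "AG", chr2 = "AGCT"))$sites$chr1,
                   integer(0))

  # invalid pattern character is a configuration error
  expect_error(degenerate_motif("RGXY"), "IUPAC")
  expect_error(degenerate_motif("RGCY", cut_offset = 5), "cut_offset")
})

test_that("scan_sites equals the brute-force sliding-window oracle", {
  set.seed(101)
  for (i in 1:30) {
    s <- random_dna(2000, gc = runif(1, 0.3, 0.7))
    expect_identical(scan_sites(c(chr = s))$sites$chr, oracle_scan(s))
  }
  # non-default degenerate motifs, including one containing N
  set.seed(102)
  s <- random_dna(5000)
  for (pat in c("GANTC", "CCWGG", "RYRY")) {
    m <- degenerate_motif(pat, cut_offset = 1L)
    expect_identical(scan_sites(c(chr = s), m)$sites$chr,
                     oracle_scan(s, pat, 1L))
  }
})

test_that("two-strand scanning of a non-palindromic motif merges both orientations", {
  set.seed(103)
  s <- random_dna(5000)
  m <- degenerate_motif("GGWC", cut_offset = 1L)
  both <- scan_sites(c(chr = s), m, both_strands = TRUE)$sites$chr
  fwd <- oracle_scan(s, "GGWC", 1L)
  # minus-strand recognition at forward window [p, p+4) cuts at p + (4 - 1)
  rev_rec <- oracle_scan(s, "GWCC", 0L)  # revcomp(GGWC) = GWCC
  expect_identical(both, sort(unique(c(fwd, rev_rec + 3L))))
})

test_that("RGCY is palindromic: reverse-complement scanning mirrors the site set", {
  set.seed(104)
  for (i in 1:10) {
    s <- random_dna(3000)
    L <- nchar(s)
    fwd <- scan_sites(c(chr = s))$sites$chr
    rev <- scan_sites(c(chr = revcomp(s)))$sites$chr
    expect_identical(rev, sort(L - fwd))
  }
})

test_that("RGCY density on uniform GC-0.5 sequence matches the 1/64 expectation", {
  set.seed(105)
  L <- 200000
  n <- scan_sites(c(chr = random_dna(L, gc = 0.5)))$total_sites
  windows <- L - 3
  expected <- windows / 64
  sd_binom <- sqrt(windows * (1 / 64) * (63 / 64))
  expect_lt(abs(n - expected), 5 * sd_binom)
})

test_that("build_fragments defines half-open inter-site fragments and conserves length", {
  si <- fake_sites(c(100, 300, 2000), 5000)
  fm <- build_fragments(si)
  expect_equal(fm$fragments$start, c(100, 300))
  expect_equal(fm$fragments$end, c(300, 2000))
  expect_false(any(fm$fragments$terminal))

  fmt <- build_fragments(si, include_terminal = TRUE)
  expect_equal(fmt$fragments$start, c(0, 100, 300, 2000))
  expect_equal(fmt$fragments$end, c(100, 300, 2000, 5000))
  expect_equal(fmt$fragments$terminal, c(TRUE, FALSE, FALSE, TRUE))

  # conservation on a scanned random genome
  set.seed(106)
  g <- c(chrA = random_dna(20000), chrB = random_dna(7000))
  si2 <- scan_sites(g)
  fm2 <- build_fragments(si2, include_terminal = TRUE)
  tot <- tapply(fm2$fragments$end - fm2$fragments$start, fm2$fragments$chrom, sum)
  expect_equal(as.numeric(tot[c("chrA", "chrB")]), c(20000, 7000))

  # consistency error when the genome lacks a chromosome
  expect_error(build_fragments(si2, genome = g["chrA"]), "absent")
})

test_that("gap_report applies a strict threshold and computes the blind fraction", {
  si <- fake_sites(c(100, 300, 2000), 5000)
  gr <- gap_report(si, threshold = 1000)
  expect_equal(gr$n_gaps, 1)
  expect_equal(gr$gap_bases, 1700)
  expect_equal(gr$blind_fraction, 0.34)
  expect_equal(gr$gaps$start, 300)

  # strictness: a gap of exactly threshold bp is not reported
  expect_equal(gap_report(si, threshold = 1700)$n_gaps, 0)

  # no sites, terminal excluded: no inter-site intervals
  expect_equal(gap_report(fake_sites(integer(0), 5000))$n_gaps, 0)
  # terminal segments become gaps only on request
  expect_equal(gap_report(fake_sites(integer(0), 5000),
                          include_terminal = TRUE)$n_gaps, 1)

  # monotonicity: raising the threshold never increases n_gaps
  set.seed(107)
  si2 <- scan_sites(c(chr = random_dna(50000, gc = 0.3)))
  n <- vapply(c(50, 100, 200, 400, 800), function(th)
    gap_report(si2, th)$n_gaps, numeric(1))
  expect_true(all(diff(n) <= 0))
  expect_lte(gap_report(si2, 50)$gap_bases, 50000)
})

test_that("site density per class matches brute-force counting and is split-invariant", {
  si <- fake_sites(c(10, 50, 120, 500, 900, 1200, 1500, 1800, 1950, 1999), 5000)
  # one class spanning 2000 bp holding all 10 sites
  states <- data.frame(chrom = "chr1", start = 0, end = 2000, class = "all")
  tab <- site_density_by_class(si, states)
  expect_equal(tab$sites_per_kbp, 5.0)
  expect_equal(tab$site_count, 10)

  # a class with intervals but no sites
  states2 <- rbind(states,
                   data.frame(chrom = "chr1", start = 3000, end = 4000,
                              class = "empty"))
  tab2 <- site_density_by_class(si, states2)
  expect_equal(tab2$sites_per_kbp[tab2$class == "empty"], 0)

  # zero-length class is omitted with a warning
  states3 <- rbind(states, data.frame(chrom = "chr1", start = 10, end = 10,
                                      class = "null"))
  expect_warning(tab3 <- site_density_by_class(si, states3), "zero")
  expect_false("null" %in% tab3$class)

  # random sites and intervals against the O(n*m) oracle
  set.seed(108)
  pos <- sort(sample(0:9999, 300))
  si4 <- fake_sites(pos, 10000)
  st <- do.call(rbind, lapply(1:12, function(i) {
    a <- sample(0:9000, 1)
    data.frame(chrom = "chr1", start = a, end = a + sample(100:900, 1),
               class = sample(c("x", "y", "z"), 1))
  }))
  tab4 <- site_density_by_class(si4, st)
  ora <- oracle_density("chr1", pos, st)
  for (cl in tab4$class) {
    expect_equal(tab4$site_count[tab4$class == cl], ora[[cl]])
  }

  # splitting an interval into abutting sub-intervals changes nothing
  split_states <- data.frame(chrom = "chr1", start = c(0, 700, 1300),
                             end = c(700, 1300, 2000), class = "all")
  expect_equal(site_density_by_class(si, split_states),
               site_density_by_class(si, states))
})

test_that("cut_usage measures fragment ends per site and tallies off-site violations", {
  si <- fake_sites(c(0, 100, 300, 600, 1000), 2000)
  states <- data.frame(chrom = "chr1", start = c(0, 500), end = c(500, 2000),
                       class = c("open", "closed"))
  # fragments tiling the cut sites: ends {0,100,100,300,300,600,600,1000}
  obs2 <- data.frame(chrom = "chr1", start = c(0, 100, 300, 600),
                     end = c(100, 300, 600, 1000))
  tab2 <- cut_usage(si, obs2, states)
  expect_equal(attr(tab2, "n_violations"), 0)
  # open holds sites {0,100,300} and 5 end events; closed {600,1000} and 3
  expect_equal(tab2$ends_per_site[tab2$class == "open"], 5 / 3)
  expect_equal(tab2$ends_per_site[tab2$class == "closed"], 3 / 2)
  expect_equal(attr(tab2, "genome_wide_mean"), 8 / 5)
  expect_equal(tab2$relative_usage, tab2$ends_per_site / (8 / 5))

  # ends off any cut position are counted as violations and excluded
  obs3 <- rbind(obs2, data.frame(chrom = "chr1", start = 123, end = 600))
  tab3 <- cut_usage(si, obs3, states)
  expect_equal(attr(tab3, "n_violations"), 1)
  expect_equal(sum(tab3$observed_fragment_ends), 9)

  expect_error(cut_usage(si, obs2[0, ], states), "empty")
})
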