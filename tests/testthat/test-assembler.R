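# shared toy fixture: single error-free read, every k-mer count 1
toy_table <- function() count_kmers("AACGTTGCAAGGTCC", k = 7)
toy_seeds <- function(tab = toy_table(), m = 0) {
  build_seed_sets(primer_pair("toy", "AACGT", "GGACC"), tab,
                  trim_len = 5, mismatches = m)
}

test_that("successors follow the k-1 overlap rule in fixed A,C,G,T order", {
  tab <- toy_table()
  succ <- successors("AACGTTG", tab, min_count = 1)
  expect_identical(succ$base, "C")
  expect_identical(succ$kmer, "ACGTTGC")
  # coverage floor: all counts are 1, so min_count = 2 gives a dead end
  expect_identical(nrow(successors("AACGTTG", tab, min_count = 2)), 0L)
  # branching: two contexts sharing a k-1 prefix give two successors in order
  tab2 <- count_kmers(c("TACGTTGAC", "TACGTTGTC"), k = 7)
  succ2 <- successors("TACGTTG", tab2, min_count = 1)
  expect_identical(succ2$base, c("A", "T"))
})

test_that("the single-read fixture assembles to exactly the read", {
  tab <- toy_table()
  seeds <- toy_seeds(tab)
  prods <- assemble_pair(seeds, tab, traversal_config(min_count = 1))
  expect_identical(nrow(prods), 1L)
  expect_identical(prods$sequence, "AACGTTGCAAGGTCC")
  expect_identical(prods$length, 15L)
  expect_identical(prods$min_coverage, 1L)
  expect_identical(prods$mean_coverage, 1)
})

test_that("min_length and max_length gate products out", {
  tab <- toy_table()
  seeds <- toy_seeds(tab)
  too_long_min <- assemble_pair(seeds, tab,
    traversal_config(min_count = 1, min_length = 20))
  expect_identical(nrow(too_long_min), 0L)
  too_short_max <- assemble_pair(seeds, tab,
    traversal_config(min_count = 1, max_length = 10))
  expect_identical(nrow(too_short_max), 0L)
})

test_that("two haplotypes differing by one substitution give two products", {
  set.seed(41)
  fwd_site <- "AACGTTGCA"; rev_site <- "GGACCTTGA"
  insert <- random_reads(1, 40, 40)
  hap1 <- paste0(fwd_site, insert, rc(rev_site))
  hap2 <- hap1
  substr(hap2, 25, 25) <- if (substr(hap1, 25, 25) == "A") "C" else "A"
  reads <- c(substring(hap1, 1:(nchar(hap1) - 19), 20:nchar(hap1)),
             substring(hap2, 1:(nchar(hap2) - 19), 20:nchar(hap2)))
  tab <- count_kmers(reads, k = 11)
  seeds <- build_seed_sets(primer_pair("hap", fwd_site, rev_site), tab,
                           trim_len = 9, mismatches = 0)
  prods <- assemble_pair(seeds, tab, traversal_config(min_count = 1))
  expect_identical(nrow(prods), 2L)
  expect_setequal(prods$sequence, c(hap1, hap2))
  diffs <- which(strsplit(prods$sequence[1], "")[[1]] !=
                 strsplit(prods$sequence[2], "")[[1]])
  expect_identical(diffs, 25L)
})

test_that("product sets match exhaustive simple-path enumeration on random genomes", {
  set.seed(47)
  fwd_site <- "ACGTTGC"; rev_site <- "TTGGACC"
  for (i in 1:15) {
    genome <- plant_genome(fwd_site, rev_site,
                           insert_len = sample(20:120, 1),
                           flank_len = sample(10:30, 1))
    reads <- substring(genome, 1:(nchar(genome) - 24), 25:nchar(genome))
    tab <- count_kmers(reads, k = 7)
    seeds <- build_seed_sets(primer_pair("rnd", fwd_site, rev_site), tab,
                             trim_len = 7, mismatches = 0)
    if (!seeds$found) next
    # uncapped so the enumeration is exhaustive; the live-path cap is
    # exercised by its own test below
    prods <- assemble_pair(seeds, tab,
                           traversal_config(min_count = 1,
                                            max_paths = 2000000L))
    expected <- oracle_assemble(kmer_counts(tab), seeds$start_kmers,
                                seeds$end_kmers, k = 7, min_count = 1)
    expect_identical(sort(prods$sequence), expected)
  }
})

test_that("every product satisfies its structural invariants", {
  set.seed(53)
  fwd_site <- "AACGTTGCAAGGTCC"; rev_site <- "TTGGACCAACGTTGC"
  genome <- plant_genome(fwd_site, rev_site, insert_len = 200, flank_len = 100)
  reads <- substring(genome, 1:(nchar(genome) - 49), 50:nchar(genome))
  tab <- count_kmers(reads, k = 17)
  pair <- primer_pair("inv", fwd_site, rev_site)
  seeds <- build_seed_sets(pair, tab, trim_len = 15, mismatches = 1)
  cfg <- traversal_config(min_count = 1, min_length = 100, max_length = 400)
  prods <- assemble_pair(seeds, tab, cfg)
  expect_gt(nrow(prods), 0L)
  # independent re-scan of each product against the table
  for (i in seq_len(nrow(prods))) {
    s <- prods$sequence[i]
    expect_identical(nchar(s), prods$length[i])
    expect_true(prods$length[i] >= cfg$min_length &&
                prods$length[i] <= cfg$max_length)
    wins <- substring(s, 1:(nchar(s) - 16), 17:nchar(s))
    counts <- kmer_count(tab, wins)
    expect_true(all(counts >= cfg$min_count))
    expect_identical(min(counts), prods$min_coverage[i])
    expect_equal(mean(counts), prods$mean_coverage[i])
    expect_true(substr(s, 1, 15) %in% mismatch_neighborhood(
      expand_iupac(trim_primer(pair$forward, 15)), 1))
  }
})

test_that("raising min_count never introduces new products", {
  set.seed(59)
  fwd_site <- "ACGTTGC"; rev_site <- "TTGGACC"
  genome <- plant_genome(fwd_site, rev_site, insert_len = 60, flank_len = 20)
  # uneven coverage: every window once, first half twice
  reads <- c(substring(genome, 1:(nchar(genome) - 24), 25:nchar(genome)),
             substring(genome, 1:30, 25:54))
  tab <- count_kmers(reads, k = 7)
  seeds <- build_seed_sets(primer_pair("mono", fwd_site, rev_site), tab,
                           trim_len = 7, mismatches = 0)
  p1 <- assemble_pair(seeds, tab, traversal_config(min_count = 1))
  p2 <- assemble_pair(seeds, tab, traversal_config(min_count = 2))
  expect_true(all(p2$sequence %in% p1$sequence))
})

test_that("the live-path cap truncates complex traversals with a warning", {
  # a ladder of bubbles: 2^6 haplotypes toggling six positions, so the
  # frontier doubles repeatedly and must exceed a small cap
  set.seed(61)
  base <- paste0("AACGTTG", random_reads(1, 28, 28), "GGTCC")  # 40 bp
  toggles <- expand.grid(rep(list(c("A", "C")), 6), stringsAsFactors = FALSE)
  haps <- vapply(seq_len(nrow(toggles)), function(i) {
    h <- base
    for (j in 1:6) substr(h, 8 + 4 * j, 8 + 4 * j) <- toggles[i, j]
    h
  }, character(1))
  reads <- unlist(lapply(haps, function(h)
    substring(h, 1:(nchar(h) - 14), 15:nchar(h))))
  tab <- count_kmers(reads, k = 7)
  seeds <- build_seed_sets(primer_pair("cplx", "AACGT", "GGACC"), tab,
                           trim_len = 5, mismatches = 0)
  expect_true(seeds$found)
  expect_warning(
    assemble_pair(seeds, tab,
                  traversal_config(min_count = 1, max_paths = 5)),
    "live-path cap")
})

test_that("run_spcr counts once and keeps pairs independent", {
  pairs <- list(primer_pair("present", "AACGT", "GGACC"),
                primer_pair("absent", "GGGGG", "CCCCAT"),
                primer_pair("present2", "AACGT", "GGACC"))
  res <- run_spcr("AACGTTGCAAGGTCC", pairs, k = 7, trim_len = 5,
                  mismatches = 0, cfg = traversal_config(min_count = 1))
  expect_identical(res$outcomes$outcome,
                   c("products_found", "primers_not_found", "products_found"))
  expect_identical(res$outcomes$n_products, c(1L, 0L, 1L))
  # same pair under two names gives identical sequences
  seqs <- split(res$products$sequence, res$products$pair_name)
  expect_identical(seqs$present, seqs$present2)
})

test_that("reverse-complementing all reads leaves products unchanged", {
  set.seed(67)
  fwd_site <- "AACGTTGCAAGGTCC"; rev_site <- "TTGGACCAACGTTGC"
  genome <- plant_genome(fwd_site, rev_site, insert_len = 150, flank_len = 80)
  reads <- substring(genome, 1:(nchar(genome) - 49), 50:nchar(genome))
  pair <- primer_pair("strand", fwd_site, rev_site)
  cfg <- traversal_config(min_count = 1)
  res_f <- run_spcr(reads, pair, k = 17, cfg = cfg)
  res_r <- run_spcr(rc(reads), pair, k = 17, cfg = cfg)
  expect_identical(res_f$products$sequence, res_r$products$sequence)
})

test_that("swapping forward and reverse primers reverse-complements products", {
  set.seed(71)
  fwd_site <- "AACGTTGCAAGGTCC"; rev_site <- "TTGGACCAACGTTGC"
  genome <- plant_genome(fwd_site, rev_site, insert_len = 150, flank_len = 80)
  reads <- substring(genome, 1:(nchar(genome) - 49), 50:nchar(genome))
  cfg <- traversal_config(min_count = 1)
  fwd_first <- run_spcr(reads, primer_pair("ab", fwd_site, rev_site),
                        k = 17, cfg = cfg)
  swapped <- run_spcr(reads, primer_pair("ba", rev_site, fwd_site),
                      k = 17, cfg = cfg)
  expect_identical(sort(rc(swapped$products$sequence)),
                   sort(fwd_first$products$sequence))
})

test_that("configuration violations are fatal before counting begins", {
  pair <- primer_pair("cfg", "AACGT", "GGACC")
  expect_error(run_spcr("AACGTTGCAAGGTCC", pair, k = 8), "odd")
  expect_error(run_spcr("AACGTTGCAAGGTCC", pair, k = 7, trim_len = 9),
               "as long as")
})
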