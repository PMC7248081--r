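test_that("break sites classify by the reference pair ending at the 5' base", {
  g <- make_genome(c(c1 = "AACGT"))
  map <- build_methylation_map(data.frame(
    contig = "c1", position = 3L, coverage = 30L, methylated_count = 30L))
  expect_equal(classify_break_sites(g, events_at(4L), map), "CmG")
  expect_equal(classify_break_sites(g, events_at(2L), map), "AA")
  expect_equal(classify_break_sites(g, events_at(1L), map), "DISCARD")
  g2 <- make_genome(c(c1 = "AANGT"))
  expect_equal(classify_break_sites(g2, events_at(3L)), "DISCARD")
  # unmethylated and unknown CpG
  mapu <- build_methylation_map(data.frame(
    contig = "c1", position = 3L, coverage = 30L, methylated_count = 0L))
  expect_equal(classify_break_sites(g, events_at(4L), mapu), "CuG")
  expect_equal(classify_break_sites(g, events_at(4L),
                                    build_methylation_map(data.frame(
                                      contig = "c1", position = 3L,
                                      coverage = 5L, methylated_count = 5L))),
               "CxG")
  # without a map, plain CG
  expect_equal(classify_break_sites(g, events_at(4L)), "CG")
  # masked base in the pair
  mask <- GenomicRanges::GRanges("c1", IRanges::IRanges(3L, 3L))
  expect_equal(classify_break_sites(g, events_at(4L), mask = mask), "DISCARD")
})

test_that("background fractions match a hand count", {
  g <- make_genome(c(c1 = "TTACGTTT"))
  p <- accumulate_background(g, events_at(4L), half_width = 2L)
  # window bases 2..5 = "TACG"; dinucleotide starts: TA, AC, CG
  expect_equal(unname(p[c("TA", "AC", "CG")]), rep(1 / 3, 3))
  expect_equal(sum(p), 1)

  g <- make_genome(c(c1 = strrep("A", 50)))
  p <- accumulate_background(g, events_at(25L), half_width = 10L)
  expect_equal(unname(p["AA"]), 1)
  expect_equal(sum(p > 0), 1L)
})

test_that("streaming rates equal the brute-force oracle on a small fixture", {
  spec <- cohort_spec(genome_length = 1000L, n_islands = 2L, island_length = 100L,
                      n_affected_islands = 1L, seed = 5L)
  sim <- simulate_genome(spec)
  mask <- GenomicRanges::GRanges(spec$contig, IRanges::IRanges(c(301L, 641L),
                                                               c(340L, 660L)))
  model <- fragmentation_model(n_reads = 100L, seed = 9L)
  ev <- simulate_breaks(sim$genome, sim$methylmap, model)
  tbl <- compute_cleavage_rates(sim$genome, ev, sim$methylmap, mask = mask,
                                half_width = 50L)
  mp <- tempfile(); write_methylation_map(sim$methylmap, mp)
  ora <- naive_rates(sim$genome, ev, read_map_tsv_plain(mp), mask = mask,
                     half_width = 50L)
  expect_equal(tbl$N, unname(ora$N))
  expect_equal(tbl$truncated, ora$truncated)
  expect_equal(tbl$discarded, ora$discarded)
  expect_equal(as.numeric(tbl$table$n), unname(ora$n[tbl$table$class]))
  expect_equal(tbl$table$p, unname(ora$p[tbl$table$class]), tolerance = 1e-12)
  defined <- !is.na(tbl$table$r)
  expect_equal(tbl$table$r[defined], unname(ora$r[tbl$table$class][defined]),
               tolerance = 1e-12)
})

test_that("shuffling event order leaves the rate table identical", {
  g <- random_genome(2000L, seed = 21)
  set.seed(8)
  ev <- events_at(sample(150:1850, 400, replace = TRUE))
  t1 <- compute_cleavage_rates(g, ev)
  t2 <- compute_cleavage_rates(g, ev[sample(nrow(ev)), , drop = FALSE])
  expect_identical(t1$table, t2$table)
  expect_identical(t1$N, t2$N)
})

test_that("enlarging the mask never increases any class count", {
  g <- random_genome(2000L, seed = 22)
  set.seed(9)
  ev <- events_at(sample(150:1850, 300, replace = TRUE))
  m1 <- GenomicRanges::GRanges("c1", IRanges::IRanges(500L, 600L))
  m2 <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(500L, 900L),
                                                      c(700L, 1100L)))
  t0 <- compute_cleavage_rates(g, ev)
  t1 <- compute_cleavage_rates(g, ev, mask = m1)
  t2 <- compute_cleavage_rates(g, ev, mask = m2)
  expect_true(all(t1$table$n <= t0$table$n))
  expect_true(all(t2$table$n <= t1$table$n))
})

test_that("truncated-window events are excluded from numerator and background", {
  g <- random_genome(300L, seed = 23)
  tbl <- compute_cleavage_rates(g, events_at(c(5L, 150L)))
  expect_equal(tbl$truncated, 1L)
  expect_equal(tbl$n_windows, 1L)
  expect_equal(sum(tbl$table$n), 1L)
})

test_that("degenerate event sets raise explicit errors", {
  g <- make_genome(c(c1 = paste0(strrep("A", 150), "N", strrep("A", 150))))
  expect_error(compute_cleavage_rates(g, events_at(integer(0))), "no events")
  # the only events break at the N base: discarded, not silently zeroed
  expect_error(compute_cleavage_rates(g, events_at(c(151L, 152L))),
               "discarded or truncated")
  expect_error(compute_cleavage_rates(g, events_at(150L), half_width = 400L),
               "wider than every contig")
})

test_that("island rate matches the hand-computable example", {
  g <- make_genome(c(c1 = paste0(strrep("T", 10), "ACGCGA", strrep("T", 10))))
  islands <- GenomicRanges::GRanges("c1", IRanges::IRanges(11L, 16L))
  names(islands) <- "c1:10-16"
  # dinucleotides of ACGCGA: AC, CG, GC, CG, GA -> p = 2/5; CG starts at 12, 14
  sc <- island_cleavage_rates(g, events_at(c(13L, 15L)), islands, N = 1000L,
                              min_cg = 1L)
  expect_equal(sc$p_island, 0.4)
  expect_equal(sc$n, 2L)
  expect_equal(sc$rate, 2 / (1000 * 0.4))
  # zero CG breaks is a zero rate, not a missing value
  sc0 <- island_cleavage_rates(g, events_at(5L), islands, N = 1000L, min_cg = 1L)
  expect_equal(sc0$rate, 0)
  expect_equal(sc0$status, "ok")
})

test_that("islands without usable CG content report status codes", {
  g <- make_genome(c(c1 = paste0(strrep("T", 30), "ACGATT", strrep("T", 30))))
  no_cg <- GenomicRanges::GRanges("c1", IRanges::IRanges(1L, 20L))
  low_cg <- GenomicRanges::GRanges("c1", IRanges::IRanges(31L, 36L))  # one CG
  sc <- island_cleavage_rates(g, events_at(40L),
                              c(no_cg, low_cg), N = 100L, min_cg = 5L)
  expect_equal(sc$status, c("no_cg", "low_cg"))
  expect_true(all(is.na(sc$rate)))
  sc2 <- island_cleavage_rates(g, events_at(40L), low_cg, N = 100L,
                               min_cg = 1L, min_support = 3L)
  expect_equal(sc2$status, "low_support")
})

test_that("island scores agree with a naive recount on a random fixture", {
  spec <- cohort_spec(genome_length = 5000L, n_islands = 4L, island_length = 200L,
                      seed = 13L)
  sim <- simulate_genome(spec)
  ev <- simulate_breaks(sim$genome, sim$methylmap,
                        fragmentation_model(n_reads = 2000L, seed = 4L))
  sc <- island_cleavage_rates(sim$genome, ev, sim$islands, N = nrow(ev),
                              min_cg = 1L)
  for (k in seq_len(length(sim$islands))) {
    ora <- naive_island_rate(sim$genome, ev, spec$contig,
                             GenomicRanges::start(sim$islands)[k],
                             GenomicRanges::end(sim$islands)[k], N = nrow(ev))
    expect_equal(sc$n[k], ora$n)
    expect_equal(sc$p_island[k], ora$p, tolerance = 1e-12)
    expect_equal(sc$rate[k], ora$rate, tolerance = 1e-12)
  }
})

test_that("rate tables round-trip through TSV", {
  g <- random_genome(1500L, seed = 31)
  set.seed(14)
  tbl <- compute_cleavage_rates(g, events_at(sample(200:1300, 500, TRUE)))
  p <- tempfile(fileext = ".tsv")
  write_rate_table(tbl, p)
  tbl2 <- read_rate_table(p)
  expect_equal(tbl2$table$class, tbl$table$class)
  expect_equal(tbl2$table$n, tbl$table$n)
  expect_equal(tbl2$table$p, tbl$table$p, tolerance = 1e-9)
  expect_equal(tbl2$table$r, tbl$table$r, tolerance = 1e-9)
  expect_equal(tbl2$N, tbl$N)
})

test_that("pooled and per-window background coincide on full unmasked windows", {
  g <- random_genome(3000L, seed = 33)
  set.seed(15)
  ev <- events_at(sample(150:2850, 200, replace = TRUE))
  pp <- accumulate_background(g, ev, p_mode = "pooled")
  pw <- accumulate_background(g, ev, p_mode = "per_window_mean")
  expect_equal(as.numeric(pp), as.numeric(pw), tolerance = 1e-12)
})
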