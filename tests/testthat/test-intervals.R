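# Interval model, BED/TE-table I/O, and set operations vs brute force.

test_that("read_bed maps fields and rejects malformed records", {
  f <- withr::local_tempfile()
  writeLines("chr1\t10\t20\tx\t0\t+", f)
  gr <- read_bed(f)
  expect_equal(as.character(seqnames(gr)), "chr1")
  expect_equal(start(gr), 11)  # 0-based 10 -> 1-based 11
  expect_equal(end(gr), 20)
  expect_equal(gr$name, "x")
  expect_equal(as.character(strand(gr)), "+")

  writeLines("chr1\t20\t10", f)
  expect_error(read_bed(f), "line 1")
  writeLines(c("chr1\t10\t20", "chr1\tx\t30"), f)
  expect_error(read_bed(f), "line 2")
  writeLines(c("# header", "", "chr2\t0\t5"), f)
  expect_equal(length(read_bed(f)), 1)

  genome <- genome_table("chr1", 100)
  writeLines("chr1\t90\t120", f)
  expect_error(read_bed(f, genome), "bounds")
  writeLines("chrX\t1\t5", f)
  expect_error(read_bed(f, genome), "unknown chromosome")
})

test_that("BED round-trips bit-identically through write_bed/read_bed", {
  set.seed(41)
  genome <- small_genome()
  gr <- random_gr(50, genome)
  gr$name <- sprintf("iv_%02d", seq_along(gr))
  gr$score <- sample(0:60, 50, replace = TRUE)
  f <- withr::local_tempfile()
  write_bed(gr, f)
  back <- read_bed(f)
  expect_equal(as.data.frame(back), as.data.frame(gr))
  # a second write of the re-read object is byte-identical
  f2 <- withr::local_tempfile()
  write_bed(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("BED12 blocks round-trip and are validated", {
  tx <- GRanges("chr1", IRanges(101, 400), strand = "+")
  tx$name <- "tx1"
  tx$score <- 0
  tx$blocks <- IRangesList(IRanges(start = c(101, 201, 351),
                                   end = c(150, 260, 400)))
  f <- withr::local_tempfile()
  write_bed(tx, f)
  fields <- strsplit(readLines(f), "\t")[[1]]
  expect_length(fields, 12)
  back <- read_bed(f)
  expect_equal(back$blocks[[1]], tx$blocks[[1]])
  # blocks not flush with the span end are rejected
  writeLines("chr1\t100\t400\ttx\t0\t+\t100\t400\t0\t1\t100\t0", f)
  expect_error(read_bed(f), "blocks")
})

test_that("read_te_table enforces the consensus invariants", {
  f <- withr::local_tempfile()
  hdr <- paste(c("chrom", "start", "end", "strand", "class", "family",
                 "subfamily", "repStart", "repEnd", "consensusLength"),
               collapse = "\t")
  writeLines(c(hdr,
               "chr1\t100\t400\t+\tSINE\tMIR\tMIRb\t10\t262\t262",
               "chr1\t500\t600\t-\tSINE\tMIR\tMIRb\t200\t100\t262",
               "chr1\t700\t800\t+\tSINE\tMIR\tMIRb\t10\t300\t262"), f)
  expect_warning(te <- read_te_table(f), "2 TE row")
  expect_length(te, 1)
  expect_equal(te$rep_start, 10L)
  expect_equal(te$rep_end, 262L)
  expect_equal(start(te), 101)

  writeLines(hdr, f)
  expect_length(suppressWarnings(read_te_table(f)), 0)
  writeLines(c("chrom\tstart\tend", "chr1\t1\t2"), f)
  expect_error(read_te_table(f), "missing column")
})

test_that("TE tables round-trip through write_te_table", {
  cfg <- tiny_config()
  te <- simulate_genome(cfg, seed = 7)$te
  f <- withr::local_tempfile()
  write_te_table(te, f)
  back <- read_te_table(f)
  expect_equal(as.data.frame(back), as.data.frame(te))
})

test_that("interval_pairs honours the half-open boundary convention", {
  # BED chr1:10-20 vs chr1:19-30 share exactly 1 bp; vs 20-30 touch only
  q <- GRanges("chr1", IRanges(11, 20))
  expect_equal(nrow(interval_pairs(q, GRanges("chr1", IRanges(20, 30)))), 1)
  expect_equal(nrow(interval_pairs(q, GRanges("chr1", IRanges(21, 30)))), 0)
})

test_that("interval_pairs matches the all-pairs oracle", {
  set.seed(42)
  genome <- small_genome()
  for (rep in 1:3) {
    q <- random_gr(120, genome)
    s <- random_gr(120, genome)
    for (sm in c(FALSE, TRUE)) {
      for (mo in c(1, 25)) {
        expect_equal(interval_pairs(q, s, strand_match = sm,
                                    min_overlap = mo),
                     oracle_pairs(q, s, strand_match = sm,
                                  min_overlap = mo),
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("window_pairs equals expansion + intersect and reduces at w=0", {
  q <- GRanges("chr1", IRanges(1001, 1010))
  s <- GRanges("chr1", IRanges(1201, 1210))  # gap 190
  expect_equal(nrow(window_pairs(q, s, w = 300)), 1)
  expect_equal(nrow(window_pairs(q, s, w = 100)), 0)

  set.seed(43)
  genome <- small_genome()
  q <- random_gr(100, genome)
  s <- random_gr(100, genome)
  expect_equal(window_pairs(q, s, w = 0), interval_pairs(q, s),
               ignore_attr = TRUE)
  # manual expansion oracle
  w <- 150
  qx <- q
  ranges(qx) <- IRanges(pmax(1, start(q) - w), end(q) + w)
  expect_equal(window_pairs(q, s, w = w, genome = genome),
               oracle_pairs(qx, s), ignore_attr = TRUE)
})

test_that("split_pairs sees exons only", {
  tx <- GRanges("chr1", IRanges(1001, 2000), strand = "+")
  tx$blocks <- IRangesList(IRanges(start = c(1001, 1601),
                                   end = c(1200, 2000)))
  intron_probe <- GRanges("chr1", IRanges(1300, 1360), strand = "+")
  expect_equal(nrow(split_pairs(intron_probe, tx)), 0)
  edge_probe <- GRanges("chr1", IRanges(1200, 1260), strand = "+")
  expect_equal(nrow(split_pairs(edge_probe, tx)), 1)
  # strand mismatch blocks the pair
  minus_probe <- GRanges("chr1", IRanges(1100, 1150), strand = "-")
  expect_equal(nrow(split_pairs(minus_probe, tx)), 0)
  expect_equal(nrow(split_pairs(minus_probe, tx, strand_match = FALSE)), 1)
})

test_that("split_pairs matches the exploded-exon oracle", {
  set.seed(44)
  genome <- small_genome()
  cfg <- tiny_config()
  tx <- simulate_transcriptome(cfg, simulate_genome(cfg, seed = 3)$te,
                               genome_table(paste0("chr", 1:2),
                                            rep(5e5, 2)),
                               seed = 5)$transcripts
  probes <- random_gr(150, genome_table(paste0("chr", 1:2), rep(5e5, 2)),
                      max_width = 80)
  # oracle: explode blocks into exon GRanges, all-pairs, map back
  b <- tx$blocks
  exons <- GRanges(rep(seqnames(tx), lengths(b)), unlist(b),
                   strand = rep(strand(tx), lengths(b)))
  exp_pairs <- oracle_pairs(probes, exons, strand_match = TRUE)
  exp_pairs$subject <- rep(seq_along(tx), lengths(b))[exp_pairs$subject]
  exp_pairs <- unique(exp_pairs)
  exp_pairs <- exp_pairs[order(exp_pairs$query, exp_pairs$subject), ]
  expect_equal(split_pairs(probes, tx), exp_pairs, ignore_attr = TRUE)
})

test_that("subtract_intervals is the overlap complement", {
  a <- GRanges("chr1", IRanges(c(1, 100), width = 10))
  b <- GRanges("chr1", IRanges(105, 106))
  expect_equal(start(subtract_intervals(a, b)), 1)
  expect_equal(length(subtract_intervals(a, GRanges())), 2)

  set.seed(45)
  genome <- small_genome()
  q <- random_gr(200, genome)
  s <- random_gr(200, genome)
  kept <- subtract_intervals(q, s)
  in_pairs <- unique(oracle_pairs(q, s)$query)
  expect_equal(as.data.frame(kept),
               as.data.frame(q[setdiff(seq_along(q), in_pairs)]))
})
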