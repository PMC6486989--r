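# Binned RPKM metaprofiles, smoothing and truncation profiles.

test_that("stratify_by_binding partitions a subfamily's copies", {
  set.seed(60)
  genome <- small_genome(1, 200000)
  te <- GRanges("chr1", IRanges(seq(1001, 91001, by = 10000), width = 200),
                te_subfamily = "MIRb")
  peaks <- GRanges("chr1", IRanges(start(te)[c(2, 5, 9)] + 50, width = 20))
  g <- stratify_by_binding(te, "MIRb", peaks)
  expect_length(g$bound, 3)
  expect_length(g$unbound, 7)
  expect_equal(sort(c(start(g$bound), start(g$unbound))), sort(start(te)))
  # oracle agreement
  bound_idx <- unique(oracle_pairs(te, peaks)$query)
  expect_equal(sort(start(g$bound)), sort(start(te)[bound_idx]))
  # no peaks -> all unbound
  g0 <- stratify_by_binding(te, "MIRb", GRanges())
  expect_length(g0$bound, 0)
  expect_length(g0$unbound, 10)
})

test_that("binned_rpkm arithmetic and overlap rule", {
  genome <- genome_table("chr1", 50000)
  anchor <- GRanges("chr1", IRanges(20001, 20200), name = "a1")
  # midpoint 0-based 20100; bin 101 covers [20100, 20150)
  tags <- GRanges("chr1", IRanges(c(20111, 20121), width = 20))
  tr <- tag_track(tags, total_mapped = 1e6)
  m <- binned_rpkm(anchor, tr, genome)
  expect_equal(dim(m), c(1, 200))
  expect_equal(m[1, 101], 2 * 1e9 / (50 * 1e6))  # = 40
  expect_equal(sum(m[1, ] > 0), 1)
  # a tag spanning two bins increments both
  tr2 <- tag_track(GRanges("chr1", IRanges(20141, 20160)),
                   total_mapped = 1e6)
  m2 <- binned_rpkm(anchor, tr2, genome)
  expect_equal(unname(m2[1, 101:102]), c(20, 20))
  expect_error(tag_track(tags, total_mapped = 0), "positive")
})

test_that("binned_rpkm matches brute-force bin counting and clips windows", {
  set.seed(61)
  genome <- genome_table("chr1", 30000)
  anchors <- GRanges("chr1", IRanges(c(15001, 2001), width = 100),
                     name = c("mid", "edge"))
  tags <- random_gr(800, genome, max_width = 60, stranded = FALSE)
  tr <- tag_track(tags, total_mapped = 1234)
  m <- binned_rpkm(anchors, tr, genome)
  for (i in 1:2) {
    mid0 <- floor((start(anchors)[i] - 1 + end(anchors)[i]) / 2)
    want <- oracle_bin_counts(mid0, "chr1", tags) * 1e9 / (50 * 1234)
    lo0 <- mid0 - 5000
    clipped <- which(lo0 + (seq_len(200) - 1) * 50 < 0)
    if (length(clipped) > 0) want[clipped] <- NA
    expect_equal(unname(m[i, ]), want)
  }
  expect_true(anyNA(m["edge", ]))
  expect_false(anyNA(m["mid", ]))
})

test_that("aggregate_profile follows the replicate/control/anchor order", {
  set.seed(62)
  genome <- genome_table("chr1", 60000)
  anchors <- GRanges("chr1", IRanges(c(10001, 30001, 50001), width = 150),
                     name = c("a", "b", "c"))
  t1 <- tag_track(random_gr(500, genome, 60, FALSE), "r1", 5e5)
  t2 <- tag_track(random_gr(500, genome, 60, FALSE), "r2", 5e5)
  # replicate == control -> exactly flat zero
  prof0 <- aggregate_profile(anchors, list(t1, t2), list(t1, t2), genome)
  expect_equal(prof0$mean, rep(0, 200))
  # single anchor, single replicate, no control -> equals binned_rpkm
  prof1 <- aggregate_profile(anchors[1], t1, NULL, genome)
  expect_equal(prof1$mean, unname(binned_rpkm(anchors[1], t1, genome)[1, ]))
  expect_equal(prof1$n, rep(1L, 200))
  # manual order-of-operations oracle
  m1 <- binned_rpkm(anchors, t1, genome)
  m2 <- binned_rpkm(anchors, t2, genome)
  ctl <- binned_rpkm(anchors, t2, genome)
  prof <- aggregate_profile(anchors, list(t1, t2), list(t2), genome)
  expect_equal(prof$mean, unname(colMeans((m1 + m2) / 2 - ctl)))
  expect_error(aggregate_profile(GRanges(), t1, NULL, genome), "anchors")
})

test_that("smooth_profile is the Epanechnikov Nadaraya-Watson smoother", {
  expect_equal(smooth_profile(rep(3.5, 200)), rep(3.5, 200))
  # spike weights fall off as 0.75(1 - (d/150)^2) in the interior
  y <- rep(0, 200); y[100] <- 1
  s <- smooth_profile(y)
  expect_equal(s[99] / s[98],
               (0.75 * (1 - (50 / 150)^2)) / (0.75 * (1 - (100 / 150)^2)))
  # full agreement with the naive O(n^2) oracle, including NA handling
  set.seed(63)
  vals <- rnorm(120)
  vals[c(5, 40, 41)] <- NA
  pos <- (seq_len(120) - 1) * 50
  got <- smooth_profile(vals, pos, bandwidth = 150)
  expect_equal(got, oracle_smooth(vals, pos, 150))
})

test_that("profile reflects under genome reflection", {
  set.seed(64)
  L <- 40000
  genome <- genome_table("chr1", L)
  # even start0+end0 so the reflected midpoint is exact
  a_s0 <- c(12000, 20000, 27000)
  anchors <- GRanges("chr1", IRanges(a_s0 + 1, width = 200), name = letters[1:3])
  tags <- GRanges("chr1", IRanges(sort(sample(seq(1, L - 60, by = 2), 400)),
                                  width = 50))
  tr <- tag_track(tags, total_mapped = 1000)
  fwd <- aggregate_profile(anchors, tr, NULL, genome)
  refl <- function(gr) GRanges("chr1",
                               IRanges(L - end(gr) + 1, L - start(gr) + 1))
  r_anchors <- refl(anchors); r_anchors$name <- anchors$name
  r_tr <- tag_track(refl(tags), total_mapped = 1000)
  rev_prof <- aggregate_profile(r_anchors, r_tr, NULL, genome)
  expect_equal(rev_prof$mean, rev(fwd$mean))
})

test_that("bound copies show elevated centre signal with planted folds", {
  cfg <- tiny_config(tag_background_rate = 0.02)
  gen <- simulate_genome(cfg, seed = 65)
  sel <- gen$te[gen$te$te_subfamily == "MIRb"]
  bound <- sel[1:20]
  unbound <- sel[21:40]
  tr <- simulate_mark_tracks(cfg, bound, gen$genome, seed = 66)
  pb <- aggregate_profile(bound, tr$replicates, list(tr$control),
                          gen$genome)
  pu <- aggregate_profile(unbound, tr$replicates, list(tr$control),
                          gen$genome)
  centre <- abs(pb$offset) <= 250
  flank_out <- abs(pb$offset) >= 3000
  expect_gt(mean(pb$mean[centre]), mean(pu$mean[centre]))
  expect_gt(mean(pb$mean[centre]), mean(pb$mean[flank_out]))
})

test_that("truncation_profile counts consensus coverage per position", {
  te <- GRanges("chr1", IRanges(rep(1, 4), width = 10),
                rep_start = c(1L, 1L, 50L, 120L),
                rep_end = c(200L, 99L, 150L, 200L),
                consensus_length = rep(200L, 4))
  prof <- truncation_profile(te)
  expect_length(prof, 200)
  expect_equal(prof[100], 0.5)  # copies 1 and 3 cover position 100
  expect_equal(prof[1], 0.5)
  expect_equal(prof[130], 0.75)
  # all full-length -> all ones
  full <- GRanges("chr1", IRanges(1:3, width = 5), rep_start = rep(1L, 3),
                  rep_end = rep(50L, 3), consensus_length = rep(50L, 3))
  expect_equal(truncation_profile(full), rep(1, 50))
  # brute-force oracle on random spans
  set.seed(67)
  rs <- sample(1:150, 30, replace = TRUE)
  re <- pmin(200L, rs + sample(10:100, 30, replace = TRUE))
  rnd <- GRanges("chr1", IRanges(seq(1, by = 300, length.out = 30),
                                 width = re - rs + 1),
                 rep_start = as.integer(rs), rep_end = as.integer(re),
                 consensus_length = rep(200L, 30))
  want <- vapply(1:200, function(p) sum(rs <= p & re >= p) / 30, 0)
  expect_equal(truncation_profile(rnd), want)
})

test_that("filter_by_mapq keeps high-quality tags and rescales", {
  tags <- GRanges("chr1", IRanges(1:10, width = 5),
                  score = c(0, 0, 1, 5, 10, 10, 20, 30, 40, 60))
  tr <- tag_track(tags, total_mapped = 10)
  expect_equal(length(filter_by_mapq(tr, 0)$tags), 10)
  f10 <- filter_by_mapq(tr, 10)
  expect_equal(length(f10$tags), 6)
  expect_equal(f10$total_mapped, 6)
  expect_equal(start(f10$tags), which(tags$score >= 10))
  zero <- filter_by_mapq(tag_track(tags[1:2], total_mapped = 2), 1)
  expect_length(zero$tags, 0)
})
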