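# Consensus liftover, normalised levels and the three statistical tests.

make_copy <- function(s1, e1, rs, re, strand = "+", cl = 300L,
                      name = "c1", chrom = "chr1") {
  GRanges(chrom, IRanges(s1, e1), strand = strand,
          te_subfamily = "X", te_class = "SINE", te_family = "X",
          rep_start = as.integer(rs), rep_end = as.integer(re),
          consensus_length = cl, name = name)
}

test_that("homologous_regions projects a TFBS across full-length copies", {
  # candidate: consensus 1..300 over BED 1000-1300 (+)
  cand <- make_copy(1001, 1300, 1, 300)
  tfbs <- GRanges("chr1", IRanges(1101, 1150))  # BED 1100-1150
  copies <- c(cand, make_copy(5001, 5300, 1, 300, name = "c2"))
  out <- homologous_regions(cand, tfbs, copies)
  expect_equal(out$c_start, c(101, 101))
  expect_equal(out$c_end, c(150, 150))
  # second copy receives BED 5100-5150
  expect_equal(start(out)[2] - 1, 5100)
  expect_equal(end(out)[2], 5150)
  # a copy covering consensus 200..300 only contributes nothing
  short <- make_copy(8001, 8101, 200, 300, name = "c3")
  out2 <- homologous_regions(cand, tfbs, short)
  expect_length(out2, 0)
  # non-overlapping TFBS is an error
  expect_error(homologous_regions(cand, GRanges("chr1", IRanges(1, 10)),
                                  copies), "overlap")
})

test_that("liftover agrees with the per-base oracle on mixed strands", {
  set.seed(80)
  cand <- make_copy(10001, 10240, 31, 270)
  tfbs <- GRanges("chr1", IRanges(10081, 10140))
  copies <- c(cand,
              make_copy(20001, 20300, 1, 300, "-", name = "m1"),
              make_copy(30001, 30140, 81, 220, "-", name = "m2"),
              make_copy(40001, 40100, 121, 220, "+", name = "p2"))
  out <- homologous_regions(cand, tfbs, copies)
  for (k in seq_along(out)) {
    host <- copies[match(out$name[k], copies$name)]
    want <- oracle_lift(out$c_start[k], out$c_end[k], host)
    expect_equal(c(start(out)[k] - 1, end(out)[k] - 1), want)
    # lifted interval bounded by its host copy
    expect_gte(start(out)[k], start(host))
    expect_lte(end(out)[k], end(host))
  }
})

test_that("normalized_level is the candidate/subfamily count ratio", {
  cand <- GRanges("chr1", IRanges(1001, 1100))
  subf <- c(cand, GRanges("chr1", IRanges(5001, 5100)))
  tags <- c(GRanges("chr1", IRanges(sample(1001:1060, 5), width = 40)),
            GRanges("chr1", IRanges(sample(5001:5060, 45), width = 40)))
  tr <- tag_track(tags)
  expect_equal(normalized_level(cand, subf, tr), 5 / 50)
  # sole copy: ratio 1
  expect_equal(normalized_level(cand, cand, tag_track(tags[1:5])), 1)
  expect_error(normalized_level(cand, GRanges("chr1", IRanges(9001, 9002)),
                                tr),
               "no tags")
})

test_that("paired_methylation_test is the lower-tail one-sample t on d", {
  set.seed(81)
  tum <- runif(6, 0.2, 0.5)
  nor <- tum + rnorm(6, 0.1, 0.05)
  res <- paired_methylation_test(tum, nor)
  d <- tum - nor
  t_hand <- mean(d) / (sd(d) / sqrt(6))
  expect_equal(res$statistic, t_hand)
  expect_equal(res$df, 5)
  expect_equal(res$p_value, pt(t_hand, 5))
  # symmetric pairs: t = 0, p = 0.5
  sym <- paired_methylation_test(c(0.3, 0.5, 0.4, 0.6),
                                 c(0.5, 0.3, 0.6, 0.4))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 0.5)
  expect_error(paired_methylation_test(c(0.3, 0.4), c(0.3, 0.4)),
               "degenerate")
})

test_that("dnase_proportion_test halves the matched-direction tail", {
  res <- dnase_proportion_test(300, 2000, 150, 2000)
  two_sided <- prop.test(c(300, 150), c(2000, 2000))
  expect_equal(res$statistic, unname(two_sided$statistic))
  expect_equal(res$p_value, two_sided$p.value / 2)
  # direction mismatch: complement of the half-tail
  rev <- dnase_proportion_test(150, 2000, 300, 2000)
  expect_equal(rev$p_value, 1 - two_sided$p.value / 2)
  # equal proportions sit at the null centre
  eq <- dnase_proportion_test(50, 1000, 50, 1000)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 0.5)
  # Yates-corrected statistic equals the direct 2x2 formula
  a <- 30; b <- 970; c0 <- 12; d0 <- 988
  N <- a + b + c0 + d0
  hand <- N * (abs(a * d0 - b * c0) - N / 2)^2 /
    ((a + b) * (c0 + d0) * (a + c0) * (b + d0))
  got <- dnase_proportion_test(a, a + b, c0, c0 + d0)
  expect_equal(got$statistic, hand)
  expect_error(dnase_proportion_test(1, 0, 1, 10))
})

test_that("luciferase activities normalise to control then wild-type", {
  plates <- expand.grid(well = 1:3,
                        construct = c("wild_type", "te_deleted",
                                      "positive_control"),
                        experiment = 1:2, stringsAsFactors = FALSE)
  plates$renilla <- 1000
  base <- c(wild_type = 4, te_deleted = 2, positive_control = 8)
  plates$firefly <- 1000 * base[plates$construct]
  act <- luciferase_relative_activity(plates)
  expect_equal(act$relative_activity[act$construct == "positive_control"],
               c(1, 1))
  # deleted has half the firefly signal -> half the wild-type activity
  wt <- act$relative_activity[act$construct == "wild_type"]
  del <- act$relative_activity[act$construct == "te_deleted"]
  expect_equal(del, wt / 2)
  # wild-type rescaling puts mean wild-type at 1
  act_wt <- luciferase_relative_activity(plates, wild_type = "wild_type")
  expect_equal(mean(act_wt$relative_activity[act_wt$construct ==
                                               "wild_type"]), 1)
  bad <- plates; bad$firefly[1] <- -1
  expect_error(luciferase_relative_activity(bad), "positive")
})

test_that("synthetic plates recover the configured construct effects", {
  cfg <- sim_config(luciferase = list(
    effects = c(wild_type = 1, te_deleted = 0.3, positive_control = 1),
    cv = 0.05, n_experiments = 3, base_renilla = 2e4, base_ratio = 5))
  plates <- simulate_luciferase(cfg, seed = 82)
  act <- luciferase_relative_activity(plates, wild_type = "wild_type")
  del <- act$relative_activity[act$construct == "te_deleted"]
  expect_lt(abs(mean(del) - 0.3), 0.08)
})

test_that("luciferase_deletion_test is the pooled-variance lower tail", {
  same <- luciferase_deletion_test(c(1, 1.1, 0.9), c(1, 1.1, 0.9))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 0.5)
  expect_equal(same$df, 4)
  # a 10-pooled-SD drop is overwhelmingly significant
  wt <- c(1, 1.05, 0.95)
  strong <- luciferase_deletion_test(wt, wt - 10 * sd(wt))
  expect_lt(strong$p_value, 0.001)
  expect_equal(strong$stars, "***")
  # hand formula on random triplets
  set.seed(83)
  for (i in 1:5) {
    a <- rnorm(3, 1, 0.1); b <- rnorm(3, 0.7, 0.1)
    sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
    t_hand <- (mean(b) - mean(a)) / (sp * sqrt(2 / 3))
    got <- luciferase_deletion_test(a, b)
    expect_equal(got$statistic, t_hand)
    expect_equal(got$p_value, pt(t_hand, 4))
  }
})

test_that("one-tailed p helpers invert printed statistics", {
  expect_equal(p_from_t_statistic(-2, 10), pt(-2, 10))
  expect_equal(p_from_t_statistic(-2, 10, tail = "upper"),
               pt(-2, 10, lower.tail = FALSE))
  expect_equal(p_from_chisq_statistic(3.84),
               pchisq(3.84, 1, lower.tail = FALSE) / 2)
})
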