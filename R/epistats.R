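# Subfamily-normalised epigenetic statistics and reporter-assay tests.
#
# Methylation and DNase sensitivity of a candidate TE are measured as the
# tag count in its TFBS footprint divided by the count over the
# homologous regions (same consensus span) of every copy in the
# subfamily; tested with a one-sample lower-tail t-test on paired
# tumour/normal differences, and a one-tailed two-sample proportion test
# respectively. Luciferase activity is firefly:Renilla per well, averaged
# over triplicates, normalised to the positive control, then to mean
# wild-type; deletions are tested with a one-tailed equal-variance t-test.

#' @noRd
te_test_result <- function(statistic, df, tail, p_value, method) {
  structure(list(statistic = statistic, df = df, tail = tail,
                 p_value = p_value, method = method),
            class = "te_test_result")
}

#' @export
print.te_test_result <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic, digits = 4),
      " df =", x$df, " tail =", x$tail,
      " p =", format(x$p_value, digits = 3), "\n")
  invisible(x)
}

# Linear genomic <-> consensus maps for one TE copy. Exact when the
# genomic span and the consensus span have equal length (no indels);
# otherwise proportional interpolation.
.g2c <- function(g0, s0, e0, rs, re, strand) {
  glen <- e0 - s0
  clen <- re - rs + 1
  if (strand == "-") rs + floor((e0 - 1 - g0) * clen / glen)
  else rs + floor((g0 - s0) * clen / glen)
}
.c2g <- function(cpos, s0, e0, rs, re, strand) {
  glen <- e0 - s0
  clen <- re - rs + 1
  if (strand == "-") s0 + floor((re - cpos) * glen / clen)
  else s0 + floor((cpos - rs) * glen / clen)
}

#' Homologous regions of a TFBS footprint across a subfamily
#'
#' Projects the TFBS footprint within a candidate TE copy onto consensus
#' coordinates via the copy's (rep_start, rep_end) alignment, then lifts
#' the consensus span back into every subfamily copy whose consensus
#' alignment covers at least 1 bp of it. Copies not covering the
#' footprint contribute nothing; lifted intervals never exceed their host
#' copy's genomic bounds.
#'
#' @param candidate_te Single-element TE GRanges (the candidate copy).
#' @param tfbs Single-element GRanges overlapping the candidate.
#' @param subfamily_copies TE GRanges of all copies of the subfamily
#'   (typically including the candidate itself).
#' @return GRanges of lifted regions with metadata columns `name` (host
#'   copy) and consensus span `c_start`/`c_end`.
#' @export
homologous_regions <- function(candidate_te, tfbs, subfamily_copies) {
  stopifnot(length(candidate_te) == 1, length(tfbs) == 1)
  cs0 <- GenomicRanges::start(candidate_te) - 1
  ce0 <- GenomicRanges::end(candidate_te)
  fs0 <- max(GenomicRanges::start(tfbs) - 1, cs0)
  fe0 <- min(GenomicRanges::end(tfbs), ce0)
  if (fs0 >= fe0 ||
      as.character(GenomicRanges::seqnames(tfbs)) !=
      as.character(GenomicRanges::seqnames(candidate_te)))
    stop("TFBS does not overlap the candidate TE")
  cstrand <- as.character(GenomicRanges::strand(candidate_te))
  if (cstrand == "*") cstrand <- "+"
  # consensus positions of the two footprint end bases
  ends_c <- c(.g2c(fs0, cs0, ce0, candidate_te$rep_start,
                   candidate_te$rep_end, cstrand),
              .g2c(fe0 - 1, cs0, ce0, candidate_te$rep_start,
                   candidate_te$rep_end, cstrand))
  c1 <- min(ends_c); c2 <- max(ends_c)

  out <- lapply(seq_along(subfamily_copies), function(i) {
    cp <- subfamily_copies[i]
    f1 <- max(c1, cp$rep_start)
    f2 <- min(c2, cp$rep_end)
    if (f1 > f2) return(NULL)
    s0 <- GenomicRanges::start(cp) - 1
    e0 <- GenomicRanges::end(cp)
    st <- as.character(GenomicRanges::strand(cp))
    if (st == "*") st <- "+"
    g <- c(.c2g(f1, s0, e0, cp$rep_start, cp$rep_end, st),
           .c2g(f2, s0, e0, cp$rep_start, cp$rep_end, st))
    g1 <- max(min(g), s0)
    g2 <- min(max(g), e0 - 1)
    GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(cp),
      ranges = IRanges::IRanges(start = g1 + 1, end = g2 + 1),
      strand = st, name = cp$name, c_start = f1, c_end = f2)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0)
    return(GenomicRanges::GRanges(name = character(),
                                  c_start = integer(), c_end = integer()))
  do.call(c, out)
}

#' Subfamily-normalised tag level
#'
#' Distinct tags overlapping the candidate region(s) divided by distinct
#' tags overlapping the full homologous region set of the subfamily; the
#' depth-normalisation used for both methylation level and DNase
#' sensitivity.
#'
#' @param candidate_regions GRanges: the candidate TE's TFBS footprint.
#' @param subfamily_regions GRanges: homologous regions across all copies
#'   (from [homologous_regions()]).
#' @param track A `tag_track`.
#' @return The ratio (a single number).
#' @export
normalized_level <- function(candidate_regions, subfamily_regions, track) {
  stopifnot(inherits(track, "tag_track"))
  n_cand <- sum(IRanges::overlapsAny(track$tags, candidate_regions,
                                     ignore.strand = TRUE))
  n_sub <- sum(IRanges::overlapsAny(track$tags, subfamily_regions,
                                    ignore.strand = TRUE))
  if (n_sub == 0) stop("no tags over the subfamily regions")
  n_cand / n_sub
}

#' Paired tumour/normal methylation test
#'
#' One-sample, one-tailed t-test on the per-pair differences
#' `d = tumour - normal`, testing whether the mean difference is below
#' zero (hypomethylation in tumours): `t = mean(d) / (sd(d) / sqrt(n))`,
#' `df = n - 1`, lower-tail p.
#'
#' @param tumour,normal Numeric vectors of normalised methylation levels,
#'   paired by position (length >= 2).
#' @return A `te_test_result`.
#' @export
paired_methylation_test <- function(tumour, normal) {
  stopifnot(length(tumour) == length(normal), length(tumour) >= 2)
  d <- tumour - normal
  if (stats::sd(d) == 0)
    stop("degenerate input: zero variance of paired differences")
  tt <- stats::t.test(d, alternative = "less")
  te_test_result(unname(tt$statistic), unname(tt$parameter), "lower",
                 tt$p.value, "one-sample one-tailed t-test (paired differences)")
}

#' One-tailed p-value from a t statistic
#'
#' Tail probability of Student's t, used to report one-sided tests from
#' their printed statistics.
#'
#' @param statistic Observed t statistic.
#' @param df Degrees of freedom.
#' @param tail `"lower"` or `"upper"`.
#' @return The one-tailed p-value.
#' @export
p_from_t_statistic <- function(statistic, df, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  stats::pt(statistic, df, lower.tail = (tail == "lower"))
}

#' One-tailed p-value from a chi-square statistic
#'
#' Half the upper-tail chi-square probability: the one-sided p of a
#' proportion test whose observed direction matches the alternative.
#'
#' @param statistic Observed chi-square statistic.
#' @param df Degrees of freedom (default 1).
#' @return The one-tailed p-value.
#' @export
p_from_chisq_statistic <- function(statistic, df = 1) {
  stats::pchisq(statistic, df, lower.tail = FALSE) / 2
}

#' One-tailed two-sample proportion test
#'
#' Chi-square proportion test (Yates continuity correction by default,
#' df = 1) comparing `x1/n1` against `x2/n2`. The one-tailed p-value is
#' half the upper-tail chi-square probability when the observed direction
#' matches `direction`, and one minus that half otherwise; equal
#' proportions give p = 0.5.
#'
#' @param x1,n1 Successes and trials in sample 1 (e.g. candidate and
#'   subfamily counts in MCF7).
#' @param x2,n2 Successes and trials in sample 2 (e.g. HMEC).
#' @param direction `"greater"` (default) tests p1 > p2, `"less"` the
#'   reverse.
#' @param correct Apply Yates continuity correction (default `TRUE`).
#' @return A `te_test_result` carrying the chi-square statistic.
#' @export
dnase_proportion_test <- function(x1, n1, x2, n2,
                                  direction = c("greater", "less"),
                                  correct = TRUE) {
  direction <- match.arg(direction)
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  pt <- suppressWarnings(stats::prop.test(c(x1, x2), c(n1, n2),
                                          correct = correct))
  stat <- unname(pt$statistic)
  half <- p_from_chisq_statistic(stat, df = 1)
  obs_dir <- sign(x1 / n1 - x2 / n2)
  want_dir <- if (direction == "greater") 1 else -1
  p <- if (obs_dir == 0 || obs_dir == want_dir) half else 1 - half
  te_test_result(stat, 1, "upper", p,
                 sprintf("one-tailed proportion test (%s)", direction))
}

#' Relative luciferase activity per construct
#'
#' Per well, the firefly:Renilla luminescence ratio; per construct within
#' each experiment, the triplicate mean ratio divided by that
#' experiment's positive-control mean. Optionally the values are further
#' normalised to the mean wild-type activity across experiments (the
#' scale on which deletions are tested).
#'
#' @param plates data.frame with columns `experiment`, `construct`,
#'   `well`, `firefly`, `renilla` (all luminescence values > 0).
#' @param positive_control Construct label of the positive control.
#' @param wild_type Construct label of the wild-type promoter; when
#'   non-`NULL`, activities are rescaled to mean wild-type = 1.
#' @return data.frame with columns `experiment`, `construct`,
#'   `relative_activity`.
#' @export
luciferase_relative_activity <- function(plates,
                                         positive_control = "positive_control",
                                         wild_type = NULL) {
  need <- c("experiment", "construct", "firefly", "renilla")
  stopifnot(all(need %in% names(plates)))
  if (any(plates$firefly <= 0) || any(plates$renilla <= 0))
    stop("luminescence values must be positive")
  plates$ratio <- plates$firefly / plates$renilla
  agg <- stats::aggregate(ratio ~ experiment + construct, plates, mean)
  pc <- agg[agg$construct == positive_control, c("experiment", "ratio")]
  if (nrow(pc) == 0) stop("positive control construct not found")
  agg$relative_activity <-
    agg$ratio / pc$ratio[match(agg$experiment, pc$experiment)]
  if (!is.null(wild_type)) {
    wt_mean <- mean(agg$relative_activity[agg$construct == wild_type])
    agg$relative_activity <- agg$relative_activity / wt_mean
  }
  out <- agg[order(agg$experiment, agg$construct),
             c("experiment", "construct", "relative_activity")]
  rownames(out) <- NULL
  out
}

#' One-tailed equal-variance t-test for TE-deletion effects
#'
#' Pooled-variance two-sample t-test (`df = n1 + n2 - 2`) with lower-tail
#' alternative: deletion reduces promoter activity. Significance stars
#' follow the 0.05 / 0.01 / 0.001 convention.
#'
#' @param wildtype,deleted Numeric vectors of relative activities across
#'   independent experiments (typically n = 3 each).
#' @return A `te_test_result` with an extra `stars` element.
#' @export
luciferase_deletion_test <- function(wildtype, deleted) {
  stopifnot(length(wildtype) >= 2, length(deleted) >= 2)
  tt <- stats::t.test(deleted, wildtype, var.equal = TRUE,
                      alternative = "less")
  res <- te_test_result(unname(tt$statistic), unname(tt$parameter),
                        "lower", tt$p.value,
                        "one-tailed equal-variance two-sample t-test")
  res$stars <- if (res$p_value < 0.001) "***"
  else if (res$p_value < 0.01) "**"
  else if (res$p_value < 0.05) "*"
  else ""
  res
}
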