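# TE-subfamily enrichment in ChIP-seq peaks.
#
# The null model is circular rotation: each chromosome's peak set is
# shifted by an independent uniform offset modulo the chromosome length
# (peaks wrapping past the end are split; split halves count as one
# peak). The expected per-subfamily overlap is the mean over rotations,
# and observed counts are tested against it with an upper-tail binomial
# test, Bonferroni-corrected over the full subfamily universe.

# Per-chromosome integer representation used by the permutation loop:
# peaks as 0-based starts/widths with original peak ids, TEs as IRanges
# with subfamily indices. Avoids GRanges construction inside the loop.
.rotation_state <- function(peaks, te, genome, universe) {
  chroms <- genome$chrom
  pk_chr <- as.character(GenomicRanges::seqnames(peaks))
  te_chr <- as.character(GenomicRanges::seqnames(te))
  sf_idx <- match(te$te_subfamily, universe)
  state <- lapply(seq_along(chroms), function(i) {
    ch <- chroms[i]
    pi <- which(pk_chr == ch)
    ti <- which(te_chr == ch)
    list(L = as.integer(genome$length[i]),
         p_start0 = GenomicRanges::start(peaks)[pi] - 1L,
         p_width = GenomicRanges::width(peaks)[pi],
         p_id = pi,
         te_ir = IRanges::IRanges(start = GenomicRanges::start(te)[ti],
                                  end = GenomicRanges::end(te)[ti]),
         te_sf = sf_idx[ti])
  })
  names(state) <- chroms
  state
}

# One rotation of one chromosome: returns per-(peak id, subfamily) hits.
.rotate_and_hit <- function(st, offset) {
  if (length(st$p_id) == 0L || length(st$te_sf) == 0L)
    return(list(id = integer(), sf = integer()))
  ns0 <- (st$p_start0 + offset) %% st$L
  ne0 <- ns0 + st$p_width
  wrap <- ne0 > st$L
  ir <- IRanges::IRanges(start = ns0 + 1L, end = pmin(ne0, st$L))
  id <- st$p_id
  if (any(wrap)) {
    ir <- c(ir, IRanges::IRanges(start = 1L, end = ne0[wrap] - st$L))
    id <- c(id, st$p_id[wrap])
  }
  hits <- IRanges::findOverlaps(ir, st$te_ir)
  list(id = id[S4Vectors::queryHits(hits)],
       sf = st$te_sf[S4Vectors::subjectHits(hits)])
}

# Distinct-peak count per subfamily from raw (id, sf) hit pairs.
.distinct_counts <- function(id, sf, n_universe) {
  if (length(id) == 0L)
    return(list(counts = integer(n_universe), n_any = 0L))
  key <- unique((id - 1) * n_universe + sf)
  list(counts = tabulate((key - 1) %% n_universe + 1, nbins = n_universe),
       n_any = length(unique(id)))
}

#' Count peaks overlapping each TE subfamily
#'
#' For every subfamily in the universe, the number of *distinct* peaks
#' overlapping at least one copy of that subfamily (a peak overlapping
#' several copies counts once per subfamily, but may count toward several
#' subfamilies). Overlap is strand-blind with a 1 bp minimum.
#'
#' @param peaks GRanges of ChIP-seq peaks.
#' @param te TE GRanges from [read_te_table()].
#' @param universe Character vector of subfamilies to report; defaults to
#'   all subfamilies present in `te` (including those with zero overlap).
#' @param peak_id Optional integer ids identifying peaks (used so that the
#'   two halves of a rotation-split peak count as one); defaults to the
#'   peak index.
#' @return A list with `counts` (named integer vector over `universe`) and
#'   `n_peaks_in_te` (distinct peaks overlapping any TE).
#' @export
count_subfamily_overlaps <- function(peaks, te, universe = NULL,
                                     peak_id = NULL) {
  if (is.null(universe)) universe <- sort(unique(te$te_subfamily))
  if (is.null(peak_id)) peak_id <- seq_along(peaks)
  hits <- GenomicRanges::findOverlaps(peaks, te, ignore.strand = TRUE)
  sf <- match(te$te_subfamily[S4Vectors::subjectHits(hits)], universe)
  keep <- !is.na(sf)
  res <- .distinct_counts(peak_id[S4Vectors::queryHits(hits)][keep],
                          sf[keep], length(universe))
  names(res$counts) <- universe
  list(counts = res$counts, n_peaks_in_te = res$n_any)
}

#' Circularly rotate peak locations
#'
#' Each chromosome's peaks are shifted by an independent uniform integer
#' offset in `[0, chromosome length)`, modulo the chromosome length. A
#' peak wrapping past the end is split into an end segment and a start
#' segment sharing one `peak_id`, so peak count (pre-split) and total
#' peak bp are conserved.
#'
#' @param peaks GRanges of peaks, all within chromosome bounds.
#' @param genome Genome table.
#' @param offsets Optional named integer vector of per-chromosome offsets
#'   (for deterministic enumeration); drawn uniformly when `NULL`.
#' @return A GRanges of rotated (possibly split) peaks with a `peak_id`
#'   metadata column indexing the original peaks.
#' @export
rotate_peaks <- function(peaks, genome, offsets = NULL) {
  universe <- "x"  # unused; reuse state builder with a dummy TE set
  st <- .rotation_state(peaks, GenomicRanges::GRanges(), genome, universe)
  if (is.null(offsets)) {
    offsets <- vapply(genome$length, function(L)
      floor(stats::runif(1) * L), 0)
    names(offsets) <- genome$chrom
  }
  out <- lapply(genome$chrom, function(ch) {
    s <- st[[ch]]
    if (length(s$p_id) == 0L) return(NULL)
    off <- offsets[[ch]]
    ns0 <- (s$p_start0 + off) %% s$L
    ne0 <- ns0 + s$p_width
    wrap <- ne0 > s$L
    data.frame(chrom = ch,
               start1 = c(ns0 + 1L, rep(1L, sum(wrap))),
               end1 = c(pmin(ne0, s$L), ne0[wrap] - s$L),
               id = c(s$p_id, s$p_id[wrap]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(GenomicRanges::GRanges(peak_id = integer()))
  GenomicRanges::GRanges(
    seqnames = out$chrom,
    ranges = IRanges::IRanges(start = out$start1, end = out$end1),
    strand = "*", peak_id = out$id)
}

#' Expected subfamily overlap under the rotation null
#'
#' Mean over `n_perm` independent circular rotations of the distinct-peak
#' overlap count for each subfamily.
#'
#' @inheritParams count_subfamily_overlaps
#' @param genome Genome table.
#' @param n_perm Number of rotations (default 10000, as for genome-scale
#'   analyses; reduce for small studies).
#' @param seed Optional integer seed; when given the RNG state is scoped
#'   to this call.
#' @return Named numeric vector of expected mean counts over `universe`.
#' @export
expected_overlap <- function(peaks, te, genome, n_perm = 10000,
                             universe = NULL, seed = NULL) {
  stopifnot(n_perm >= 1)
  if (is.null(universe)) universe <- sort(unique(te$te_subfamily))
  run <- function() {
    st <- .rotation_state(peaks, te, genome, universe)
    sums <- numeric(length(universe))
    for (p in seq_len(n_perm)) {
      ids <- vector("list", length(st))
      sfs <- vector("list", length(st))
      for (i in seq_along(st)) {
        off <- floor(stats::runif(1) * st[[i]]$L)
        h <- .rotate_and_hit(st[[i]], off)
        ids[[i]] <- h$id
        sfs[[i]] <- h$sf
      }
      d <- .distinct_counts(unlist(ids), unlist(sfs), length(universe))
      sums <- sums + d$counts
    }
    stats::setNames(sums / n_perm, universe)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Binomial enrichment test for TE subfamilies
#'
#' Given observed and rotation-expected overlap counts, tests each
#' subfamily for enrichment with an upper-tail binomial test:
#' `p0 = expected_mean / n_total` (floored at `1/(n_perm * n_total)` when
#' the rotation estimate is zero), `p = P(X >= observed)` for
#' `X ~ Binomial(n_total, p0)`, Bonferroni-adjusted over the subfamily
#' universe. The enrichment ratio is `observed / expected_mean`
#' (`Inf` when the expectation is zero but the observation is not).
#'
#' @param observed Integer vector of observed distinct-peak counts.
#' @param expected_mean Numeric vector of rotation-mean counts.
#' @param n_total Total number of peaks in the set.
#' @param n_subfamilies Bonferroni divisor: size of the subfamily
#'   universe tested.
#' @param n_perm Permutation count used for `expected_mean` (sets the
#'   zero-expectation floor).
#' @return data.frame with columns `observed`, `expected_mean`, `p0`,
#'   `p_value`, `p_adj`, `enrichment_ratio`.
#' @export
binomial_enrichment <- function(observed, expected_mean, n_total,
                                n_subfamilies, n_perm = 10000) {
  stopifnot(n_total > 0, n_subfamilies >= 1,
            length(observed) == length(expected_mean))
  if (any(observed > n_total))
    stop("observed count exceeds total peak number")
  if (any(observed < 0) || any(expected_mean < 0))
    stop("counts must be non-negative")
  p0 <- expected_mean / n_total
  p0[p0 == 0] <- 1 / (n_perm * n_total)
  p0 <- pmin(p0, 1)
  p_value <- stats::pbinom(observed - 1, n_total, p0, lower.tail = FALSE)
  er <- ifelse(expected_mean > 0, observed / expected_mean,
               ifelse(observed > 0, Inf, 0))
  data.frame(observed = observed, expected_mean = expected_mean, p0 = p0,
             p_value = p_value,
             p_adj = pmin(1, p_value * n_subfamilies),
             enrichment_ratio = er)
}

#' Bonferroni significance threshold
#'
#' The per-test p-value threshold controlling family-wise error at
#' `alpha` over `n_subfamilies` tests: `alpha / n_subfamilies`.
#'
#' @param n_subfamilies Number of subfamilies tested.
#' @param alpha Family-wise error rate (default 0.05).
#' @return The threshold, a single number.
#' @export
significance_threshold <- function(n_subfamilies, alpha = 0.05) {
  stopifnot(n_subfamilies >= 1, alpha > 0)
  alpha / n_subfamilies
}

#' Full TE-subfamily enrichment analysis of a peak set
#'
#' Observed counting, rotation permutation expectation, binomial testing
#' and Bonferroni correction in one call.
#'
#' @inheritParams expected_overlap
#' @param alpha Family-wise error rate for the `significant` flag.
#' @return data.frame with one row per subfamily in the universe:
#'   `subfamily`, `te_class`, `te_family`, `observed`, `expected_mean`,
#'   `p0`, `p_value`, `p_adj`, `enrichment_ratio`, `significant` (0/1).
#'   Attributes `n_perm`, `n_total`, `n_peaks_in_te`, `seed`, `threshold`
#'   record the run.
#' @export
te_enrichment <- function(peaks, te, genome, n_perm = 10000, alpha = 0.05,
                          seed = NULL) {
  universe <- sort(unique(te$te_subfamily))
  obs <- count_subfamily_overlaps(peaks, te, universe = universe)
  exp_mean <- expected_overlap(peaks, te, genome, n_perm = n_perm,
                               universe = universe, seed = seed)
  res <- binomial_enrichment(unname(obs$counts), unname(exp_mean),
                             n_total = length(peaks),
                             n_subfamilies = length(universe),
                             n_perm = n_perm)
  thr <- significance_threshold(length(universe), alpha)
  m <- match(universe, te$te_subfamily)
  out <- cbind(data.frame(subfamily = universe,
                          te_class = te$te_class[m],
                          te_family = te$te_family[m],
                          stringsAsFactors = FALSE),
               res,
               significant = as.integer(res$p_value < thr))
  attr(out, "n_perm") <- n_perm
  attr(out, "n_total") <- length(peaks)
  attr(out, "n_peaks_in_te") <- obs$n_peaks_in_te
  attr(out, "seed") <- seed
  attr(out, "threshold") <- thr
  out
}

#' Percentage of peaks in TEs, to one decimal place
#'
#' The accounting convention for per-TF summary tables: `100 * k / n`
#' rounded to one decimal place.
#'
#' @param k Number of peaks overlapping any TE.
#' @param n Total peak number (> 0, or the result is 0.0 when k = 0).
#' @return Percentage rounded to one decimal.
#' @export
percent_peaks_in_te <- function(k, n) {
  stopifnot(all(k >= 0), all(n > 0), all(k <= n))
  round(100 * k / n, 1)
}

#' Per-TF summary of peak/TE overlap
#'
#' One row per peak set: total peaks, distinct peaks overlapping any TE,
#' and the percentage to one decimal place.
#'
#' @param peak_sets A named list; each element is either a GRanges or a
#'   list with elements `peaks` (GRanges), `tf` and `source`.
#' @param te TE GRanges.
#' @return data.frame with columns `tf`, `source`, `n_total`,
#'   `n_in_te`, `pct_in_te`.
#' @export
peak_te_summary <- function(peak_sets, te) {
  rows <- lapply(seq_along(peak_sets), function(i) {
    ps <- peak_sets[[i]]
    if (methods::is(ps, "GRanges"))
      ps <- list(tf = names(peak_sets)[i], source = "", peaks = ps)
    k <- count_subfamily_overlaps(ps$peaks, te)$n_peaks_in_te
    n <- length(ps$peaks)
    data.frame(tf = ps$tf, source = ps$source, n_total = n, n_in_te = k,
               pct_in_te = percent_peaks_in_te(k, n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
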