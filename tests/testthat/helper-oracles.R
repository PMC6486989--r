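# Brute-force oracles, independent of the package's interval machinery.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# All-pairs overlap oracle on GRanges (1-based closed arithmetic).
oracle_pairs <- function(query, subject, strand_match = FALSE,
                         min_overlap = 1) {
  qs <- start(query); qe <- end(query)
  ss <- start(subject); se <- end(subject)
  qc <- as.character(seqnames(query)); sc <- as.character(seqnames(subject))
  qst <- as.character(strand(query)); sst <- as.character(strand(subject))
  rows <- list()
  for (i in seq_along(query)) {
    for (j in seq_along(subject)) {
      if (qc[i] != sc[j]) next
      ov <- min(qe[i], se[j]) - max(qs[i], ss[j]) + 1
      if (ov < min_overlap) next
      if (strand_match && qst[i] != "*" && sst[j] != "*" &&
          qst[i] != sst[j]) next
      rows[[length(rows) + 1]] <- c(i, j)
    }
  }
  if (length(rows) == 0)
    return(data.frame(query = integer(), subject = integer()))
  m <- do.call(rbind, rows)
  df <- data.frame(query = m[, 1], subject = m[, 2])
  df[order(df$query, df$subject), , drop = FALSE]
}

# Random stranded intervals on a genome table.
random_gr <- function(n, genome, max_width = 500, stranded = TRUE) {
  ci <- sample.int(nrow(genome), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  s0 <- floor(runif(n) * (genome$length[ci] - w))
  GRanges(seqnames = genome$chrom[ci],
          ranges = IRanges(start = s0 + 1, width = w),
          strand = if (stranded) sample(c("+", "-", "*"), n, replace = TRUE)
          else "*")
}

# Per-subfamily distinct-peak overlap counts, brute force.
oracle_subfamily_counts <- function(peaks, te, universe) {
  counts <- setNames(integer(length(universe)), universe)
  any_te <- 0L
  for (i in seq_along(peaks)) {
    hit_sf <- character()
    for (j in seq_along(te)) {
      if (as.character(seqnames(peaks))[i] != as.character(seqnames(te))[j])
        next
      if (min(end(peaks)[i], end(te)[j]) -
          max(start(peaks)[i], start(te)[j]) + 1 >= 1)
        hit_sf <- c(hit_sf, te$te_subfamily[j])
    }
    hit_sf <- unique(hit_sf)
    if (length(hit_sf) > 0) any_te <- any_te + 1L
    counts[hit_sf] <- counts[hit_sf] + 1L
  }
  list(counts = counts, n_peaks_in_te = any_te)
}

# Naive O(n^2) Nadaraya-Watson Epanechnikov smoother with NA handling.
oracle_smooth <- function(values, positions, bandwidth) {
  out <- numeric(length(values))
  for (i in seq_along(values)) {
    num <- 0; den <- 0
    for (j in seq_along(values)) {
      if (is.na(values[j])) next
      u <- abs(positions[i] - positions[j]) / bandwidth
      if (u > 1) next
      k <- 0.75 * (1 - u^2)
      num <- num + k * values[j]
      den <- den + k
    }
    out[i] <- if (den == 0) NA_real_ else num / den
  }
  out
}

# Per-bin tag counts for one anchor window, brute force (1 bp overlap).
oracle_bin_counts <- function(mid0, chrom, tags, flank = 5000,
                              binwidth = 50) {
  n_bins <- 2 * flank / binwidth
  counts <- integer(n_bins)
  ts0 <- start(tags) - 1; te0 <- end(tags)
  tc <- as.character(seqnames(tags))
  for (b in seq_len(n_bins)) {
    bs0 <- mid0 - flank + (b - 1) * binwidth
    be0 <- bs0 + binwidth
    counts[b] <- sum(tc == chrom & ts0 < be0 & te0 > bs0)
  }
  counts
}

# Per-base consensus liftover oracle for one copy (linear map).
oracle_lift <- function(c1, c2, copy) {
  s0 <- start(copy) - 1; e0 <- end(copy)
  rs <- copy$rep_start; re <- copy$rep_end
  st <- as.character(strand(copy))
  glen <- e0 - s0; clen <- re - rs + 1
  g <- integer(0)
  for (g0 in s0:(e0 - 1)) {
    cpos <- if (st == "-") rs + floor((e0 - 1 - g0) * clen / glen)
    else rs + floor((g0 - s0) * clen / glen)
    if (cpos >= c1 && cpos <= c2) g <- c(g, g0)
  }
  if (length(g) == 0) return(NULL)
  c(min(g), max(g))  # 0-based base positions
}

small_genome <- function(n_chrom = 2, len = 100000) {
  genome_table(paste0("chr", seq_len(n_chrom)), rep(len, n_chrom))
}

# Small fast simulation config for unit tests.
tiny_config <- function(...) {
  cat_df <- default_subfamily_catalogue()
  cat_df$n_copies <- pmax(10, round(cat_df$n_copies / 10))
  defaults <- list(n_chrom = 2, chrom_length = 5e5, subfamilies = cat_df,
                   n_peaks = 300, tag_background_rate = 0.005,
                   n_genes = 10, n_probes = 40, n_intron_probes = 4,
                   n_planted_promoters = 5, n_decoys_per_class = 4)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
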