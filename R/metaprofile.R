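# Epigenetic metaprofiles around TE copies.
#
# A 10 kb window centred on each TE copy (element midpoint) is divided
# into 200 bins of 50 bp. Tag counts per bin (>= 1 bp overlap, so one tag
# can increment adjacent bins) are converted to RPKM, averaged across
# replicates, control-subtracted per anchor, averaged across anchors, and
# smoothed with an Epanechnikov-kernel Nadaraya-Watson smoother. Bins
# clipped at chromosome bounds are missing and excluded from anchor means.

#' Construct a tag track
#'
#' A labelled set of aligned-read intervals plus the library size used
#' for per-million scaling (which may exceed the number of tags present
#' if the file is a subset).
#'
#' @param tags GRanges of aligned read spans (optionally with a `score`
#'   metadata column carrying mapping quality).
#' @param label Track label (mark + replicate, or control).
#' @param total_mapped Total mapped reads for RPKM scaling (> 0); defaults
#'   to the number of tags.
#' @return An object of class `tag_track`.
#' @export
tag_track <- function(tags, label = "track", total_mapped = length(tags)) {
  if (is.na(total_mapped) || total_mapped <= 0)
    stop("total_mapped must be positive")
  structure(list(tags = tags, label = label,
                 total_mapped = as.numeric(total_mapped)),
            class = "tag_track")
}

#' Read a tag track from BED
#'
#' @param path BED file of aligned read spans.
#' @param label Track label.
#' @param total_mapped Library size; defaults to the number of records.
#' @param genome Optional genome table.
#' @return A `tag_track`.
#' @export
read_tag_track <- function(path, label = basename(path),
                           total_mapped = NULL, genome = NULL) {
  tags <- read_bed(path, genome = genome)
  tag_track(tags, label = label,
            total_mapped = if (is.null(total_mapped)) length(tags)
            else total_mapped)
}

#' Filter a tag track by mapping quality
#'
#' Removes tags whose BED score (mapping quality) is below `min_quality`
#' and recomputes `total_mapped` as the retained count, so RPKM scaling
#' refers to the filtered library.
#'
#' @param track A `tag_track` whose tags carry a `score` column.
#' @param min_quality Minimum quality to retain (0 keeps everything).
#' @return The filtered `tag_track`.
#' @export
filter_by_mapq <- function(track, min_quality) {
  stopifnot(inherits(track, "tag_track"))
  if (min_quality > 0) {
    q <- track$tags$score
    if (is.null(q)) stop("track tags carry no quality scores")
    q[is.na(q)] <- 0
    track$tags <- track$tags[q >= min_quality]
  }
  n <- length(track$tags)
  if (n == 0) {
    track$total_mapped <- 1  # empty track: avoid division by zero; all bins 0
    attr(track, "empty") <- TRUE
  } else track$total_mapped <- n
  track
}

#' Split a subfamily's copies by TF binding
#'
#' Partitions the copies of one subfamily into those overlapping at least
#' one peak (bound) and the rest (unbound); strand-blind 1 bp overlap.
#'
#' @param te TE GRanges.
#' @param subfamily Subfamily name to stratify.
#' @param peaks GRanges of TFBS peaks.
#' @return A list with GRanges elements `bound` and `unbound`.
#' @export
stratify_by_binding <- function(te, subfamily, peaks) {
  sel <- te[te$te_subfamily == subfamily]
  hit <- IRanges::overlapsAny(sel, peaks, ignore.strand = TRUE)
  list(bound = sel[hit], unbound = sel[!hit])
}

#' @noRd
.bin_offsets <- function(flank = 5000, binwidth = 50) {
  n_bins <- 2 * flank / binwidth
  seq_len(n_bins) * binwidth - binwidth / 2 - flank  # bin centres vs midpoint
}

#' Binned RPKM coverage around anchors
#'
#' For each anchor (TE copy), a window of `2 * flank` bp centred on the
#' element midpoint is split into `binwidth`-bp bins; tags overlapping a
#' bin by >= 1 bp are counted and converted to
#' `RPKM = count * 1e9 / (binwidth * total_mapped)`. Bins extending past
#' chromosome bounds are `NA`.
#'
#' @param anchors GRanges of TE copies (or any anchors).
#' @param track A `tag_track`.
#' @param genome Genome table (for bounds clipping).
#' @param flank Half-window in bp (default 5000).
#' @param binwidth Bin width in bp (default 50).
#' @return Numeric matrix, anchors x bins; column names are bin-centre
#'   offsets relative to the anchor midpoint.
#' @export
binned_rpkm <- function(anchors, track, genome, flank = 5000, binwidth = 50) {
  stopifnot(inherits(track, "tag_track"))
  n_bins <- as.integer(2 * flank / binwidth)
  n_a <- length(anchors)
  mid0 <- floor((GenomicRanges::start(anchors) - 1 +
                   GenomicRanges::end(anchors)) / 2)
  chr <- as.character(GenomicRanges::seqnames(anchors))
  L <- genome$length[match(chr, genome$chrom)]
  a_idx <- rep(seq_len(n_a), each = n_bins)
  b_idx <- rep(seq_len(n_bins), times = n_a)
  bs0 <- mid0[a_idx] - flank + (b_idx - 1) * binwidth
  be0 <- bs0 + binwidth
  ok <- bs0 >= 0 & be0 <= L[a_idx]
  mat <- matrix(NA_real_, n_a, n_bins,
                dimnames = list(anchors$name, .bin_offsets(flank, binwidth)))
  if (any(ok)) {
    bins <- GenomicRanges::GRanges(
      seqnames = chr[a_idx][ok],
      ranges = IRanges::IRanges(start = bs0[ok] + 1, end = be0[ok]))
    counts <- GenomicRanges::countOverlaps(bins, track$tags,
                                           ignore.strand = TRUE)
    mat[cbind(a_idx[ok], b_idx[ok])] <-
      counts * 1e9 / (binwidth * track$total_mapped)
  }
  mat
}

#' Replicate-averaged, control-subtracted profile
#'
#' Fixed order of operations: per anchor and bin, RPKM is averaged across
#' replicate tracks, then the mean control RPKM (pooled across control
#' tracks) is subtracted, then values are averaged across anchors.
#' Missing (clipped) bins are excluded from the anchor mean, with the
#' per-bin effective n reported.
#'
#' @param anchors GRanges of TE copies.
#' @param replicate_tracks List of `tag_track`s for the mark.
#' @param control_tracks Optional list of control `tag_track`s (`NULL`
#'   for no subtraction).
#' @inheritParams binned_rpkm
#' @return data.frame with columns `offset` (bin centre relative to the
#'   anchor midpoint), `mean` (across anchors) and `n` (anchors
#'   contributing to each bin).
#' @export
aggregate_profile <- function(anchors, replicate_tracks,
                              control_tracks = NULL, genome,
                              flank = 5000, binwidth = 50) {
  if (length(anchors) == 0) stop("no anchors to profile")
  if (inherits(replicate_tracks, "tag_track"))
    replicate_tracks <- list(replicate_tracks)
  if (inherits(control_tracks, "tag_track"))
    control_tracks <- list(control_tracks)
  mean_mats <- function(tracks) {
    mats <- lapply(tracks, function(tr)
      binned_rpkm(anchors, tr, genome, flank, binwidth))
    Reduce(`+`, mats) / length(mats)
  }
  m <- mean_mats(replicate_tracks)
  if (!is.null(control_tracks) && length(control_tracks) > 0)
    m <- m - mean_mats(control_tracks)
  data.frame(offset = .bin_offsets(flank, binwidth),
             mean = colMeans(m, na.rm = TRUE),
             n = colSums(!is.na(m)),
             row.names = NULL)
}

#' Epanechnikov-kernel smoothing of a profile curve
#'
#' Nadaraya-Watson smoothing of per-bin values at their bin-centre
#' positions with the kernel `K(u) = 0.75 (1 - u^2)` for `|u| <= 1`,
#' `u = distance / bandwidth`. A constant curve is returned unchanged;
#' `NA` values are excluded from the local weighted averages.
#'
#' @param values Numeric vector of bin values.
#' @param positions Bin-centre positions in bp; defaults to a regular
#'   50 bp grid.
#' @param bandwidth Kernel bandwidth in bp (default 150, i.e. three bins
#'   on a 50 bp grid).
#' @return Smoothed numeric vector, same length as `values`.
#' @export
smooth_profile <- function(values, positions = NULL, bandwidth = 150) {
  n <- length(values)
  if (is.null(positions)) positions <- (seq_len(n) - 1) * 50
  stopifnot(length(positions) == n, bandwidth > 0)
  u <- abs(outer(positions, positions, `-`)) / bandwidth
  w <- ifelse(u <= 1, 0.75 * (1 - u^2), 0)
  ok <- !is.na(values)
  v <- ifelse(ok, values, 0)
  num <- w[, ok, drop = FALSE] %*% v[ok]
  den <- rowSums(w[, ok, drop = FALSE])
  out <- as.numeric(num) / den
  out[den == 0] <- NA_real_
  out
}

#' Bound vs unbound metaprofile for one subfamily
#'
#' The full per-subfamily profiling workflow: stratify copies by TF
#' binding, compute replicate-averaged control-subtracted profiles for
#' both groups, and smooth them.
#'
#' @param te TE GRanges.
#' @param subfamily Subfamily to profile.
#' @param peaks TFBS peaks used for stratification.
#' @param mark_tracks List of replicate `tag_track`s for the histone mark.
#' @param control_tracks Optional list of control `tag_track`s.
#' @inheritParams aggregate_profile
#' @param bandwidth Smoothing bandwidth in bp.
#' @return data.frame with columns `bin_centre_offset`, `bound_mean`,
#'   `bound_smoothed`, `bound_n`, `unbound_mean`, `unbound_smoothed`,
#'   `unbound_n`.
#' @export
profile_curves <- function(te, subfamily, peaks, mark_tracks,
                           control_tracks = NULL, genome,
                           flank = 5000, binwidth = 50, bandwidth = 150) {
  groups <- stratify_by_binding(te, subfamily, peaks)
  prof <- lapply(groups, function(g)
    aggregate_profile(g, mark_tracks, control_tracks, genome,
                      flank, binwidth))
  data.frame(
    bin_centre_offset = prof$bound$offset,
    bound_mean = prof$bound$mean,
    bound_smoothed = smooth_profile(prof$bound$mean, prof$bound$offset,
                                    bandwidth),
    bound_n = prof$bound$n,
    unbound_mean = prof$unbound$mean,
    unbound_smoothed = smooth_profile(prof$unbound$mean,
                                      prof$unbound$offset, bandwidth),
    unbound_n = prof$unbound$n)
}

#' Consensus-coordinate truncation profile
#'
#' For a group of copies of one subfamily, the fraction of copies whose
#' consensus alignment (`rep_start..rep_end`, 1-based inclusive) covers
#' each consensus position: a vector of length `consensus_length` with
#' values in [0, 1].
#'
#' @param te_group GRanges of copies from a single subfamily (all sharing
#'   one `consensus_length`).
#' @return Numeric vector of per-position coverage fractions.
#' @export
truncation_profile <- function(te_group) {
  if (length(te_group) == 0) stop("empty TE group")
  cl <- unique(te_group$consensus_length)
  if (length(cl) != 1)
    stop("copies span multiple consensus lengths; supply one subfamily")
  cov <- IRanges::coverage(
    IRanges::IRanges(start = te_group$rep_start, end = te_group$rep_end),
    width = cl)
  as.numeric(cov) / length(te_group)
}
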