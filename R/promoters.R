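# Hierarchical discovery of TE-derived promoters.
#
# Probe annotation assigns each probe to all matching transcripts from
# the highest-priority tier (mRNA > lncRNA tier 1 > lncRNA tier 2) with
# strand-matched exon-aware overlap. Promoter discovery chains:
# CAGE clusters near a TFBS (300 bp window) -> overlapping a TE copy ->
# fully inside a strand-matched promoter (TSS +/- 1 kb) of an annotated
# transcript, emitting candidates plus the stage-count funnel.

#' Annotate probes with transcripts by priority tier
#'
#' Each probe is annotated with all transcripts it overlaps (strand-
#' matched, exon-aware) from the highest-priority tier that yields at
#' least one hit; lower tiers are not consulted for that probe. Probes
#' matching no tier are dropped and counted.
#'
#' @param probes GRanges of aligned probes (stranded; `name` column used
#'   as probe id when present).
#' @param tiers Ordered named list of transcript GRanges (each with
#'   `blocks`, `transcript_id`, `gene_id` metadata), highest priority
#'   first, e.g. `list(mRNA = ..., lncRNA_tier1 = ..., lncRNA_tier2 = ...)`.
#' @return data.frame with one row per (probe, transcript) annotation:
#'   `probe`, `tier`, `transcript_id`, `gene_id`. Attributes `n_dropped`
#'   (unannotatable probes) and `tier_counts` (probes per tier).
#' @export
annotate_probes <- function(probes, tiers) {
  stopifnot(length(tiers) >= 1, !is.null(names(tiers)))
  probe_id <- if (!is.null(probes$name)) probes$name
  else as.character(seq_along(probes))
  unassigned <- rep(TRUE, length(probes))
  rows <- list()
  for (tier_name in names(tiers)) {
    tx <- tiers[[tier_name]]
    if (length(tx) == 0 || !any(unassigned)) next
    idx <- which(unassigned)
    pr <- split_pairs(probes[idx], tx, strand_match = TRUE)
    if (nrow(pr) == 0) next
    rows[[tier_name]] <- data.frame(
      probe = probe_id[idx[pr$query]],
      tier = tier_name,
      transcript_id = tx$transcript_id[pr$subject],
      gene_id = tx$gene_id[pr$subject],
      stringsAsFactors = FALSE)
    unassigned[idx[unique(pr$query)]] <- FALSE
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(probe = character(), tier = character(),
               transcript_id = character(), gene_id = character())
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(unassigned)
  attr(out, "tier_counts") <- vapply(names(tiers), function(tn)
    length(unique(out$probe[out$tier == tn])), 0L)
  out
}

#' Promoter regions of transcripts
#'
#' The promoter of a transcript is the `2 * half_width` bp region around
#' its 5' end: for a plus-strand transcript the TSS is the transcript
#' start, for minus strand the transcript end. `mode = "centered"` places
#' the region symmetrically around the TSS; `mode = "upstream"` anchors
#' the full `2 * half_width` upstream of it. Regions are clipped at
#' chromosome bounds and inherit the transcript strand.
#'
#' @param transcripts Stranded GRanges of transcripts (strand `+`/`-`).
#' @param half_width Half-width in bp (default 1000, i.e. a 2 kb region).
#' @param genome Optional genome table for clipping.
#' @param mode `"centered"` (default) or `"upstream"`.
#' @return GRanges of promoter regions, parallel to `transcripts`.
#' @export
promoter_region <- function(transcripts, half_width = 1000, genome = NULL,
                            mode = c("centered", "upstream")) {
  mode <- match.arg(mode)
  s <- as.character(GenomicRanges::strand(transcripts))
  if (any(!s %in% c("+", "-")))
    stop("transcripts must be stranded (+/-)")
  # 0-based TSS position: start-1 for +, end for - (half-open sense)
  tss0 <- ifelse(s == "+", GenomicRanges::start(transcripts) - 1,
                 GenomicRanges::end(transcripts))
  if (mode == "centered") {
    p_start0 <- tss0 - half_width
    p_end0 <- tss0 + half_width
  } else {
    p_start0 <- ifelse(s == "+", tss0 - 2 * half_width, tss0)
    p_end0 <- ifelse(s == "+", tss0, tss0 + 2 * half_width)
  }
  p_start0 <- pmax(0, p_start0)
  if (!is.null(genome)) {
    L <- genome$length[match(as.character(GenomicRanges::seqnames(transcripts)),
                             genome$chrom)]
    p_end0 <- pmin(p_end0, L)
  }
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(transcripts),
    ranges = IRanges::IRanges(start = p_start0 + 1, end = p_end0),
    strand = s)
  GenomicRanges::mcols(out) <- GenomicRanges::mcols(transcripts)[
    intersect(c("transcript_id", "gene_id", "tier"),
              names(GenomicRanges::mcols(transcripts)))]
  out
}

#' Discover TE-derived promoter candidates
#'
#' The hierarchical filtering pipeline, in fixed order: (1) keep CAGE
#' clusters within `window` bp of at least one TFBS peak (any TF, pooled;
#' TF names recorded); (2) of those, keep clusters overlapping at least
#' one TE copy; (3) of those, keep clusters lying fully inside a
#' strand-matched promoter region of an annotated transcript. One
#' candidate row is emitted per (cluster, transcript, TE, TF)
#' combination; the funnel records cluster counts surviving each stage
#' and the genes/transcripts represented.
#'
#' @param cage Stranded GRanges of CAGE clusters (`name` = cluster id).
#' @param peak_sets Named list of TFBS peak GRanges, names are TF labels
#'   (a single GRanges is accepted and labelled `"TF"`).
#' @param te TE GRanges.
#' @param transcripts Stranded GRanges of candidate-gene transcripts with
#'   `transcript_id` and `gene_id` metadata.
#' @param genome Optional genome table (promoter clipping).
#' @param window TFBS proximity window in bp (default 300).
#' @param half_width Promoter half-width in bp (default 1000).
#' @param mode Promoter placement mode, see [promoter_region()].
#' @param allow_genes Optional character vector restricting candidates to
#'   these gene ids (the literature-curation allow-list).
#' @return A list with `candidates` (data.frame: `gene_id`,
#'   `transcript_id`, `cage_id`, `te_name`, `te_subfamily`, `te_coords`,
#'   `tf`, `promoter_coords`) and `funnel` (data.frame: `stage`, `n`).
#' @export
discover_te_promoters <- function(cage, peak_sets, te, transcripts,
                                  genome = NULL, window = 300,
                                  half_width = 1000,
                                  mode = c("centered", "upstream"),
                                  allow_genes = NULL) {
  mode <- match.arg(mode)
  if (length(cage) == 0) stop("empty CAGE input")
  if (methods::is(peak_sets, "GRanges")) peak_sets <- list(TF = peak_sets)
  cage_id <- if (!is.null(cage$name)) cage$name
  else as.character(seq_along(cage))

  pooled <- do.call(c, lapply(unname(peak_sets), function(g) {
    GenomicRanges::mcols(g) <- NULL
    g
  }))
  tf_of_peak <- rep(names(peak_sets), vapply(peak_sets, length, 0L))

  # stage 1: CAGE near a TFBS (strand-blind window)
  p1 <- window_pairs(cage, pooled, w = window, genome = genome)
  s1 <- sort(unique(p1$query))
  # stage 2: of those, overlap a TE copy (strand-blind)
  p2 <- interval_pairs(cage[s1], te)
  s2 <- s1[sort(unique(p2$query))]
  # stage 3: fully inside a strand-matched promoter
  prom <- promoter_region(transcripts, half_width = half_width,
                          genome = genome, mode = mode)
  h3 <- GenomicRanges::findOverlaps(cage[s2], prom, type = "within",
                                    ignore.strand = FALSE)
  s3 <- s2[sort(unique(S4Vectors::queryHits(h3)))]

  # assemble per-(cluster, transcript, TE, TF) candidate rows
  tf_by_cage <- split(tf_of_peak[p1$subject], p1$query)
  te_by_cage <- split(p2$subject, s1[p2$query])
  rows <- lapply(seq_along(s3), function(k) {
    ci <- s3[k]
    tx <- S4Vectors::subjectHits(h3)[S4Vectors::queryHits(h3) ==
                                       match(ci, s2)]
    tes <- te_by_cage[[as.character(ci)]]
    tfs <- sort(unique(tf_by_cage[[as.character(ci)]]))
    g <- expand.grid(tx = tx, te = tes, tf = tfs,
                     stringsAsFactors = FALSE)
    data.frame(
      gene_id = prom$gene_id[g$tx],
      transcript_id = prom$transcript_id[g$tx],
      cage_id = cage_id[ci],
      te_name = te$name[g$te],
      te_subfamily = te$te_subfamily[g$te],
      te_coords = sprintf("%s:%d-%d",
                          as.character(GenomicRanges::seqnames(te))[g$te],
                          GenomicRanges::start(te)[g$te] - 1,
                          GenomicRanges::end(te)[g$te]),
      tf = g$tf,
      promoter_coords = sprintf("%s:%d-%d",
                                as.character(GenomicRanges::seqnames(prom))[g$tx],
                                GenomicRanges::start(prom)[g$tx] - 1,
                                GenomicRanges::end(prom)[g$tx]),
      stringsAsFactors = FALSE)
  })
  candidates <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(gene_id = character(), transcript_id = character(),
               cage_id = character(), te_name = character(),
               te_subfamily = character(), te_coords = character(),
               tf = character(), promoter_coords = character())
  if (!is.null(allow_genes))
    candidates <- candidates[candidates$gene_id %in% allow_genes, ,
                             drop = FALSE]
  rownames(candidates) <- NULL
  funnel <- data.frame(
    stage = c("cage_clusters", "near_tfbs", "in_te", "in_promoter",
              "genes", "transcripts"),
    n = c(length(cage), length(s1), length(s2), length(s3),
          length(unique(candidates$gene_id)),
          length(unique(candidates$transcript_id))))
  list(candidates = candidates, funnel = funnel)
}

#' Stage-count funnel of a discovery run
#'
#' Convenience accessor returning the funnel table of
#' [discover_te_promoters()] output; stage counts are non-increasing
#' along the cluster stages.
#'
#' @param discovery The list returned by [discover_te_promoters()].
#' @return The `funnel` data.frame.
#' @export
funnel_report <- function(discovery) discovery$funnel
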