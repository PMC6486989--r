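# Seeded synthetic-data generator.
#
# Emulates every input the pipeline consumes — a multi-chromosome genome
# tiled with non-overlapping TE copies from a named subfamily catalogue,
# ChIP-seq peaks with configurable planted subfamily enrichment, Poisson
# tag tracks with elevated coverage around bound copies, a transcriptome
# with tiered transcripts / CAGE clusters / probes including planted
# TE-derived promoter positives and single-violation decoys, paired
# tumour/normal count tables and luciferase plates — with ground truth
# recorded for every planted feature. Fully deterministic under a seed.

#' Default TE subfamily catalogue
#'
#' Thirty subfamilies spanning the four major TE classes (LINE, SINE,
#' LTR, DNA) with field-typical consensus lengths, copy numbers scaled so
#' the default genome carries ~5000 copies at ~40% TE density, and a
#' probability of a copy being full length (the rest are truncated).
#'
#' @return data.frame with columns `subfamily`, `family`, `class`,
#'   `consensus_length`, `n_copies`, `p_full`.
#' @export
default_subfamily_catalogue <- function() {
  df <- rbind(
    data.frame(subfamily = c("L1PA2", "L1PA3", "L1MB7", "L1HS"),
               family = "L1", class = "LINE",
               consensus_length = c(6000, 6000, 5000, 6000), n_copies = 50),
    data.frame(subfamily = c("L2a", "L2b", "L2c"),
               family = "L2", class = "LINE",
               consensus_length = 3300, n_copies = 150),
    data.frame(subfamily = c("AluJb", "AluSx", "AluY", "AluSq"),
               family = "Alu", class = "SINE",
               consensus_length = 300, n_copies = c(300, 300, 250, 250)),
    data.frame(subfamily = c("MIRb", "MIR3", "MIR", "MIRc"),
               family = "MIR", class = "SINE",
               consensus_length = c(270, 260, 260, 270),
               n_copies = c(450, 250, 250, 250)),
    data.frame(subfamily = c("LTR7C", "LTR12C", "MER41B"),
               family = "ERV1", class = "LTR",
               consensus_length = c(450, 1600, 600), n_copies = 110),
    data.frame(subfamily = c("LTR16A", "MLT2B4"),
               family = "ERVL", class = "LTR",
               consensus_length = c(450, 500), n_copies = 110),
    data.frame(subfamily = c("MLT1A", "THE1B"),
               family = "ERVL-MaLR", class = "LTR",
               consensus_length = c(380, 350), n_copies = 110),
    data.frame(subfamily = "LTR5_Hs", family = "ERVK", class = "LTR",
               consensus_length = 1000, n_copies = 110),
    data.frame(subfamily = c("MER20", "Charlie1a", "MER136"),
               family = "hAT-Charlie", class = "DNA",
               consensus_length = c(220, 2700, 200), n_copies = 130),
    data.frame(subfamily = c("Tigger1", "MER44A"),
               family = "TcMar-Tigger", class = "DNA",
               consensus_length = c(2400, 1300), n_copies = 130),
    data.frame(subfamily = "MER30", family = "hAT-Tip100", class = "DNA",
               consensus_length = 250, n_copies = 130),
    data.frame(subfamily = "MER81", family = "hAT-Blackjack",
               class = "DNA", consensus_length = 120, n_copies = 130))
  df$p_full <- 0.3
  rownames(df) <- NULL
  df
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator with defaults
#' sized for stable permutation estimates at minutes-scale runtimes:
#' 4 chromosomes of 2 Mb, ~5000 TE copies over 30 subfamilies, 2000
#' ChIP-seq peaks.
#'
#' @param n_chrom,chrom_length Chromosome count and common length (bp).
#' @param subfamilies Subfamily catalogue data.frame
#'   ([default_subfamily_catalogue()]).
#' @param planted_enrichment Named numeric vector: subfamily -> fold over
#'   the background peak-overlap probability (empty = no planted signal).
#' @param n_peaks Number of ChIP-seq peaks per set.
#' @param peak_width Integer range (min, max) of peak widths.
#' @param tag_background_rate Background tag rate per bp per track.
#' @param tag_length Tag (read span) length in bp.
#' @param tag_fold Coverage fold within bound-copy windows for active
#'   marks.
#' @param tag_halfwidth Half-width (bp) of the elevated window around a
#'   bound copy midpoint.
#' @param n_replicates Replicate tracks per mark.
#' @param n_genes Background gene count for the transcriptome.
#' @param tier_props Proportions of transcripts in tiers mRNA /
#'   lncRNA_tier1 / lncRNA_tier2.
#' @param n_probes Number of exonic probes; `n_intron_probes` additional
#'   intron-only probes (unannotatable by construction).
#' @param n_intron_probes See `n_probes`.
#' @param n_planted_promoters Planted promoter positives.
#' @param n_decoys_per_class Decoys per violation class (window / te /
#'   promoter / strand).
#' @param cage_width CAGE cluster width (bp).
#' @param tfbs_window TFBS proximity window (bp) the positives satisfy.
#' @param promoter_halfwidth Promoter half-width (bp).
#' @param methylation List: `n_pairs`, `delta` (tumour - normal mean
#'   difference of normalised levels), `sd` (per-pair difference SD),
#'   `baseline` (normal-sample mean level), `depth` (subfamily read
#'   depth, sets rounding granularity).
#' @param dnase List: `p_base` (HMEC candidate/subfamily proportion),
#'   `ratio` (MCF7 fold), `depth` (subfamily counts per cell line).
#' @param luciferase List: `effects` (named relative activity per
#'   construct), `cv` (lognormal well noise), `n_experiments`,
#'   `base_renilla`, `base_ratio`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 4,
                       chrom_length = 2e6,
                       subfamilies = default_subfamily_catalogue(),
                       planted_enrichment = numeric(),
                       n_peaks = 2000,
                       peak_width = c(150L, 400L),
                       tag_background_rate = 0.02,
                       tag_length = 50L,
                       tag_fold = 5,
                       tag_halfwidth = 500L,
                       n_replicates = 2L,
                       n_genes = 60L,
                       tier_props = c(mRNA = 0.7, lncRNA_tier1 = 0.15,
                                      lncRNA_tier2 = 0.15),
                       n_probes = 120L,
                       n_intron_probes = 10L,
                       n_planted_promoters = 20L,
                       n_decoys_per_class = 50L,
                       cage_width = 20L,
                       tfbs_window = 300L,
                       promoter_halfwidth = 1000L,
                       methylation = list(n_pairs = 6L, delta = -0.2,
                                          sd = 0.15, baseline = 0.5,
                                          depth = 2e5),
                       dnase = list(p_base = 0.01, ratio = 2,
                                    depth = 2e4),
                       luciferase = list(
                         effects = c(wild_type = 1, te_deleted = 0.3,
                                     positive_control = 1),
                         cv = 0.1, n_experiments = 3L,
                         base_renilla = 2e4, base_ratio = 5)) {
  stopifnot(n_chrom >= 1, chrom_length > 0,
            all(planted_enrichment >= 0),
            all(tier_props >= 0), abs(sum(tier_props) - 1) < 1e-8)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

.with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

#' Simulate a genome tiled with TE copies
#'
#' Chromosomes of the configured lengths are populated with
#' non-overlapping TE copies placed uniformly (random gaps), with
#' truncation draws setting `rep_start`/`rep_end` on each subfamily
#' consensus; the genomic width of a copy equals its consensus span, so
#' consensus liftovers are exact.
#'
#' @param config A `sim_config`.
#' @param seed Optional integer seed (RNG state scoped to the call).
#' @return List with `genome` (genome table) and `te` (TE GRanges).
#' @export
simulate_genome <- function(config, seed = NULL) {
  .with_seed_maybe(seed, {
    cat_df <- config$subfamilies
    genome <- genome_table(paste0("chr", seq_len(config$n_chrom)),
                           rep(config$chrom_length, config$n_chrom))
    n <- sum(cat_df$n_copies)
    if (n == 0) {
      te <- GenomicRanges::GRanges(
        te_class = character(), te_family = character(),
        te_subfamily = character(), rep_start = integer(),
        rep_end = integer(), consensus_length = integer(),
        name = character())
      return(list(genome = genome, te = te))
    }
    sf_idx <- rep(seq_len(nrow(cat_df)), cat_df$n_copies)
    cl <- cat_df$consensus_length[sf_idx]
    full <- stats::runif(n) < cat_df$p_full[sf_idx]
    len <- ifelse(full, cl, pmax(30, round(stats::runif(n, 0.25, 1) * cl)))
    len <- pmin(len, cl)
    rs <- ifelse(full, 1L,
                 1L + floor(stats::runif(n) * (cl - len + 1)))
    re <- rs + len - 1
    chrom_i <- sample.int(config$n_chrom, n, replace = TRUE,
                          prob = genome$length)
    pieces <- lapply(seq_len(config$n_chrom), function(ci) {
      sel <- which(chrom_i == ci)
      if (length(sel) == 0) return(NULL)
      sel <- sel[sample.int(length(sel))]
      w <- len[sel]
      L <- genome$length[ci]
      free <- L - sum(w)
      if (free < 0)
        stop("TE catalogue too dense for chromosome length")
      m <- length(sel)
      gaps <- diff(c(0, sort(stats::runif(m)), 1)) * free
      starts0 <- floor(cumsum(gaps[seq_len(m)]) +
                         c(0, cumsum(w))[seq_len(m)])
      data.frame(idx = sel, chrom = genome$chrom[ci],
                 start0 = starts0, end0 = starts0 + w)
    })
    placed <- do.call(rbind, pieces)
    placed <- placed[order(match(placed$chrom, genome$chrom),
                           placed$start0), ]
    i <- placed$idx
    te <- GenomicRanges::GRanges(
      seqnames = placed$chrom,
      ranges = IRanges::IRanges(start = placed$start0 + 1,
                                end = placed$end0),
      strand = sample(c("+", "-"), nrow(placed), replace = TRUE),
      te_class = cat_df$class[sf_idx[i]],
      te_family = cat_df$family[sf_idx[i]],
      te_subfamily = cat_df$subfamily[sf_idx[i]],
      rep_start = as.integer(rs[i]), rep_end = as.integer(re[i]),
      consensus_length = as.integer(cl[i]),
      name = sprintf("te_%05d", seq_len(nrow(placed))))
    te <- .set_seqinfo(te, genome)
    list(genome = genome, te = te)
  })
}

#' Simulate a ChIP-seq peak set with planted subfamily enrichment
#'
#' Each peak is either planted on a random copy of a configured
#' subfamily (with extra probability `(fold - 1) * subfamily bp fraction`,
#' so total overlap probability is about `fold` times background) or
#' placed uniformly on the genome.
#'
#' @param config A `sim_config`.
#' @param te TE GRanges from [simulate_genome()].
#' @param genome Genome table.
#' @param seed Optional seed.
#' @return List with `peaks` (GRanges, `name` column) and `truth`
#'   (data.frame `peak`, `planted_subfamily` with `NA` for background).
#' @export
simulate_peaks <- function(config, te, genome, seed = NULL) {
  .with_seed_maybe(seed, {
    n <- config$n_peaks
    if (n == 0) {
      return(list(peaks = GenomicRanges::GRanges(name = character()),
                  truth = data.frame(peak = character(),
                                     planted_subfamily = character())))
    }
    G <- sum(genome$length)
    w <- sample(seq(config$peak_width[1], config$peak_width[2]), n,
                replace = TRUE)
    folds <- config$planted_enrichment
    folds <- folds[folds > 1]
    # background overlap probability of a random peak with subfamily sf:
    # a peak of width w overlaps a copy of length len from (len + w - 1)
    # start positions, so p_bg = sum(len_c + w_mean - 1) / G
    w_mean <- mean(config$peak_width)
    p_extra <- vapply(names(folds), function(sf) {
      lens <- GenomicRanges::width(te)[te$te_subfamily == sf]
      (folds[[sf]] - 1) * sum(lens + w_mean - 1) / G
    }, 0)
    if (sum(p_extra) >= 1) stop("planted enrichment folds too large")
    cat_lab <- c(names(folds), ".bg")
    category <- if (length(p_extra) > 0)
      sample(cat_lab, n, replace = TRUE, prob = c(p_extra, 1 - sum(p_extra)))
    else rep(".bg", n)
    chrom <- character(n); start0 <- numeric(n)
    bg <- category == ".bg"
    if (any(bg)) {
      ci <- sample.int(nrow(genome), sum(bg), replace = TRUE,
                       prob = genome$length)
      chrom[bg] <- genome$chrom[ci]
      start0[bg] <- floor(stats::runif(sum(bg)) *
                            (genome$length[ci] - w[bg]))
    }
    for (sf in names(folds)) {
      sel <- which(category == sf)
      if (length(sel) == 0) next
      copies <- which(te$te_subfamily == sf)
      pick <- copies[sample.int(length(copies), length(sel),
                                replace = TRUE)]
      cs0 <- GenomicRanges::start(te)[pick] - 1
      ce0 <- GenomicRanges::end(te)[pick]
      lo <- cs0 - w[sel] + 1
      hi <- ce0 - 1
      pos <- lo + floor(stats::runif(length(sel)) * (hi - lo + 1))
      ch <- as.character(GenomicRanges::seqnames(te))[pick]
      L <- genome$length[match(ch, genome$chrom)]
      chrom[sel] <- ch
      start0[sel] <- pmax(0, pmin(pos, L - w[sel]))
    }
    nm <- sprintf("peak_%05d", seq_len(n))
    peaks <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = start0 + 1, width = w),
      strand = "*", name = nm)
    peaks <- .set_seqinfo(peaks, genome)
    list(peaks = peaks,
         truth = data.frame(
           peak = nm,
           planted_subfamily = ifelse(category == ".bg", NA, category),
           stringsAsFactors = FALSE))
  })
}

# One Poisson tag track: uniform background, plus extra tags at
# (fold - 1) x background rate within the given windows.
.simulate_track <- function(config, genome, windows, fold, label) {
  tl <- config$tag_length
  rate <- config$tag_background_rate
  parts <- lapply(seq_len(nrow(genome)), function(ci) {
    L <- genome$length[ci]
    n_bg <- stats::rpois(1, rate * L)
    s0 <- floor(stats::runif(n_bg) * (L - tl))
    data.frame(chrom = rep(genome$chrom[ci], n_bg), start0 = s0)
  })
  if (fold > 1 && length(windows) > 0) {
    wlen <- GenomicRanges::width(windows)
    n_ex <- stats::rpois(length(windows), (fold - 1) * rate * wlen)
    wi <- rep(seq_along(windows), n_ex)
    if (length(wi) > 0) {
      ws0 <- GenomicRanges::start(windows)[wi] - 1
      we0 <- GenomicRanges::end(windows)[wi]
      ch <- as.character(GenomicRanges::seqnames(windows))[wi]
      L <- genome$length[match(ch, genome$chrom)]
      s0 <- ws0 + floor(stats::runif(length(wi)) * (we0 - ws0 - tl))
      s0 <- pmax(0, pmin(s0, L - tl))
      parts <- c(parts, list(data.frame(chrom = ch, start0 = s0)))
    }
  }
  df <- do.call(rbind, parts)
  tags <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start0 + 1, width = tl),
    strand = "*")
  tags$score <- rep(30, length(tags))
  tag_track(tags, label = label, total_mapped = length(tags))
}

#' Simulate histone-mark tag tracks around bound copies
#'
#' Replicate tracks carry Poisson background plus `tag_fold` x coverage
#' within `tag_halfwidth` of each bound copy's midpoint; the control
#' track is pure background at the same rate.
#'
#' @param config A `sim_config`.
#' @param bound GRanges of bound TE copies (elevated windows are centred
#'   on their midpoints).
#' @param genome Genome table.
#' @param mark Mark label used in track names.
#' @param seed Optional seed.
#' @return List with `replicates` (list of `tag_track`) and `control`
#'   (a `tag_track`).
#' @export
simulate_mark_tracks <- function(config, bound, genome, mark = "H3K27ac",
                                 seed = NULL) {
  .with_seed_maybe(seed, {
    mid0 <- floor((GenomicRanges::start(bound) - 1 +
                     GenomicRanges::end(bound)) / 2)
    ch <- as.character(GenomicRanges::seqnames(bound))
    L <- genome$length[match(ch, genome$chrom)]
    ws0 <- pmax(0, mid0 - config$tag_halfwidth)
    we0 <- pmin(L, mid0 + config$tag_halfwidth)
    windows <- if (length(bound) > 0)
      GenomicRanges::GRanges(seqnames = ch,
                             ranges = IRanges::IRanges(start = ws0 + 1,
                                                       end = we0))
    else GenomicRanges::GRanges()
    reps <- lapply(seq_len(config$n_replicates), function(r)
      .simulate_track(config, genome, windows, config$tag_fold,
                      sprintf("%s_r%d", mark, r)))
    ctrl <- .simulate_track(config, genome, windows, 1, "input_control")
    list(replicates = reps, control = ctrl)
  })
}

# Exon blocks for a transcript spanning [start0, start0 + len): first
# block flush with the span start, last flush with the end (BED12).
.make_blocks <- function(start0, len, n_exons) {
  if (n_exons == 1 || len < 40 * n_exons)
    return(IRanges::IRanges(start = start0 + 1, width = len))
  b <- sort(sample(seq(20, len - 20), 2 * (n_exons - 1)))
  es <- c(0, b[seq(2, length(b), 2)])
  ee <- c(b[seq(1, length(b), 2)], len)
  IRanges::IRanges(start = start0 + es + 1, end = start0 + ee)
}

#' Simulate a transcriptome with planted TE-derived promoters
#'
#' Every transcript (and every planted-promoter construction) occupies
#' its own disjoint 25 kb genomic slot, so ground truth is unambiguous:
#' planted positives satisfy all discovery predicates (CAGE in a TE,
#' within the TFBS window of a planted peak, fully inside a strand-
#' matched promoter); each decoy violates exactly one predicate (TFBS
#' window / TE overlap / promoter containment / strand); background CAGE
#' clusters sit at transcript 5' ends in peak-free slots. Probes are
#' placed on exons with known tier (plus intron-only probes that drop
#' out of annotation by construction).
#'
#' @param config A `sim_config`.
#' @param te TE GRanges.
#' @param genome Genome table.
#' @param seed Optional seed.
#' @return List with `transcripts` (GRanges with `blocks`,
#'   `transcript_id`, `gene_id`, `tier`), `cage`, `probes`,
#'   `tfbs_peak_sets` (named list of GRanges) and `truth` (list:
#'   `positives`, `decoys`, `probe_tiers`, `n_unannotatable_probes`).
#' @export
simulate_transcriptome <- function(config, te, genome, seed = NULL) {
  .with_seed_maybe(seed, {
    slot_width <- 25000
    margin <- 3000
    hw <- config$promoter_halfwidth
    cw <- config$cage_width
    slots <- do.call(rbind, lapply(seq_len(nrow(genome)), function(ci) {
      k <- floor(genome$length[ci] / slot_width)
      data.frame(chrom = genome$chrom[ci],
                 start0 = (seq_len(k) - 1) * slot_width)
    }))
    need <- config$n_genes + config$n_planted_promoters +
      4 * config$n_decoys_per_class
    if (need > nrow(slots))
      stop("genome too small for the requested transcriptome: ",
           need, " slots needed, ", nrow(slots), " available")
    slots <- slots[sample.int(nrow(slots)), ]
    slot_no <- 0
    next_slot <- function() {
      slot_no <<- slot_no + 1
      if (slot_no > nrow(slots))
        stop("ran out of genomic slots; enlarge the genome or reduce ",
             "the transcriptome size")
      slots[slot_no, ]
    }

    tx_rows <- list(); cage_rows <- list(); peak_rows <- list()
    tiers <- names(config$tier_props)
    tfs <- c("cebpb", "e2f1", "myc")
    tx_n <- 0; cage_n <- 0; peak_n <- 0
    add_tx <- function(chrom, start0, len, strand, tier) {
      tx_n <<- tx_n + 1
      k <- sample(1:5, 1)
      tx_rows[[tx_n]] <<- list(
        chrom = chrom, start0 = start0, end0 = start0 + len,
        strand = strand, tier = tier,
        transcript_id = sprintf("tx_%04d", tx_n),
        gene_id = sprintf("gene_%04d", tx_n),
        blocks = .make_blocks(start0, len, k))
      tx_n
    }
    add_cage <- function(chrom, start0, strand, width = cw) {
      cage_n <<- cage_n + 1
      cage_rows[[cage_n]] <<- list(chrom = chrom, start0 = start0,
                                   end0 = start0 + width, strand = strand,
                                   name = sprintf("cage_%04d", cage_n))
      cage_rows[[cage_n]]$name
    }
    add_peak <- function(chrom, start0, width, tf) {
      peak_n <<- peak_n + 1
      peak_rows[[peak_n]] <<- list(chrom = chrom, start0 = start0,
                                   end0 = start0 + width, tf = tf,
                                   name = sprintf("tfbs_%04d", peak_n))
    }

    # --- background genes (peak-free slots; CAGE at the 5' end) ---
    for (g in seq_len(config$n_genes)) {
      sl <- next_slot()
      strand <- sample(c("+", "-"), 1)
      len <- sample(2000:15000, 1)
      s0 <- sl$start0 + margin
      tier <- sample(tiers, 1, prob = config$tier_props)
      add_tx(sl$chrom, s0, len, strand, tier)
      tss0 <- if (strand == "+") s0 else s0 + len
      cg0 <- if (strand == "+") tss0 else tss0 - cw
      add_cage(sl$chrom, cg0, strand)
    }

    # --- planted promoter constructions ---
    te_chr <- as.character(GenomicRanges::seqnames(te))
    te_s0 <- GenomicRanges::start(te) - 1
    te_e0 <- GenomicRanges::end(te)
    pick_te_in <- function(chrom, lo0, hi0, min_w) {
      sel <- which(te_chr == chrom & te_s0 >= lo0 & te_e0 <= hi0 &
                     te_e0 - te_s0 >= min_w)
      if (length(sel) == 0) NA_integer_ else sel[sample.int(length(sel), 1)]
    }
    te_free_start <- function(chrom, lo0, hi0, width) {
      # a start such that [start, start + width) overlaps no TE copy
      cand <- lo0 + floor(stats::runif(200) * (hi0 - lo0 - width))
      sel <- te_chr == chrom
      for (p in cand) {
        if (!any(sel & te_s0 < p + width & te_e0 > p)) return(p)
      }
      NA_real_
    }
    place_construct <- function(kind) {
      # returns TRUE on success
      sl <- next_slot()
      lo0 <- sl$start0 + margin
      hi0 <- sl$start0 + slot_width - margin
      strand <- sample(c("+", "-"), 1)
      tf <- sample(tfs, 1)
      if (kind == "te") {
        cg0 <- te_free_start(sl$chrom, lo0 + hw, hi0 - hw, cw)
        if (is.na(cg0)) return(NULL)
      } else {
        ti <- pick_te_in(sl$chrom, lo0 + hw, hi0 - hw, cw + 4)
        if (is.na(ti)) return(NULL)
        cg0 <- te_s0[ti] + 1 +
          floor(stats::runif(1) * (te_e0[ti] - te_s0[ti] - cw - 1))
      }
      cage_strand <- if (kind == "strand")
        setdiff(c("+", "-"), strand) else strand
      cid <- add_cage(sl$chrom, cg0, cage_strand)
      # TFBS peak: gap from the cluster edge
      gap <- if (kind == "window") sample(320:800, 1) else sample(0:250, 1)
      pw <- 200
      p0 <- if (stats::runif(1) < 0.5) cg0 + cw + gap else cg0 - gap - pw
      add_peak(sl$chrom, p0, pw, tf)
      # host transcript whose promoter does (or, for "promoter", does
      # not) contain the cluster
      if (kind == "promoter") {
        tss0 <- cg0 + cw + hw + sample(200:1500, 1)
      } else {
        tlo <- cg0 + cw - hw + 50
        thi <- cg0 + hw - 50
        tss0 <- tlo + floor(stats::runif(1) * (thi - tlo + 1))
      }
      len <- sample(1000:6000, 1)
      if (strand == "+") {
        len <- min(len, sl$start0 + slot_width - 200 - tss0)
        tx_s0 <- tss0
      } else {
        len <- min(len, tss0 - sl$start0 - 200)
        tx_s0 <- tss0 - len
      }
      if (len < 500) return(NULL)
      add_tx(sl$chrom, tx_s0, len, strand, "mRNA")
      list(cage_id = cid, tf = tf)
    }
    positives <- character()
    for (i in seq_len(config$n_planted_promoters)) {
      res <- NULL
      while (is.null(res)) res <- place_construct("positive")
      positives <- c(positives, res$cage_id)
    }
    decoys <- data.frame(cage_id = character(), violation = character())
    for (kind in c("window", "te", "promoter", "strand")) {
      for (i in seq_len(config$n_decoys_per_class)) {
        res <- NULL
        while (is.null(res)) res <- place_construct(kind)
        decoys <- rbind(decoys,
                        data.frame(cage_id = res$cage_id,
                                   violation = kind))
      }
    }

    # --- assemble GRanges ---
    tx_df <- do.call(rbind, lapply(tx_rows, function(r)
      data.frame(chrom = r$chrom, start0 = r$start0, end0 = r$end0,
                 strand = r$strand, tier = r$tier,
                 transcript_id = r$transcript_id, gene_id = r$gene_id)))
    transcripts <- GenomicRanges::GRanges(
      seqnames = tx_df$chrom,
      ranges = IRanges::IRanges(start = tx_df$start0 + 1,
                                end = tx_df$end0),
      strand = tx_df$strand,
      tier = tx_df$tier, transcript_id = tx_df$transcript_id,
      gene_id = tx_df$gene_id, name = tx_df$transcript_id)
    transcripts$blocks <- methods::as(lapply(tx_rows, `[[`, "blocks"),
                                      "IRangesList")
    cg_df <- do.call(rbind, lapply(cage_rows, as.data.frame))
    cage <- GenomicRanges::GRanges(
      seqnames = cg_df$chrom,
      ranges = IRanges::IRanges(start = cg_df$start0 + 1,
                                end = cg_df$end0),
      strand = cg_df$strand, name = cg_df$name)
    pk_df <- do.call(rbind, lapply(peak_rows, as.data.frame))
    tfbs <- GenomicRanges::GRanges(
      seqnames = pk_df$chrom,
      ranges = IRanges::IRanges(start = pk_df$start0 + 1,
                                end = pk_df$end0),
      strand = "*", name = pk_df$name, tf = pk_df$tf)
    tfbs_peak_sets <- lapply(split(seq_along(tfbs), tfbs$tf),
                             function(i) tfbs[i])

    # --- probes on exons (known tier) + intron-only probes ---
    probe_rows <- list(); probe_truth <- list()
    for (p in seq_len(config$n_probes)) {
      ti <- sample.int(length(transcripts), 1)
      b <- transcripts$blocks[[ti]]
      e <- sample.int(length(b), 1)
      plen <- min(60, IRanges::width(b)[e])
      p0 <- IRanges::start(b)[e] - 1 +
        floor(stats::runif(1) * (IRanges::width(b)[e] - plen + 1))
      probe_rows[[p]] <- list(
        chrom = as.character(GenomicRanges::seqnames(transcripts))[ti],
        start0 = p0, end0 = p0 + plen,
        strand = as.character(GenomicRanges::strand(transcripts))[ti],
        name = sprintf("probe_%04d", p))
      probe_truth[[p]] <- data.frame(probe = sprintf("probe_%04d", p),
                                     tier = transcripts$tier[ti])
    }
    n_intron <- 0
    multi <- which(lengths(transcripts$blocks) >= 2)
    for (q in seq_len(config$n_intron_probes)) {
      ti <- multi[sample.int(length(multi), 1)]
      b <- transcripts$blocks[[ti]]
      gaps_s <- IRanges::end(b)[-length(b)] + 1
      gaps_e <- IRanges::start(b)[-1] - 1
      wide <- which(gaps_e - gaps_s + 1 >= 30)
      if (length(wide) == 0) next
      gi <- wide[sample.int(length(wide), 1)]
      plen <- min(30, gaps_e[gi] - gaps_s[gi] + 1)
      p0 <- gaps_s[gi] - 1
      n_intron <- n_intron + 1
      idx <- config$n_probes + n_intron
      probe_rows[[idx]] <- list(
        chrom = as.character(GenomicRanges::seqnames(transcripts))[ti],
        start0 = p0, end0 = p0 + plen,
        strand = as.character(GenomicRanges::strand(transcripts))[ti],
        name = sprintf("probe_%04d", idx))
    }
    pr_df <- do.call(rbind, lapply(probe_rows, as.data.frame))
    probes <- GenomicRanges::GRanges(
      seqnames = pr_df$chrom,
      ranges = IRanges::IRanges(start = pr_df$start0 + 1,
                                end = pr_df$end0),
      strand = pr_df$strand, name = pr_df$name)

    list(transcripts = transcripts, cage = cage, probes = probes,
         tfbs_peak_sets = tfbs_peak_sets,
         truth = list(positives = positives, decoys = decoys,
                      probe_tiers = do.call(rbind, probe_truth),
                      n_unannotatable_probes = n_intron))
  })
}

#' Simulate paired tumour/normal methylation counts
#'
#' Normal-sample normalised levels sit near the configured baseline;
#' tumour levels differ by a per-pair difference drawn from
#' `Normal(delta, sd)`, realised as candidate/subfamily count pairs at
#' the configured depth (so level = candidate / subfamily up to
#' rounding).
#'
#' @param config A `sim_config`.
#' @param seed Optional seed.
#' @return data.frame with columns `sample`, `condition`
#'   (tumour/normal), `candidate_count`, `subfamily_count`.
#' @export
simulate_paired_counts <- function(config, seed = NULL) {
  .with_seed_maybe(seed, {
    m <- config$methylation
    n <- m$n_pairs
    normal <- pmin(0.95, pmax(0.05,
                              m$baseline + stats::rnorm(n, 0, 0.05)))
    tumour <- pmax(0.01, normal + m$delta + stats::rnorm(n, 0, m$sd))
    depth <- round(m$depth)
    df <- data.frame(
      sample = rep(sprintf("pair_%02d", seq_len(n)), 2),
      condition = rep(c("tumour", "normal"), each = n),
      candidate_count = c(round(tumour * depth), round(normal * depth)),
      subfamily_count = depth,
      stringsAsFactors = FALSE)
    df[order(df$sample, df$condition), ]
  })
}

#' Paired levels from a counts table
#'
#' Normalised levels (`candidate_count / subfamily_count`) pivoted into
#' paired tumour/normal vectors, ordered by sample id.
#'
#' @param counts data.frame as from [simulate_paired_counts()].
#' @return List with numeric vectors `tumour` and `normal`.
#' @export
paired_levels <- function(counts) {
  counts$level <- counts$candidate_count / counts$subfamily_count
  t_rows <- counts[counts$condition == "tumour", ]
  n_rows <- counts[counts$condition == "normal", ]
  t_rows <- t_rows[order(t_rows$sample), ]
  n_rows <- n_rows[order(n_rows$sample), ]
  stopifnot(identical(t_rows$sample, n_rows$sample))
  list(tumour = t_rows$level, normal = n_rows$level)
}

#' Simulate DNase candidate/subfamily counts for two cell lines
#'
#' Candidate counts are binomial draws from the subfamily depth at the
#' base proportion (HMEC) and `ratio` times it (MCF7).
#'
#' @param config A `sim_config`.
#' @param seed Optional seed.
#' @return data.frame with columns `cell_line`, `candidate_count`,
#'   `subfamily_count`.
#' @export
simulate_dnase_counts <- function(config, seed = NULL) {
  .with_seed_maybe(seed, {
    d <- config$dnase
    depth <- round(d$depth)
    data.frame(
      cell_line = c("MCF7", "HMEC"),
      candidate_count = c(stats::rbinom(1, depth, min(1, d$p_base * d$ratio)),
                          stats::rbinom(1, depth, d$p_base)),
      subfamily_count = depth,
      stringsAsFactors = FALSE)
  })
}

#' Simulate dual-luciferase plates
#'
#' Per experiment, construct and well: Renilla luminescence is lognormal
#' around the configured base; firefly is Renilla times the base ratio,
#' the construct's true relative effect, and lognormal noise.
#'
#' @param config A `sim_config`.
#' @param seed Optional seed.
#' @return data.frame with columns `experiment`, `construct`, `well`,
#'   `firefly`, `renilla`.
#' @export
simulate_luciferase <- function(config, seed = NULL) {
  .with_seed_maybe(seed, {
    lc <- config$luciferase
    grid <- expand.grid(well = 1:3,
                        construct = names(lc$effects),
                        experiment = seq_len(lc$n_experiments),
                        stringsAsFactors = FALSE)
    sdlog <- sqrt(log(1 + lc$cv^2))
    renilla <- stats::rlnorm(nrow(grid), log(lc$base_renilla), sdlog)
    firefly <- renilla * lc$base_ratio * lc$effects[grid$construct] *
      stats::rlnorm(nrow(grid), 0, sdlog)
    data.frame(experiment = grid$experiment, construct = grid$construct,
               well = grid$well, firefly = firefly, renilla = renilla,
               stringsAsFactors = FALSE)
  })
}

#' Generate and write a complete synthetic dataset
#'
#' Runs every generator under sub-seeds derived from `seed` and writes
#' the full input tree: `chrom.sizes`, `te_table.tsv`, `peaks_<tf>.bed`,
#' `tags_<mark>_r<k>.bed` + `tags_control.bed`, `totals.tsv`,
#' `transcripts_tier{0,1,2}.bed12`, `cage.bed`, `probes.bed`,
#' `tfbs_<tf>.bed`, `methylation_counts.tsv`, `dnase_counts.tsv`,
#' `luciferase.tsv` and `truth.json`. Byte-identical across runs with
#' the same config and seed.
#'
#' @param config A `sim_config`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param profile_subfamily Subfamily whose peak-bound copies anchor the
#'   elevated tag windows.
#' @return Invisibly, a list with all in-memory objects and file paths.
#' @export
simulate_dataset <- function(config, out_dir, seed,
                             profile_subfamily = "MIRb") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- simulate_genome(config, seed = seed + 1)
  pk <- simulate_peaks(config, gen$te, gen$genome, seed = seed + 2)
  groups <- stratify_by_binding(gen$te, profile_subfamily, pk$peaks)
  tr <- simulate_mark_tracks(config, groups$bound, gen$genome,
                             seed = seed + 3)
  tx <- simulate_transcriptome(config, gen$te, gen$genome,
                               seed = seed + 4)
  meth <- simulate_paired_counts(config, seed = seed + 5)
  dnase <- simulate_dnase_counts(config, seed = seed + 6)
  luc <- simulate_luciferase(config, seed = seed + 7)

  p <- function(f) file.path(out_dir, f)
  write_genome_table(gen$genome, p("chrom.sizes"))
  write_te_table(gen$te, p("te_table.tsv"),
                 comments = sprintf("seed=%d", seed))
  write_bed(pk$peaks, p("peaks_chipseq.bed"))
  totals <- data.frame(track = character(), total_mapped = numeric())
  for (i in seq_along(tr$replicates)) {
    trk <- tr$replicates[[i]]
    write_bed(trk$tags, p(sprintf("tags_%s.bed", trk$label)))
    totals <- rbind(totals, data.frame(track = trk$label,
                                       total_mapped = trk$total_mapped))
  }
  write_bed(tr$control$tags, p("tags_control.bed"))
  totals <- rbind(totals, data.frame(track = "control",
                                     total_mapped = tr$control$total_mapped))
  write_tsv(totals, p("totals.tsv"))
  tiers <- c(mRNA = 0, lncRNA_tier1 = 1, lncRNA_tier2 = 2)
  for (tn in names(tiers)) {
    sel <- tx$transcripts[tx$transcripts$tier == tn]
    GenomicRanges::mcols(sel) <-
      GenomicRanges::mcols(sel)[c("name", "blocks")]
    write_bed(sel, p(sprintf("transcripts_tier%d.bed12", tiers[[tn]])))
  }
  write_bed(tx$cage, p("cage.bed"))
  write_bed(tx$probes, p("probes.bed"))
  for (tf in names(tx$tfbs_peak_sets)) {
    sel <- tx$tfbs_peak_sets[[tf]]
    GenomicRanges::mcols(sel) <- GenomicRanges::mcols(sel)["name"]
    write_bed(sel, p(sprintf("tfbs_%s.bed", tf)))
  }
  write_tsv(meth, p("methylation_counts.tsv"))
  write_tsv(dnase, p("dnase_counts.tsv"))
  write_tsv(luc, p("luciferase.tsv"))
  truth <- list(
    seed = seed,
    planted_enrichment = as.list(config$planted_enrichment),
    peak_truth = pk$truth,
    profile_subfamily = profile_subfamily,
    n_bound = length(groups$bound),
    tag_fold = config$tag_fold,
    promoter_positives = tx$truth$positives,
    promoter_decoys = tx$truth$decoys,
    probe_tiers = tx$truth$probe_tiers,
    methylation_delta = config$methylation$delta,
    dnase_ratio = config$dnase$ratio,
    luciferase_effects = as.list(config$luciferase$effects))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(genome = gen$genome, te = gen$te, peaks = pk$peaks,
                 tracks = tr, transcriptome = tx, methylation = meth,
                 dnase = dnase, luciferase = luc, truth = truth,
                 dir = out_dir))
}
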