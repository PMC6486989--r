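# Interval data model and file formats.
#
# Internally everything is a GRanges (1-based, closed). BED files are
# 0-based half-open; conversion happens only in the readers/writers here.
# RepeatMasker-style consensus coordinates (rep_start/rep_end) stay 1-based
# inclusive, as in the source tables.

#' Read a chromosome-sizes table
#'
#' Two tab-separated columns: chromosome identifier and length in bp.
#' Lines starting with `#` are ignored.
#'
#' @param path Path to a `chrom.sizes`-style file.
#' @return A data.frame with columns `chrom` (character) and `length`
#'   (integer), in file order.
#' @export
read_genome_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_table(df$chrom, df$length)
}

#' Construct and validate a genome table
#'
#' @param chrom Character vector of unique chromosome identifiers.
#' @param length Strictly positive chromosome lengths (bp).
#' @return A data.frame with columns `chrom` and `length`; order is
#'   preserved and significant (it fixes output ordering downstream).
#' @export
genome_table <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("duplicate chromosome identifiers")
  if (any(is.na(length)) || any(length <= 0) || any(length != floor(length)))
    stop("chromosome lengths must be positive integers")
  data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
}

#' @noRd
genome_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = genome$chrom,
                        seqlengths = as.integer(genome$length))
}

# attach a genome's Seqinfo, reordering seqlevels to the genome order
.set_seqinfo <- function(gr, genome) {
  GenomeInfoDb::seqlevels(gr) <- genome$chrom
  GenomeInfoDb::seqinfo(gr) <- genome_seqinfo(genome)
  gr
}

#' Write a chromosome-sizes table
#' @param genome Genome table from [genome_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_table <- function(genome, path) {
  utils::write.table(genome, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Split tab-delimited lines, dropping comment/empty lines but remembering
# original line numbers for error messages.
.read_tab_lines <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

.bed_field <- function(fields, lineno, i, n_have) {
  ifelse(n_have >= i, vapply(fields, function(f) f[i], ""), NA_character_)
}

#' Read a BED file (BED3 to BED12)
#'
#' Standard BED convention: 0-based half-open coordinates, strand in
#' column 6 (`.` meaning unstranded). BED12 block fields, when present,
#' are parsed into an absolute-coordinate `blocks` metadata column
#' (an [IRanges::IRangesList]).
#'
#' @param path Path to a BED file. Lines starting with `#` are skipped.
#' @param genome Optional genome table; when supplied, intervals must lie
#'   within chromosome bounds and the returned GRanges carries its Seqinfo.
#' @return A [GenomicRanges::GRanges] in file order, with metadata columns
#'   `name` and `score` when present (missing score `.` becomes `NA`), and
#'   `blocks` for BED12.
#' @export
read_bed <- function(path, genome = NULL) {
  parsed <- .read_tab_lines(path)
  fields <- parsed$fields
  lineno <- parsed$lineno
  if (length(fields) == 0L) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(genome)) gr <- .set_seqinfo(gr, genome)
    return(gr)
  }
  n_have <- lengths(fields)
  bad <- n_have < 3L | n_have > 12L
  if (any(bad))
    stop("malformed BED line ", lineno[which(bad)[1]], ": expected 3-12 fields")
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- is.na(start0) | is.na(end0)
  if (any(bad))
    stop("malformed BED line ", lineno[which(bad)[1]], ": non-numeric coordinates")
  bad <- start0 < 0 | start0 >= end0
  if (any(bad))
    stop("invalid interval at line ", lineno[which(bad)[1]],
         ": require 0 <= start < end")
  name <- .bed_field(fields, lineno, 4L, n_have)
  score_chr <- .bed_field(fields, lineno, 5L, n_have)
  score <- suppressWarnings(as.numeric(ifelse(score_chr == ".", NA, score_chr)))
  strand <- .bed_field(fields, lineno, 6L, n_have)
  strand[is.na(strand)] <- "."
  bad <- !strand %in% c("+", "-", ".")
  if (any(bad))
    stop("invalid strand at line ", lineno[which(bad)[1]])
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = ifelse(strand == ".", "*", strand))
  if (any(n_have >= 4L)) gr$name <- name
  if (any(n_have >= 5L)) gr$score <- score
  if (any(n_have >= 12L)) {
    if (!all(n_have == 12L))
      stop("mixed BED12/non-BED12 records in ", path)
    n_block <- as.integer(vapply(fields, `[`, "", 10L))
    sizes <- strsplit(vapply(fields, `[`, "", 11L), ",", fixed = TRUE)
    offs <- strsplit(vapply(fields, `[`, "", 12L), ",", fixed = TRUE)
    blocks <- lapply(seq_along(fields), function(i) {
      sz <- as.numeric(sizes[[i]][seq_len(n_block[i])])
      of <- as.numeric(offs[[i]][seq_len(n_block[i])])
      IRanges::IRanges(start = start0[i] + of + 1, width = sz)
    })
    blocks <- methods::as(blocks, "IRangesList")
    ok <- .validate_blocks(blocks, start0 + 1, end0)
    if (!all(ok))
      stop("invalid BED12 blocks at line ", lineno[which(!ok)[1]],
           ": blocks must be sorted, non-overlapping, within the span, ",
           "and flush with both span ends")
    gr$blocks <- blocks
  }
  if (!is.null(genome)) {
    si <- genome_seqinfo(genome)
    miss <- !chrom %in% genome$chrom
    if (any(miss))
      stop("unknown chromosome at line ", lineno[which(miss)[1]],
           ": ", chrom[which(miss)[1]])
    over <- end0 > genome$length[match(chrom, genome$chrom)]
    if (any(over))
      stop("interval at line ", lineno[which(over)[1]],
           " exceeds chromosome bounds")
    gr <- .set_seqinfo(gr, genome)
  }
  gr
}

# blocks sorted, non-overlapping, contained in [start, end], first block
# starts at span start and last ends at span end (BED12 contract)
.validate_blocks <- function(blocks, start1, end1) {
  vapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    if (length(b) == 0L) return(FALSE)
    s <- IRanges::start(b); e <- IRanges::end(b)
    all(diff(s) > 0) && all(s[-1] > e[-length(e)]) &&
      s[1] == start1[i] && e[length(e)] == end1[i] &&
      all(s >= start1[i]) && all(e <= end1[i])
  }, TRUE)
}

#' Write a GRanges as BED
#'
#' Inverse of [read_bed()]: emits BED3/4/5/6 depending on the metadata
#' columns present, or BED12 when a `blocks` column exists. Coordinates
#' are converted back to 0-based half-open.
#'
#' @param gr A GRanges, optionally with `name`, `score` and `blocks`
#'   metadata columns.
#' @param path Output path.
#' @param comments Optional character vector written first as `#` lines.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, comments = NULL) {
  s <- as.character(GenomicRanges::strand(gr))
  s[s == "*"] <- "."
  cols <- list(as.character(GenomicRanges::seqnames(gr)),
               format(GenomicRanges::start(gr) - 1, scientific = FALSE, trim = TRUE),
               format(GenomicRanges::end(gr), scientific = FALSE, trim = TRUE))
  has <- function(x) x %in% names(GenomicRanges::mcols(gr))
  want_blocks <- has("blocks")
  if (has("name") || has("score") || any(s != ".") || want_blocks)
    cols <- c(cols, list(if (has("name")) gr$name else rep(".", length(gr))))
  if (has("score") || any(s != ".") || want_blocks) {
    sc <- if (has("score")) gr$score else rep(NA_real_, length(gr))
    cols <- c(cols, list(ifelse(is.na(sc), ".", format(sc, scientific = FALSE, trim = TRUE))))
  }
  if (any(s != ".") || want_blocks) cols <- c(cols, list(s))
  if (want_blocks) {
    b <- gr$blocks
    start0 <- GenomicRanges::start(gr) - 1
    sizes <- vapply(seq_along(b), function(i)
      paste0(IRanges::width(b[[i]]), collapse = ","), "")
    offs <- vapply(seq_along(b), function(i)
      paste0(IRanges::start(b[[i]]) - 1 - start0[i], collapse = ","), "")
    cols <- c(cols, list(cols[[2]], cols[[3]], rep("0", length(gr)),
                         as.character(lengths(b)), sizes, offs))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  if (length(gr) > 0)
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read a TE annotation table
#'
#' A simplified RepeatMasker-style TSV with header columns `chrom`,
#' `start` (0-based), `end`, `strand`, `class`, `family`, `subfamily`,
#' `repStart`, `repEnd`, `consensusLength`. Consensus coordinates are
#' 1-based inclusive on the subfamily consensus sequence and must satisfy
#' `1 <= repStart <= repEnd <= consensusLength` (minus-strand copies must
#' arrive with this already resolved). Rows violating any invariant are
#' dropped with a single warning reporting the count.
#'
#' @param path Path to the TE table.
#' @param genome Optional genome table for bounds checking/Seqinfo.
#' @return A GRanges with metadata columns `te_class`, `te_family`,
#'   `te_subfamily`, `rep_start`, `rep_end`, `consensus_length` and `name`
#'   (a per-copy identifier; generated when absent).
#' @export
read_te_table <- function(path, genome = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "class", "family",
            "subfamily", "repStart", "repEnd", "consensusLength")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("TE table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  ok <- !is.na(df$start) & !is.na(df$end) & df$start >= 0 & df$start < df$end &
    df$strand %in% c("+", "-", ".") &
    !is.na(df$repStart) & !is.na(df$repEnd) & !is.na(df$consensusLength) &
    df$repStart >= 1 & df$repStart <= df$repEnd &
    df$repEnd <= df$consensusLength
  if (!is.null(genome))
    ok <- ok & df$chrom %in% genome$chrom &
      df$end <= genome$length[match(df$chrom, genome$chrom)]
  if (any(!ok))
    warning(sum(!ok), " TE row(s) rejected (invariant violations)")
  df <- df[ok, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = ifelse(df$strand == ".", "*", df$strand),
    te_class = df$class, te_family = df$family, te_subfamily = df$subfamily,
    rep_start = as.integer(df$repStart), rep_end = as.integer(df$repEnd),
    consensus_length = as.integer(df$consensusLength))
  gr$name <- if ("name" %in% names(df)) df$name else
    sprintf("te_%06d", seq_len(nrow(df)))
  if (!is.null(genome)) gr <- .set_seqinfo(gr, genome)
  gr
}

#' Write a TE annotation table
#' @param te TE GRanges as returned by [read_te_table()].
#' @param path Output path.
#' @param comments Optional `#` header comments.
#' @return `path`, invisibly.
#' @export
write_te_table <- function(te, path, comments = NULL) {
  s <- as.character(GenomicRanges::strand(te))
  s[s == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(te)),
                   start = GenomicRanges::start(te) - 1,
                   end = GenomicRanges::end(te),
                   strand = s,
                   class = te$te_class, family = te$te_family,
                   subfamily = te$te_subfamily,
                   repStart = te$rep_start, repEnd = te$rep_end,
                   consensusLength = te$consensus_length,
                   name = te$name,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0)
    writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}

#' Overlapping pairs between two interval sets
#'
#' `bedtools intersect`-style pairing: every (query, subject) pair sharing
#' at least `min_overlap` bp on the same chromosome, optionally requiring
#' matching strand (`*` matches either strand).
#'
#' @param query,subject GRanges.
#' @param strand_match Require same strand (default `FALSE`).
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return data.frame with integer columns `query` and `subject` (indices
#'   into the inputs), ordered by query then subject.
#' @export
interval_pairs <- function(query, subject, strand_match = FALSE,
                           min_overlap = 1L) {
  hits <- GenomicRanges::findOverlaps(query, subject,
                                      minoverlap = min_overlap,
                                      ignore.strand = !strand_match)
  df <- data.frame(query = S4Vectors::queryHits(hits),
                   subject = S4Vectors::subjectHits(hits))
  df[order(df$query, df$subject), , drop = FALSE]
}

#' Pairs within a symmetric window
#'
#' `bedtools window -w`-style pairing: each query interval is expanded by
#' `w` bp on both sides (clipped at chromosome bounds when a genome table
#' is given) before overlap testing. With `w = 0` this is exactly
#' [interval_pairs()].
#'
#' @inheritParams interval_pairs
#' @param w Window half-extension in bp (>= 0).
#' @param genome Optional genome table used to clip expanded queries.
#' @return data.frame as in [interval_pairs()].
#' @export
window_pairs <- function(query, subject, w, genome = NULL,
                         strand_match = FALSE) {
  stopifnot(w >= 0)
  ex <- query
  new_start <- pmax(1, GenomicRanges::start(query) - w)
  new_end <- GenomicRanges::end(query) + w
  if (!is.null(genome)) {
    lens <- genome$length[match(as.character(GenomicRanges::seqnames(query)),
                                genome$chrom)]
    new_end <- pmin(new_end, lens)
  }
  IRanges::ranges(ex) <- IRanges::IRanges(start = new_start, end = new_end)
  interval_pairs(ex, subject, strand_match = strand_match)
}

#' Exon-aware (split) overlap pairs
#'
#' `bedtools intersect -split`-style pairing against transcript models:
#' overlap is evaluated against exon blocks only, so intron-only overlap
#' yields no pair. Strand matching is on by default (the `-s` use case).
#'
#' @param query GRanges (e.g. probe alignments).
#' @param transcripts GRanges with a `blocks` metadata column (BED12).
#' @param strand_match Require same strand (default `TRUE`).
#' @return data.frame with columns `query` and `subject` (transcript
#'   index), deduplicated and ordered.
#' @export
split_pairs <- function(query, transcripts, strand_match = TRUE) {
  if (is.null(transcripts$blocks))
    stop("transcripts must carry a 'blocks' metadata column")
  b <- transcripts$blocks
  tx_idx <- rep(seq_along(transcripts), lengths(b))
  exons <- GenomicRanges::GRanges(
    seqnames = rep(GenomicRanges::seqnames(transcripts), lengths(b)),
    ranges = unlist(b, use.names = FALSE),
    strand = rep(GenomicRanges::strand(transcripts), lengths(b)))
  hits <- GenomicRanges::findOverlaps(query, exons,
                                      ignore.strand = !strand_match)
  df <- unique(data.frame(query = S4Vectors::queryHits(hits),
                          subject = tx_idx[S4Vectors::subjectHits(hits)]))
  df[order(df$query, df$subject), , drop = FALSE]
}

#' Remove query intervals overlapping a subject set
#'
#' `bedtools intersect -v`-style complement: returns the query intervals
#' with zero overlap against any subject interval (strand-blind).
#'
#' @param query,subject GRanges.
#' @return The non-overlapping subset of `query`.
#' @export
subtract_intervals <- function(query, subject) {
  hit <- IRanges::overlapsAny(query, subject, ignore.strand = TRUE)
  query[!hit]
}

#' Write a data.frame as a commented TSV
#'
#' Column header plus optional `#` comment lines recording provenance
#' (seed, parameters) above it; the standard output format of the
#' pipeline's tabular results.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param comments Optional character vector of comment lines.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    cols <- lapply(df, function(x)
      if (is.numeric(x)) format(x, scientific = FALSE, trim = TRUE, digits = 15)
      else as.character(x))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}
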