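# Break calling: UMI merge, PCR deduplication, and the positioning/strand
# convention that turns a mapped read into a single-nucleotide break signal.
#
# A read of this protocol is the reverse complement of the captured fragment
# whose 5' end abuts the free 3'-OH left by the break. The signal nucleotide
# is therefore the base immediately upstream of the read's 5' end, on the
# strand opposite to the mapping strand, so that the original break lies on
# the 5' side of the signal nucleotide on its own strand.

#' Merge the UMI read into the genomic read's name
#'
#' @param r1_name Name of the genomic read.
#' @param r2_sequence UMI sequence (second read).
#' @param umi_length Expected UMI length (default 10).
#' @return `r1_name` with `"_"` and the UMI appended. Downstream parsing
#'   takes the substring after the *last* underscore, so underscores in
#'   `r1_name` are safe.
#' @export
merge_umi <- function(r1_name, r2_sequence, umi_length = 10L) {
  if (any(nchar(r2_sequence) != umi_length)) {
    stop(sprintf("UMI must be exactly %d bases", umi_length))
  }
  if (any(grepl("[^ACGTN]", r2_sequence))) {
    stop("UMI must be over the A/C/G/T/N alphabet")
  }
  paste0(r1_name, "_", r2_sequence)
}

# Mapped 5'-end coordinate: ligation-defined end of the fragment.
five_prime_end <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end - 1L)
}

#' Remove PCR duplicates by position and exact UMI
#'
#' Reads sharing (chromosome, mapping strand, mapped 5'-end coordinate, exact
#' UMI string) are collapsed to one representative: the highest-MAPQ read,
#' ties broken by input order. Output preserves first-occurrence order of the
#' surviving keys. The 5' end (not the full interval) defines the key because
#' sonication makes 3' ends variable while the 5' end is fixed by ligation.
#' No edit-distance UMI clustering is performed (unique-UMI grouping).
#'
#' @param reads Aligned-read data.frame (`chrom, start, end, strand, umi,
#'   mapq`).
#' @return Deduplicated aligned-read data.frame.
#' @export
deduplicate <- function(reads) {
  if (nrow(reads) == 0) return(reads)
  key <- paste(reads$chrom, reads$strand, five_prime_end(reads), reads$umi,
               sep = "\r")
  # stable sort by decreasing mapq: first row per key is the winner
  o <- order(-reads$mapq)
  first_in_key <- o[!duplicated(key[o])]
  # restore first-occurrence order of keys
  first_seen <- match(unique(key), key)
  winner <- first_in_key[match(key[first_seen], key[first_in_key])]
  out <- reads[winner, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Position break signals for a set of reads
#'
#' For a read mapped to `+`, the signal nucleotide sits at `start - 1` on the
#' `-` strand; for a read mapped to `-`, at `end` (one past the rightmost
#' aligned base, i.e. immediately 5' of the read in read orientation) on the
#' `+` strand. Reads whose signal coordinate falls outside
#' `[0, chrom_length)` are dropped and counted.
#'
#' @param reads Aligned-read data.frame.
#' @param genome A [Genome()] object; all reads must map to its chromosomes.
#' @return List with `breaks` (data.frame `chrom, pos, strand, mapq`) and
#'   `n_dropped` (reads whose signal fell off the chromosome).
#' @export
position_breaks <- function(reads, genome) {
  stopifnot(inherits(genome, "Genome"))
  unknown <- !reads$chrom %in% names(genome)
  if (any(unknown)) {
    stop("read(s) on unknown chromosome(s): ",
         paste(unique(reads$chrom[unknown]), collapse = ", "))
  }
  pos <- ifelse(reads$strand == "+", reads$start - 1L, reads$end)
  strand <- other_strand(reads$strand)
  lens <- genome_lengths(genome)[reads$chrom]
  keep <- pos >= 0L & pos < lens
  breaks <- data.frame(chrom = reads$chrom[keep], pos = as.integer(pos[keep]),
                       strand = strand[keep], mapq = reads$mapq[keep],
                       stringsAsFactors = FALSE)
  rownames(breaks) <- NULL
  list(breaks = breaks, n_dropped = sum(!keep))
}

#' Call one break signal from one read
#'
#' Single-read convenience wrapper around [position_breaks()].
#'
#' @param read One-row aligned-read data.frame.
#' @param genome A [Genome()] object.
#' @return One-row break data.frame, or `NULL` if the signal coordinate falls
#'   outside the chromosome.
#' @export
call_break <- function(read, genome) {
  res <- position_breaks(read[1, , drop = FALSE], genome)
  if (nrow(res$breaks) == 0) NULL else res$breaks
}

#' Call deduplicated break signals for one sample
#'
#' Pipeline: deduplicate by (position, strand, UMI), drop reads below the
#' MAPQ threshold, position the break signal for each survivor. Read counts
#' across the processing steps are reported in the returned accounting and
#' logged to stderr.
#'
#' @param reads Aligned-read data.frame.
#' @param genome A [Genome()] object.
#' @param min_mapq Minimum MAPQ kept after deduplication (default 0 = keep
#'   all).
#' @param sample_id Sample label stored on the result.
#' @return A `SampleBreakSet`: list with `sample_id`, `breaks` (break
#'   data.frame), `M` (normalization factor, `NULL` until computed by
#'   [normalization_factor()]), and `stats` (accounting counters `n_input`,
#'   `n_deduplicated`, `n_below_mapq`, `n_off_genome`, `n_emitted`).
#' @export
call_breaks <- function(reads, genome, min_mapq = 0L, sample_id = "sample") {
  n_input <- nrow(reads)
  dedup <- deduplicate(reads)
  n_dedup <- nrow(dedup)
  keep <- dedup$mapq >= min_mapq
  n_below <- sum(!keep)
  res <- if (any(keep)) {
    position_breaks(dedup[keep, , drop = FALSE], genome)
  } else {
    list(breaks = data.frame(chrom = character(0), pos = integer(0),
                             strand = character(0), mapq = integer(0),
                             stringsAsFactors = FALSE),
         n_dropped = 0L)
  }
  stats <- list(n_input = n_input, n_deduplicated = n_dedup,
                n_below_mapq = n_below, n_off_genome = res$n_dropped,
                n_emitted = nrow(res$breaks))
  ts_log("info",
         "%s: %d reads in, %d after dedup, %d below MAPQ %d, %d off-genome, %d breaks emitted",
         sample_id, n_input, n_dedup, n_below, min_mapq, res$n_dropped,
         nrow(res$breaks))
  structure(list(sample_id = sample_id, breaks = res$breaks, M = NULL,
                 stats = stats),
            class = "SampleBreakSet")
}

#' @export
print.SampleBreakSet <- function(x, ...) {
  cat(sprintf("SampleBreakSet '%s': %d break signals%s\n", x$sample_id,
              nrow(x$breaks),
              if (is.null(x$M)) "" else sprintf(", M = %.4g", x$M)))
  invisible(x)
}
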