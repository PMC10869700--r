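# Nicking-endonuclease validation (precision / sensitivity against motif
# ground truth), treated-vs-control bin statistics, and correlation of the
# break landscape with external feature tracks.

#' Enumerate motif sites and their expected signal nucleotides
#'
#' Finds every occurrence of `motif` on the plus strand (substring match)
#' and minus strand (reverse-complement match), including overlapping
#' occurrences. A nick immediately 5' of the motif puts the signal
#' nucleotide at the first base of the motif read on its own strand: for a
#' plus-strand occurrence starting at `p` that is `(p, +)`; for a
#' minus-strand occurrence whose reverse complement spans `[q, q + m)` on
#' the reference it is `(q + m - 1, -)`.
#'
#' @param genome A [Genome()] object.
#' @param motif Recognition sequence over A/C/G/T.
#' @return Data.frame `chrom, pos, strand` ordered by (chrom, pos, strand).
#' @export
find_motif_sites <- function(genome, motif) {
  stopifnot(inherits(genome, "Genome"), nchar(motif) >= 1,
            !grepl("[^ACGT]", motif))
  m <- nchar(motif)
  pat <- Biostrings::DNAString(motif)
  rows <- list()
  for (chrom in names(genome)) {
    subject <- Biostrings::DNAString(genome[[chrom]])
    fwd <- Biostrings::start(Biostrings::matchPattern(pat, subject))
    rev <- Biostrings::start(
      Biostrings::matchPattern(Biostrings::reverseComplement(pat), subject))
    rows[[chrom]] <- data.frame(
      chrom = chrom,
      pos = c(fwd - 1L, rev - 1L + m - 1L),
      strand = rep(c("+", "-"), c(length(fwd), length(rev))),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif precision of a break set
#'
#' A break record matches when the `nchar(motif)`-length sequence starting
#' at its signal nucleotide, read on the signal strand (reverse-complemented
#' for minus-strand breaks), equals the motif. Precision is the matching
#' fraction over all break records, multiplicity counted; breaks whose
#' downstream window runs off the chromosome count as non-matching and are
#' reported.
#'
#' @param breaks Break data.frame.
#' @param genome A [Genome()] object.
#' @param motif Recognition sequence.
#' @return List with `n_breaks`, `n_matching`, `precision` (`NA` with
#'   `defined = FALSE` for an empty break set) and `n_unscorable` (windows
#'   off the chromosome).
#' @export
motif_precision <- function(breaks, genome, motif) {
  m <- nchar(motif)
  n <- nrow(breaks)
  if (n == 0) {
    warning("empty break set: precision undefined")
    return(list(n_breaks = 0L, n_matching = 0L, precision = NA_real_,
                defined = FALSE, n_unscorable = 0L))
  }
  lens <- genome_lengths(genome)[breaks$chrom]
  plus <- breaks$strand == "+"
  lo <- ifelse(plus, breaks$pos, breaks$pos - m + 1L)
  hi <- ifelse(plus, breaks$pos + m - 1L, breaks$pos)
  ok <- lo >= 0 & hi < lens
  seqs <- rep(NA_character_, n)
  for (chrom in unique(breaks$chrom[ok])) {
    i <- ok & breaks$chrom == chrom
    seqs[i] <- substring(genome[[chrom]], lo[i] + 1L, hi[i] + 1L)
  }
  if (any(ok & !plus)) seqs[ok & !plus] <- revcomp(seqs[ok & !plus])
  matching <- !is.na(seqs) & seqs == motif
  list(n_breaks = n, n_matching = sum(matching),
       precision = sum(matching) / n, defined = TRUE,
       n_unscorable = sum(!ok))
}

#' Motif sensitivity of a break set
#'
#' A site counts as detected when at least one break record coincides
#' exactly with its `(chrom, pos, strand)` signal nucleotide; the incision
#' coordinate is deterministic under the positioning convention, so no
#' tolerance window is applied by default.
#'
#' @param breaks Break data.frame.
#' @param sites Motif sites from [find_motif_sites()].
#' @param slop Coordinate tolerance in bases for exploratory use
#'   (default 0).
#' @return List with `n_sites`, `n_detected`, `sensitivity`.
#' @export
motif_sensitivity <- function(breaks, sites, slop = 0L) {
  if (nrow(sites) == 0) stop("no motif sites in the genome")
  if (slop == 0) {
    key_b <- paste(breaks$chrom, breaks$pos, breaks$strand, sep = "\r")
    key_s <- paste(sites$chrom, sites$pos, sites$strand, sep = "\r")
    detected <- key_s %in% key_b
  } else {
    detected <- vapply(seq_len(nrow(sites)), function(i) {
      any(breaks$chrom == sites$chrom[i] & breaks$strand == sites$strand[i] &
            abs(breaks$pos - sites$pos[i]) <= slop)
    }, logical(1))
  }
  list(n_sites = nrow(sites), n_detected = sum(detected),
       sensitivity = sum(detected) / nrow(sites))
}

#' Complete nickase validation result
#'
#' Convenience wrapper combining [find_motif_sites()], [motif_precision()]
#' and [motif_sensitivity()].
#'
#' @param breaks Break data.frame.
#' @param genome A [Genome()] object.
#' @param motif Recognition sequence.
#' @return List merging the precision and sensitivity components.
#' @export
validate_nickase <- function(breaks, genome, motif) {
  sites <- find_motif_sites(genome, motif)
  prec <- motif_precision(breaks, genome, motif)
  sens <- motif_sensitivity(breaks, sites)
  c(prec, sens)
}

#' One-sided Mann-Whitney U test: treated greater than control
#'
#' Tests whether per-bin normalized break counts of the treated sample are
#' stochastically greater than the control's. Without ties and for modest
#' group sizes the exact U distribution is used; otherwise the normal
#' approximation with average ranks, tie correction and continuity
#' correction.
#'
#' @param treated_bins,control_bins `BinTrack` data.frames from
#'   [bin_genome()] on a matched bin grid, or bare numeric vectors.
#' @return List with `p_value`, `statistic` (U for the treated group) and
#'   `degenerate` (TRUE when all values in both groups are identical, in
#'   which case p = 1).
#' @export
mannwhitney_treated_vs_control <- function(treated_bins, control_bins) {
  x <- if (is.data.frame(treated_bins)) treated_bins$C else treated_bins
  y <- if (is.data.frame(control_bins)) control_bins$C else control_bins
  if (is.data.frame(treated_bins) && is.data.frame(control_bins) &&
      nrow(treated_bins) != nrow(control_bins)) {
    stop("treated and control tracks must share the bin grid")
  }
  if (length(x) + length(y) < 8) stop("need at least 8 bins in total")
  if (length(unique(c(x, y))) == 1) {
    return(list(p_value = 1, statistic = length(x) * length(y) / 2,
                degenerate = TRUE))
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- !has_ties && length(x) <= 50 && length(y) <= 50
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                            exact = exact, correct = TRUE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       degenerate = FALSE)
}

#' Correlate a break landscape with a feature track, per bin
#'
#' Feature abundance per bin is the number of peak intervals overlapping the
#' bin (for a peak track) or the summed TPM of genes whose TSS falls in the
#' bin (for expression). The association is Spearman's rho over bins.
#'
#' @param bintrack A `BinTrack` from [bin_genome()].
#' @param feature Either a peak data.frame (`chrom, start, end`) or a gene
#'   model data.frame with `tss` and `tpm` columns.
#' @param mode `"count"` (overlapping peaks; default) or `"coverage"`
#'   (bases covered by peaks) for peak tracks.
#' @return List with `rho` and `defined` (FALSE when the feature has zero
#'   variance across bins).
#' @export
feature_correlation <- function(bintrack, feature,
                                mode = c("count", "coverage")) {
  mode <- match.arg(mode)
  bins <- GenomicRanges::GRanges(bintrack$chrom,
                                 IRanges::IRanges(bintrack$start + 1L,
                                                  bintrack$end))
  if (all(c("tss", "tpm") %in% names(feature))) {
    tss <- GenomicRanges::GRanges(feature$chrom,
                                  IRanges::IRanges(feature$tss + 1L,
                                                   width = 1L))
    hits <- GenomicRanges::findOverlaps(tss, bins, ignore.strand = TRUE)
    abundance <- rep(0, nrow(bintrack))
    agg <- tapply(feature$tpm[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits), sum)
    abundance[as.integer(names(agg))] <- agg
  } else {
    peaks <- GenomicRanges::GRanges(feature$chrom,
                                    IRanges::IRanges(feature$start + 1L,
                                                     feature$end))
    if (mode == "count") {
      abundance <- GenomicRanges::countOverlaps(bins, peaks,
                                                ignore.strand = TRUE)
    } else {
      cov <- GenomicRanges::coverage(GenomicRanges::reduce(peaks))
      abundance <- vapply(seq_len(nrow(bintrack)), function(i) {
        chrom <- bintrack$chrom[i]
        if (!chrom %in% names(cov)) return(0)
        v <- cov[[chrom]]
        lo <- bintrack$start[i] + 1L
        hi <- min(bintrack$end[i], length(v))
        if (lo > hi) 0 else sum(as.integer(S4Vectors::window(v, lo, hi)))
      }, numeric(1))
    }
  }
  if (stats::sd(abundance) == 0 || stats::sd(bintrack$C) == 0) {
    warning("zero-variance input: correlation undefined")
    return(list(rho = NA_real_, defined = FALSE))
  }
  list(rho = stats::cor(bintrack$C, abundance, method = "spearman"),
       defined = TRUE)
}
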