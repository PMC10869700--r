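# Per-gene / per-strand-class break quantification, the sample normalization
# factor anchored on unexpressed genes, expression tiers, and genomic
# binning. Normalized counts are C(s,f) = N(s,f) / (L(f) * M(s)) in
# arbitrary units, where M(s) is the mean break density (breaks per kb) on
# the transcribed strands of unexpressed genes — so the mean normalized
# count of that reference class is exactly 1.

#' Transcribed (template) strand of a gene
#'
#' The transcribed strand is the template (antisense) strand: the opposite of
#' the annotation strand.
#'
#' @param annotation_strand Character vector over `{"+", "-"}` (or a gene
#'   data.frame, from which the `strand` column is taken).
#' @return Character vector of transcribed-strand symbols.
#' @export
transcribed_strand <- function(annotation_strand) {
  if (is.data.frame(annotation_strand)) {
    annotation_strand <- annotation_strand$strand
  }
  other_strand(annotation_strand)
}

# GRanges of break signal nucleotides (1-based width-1) and gene bodies.
breaks_gr <- function(breaks) {
  GenomicRanges::GRanges(breaks$chrom,
                         IRanges::IRanges(breaks$pos + 1L, width = 1L))
}

genes_gr <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start + 1L, genes$end))
}

#' Count breaks per gene and strand class
#'
#' Breaks are counted over the genomic gene-body interval `[start, end)`
#' regardless of orientation; a break whose signal nucleotide coordinate
#' equals `end` is outside (half-open). A break on the transcribed (template)
#' strand of the gene is counted in strand class `transcribed`; a break on
#' the annotation (sense) strand in `non_transcribed`. Breaks in regions
#' shared by overlapping genes count for every overlapping gene.
#'
#' @param breaks Break data.frame (`chrom, pos, strand, ...`); row
#'   multiplicity encodes abundance.
#' @param genes Gene model data.frame.
#' @return Data.frame with one row per gene x strand class: `gene_id`,
#'   `strand_class`, `N` (raw count) and `L_kb` (gene length in kb).
#' @export
count_gene_breaks <- function(breaks, genes) {
  n <- nrow(genes)
  N_ts <- integer(n)
  N_nts <- integer(n)
  if (nrow(breaks) > 0 && n > 0) {
    hits <- GenomicRanges::findOverlaps(breaks_gr(breaks), genes_gr(genes),
                                        ignore.strand = TRUE)
    bi <- S4Vectors::queryHits(hits)
    gi <- S4Vectors::subjectHits(hits)
    is_ts <- breaks$strand[bi] == transcribed_strand(genes$strand[gi])
    N_ts <- tabulate(gi[is_ts], nbins = n)
    N_nts <- tabulate(gi[!is_ts], nbins = n)
  }
  data.frame(
    gene_id = rep(genes$gene_id, 2),
    strand_class = rep(c("transcribed", "non_transcribed"), each = n),
    N = c(N_ts, N_nts),
    L_kb = rep(genes$length_kb, 2),
    stringsAsFactors = FALSE)
}

#' Sample normalization factor from unexpressed genes
#'
#' `M(s)` is the arithmetic mean of `N / L_kb` over the transcribed strands
#' of not-expressed genes: the endogenous break density the treatment cannot
#' have caused. After normalization by `M`, the mean normalized count of
#' that reference class is exactly 1.
#'
#' @param gene_counts Output of [count_gene_breaks()].
#' @param tiers Output of [assign_tiers()] (or any data.frame with `gene_id`
#'   and `tier` columns).
#' @return The scalar `M > 0`.
#' @export
normalization_factor <- function(gene_counts, tiers) {
  unexpr <- tiers$gene_id[tiers$tier == "not_expressed"]
  ref <- gene_counts[gene_counts$strand_class == "transcribed" &
                       gene_counts$gene_id %in% unexpr, , drop = FALSE]
  if (nrow(ref) == 0) {
    stop("normalization reference class empty: no unexpressed genes")
  }
  M <- mean(ref$N / ref$L_kb)
  if (M == 0) {
    stop(paste0("normalization factor is 0 (no breaks on transcribed ",
                "strands of unexpressed genes); consider a pseudocount"))
  }
  M
}

#' Normalize gene break counts
#'
#' Fills `C = N / (L_kb * M)`; raw `N` and `L_kb` are retained.
#'
#' @param gene_counts Output of [count_gene_breaks()].
#' @param M Sample normalization factor (> 0).
#' @return `gene_counts` with a `C` column added.
#' @export
normalize_counts <- function(gene_counts, M) {
  stopifnot(M > 0)
  gene_counts$C <- gene_counts$N / (gene_counts$L_kb * M)
  gene_counts
}

tier_cuts <- c(25, 50, 70, 80, 90, 95, 100)
tier_labels <- c("not_expressed", paste0("<=", tier_cuts, "%"))

#' Assign expression tiers by TPM percentile
#'
#' Genes with TPM exactly 0 (or at most `tpm_zero_threshold`) form the
#' `not_expressed` class. Expressed genes are ranked by TPM and assigned the
#' smallest cut point among 25/50/70/80/90/95/100 that is >= their
#' average-rank percentile; average ranks guarantee that equal TPMs never
#' straddle a tier boundary.
#'
#' @param genes Gene model data.frame with a `tpm` column.
#' @param tpm_zero_threshold TPM at or below which a gene counts as not
#'   expressed (default 0).
#' @return Data.frame with `gene_id`, `tpm` and ordered factor `tier`.
#' @export
assign_tiers <- function(genes, tpm_zero_threshold = 0) {
  tier <- rep(tier_labels[1], nrow(genes))
  expressed <- genes$tpm > tpm_zero_threshold
  if (any(expressed)) {
    pct <- 100 * rank(genes$tpm[expressed], ties.method = "average") /
      sum(expressed)
    idx <- findInterval(pct, tier_cuts, left.open = TRUE) + 1L
    tier[expressed] <- tier_labels[idx + 1L]
  }
  data.frame(gene_id = genes$gene_id, tpm = genes$tpm,
             tier = factor(tier, levels = tier_labels, ordered = TRUE),
             stringsAsFactors = FALSE)
}

#' Select the top expressed protein-coding genes
#'
#' The gene set used for metagene profiles and context analysis: the top
#' `fraction` of protein-coding genes ranked by TPM (ties kept together by
#' average rank, so the set may be slightly larger than `fraction * n`).
#'
#' @param genes Gene model data.frame with `tpm` and `coding`.
#' @param fraction Fraction of coding genes to keep (default 0.30).
#' @return Subset of `genes`.
#' @export
top_expressed_genes <- function(genes, fraction = 0.30) {
  stopifnot(fraction > 0, fraction <= 1)
  g <- genes[genes$coding, , drop = FALSE]
  pct <- rank(g$tpm, ties.method = "average") / nrow(g)
  out <- g[pct > 1 - fraction, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Box-plot style summary of normalized counts per tier and strand class
#'
#' For each expression tier and strand class: n, mean, median, quartiles
#' (linear interpolation), and whiskers extending to the furthest data point
#' within 1.5 times the interquartile range of the box.
#'
#' @param gene_counts Normalized counts from [normalize_counts()].
#' @param tiers Output of [assign_tiers()].
#' @return Data.frame with one row per tier x strand class; statistics are
#'   `NA` for empty tiers (n = 0).
#' @export
summarize_tiers <- function(gene_counts, tiers) {
  gc2 <- merge(gene_counts, tiers[, c("gene_id", "tier")], by = "gene_id")
  grid <- expand.grid(tier = tier_labels,
                      strand_class = c("transcribed", "non_transcribed"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- gc2$C[gc2$tier == grid$tier[i] &
                 gc2$strand_class == grid$strand_class[i]]
    if (length(x) == 0) {
      return(data.frame(tier = grid$tier[i],
                        strand_class = grid$strand_class[i], n = 0L,
                        mean = NA_real_, median = NA_real_, q1 = NA_real_,
                        q3 = NA_real_, whisker_lo = NA_real_,
                        whisker_hi = NA_real_))
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(tier = grid$tier[i], strand_class = grid$strand_class[i],
               n = length(x), mean = mean(x), median = q[2], q1 = q[1],
               q3 = q[3],
               whisker_lo = min(x[x >= q[1] - 1.5 * iqr]),
               whisker_hi = max(x[x <= q[3] + 1.5 * iqr]))
  })
  out <- do.call(rbind, rows)
  out$tier <- factor(out$tier, levels = tier_labels, ordered = TRUE)
  out[order(out$strand_class, out$tier), , drop = FALSE]
}

#' Spearman correlation of expression and normalized break count
#'
#' Computed on the continuous (untiered) TPM and C values of one strand
#' class, with average ranks for ties.
#'
#' @param gene_counts Normalized counts from [normalize_counts()].
#' @param genes Gene model data.frame with `tpm`.
#' @param strand_class `"transcribed"` or `"non_transcribed"`.
#' @return List with `rho` (NA when undefined) and `defined` (FALSE when
#'   either vector is constant).
#' @export
spearman_expression_correlation <- function(gene_counts, genes,
                                            strand_class = "transcribed") {
  sel <- gene_counts[gene_counts$strand_class == strand_class, , drop = FALSE]
  if (nrow(sel) < 3) stop("need at least 3 genes")
  tpm <- genes$tpm[match(sel$gene_id, genes$gene_id)]
  if (stats::sd(tpm) == 0 || stats::sd(sel$C) == 0) {
    warning("constant input vector: Spearman correlation undefined")
    return(list(rho = NA_real_, defined = FALSE))
  }
  list(rho = stats::cor(tpm, sel$C, method = "spearman"), defined = TRUE)
}

#' Bin break counts along the genome
#'
#' Tiles every chromosome with fixed-width bins (the last bin of a
#' chromosome may be short), counts break records per bin (half-open: a
#' break at coordinate `k * width` belongs to bin `k`), and normalizes with
#' the same `C = N / (L_kb * M)` formula, where `L_kb` is the actual bin
#' width in kb.
#'
#' @param breaks Break data.frame.
#' @param genome A [Genome()] object.
#' @param width Bin width in bases (default 100000).
#' @param strand_mode `"merged"` (both strands together) or `"separate"`.
#' @param M Sample normalization factor.
#' @return A `BinTrack` data.frame: `chrom, bin, start, end, strand, N, C`
#'   (strand is `"*"` in merged mode).
#' @export
bin_genome <- function(breaks, genome, width = 100000L,
                       strand_mode = c("merged", "separate"), M = 1) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(width >= 1, M > 0)
  breaks <- check_chromosomes(breaks, genome)
  lens <- genome_lengths(genome)
  strands <- if (strand_mode == "merged") "*" else c("+", "-")
  out <- list()
  for (chrom in names(genome)) {
    n_bins <- ceiling(lens[[chrom]] / width)
    starts <- (seq_len(n_bins) - 1L) * as.integer(width)
    ends <- pmin(starts + as.integer(width), lens[[chrom]])
    sel_chrom <- breaks$chrom == chrom
    for (s in strands) {
      sel <- sel_chrom & (s == "*" | breaks$strand == s)
      bin_idx <- breaks$pos[sel] %/% as.integer(width) + 1L
      N <- tabulate(bin_idx, nbins = n_bins)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, bin = seq_len(n_bins) - 1L, start = starts, end = ends,
        strand = s, N = N, C = N / (((ends - starts) / 1000) * M),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "width") <- as.integer(width)
  attr(res, "strand_mode") <- strand_mode
  class(res) <- c("BinTrack", "data.frame")
  res
}

#' Per-bin fold change relative to the sample median
#'
#' Divides each bin's normalized count by the median normalized count across
#' bins of the sample.
#'
#' @param bintrack A `BinTrack` from [bin_genome()].
#' @return The track with a `fold_change` column added; the output median is
#'   1 by construction.
#' @export
fold_change_vs_median <- function(bintrack) {
  med <- stats::median(bintrack$C)
  if (med == 0) {
    stop(paste0("median bin count is 0; exclude empty scaffolds before ",
                "computing fold changes"))
  }
  bintrack$fold_change <- bintrack$C / med
  bintrack
}
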