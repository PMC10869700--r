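# Metagene and TSS-anchored break profiles, divergent-transcription flank
# quantification, and gene-anchored G-content control. Gene coordinates are
# always oriented so the TSS is zero and transcription runs rightward.

#' Map a break into gene-anchored coordinates
#'
#' Coordinates are adjusted so the TSS is zero and gene directionality is
#' rightward: for a `+` gene the offset is `pos - TSS`, for a `-` gene
#' `TSS - pos`. The strand class is `transcribed` when the break strand
#' equals the gene's template strand, else `non_transcribed`.
#'
#' @param breaks Break data.frame.
#' @param gene One-row gene model data.frame.
#' @return Data.frame with `offset` (signed bases from TSS) and
#'   `strand_class` for the breaks on the gene's chromosome.
#' @export
to_gene_coordinates <- function(breaks, gene) {
  b <- breaks[breaks$chrom == gene$chrom, , drop = FALSE]
  offset <- if (gene$strand == "+") b$pos - gene$tss else gene$tss - b$pos
  data.frame(offset = as.integer(offset),
             strand_class = ifelse(b$strand == transcribed_strand(gene$strand),
                                   "transcribed", "non_transcribed"),
             stringsAsFactors = FALSE)
}

#' Profile binning specification
#'
#' Describes the gene-anchored window and its binning for
#' [metagene_profile()]: an upstream flank and a downstream flank in
#' absolute bins of `flank_bin` bases each, and a gene body divided into
#' `body_bins` relative bins each spanning the fraction `alpha = 1 /
#' body_bins` of the gene length.
#'
#' @param upstream,downstream Flank lengths in bases; must be multiples of
#'   `flank_bin`.
#' @param flank_bin Absolute flank bin width in bases.
#' @param body_bins Number of relative bins across the gene body.
#' @return A validated `ProfileSpec` list (`alpha = 1 / body_bins`).
#' @export
profile_spec <- function(upstream = 5000L, downstream = 5000L,
                         flank_bin = 250L, body_bins = 20L) {
  stopifnot(upstream >= 0, downstream >= 0, flank_bin >= 1, body_bins >= 1,
            upstream %% flank_bin == 0, downstream %% flank_bin == 0)
  structure(list(upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 flank_bin = as.integer(flank_bin),
                 body_bins = as.integer(body_bins),
                 alpha = 1 / body_bins),
            class = "ProfileSpec")
}

# Assign every break to every gene window it falls into, in gene-anchored
# coordinates. Returns (gene_idx, offset, strand_class) rows. `upstream` /
# `downstream` extend beyond the TSS / TES in gene orientation.
map_breaks_to_genes <- function(breaks, genes, upstream, downstream) {
  if (nrow(breaks) == 0 || nrow(genes) == 0) {
    return(data.frame(break_idx = integer(0), gene_idx = integer(0),
                      offset = integer(0), strand_class = character(0),
                      stringsAsFactors = FALSE))
  }
  win_start <- ifelse(genes$strand == "+", genes$start - upstream,
                      genes$start - downstream)
  win_end <- ifelse(genes$strand == "+", genes$end + downstream,
                    genes$end + upstream)
  win <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(win_start + 1L, win_end))
  hits <- GenomicRanges::findOverlaps(breaks_gr(breaks), win,
                                      ignore.strand = TRUE)
  bi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  plus <- genes$strand[gi] == "+"
  offset <- ifelse(plus, breaks$pos[bi] - genes$tss[gi],
                   genes$tss[gi] - breaks$pos[bi])
  sc <- ifelse(breaks$strand[bi] == transcribed_strand(genes$strand[gi]),
               "transcribed", "non_transcribed")
  data.frame(break_idx = bi, gene_idx = gi, offset = as.integer(offset),
             strand_class = sc, stringsAsFactors = FALSE)
}

# Genes whose full profile window fits inside the chromosome.
genes_with_full_window <- function(genes, genome, upstream, downstream) {
  lens <- genome_lengths(genome)[genes$chrom]
  lo <- ifelse(genes$strand == "+", genes$start - upstream,
               genes$start - downstream)
  hi <- ifelse(genes$strand == "+", genes$end + downstream,
               genes$end + upstream)
  lo >= 0 & hi <= lens
}

# Mean / 95% CI across genes for each column of a per-gene matrix of
# normalized counts.
profile_stats <- function(C_mat, bin_meta) {
  n <- nrow(C_mat)
  m <- colMeans(C_mat)
  se <- apply(C_mat, 2, stats::sd) / sqrt(n)
  cbind(bin_meta,
        data.frame(mean = m, ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se,
                   n_genes = n, row.names = NULL))
}

#' Metagene break profile with flanks and relative body bins
#'
#' For each gene of the set and each strand class, breaks are counted per
#' bin: absolute `flank_bin`-base bins across the upstream and downstream
#' flanks and `body_bins` relative bins each spanning the fraction
#' `alpha = 1 / body_bins` of the gene body (real-valued boundaries; a break
#' exactly on a boundary belongs to the higher bin). Bin counts are
#' normalized to break density `C = N / (L_bin_kb * M)` and averaged across
#' genes with a 95% confidence interval (normal approximation,
#' mean +/- 1.96 SE). Genes whose full window does not fit inside their
#' chromosome are excluded and counted.
#'
#' @param breaks Break data.frame.
#' @param genes Gene set `G` (e.g. top 30% expressed protein-coding genes).
#' @param genome A [Genome()] object.
#' @param spec A [profile_spec()].
#' @param M Sample normalization factor.
#' @return A `ProfileResult` data.frame: one row per strand class x bin with
#'   `region` (upstream/body/downstream), `bin`, `bin_start`/`bin_end`
#'   (gene-anchored; body bins in fractions of gene length), `mean`,
#'   `ci_lo`, `ci_hi`, `n_genes`; attribute `n_excluded` counts genes with
#'   truncated windows.
#' @export
metagene_profile <- function(breaks, genes, genome, spec = profile_spec(),
                             M = 1) {
  stopifnot(inherits(spec, "ProfileSpec"))
  if (nrow(genes) == 0) stop("empty gene set")
  full <- genes_with_full_window(genes, genome, spec$upstream, spec$downstream)
  n_excluded <- sum(!full)
  genes <- genes[full, , drop = FALSE]
  if (nrow(genes) == 0) stop("no gene retains a full profile window")

  n_up <- spec$upstream %/% spec$flank_bin
  n_down <- spec$downstream %/% spec$flank_bin
  n_bins <- n_up + spec$body_bins + n_down
  mapped <- map_breaks_to_genes(breaks, genes, spec$upstream, spec$downstream)

  gene_len <- genes$end - genes$start
  # per-gene bin lengths in kb: flanks fixed, body bins alpha * L(g)
  bin_len_kb <- cbind(
    matrix(spec$flank_bin / 1000, nrow(genes), n_up),
    matrix(rep(spec$alpha * gene_len / 1000, spec$body_bins), nrow(genes),
           spec$body_bins),
    matrix(spec$flank_bin / 1000, nrow(genes), n_down))

  bin_meta <- data.frame(
    region = c(rep("upstream", n_up), rep("body", spec$body_bins),
               rep("downstream", n_down)),
    bin = c(seq_len(n_up), seq_len(spec$body_bins), seq_len(n_down)),
    bin_start = c(-spec$upstream + (seq_len(n_up) - 1L) * spec$flank_bin,
                  (seq_len(spec$body_bins) - 1L) * spec$alpha,
                  (seq_len(n_down) - 1L) * spec$flank_bin),
    bin_end = c(-spec$upstream + seq_len(n_up) * spec$flank_bin,
                seq_len(spec$body_bins) * spec$alpha,
                seq_len(n_down) * spec$flank_bin))

  out <- list()
  for (sc in c("transcribed", "non_transcribed")) {
    sel <- mapped[mapped$strand_class == sc, , drop = FALSE]
    L <- gene_len[sel$gene_idx]
    off <- sel$offset
    bin_id <- integer(nrow(sel))
    up <- off < 0
    body <- off >= 0 & off < L
    down <- off >= L
    bin_id[up] <- (off[up] + spec$upstream) %/% spec$flank_bin + 1L
    bin_id[body] <- n_up +
      pmin(floor(off[body] / (spec$alpha * L[body])), spec$body_bins - 1) + 1L
    bin_id[down] <- n_up + spec$body_bins +
      (off[down] - L[down]) %/% spec$flank_bin + 1L
    inside <- bin_id >= 1L & bin_id <= n_bins
    N_mat <- matrix(0L, nrow(genes), n_bins)
    if (any(inside)) {
      tab <- table(factor(sel$gene_idx[inside], levels = seq_len(nrow(genes))),
                   factor(bin_id[inside], levels = seq_len(n_bins)))
      N_mat <- matrix(as.integer(tab), nrow(genes), n_bins)
    }
    C_mat <- N_mat / (bin_len_kb * M)
    st <- profile_stats(C_mat, bin_meta)
    st$strand_class <- sc
    out[[sc]] <- st
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_excluded") <- n_excluded
  class(res) <- c("ProfileResult", "data.frame")
  res
}

length_group_labels <- c("<=10kb", "<=22kb", "<=50kb", ">50kb")

# Gene-length stratum per the <=10 / <=22 / <=50 / >50 kb grouping
# (boundaries inclusive on the left-closed upper side).
gene_length_group <- function(length_kb, thresholds = c(10, 22, 50)) {
  idx <- findInterval(length_kb, thresholds, left.open = TRUE) + 1L
  factor(length_group_labels[idx], levels = length_group_labels)
}

#' TSS-anchored profile stratified by gene length
#'
#' Absolute-bin profile across a TSS-centered window (default +/- 5 kb), with
#' genes stratified into length groups (<=10, (10,22], (22,50], >50 kb by
#' default). The window is TSS-anchored: positions beyond a short gene's TES
#' are still counted. Genes whose window leaves the chromosome are excluded
#' and counted; empty groups are omitted with a warning.
#'
#' @param breaks Break data.frame.
#' @param genes Gene set data.frame.
#' @param genome A [Genome()] object.
#' @param window Half-window in bases (default 5000).
#' @param bin Bin width in bases; must divide `window`.
#' @param length_thresholds Group boundaries in kb.
#' @param M Sample normalization factor.
#' @return A `ProfileResult` data.frame with columns as in
#'   [metagene_profile()] plus `length_group`; `bin_start`/`bin_end` are
#'   TSS-relative bases.
#' @export
tss_profile_by_length <- function(breaks, genes, genome, window = 5000L,
                                  bin = 100L, length_thresholds = c(10, 22, 50),
                                  M = 1) {
  stopifnot(window %% bin == 0)
  lens <- genome_lengths(genome)[genes$chrom]
  lo <- genes$tss - window
  hi <- genes$tss + window
  full <- lo >= 0 & hi <= lens
  n_excluded <- sum(!full)
  genes <- genes[full, , drop = FALSE]
  if (nrow(genes) == 0) stop("no gene retains a full TSS window")

  group <- gene_length_group(genes$length_kb, length_thresholds)
  window <- as.integer(window)
  bin <- as.integer(bin)
  n_bins <- 2L * window %/% bin
  bin_meta <- data.frame(
    region = "tss_window", bin = seq_len(n_bins),
    bin_start = -window + (seq_len(n_bins) - 1L) * bin,
    bin_end = -window + seq_len(n_bins) * bin)
  mapped_all <- local({
    # map against TSS-centered pseudo-genes so offsets are TSS-anchored
    pg <- genes
    pg$start <- ifelse(genes$strand == "+", genes$tss, genes$tss)
    pg$end <- pg$start + 1L
    pg$tss <- genes$tss
    map_breaks_to_genes(breaks, pg, window, window - 1L)
  })

  out <- list()
  for (lg in levels(group)) {
    gsel <- which(group == lg)
    if (length(gsel) == 0) {
      warning("empty gene-length group omitted: ", lg)
      next
    }
    for (sc in c("transcribed", "non_transcribed")) {
      sel <- mapped_all[mapped_all$strand_class == sc &
                          mapped_all$gene_idx %in% gsel, , drop = FALSE]
      off <- sel$offset
      inside <- off >= -window & off < window
      bin_id <- (off[inside] + window) %/% bin + 1L
      N_mat <- matrix(0L, length(gsel), n_bins)
      if (any(inside)) {
        tab <- table(factor(match(sel$gene_idx[inside], gsel),
                            levels = seq_along(gsel)),
                     factor(bin_id, levels = seq_len(n_bins)))
        N_mat <- matrix(as.integer(tab), length(gsel), n_bins)
      }
      C_mat <- N_mat / ((bin / 1000) * M)
      st <- profile_stats(C_mat, bin_meta)
      st$strand_class <- sc
      st$length_group <- lg
      out[[paste(lg, sc)]] <- st
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_excluded") <- n_excluded
  class(res) <- c("ProfileResult", "data.frame")
  res
}

#' Strand-specific G content in gene-anchored coordinates
#'
#' Mean fraction of G on each strand class per bin across a TSS-centered
#' window, computed from the reference genome. On the non-transcribed
#' (sense) strand the G fraction at a position is the fraction of reference
#' G (for `+` genes) read in gene orientation; the transcribed strand is its
#' complement, so its G fraction equals the sense-strand C fraction.
#'
#' @param genes Gene set data.frame.
#' @param genome A [Genome()] object.
#' @param window Half-window around the TSS in bases.
#' @param bin Bin width in bases; must divide `window`.
#' @return Data.frame with `strand_class`, `bin_start`, `bin_end`,
#'   `g_fraction`, `n_genes`.
#' @export
gc_profile <- function(genes, genome, window = 5000L, bin = 100L) {
  stopifnot(window %% bin == 0)
  lens <- genome_lengths(genome)[genes$chrom]
  full <- genes$tss - window >= 0 & genes$tss + window <= lens
  genes <- genes[full, , drop = FALSE]
  if (nrow(genes) == 0) stop("no gene retains a full TSS window")
  n_bins <- as.integer(2L * window %/% bin)
  g_counts <- matrix(0, nrow(genes), n_bins)  # sense-strand G
  c_counts <- matrix(0, nrow(genes), n_bins)  # sense-strand C
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    seq <- genome_subseq(genome, g$chrom, g$tss - window, g$tss + window)
    if (g$strand == "-") seq <- revcomp(seq)
    raw <- charToRaw(seq)
    g_counts[i, ] <- colSums(matrix(raw == as.raw(71L), nrow = bin)) / bin
    c_counts[i, ] <- colSums(matrix(raw == as.raw(67L), nrow = bin)) / bin
  }
  meta <- data.frame(bin_start = -window + (seq_len(n_bins) - 1L) * bin,
                     bin_end = -window + seq_len(n_bins) * bin)
  rbind(
    cbind(data.frame(strand_class = "non_transcribed"), meta,
          data.frame(g_fraction = colMeans(g_counts), n_genes = nrow(genes))),
    cbind(data.frame(strand_class = "transcribed"), meta,
          data.frame(g_fraction = colMeans(c_counts), n_genes = nrow(genes))))
}

#' Per-gene normalized counts in the two divergent-transcription flanks
#'
#' For each gene: the normalized break count within `flank` bases downstream
#' of the TSS on the transcribed strand (the gene-body branch) and within
#' `flank` bases upstream of the TSS on the non-transcribed strand (the
#' divergent branch), both with `L = flank` kb in the normalization. Genes
#' whose upstream or downstream flank leaves the chromosome are excluded and
#' counted.
#'
#' @param breaks Break data.frame.
#' @param genes Gene set data.frame.
#' @param genome A [Genome()] object.
#' @param flank Flank length in bases (default 5000).
#' @param M Sample normalization factor.
#' @return Data.frame with one row per retained gene: `gene_id`,
#'   `C_downstream_ts`, `C_upstream_nts`; attribute `n_excluded`.
#' @export
flank_counts <- function(breaks, genes, genome, flank = 5000L, M = 1) {
  lens <- genome_lengths(genome)[genes$chrom]
  full <- genes$tss - flank >= 0 & genes$tss + flank <= lens
  n_excluded <- sum(!full)
  genes <- genes[full, , drop = FALSE]
  mapped <- map_breaks_to_genes(breaks, local({
    pg <- genes
    pg$start <- genes$tss
    pg$end <- genes$tss + 1L
    pg
  }), flank, flank - 1L)
  down <- mapped$offset >= 0 & mapped$offset < flank &
    mapped$strand_class == "transcribed"
  up <- mapped$offset < 0 & mapped$offset >= -flank &
    mapped$strand_class == "non_transcribed"
  n <- nrow(genes)
  N_down <- tabulate(mapped$gene_idx[down], nbins = n)
  N_up <- tabulate(mapped$gene_idx[up], nbins = n)
  out <- data.frame(gene_id = genes$gene_id,
                    C_downstream_ts = N_down / ((flank / 1000) * M),
                    C_upstream_nts = N_up / ((flank / 1000) * M),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Endogenous-background threshold for the divergent branch
#'
#' The upper quartile (75th percentile, linear interpolation) of the
#' upstream non-transcribed-strand flank count among not-expressed genes:
#' breaks below it are consistent with endogenous damage not caused by the
#' treatment. Also reports, per expression tier, the fraction of genes whose
#' upstream flank count falls below the threshold.
#'
#' @param flanks Output of [flank_counts()].
#' @param tiers Output of [assign_tiers()].
#' @return List with `threshold` and `fraction_below` (named by tier).
#' @export
background_threshold <- function(flanks, tiers) {
  merged <- merge(flanks, tiers[, c("gene_id", "tier")], by = "gene_id")
  ref <- merged$C_upstream_nts[merged$tier == "not_expressed"]
  if (length(ref) < 4) {
    stop("need at least 4 unexpressed genes for the background threshold")
  }
  thr <- unname(stats::quantile(ref, 0.75))
  frac <- vapply(tier_labels, function(tl) {
    x <- merged$C_upstream_nts[merged$tier == tl]
    if (length(x) == 0) NA_real_ else mean(x < thr)
  }, numeric(1))
  list(threshold = thr, fraction_below = frac)
}

#' Select breaks in the regions most affected by transcription-coupled damage
#'
#' Keeps break records on the transcribed strand within a gene body
#' `[TSS, TES]` or on the non-transcribed strand within `upstream` bases
#' upstream of the TSS, tagging each kept break with its region. Used to
#' restrict sequence-context analysis to regions where incision-derived
#' breaks dominate the background.
#'
#' @param breaks Break data.frame.
#' @param genes Gene set data.frame.
#' @param upstream Upstream reach in bases (default 5000).
#' @return Subset of `breaks` with a `region` column
#'   (`"body"`/`"upstream"`); a break satisfying both rules for different
#'   genes is kept once per rule.
#' @export
select_breaks_in_regions <- function(breaks, genes, upstream = 5000L) {
  mapped <- map_breaks_to_genes(breaks, genes, upstream, 0L)
  L <- (genes$end - genes$start)[mapped$gene_idx]
  body <- mapped$strand_class == "transcribed" &
    mapped$offset >= 0 & mapped$offset < L
  up <- mapped$strand_class == "non_transcribed" &
    mapped$offset < 0 & mapped$offset >= -upstream
  sel <- body | up
  out <- breaks[mapped$break_idx[sel], , drop = FALSE]
  out$region <- ifelse(body[sel], "body", "upstream")
  rownames(out) <- NULL
  out
}
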