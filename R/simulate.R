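# Synthetic-data generator: genomes, gene sets with expression, planted
# break landscapes with the statistical structure the downstream analysis
# assumes, read simulation (the inverse of break calling), and a
# nicking-endonuclease control. Everything is deterministic under the
# configured seed.

#' Simulation configuration
#'
#' Bundles all generator parameters with validation. The damage model the
#' generator plants is multiplicative Poisson:
#'
#' * transcribed (template) strand of an expressed gene, distance `d`
#'   downstream of the TSS inside the gene body:
#'   rate per kb = `breaks_per_kb_at_reference_tpm * (tpm / reference_tpm) *
#'   exp(-d / tss_decay_length)`;
#' * non-transcribed strand, distance `u` upstream of the TSS within
#'   `divergent_extent` (the divergent-transcription branch):
#'   `divergent_ratio` times the same TPM-scaled decaying rate;
#' * both strands are zero within `promoter_dead_zone` bases immediately
#'   upstream of the TSS;
#' * a uniform endogenous background of `background_rate` breaks per kb on
#'   each strand, genome-wide, unaffected by the incision sequence
#'   preference.
#'
#' Incision-derived breaks (transcribed and divergent components) at
#' positions whose base one nucleotide downstream of the signal nucleotide
#' (offset +1; "+2 relative to the break") is G carry a multiplicative
#' intensity weight `g_plus2_weight`.
#'
#' @param seed Integer seed fixing every generated byte.
#' @param genome_length Genome size in bases.
#' @param gc_fraction GC content of the i.i.d. genome.
#' @param n_genes Number of genes.
#' @param gene_length_bounds Log-uniform bounds (bases) for gene lengths.
#' @param unexpressed_fraction Fraction of genes with TPM exactly 0
#'   (`round(n_genes * unexpressed_fraction)` genes).
#' @param tpm_meanlog,tpm_sdlog Log-normal parameters of expressed-gene TPM.
#' @param breaks_per_kb_at_reference_tpm Transcribed-strand rate anchor:
#'   expected breaks/kb at the TSS of a gene expressed at `reference_tpm`.
#' @param reference_tpm TPM at which the rate anchor applies.
#' @param tss_decay_length Exponential decay length (bases) of damage
#'   downstream of the TSS.
#' @param divergent_ratio Upstream (non-transcribed strand) intensity
#'   relative to the downstream transcribed-strand intensity.
#' @param divergent_extent Reach of the divergent branch upstream of the TSS
#'   (bases).
#' @param promoter_dead_zone Promoter region upstream of the TSS devoid of
#'   induced breaks on both strands (bases).
#' @param background_rate Uniform endogenous background, breaks per kb per
#'   strand.
#' @param g_plus2_weight Multiplicative intensity preference (>= 1) for a G
#'   one base downstream of the signal nucleotide.
#' @param read_length Simulated read length (bases).
#' @param mean_fragment Mean sonication fragment length (bases).
#' @param duplication_rate Per-break probability of PCR duplication; the
#'   number of extra copies is geometric with this success probability.
#' @param umi_length UMI length (bases).
#' @return A validated `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 1e6,
                       gc_fraction = 0.5,
                       n_genes = 50L,
                       gene_length_bounds = c(2000, 50000),
                       unexpressed_fraction = 0.12,
                       tpm_meanlog = 2,
                       tpm_sdlog = 1.2,
                       breaks_per_kb_at_reference_tpm = 2,
                       reference_tpm = 10,
                       tss_decay_length = 1500,
                       divergent_ratio = 0.5,
                       divergent_extent = 5000,
                       promoter_dead_zone = 100,
                       background_rate = 0.5,
                       g_plus2_weight = 3,
                       read_length = 100L,
                       mean_fragment = 300,
                       duplication_rate = 0.2,
                       umi_length = 10L) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
              gene_length_bounds = gene_length_bounds,
              unexpressed_fraction = unexpressed_fraction,
              tpm_meanlog = tpm_meanlog, tpm_sdlog = tpm_sdlog,
              breaks_per_kb_at_reference_tpm = breaks_per_kb_at_reference_tpm,
              reference_tpm = reference_tpm,
              tss_decay_length = tss_decay_length,
              divergent_ratio = divergent_ratio,
              divergent_extent = as.integer(divergent_extent),
              promoter_dead_zone = as.integer(promoter_dead_zone),
              background_rate = background_rate,
              g_plus2_weight = g_plus2_weight,
              read_length = as.integer(read_length),
              mean_fragment = mean_fragment,
              duplication_rate = duplication_rate,
              umi_length = as.integer(umi_length))
  stopifnot(cfg$genome_length > 0,
            cfg$gc_fraction > 0, cfg$gc_fraction < 1,
            cfg$n_genes >= 0,
            length(cfg$gene_length_bounds) == 2,
            cfg$gene_length_bounds[1] > 0,
            cfg$gene_length_bounds[1] <= cfg$gene_length_bounds[2],
            cfg$unexpressed_fraction >= 0, cfg$unexpressed_fraction <= 1,
            cfg$breaks_per_kb_at_reference_tpm >= 0,
            cfg$reference_tpm > 0,
            cfg$tss_decay_length > 0,
            cfg$divergent_ratio >= 0, cfg$divergent_ratio <= 1,
            cfg$divergent_extent >= 0,
            cfg$promoter_dead_zone >= 0,
            cfg$background_rate >= 0,
            cfg$g_plus2_weight >= 1,
            cfg$read_length >= 20,
            cfg$mean_fragment >= 20,
            cfg$duplication_rate >= 0, cfg$duplication_rate < 1,
            cfg$umi_length >= 1)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Choose the G-preference weight for a target context fraction
#'
#' On an i.i.d. genome where the probability of G at any position of a strand
#' is `p_g`, a multiplicative weight `w` on G-context positions produces an
#' expected G fraction at offset +1 of `w * p_g / (w * p_g + 1 - p_g)`.
#' This helper inverts that relation.
#'
#' @param target_fraction Desired G fraction at offset +1 among
#'   incision-derived breaks.
#' @param gc_fraction GC content of the genome (per-strand G probability is
#'   `gc_fraction / 2`).
#' @return The weight `w`.
#' @export
g_weight_for_fraction <- function(target_fraction, gc_fraction = 0.5) {
  p <- gc_fraction / 2
  stopifnot(target_fraction > 0, target_fraction < 1, p > 0, p < 1)
  target_fraction * (1 - p) / (p * (1 - target_fraction))
}

#' Simulate a genome and a non-overlapping gene set with expression
#'
#' Bases are i.i.d. at the configured GC content. Genes are placed without
#' overlap, separated by at least `2 * divergent_extent`, with random
#' strands. Exactly `round(n_genes * unexpressed_fraction)` genes get TPM 0;
#' the rest draw log-normal TPMs. All genes are flagged protein-coding.
#'
#' @param config A [sim_config()] object.
#' @return List with `genome` ([Genome()]) and `genes` (gene model
#'   data.frame as from [read_genes()]).
#' @export
simulate_genome_and_genes <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withr::with_seed(derive_seed(config$seed, 1L), {
    p <- c(A = (1 - config$gc_fraction) / 2, C = config$gc_fraction / 2,
           G = config$gc_fraction / 2, T = (1 - config$gc_fraction) / 2)
    seq <- paste(sample(names(p), config$genome_length, replace = TRUE,
                        prob = p), collapse = "")
    genome <- Genome(c(chr1 = seq))

    n <- config$n_genes
    if (n == 0) {
      genes <- finalize_genes(data.frame(gene_id = character(0),
                                         chrom = character(0),
                                         start = integer(0), end = integer(0),
                                         strand = character(0),
                                         coding = logical(0),
                                         tpm = numeric(0)))
      return(list(genome = genome, genes = genes))
    }
    lb <- log(config$gene_length_bounds)
    lens <- as.integer(round(exp(stats::runif(n, lb[1], lb[2]))))
    spacing <- 2L * config$divergent_extent
    needed <- sum(lens) + (n + 1L) * spacing
    if (needed > config$genome_length) {
      stop(sprintf(paste0("cannot pack %d genes (%d bases incl. spacing) ",
                          "into a %d-base genome; increase genome_length"),
                   n, needed, config$genome_length))
    }
    # distribute the slack randomly across the n+1 gaps
    slack <- config$genome_length - needed
    cuts <- sort(sample.int(slack + 1L, n + 1L, replace = TRUE) - 1L)
    extra <- diff(c(0L, cuts))
    starts <- integer(n)
    cursor <- 0L
    for (i in seq_len(n)) {
      cursor <- cursor + spacing + extra[i]
      starts[i] <- cursor
      cursor <- cursor + lens[i]
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tpm <- stats::rlnorm(n, config$tpm_meanlog, config$tpm_sdlog)
    n_unexpr <- round(n * config$unexpressed_fraction)
    if (n_unexpr > 0) tpm[sample.int(n, n_unexpr)] <- 0
    genes <- finalize_genes(data.frame(
      gene_id = sprintf("gene%04d", seq_len(n)), chrom = "chr1",
      start = starts, end = starts + lens, strand = strand,
      coding = TRUE, tpm = tpm, stringsAsFactors = FALSE))
    list(genome = genome, genes = genes)
  })
}

# Per-position Poisson draw over a lambda vector; returns 0-based positions
# (relative to `offset0`) repeated by their drawn counts.
draw_positions <- function(lambda, offset0 = 0L) {
  counts <- stats::rpois(length(lambda), lambda)
  nz <- which(counts > 0L)
  rep(offset0 + nz - 1L, counts[nz])
}

# Precomputed per-chromosome indicators of reference G and C bases.
base_flags <- function(genome) {
  lapply(unclass(genome), function(seq) {
    raw <- charToRaw(seq)
    list(G = raw == as.raw(71L), C = raw == as.raw(67L))
  })
}

# G-context indicator for candidate signal positions: TRUE when the base one
# position downstream of the signal nucleotide, read on `strand`, is G.
# On the "+" strand that is a reference G at pos + 1; on the "-" strand a
# reference C at pos - 1 (its complement on the minus strand is G).
g_at_plus1 <- function(flags, chrom, pos, strand) {
  f <- flags[[chrom]]
  len <- length(f$G)
  nb_pos <- ifelse(strand == "+", pos + 1L, pos - 1L)
  ok <- nb_pos >= 0L & nb_pos < len
  out <- logical(length(pos))
  plus <- ok & strand == "+"
  minus <- ok & strand == "-"
  out[plus] <- f$G[nb_pos[plus] + 1L]
  out[minus] <- f$C[nb_pos[minus] + 1L]
  out
}

#' Plant a break landscape with known structure
#'
#' Draws breaks from the inhomogeneous Poisson damage model described in
#' [sim_config()], labels each break with its provenance (`transcribed`,
#' `divergent`, `background`), and records per-gene expected counts for the
#' gene body and the 5-kb flanks so recovery tests can compare against
#' closed-form truth.
#'
#' @param genome A [Genome()] object.
#' @param genes Gene model data.frame.
#' @param config A [sim_config()] object.
#' @return A `TruthSet`: list with `breaks` (break data.frame plus `label`
#'   column), `gene_expected` (per-gene expected counts: `body_ts`,
#'   `body_nts`, `flank_down_ts`, `flank_up_nts`) and `config`.
#' @export
plant_breaks <- function(genome, genes, config) {
  stopifnot(inherits(genome, "Genome"), inherits(config, "SimulationConfig"))
  withr::with_seed(derive_seed(config$seed, 2L), {
    lens <- genome_lengths(genome)
    flags <- base_flags(genome)
    per_base_bg <- config$background_rate / 1000

    all_chrom <- character(0); all_pos <- integer(0)
    all_strand <- character(0); all_label <- character(0)

    # uniform endogenous background, both strands, genome-wide
    if (per_base_bg > 0) {
      for (chrom in names(genome)) {
        for (strand in c("+", "-")) {
          pos <- draw_positions(rep(per_base_bg, lens[[chrom]]))
          all_chrom <- c(all_chrom, rep(chrom, length(pos)))
          all_pos <- c(all_pos, pos)
          all_strand <- c(all_strand, rep(strand, length(pos)))
          all_label <- c(all_label, rep("background", length(pos)))
        }
      }
    }

    n <- nrow(genes)
    expected <- data.frame(gene_id = genes$gene_id,
                           body_ts = 0, body_nts = 0,
                           flank_down_ts = 0, flank_up_nts = 0,
                           stringsAsFactors = FALSE)
    flank <- 5000L

    for (i in seq_len(n)) {
      g <- genes[i, ]
      clen <- lens[[g$chrom]]
      gene_len <- g$end - g$start
      base_rate <- config$breaks_per_kb_at_reference_tpm / 1000 *
        (g$tpm / config$reference_tpm)
      ts <- other_strand(g$strand)

      # transcribed-strand component over the gene body
      if (base_rate > 0) {
        d <- seq_len(gene_len) - 1L      # distance downstream of TSS
        lam <- base_rate * exp(-d / config$tss_decay_length)
        pos <- if (g$strand == "+") g$start + d else g$end - 1L - d
        gwt <- g_at_plus1(flags, g$chrom, pos, rep(ts, gene_len))
        lam <- lam * ifelse(gwt, config$g_plus2_weight, 1)
        hit <- draw_positions(lam)
        hit_pos <- pos[hit + 1L]
        all_chrom <- c(all_chrom, rep(g$chrom, length(hit_pos)))
        all_pos <- c(all_pos, hit_pos)
        all_strand <- c(all_strand, rep(ts, length(hit_pos)))
        all_label <- c(all_label, rep("transcribed", length(hit_pos)))
        expected$body_ts[i] <- sum(lam)
        expected$flank_down_ts[i] <- sum(lam[seq_len(min(flank, gene_len))])

        # divergent branch: non-transcribed strand, upstream of the TSS,
        # outside the promoter dead zone, within divergent_extent
        if (config$divergent_ratio > 0 &&
            config$divergent_extent > config$promoter_dead_zone) {
          u <- seq.int(config$promoter_dead_zone + 1L,
                       config$divergent_extent)  # distance upstream of TSS
          upos <- if (g$strand == "+") g$tss - u else g$tss + u
          inside <- upos >= 0L & upos < clen
          u <- u[inside]; upos <- upos[inside]
          if (length(u) > 0) {
            lam_u <- config$divergent_ratio * base_rate *
              exp(-u / config$tss_decay_length)
            gwt_u <- g_at_plus1(flags, g$chrom, upos,
                                rep(g$strand, length(upos)))
            lam_u <- lam_u * ifelse(gwt_u, config$g_plus2_weight, 1)
            hit <- draw_positions(lam_u)
            hit_pos <- upos[hit + 1L]
            all_chrom <- c(all_chrom, rep(g$chrom, length(hit_pos)))
            all_pos <- c(all_pos, hit_pos)
            all_strand <- c(all_strand, rep(g$strand, length(hit_pos)))
            all_label <- c(all_label, rep("divergent", length(hit_pos)))
            expected$flank_up_nts[i] <- sum(lam_u[u <= flank])
          }
        }
      }
      # expected background contributions to the recorded regions
      expected$body_ts[i] <- expected$body_ts[i] + per_base_bg * gene_len
      expected$body_nts[i] <- expected$body_nts[i] + per_base_bg * gene_len
      expected$flank_down_ts[i] <- expected$flank_down_ts[i] +
        per_base_bg * min(flank, gene_len)
      expected$flank_up_nts[i] <- expected$flank_up_nts[i] + per_base_bg * flank
    }

    breaks <- data.frame(chrom = all_chrom, pos = all_pos, strand = all_strand,
                         mapq = 60L, label = all_label,
                         stringsAsFactors = FALSE)
    o <- order(breaks$chrom, breaks$pos, breaks$strand)
    breaks <- breaks[o, , drop = FALSE]
    rownames(breaks) <- NULL
    structure(list(breaks = breaks, gene_expected = expected, config = config),
              class = "TruthSet")
  })
}

#' @export
print.TruthSet <- function(x, ...) {
  cat(sprintf("TruthSet: %d planted breaks (%s)\n", nrow(x$breaks),
              paste(sprintf("%s: %d", names(table(x$breaks$label)),
                            table(x$breaks$label)), collapse = ", ")))
  invisible(x)
}

# Random UMIs, one per row, as fixed-length strings.
random_umis <- function(n, umi_length) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * umi_length, replace = TRUE),
              nrow = n)
  apply(m, 1, paste, collapse = "")
}

#' Emit UMI-tagged reads for planted breaks
#'
#' Inverse of the break-positioning convention: a break with signal
#' nucleotide at `(pos, +)` yields a read on mapping strand `-` ending at
#' `pos` (half-open), and a break at `(pos, -)` yields a read on `+` starting
#' at `pos + 1`. Read length is the minimum of the configured read length,
#' a sonication fragment draw, and the distance to the chromosome edge; reads
#' that cannot reach 20 bases are skipped and counted. Each primary read gets
#' a fresh random UMI; PCR duplicates (geometric count with success
#' probability `duplication_rate`) share the primary read's coordinates and
#' UMI. Output order is a deterministic shuffle.
#'
#' @param truth A `TruthSet` from [plant_breaks()] or [simulate_nickase()].
#' @param genome A [Genome()] object.
#' @param config A [sim_config()] object.
#' @return List with `reads` (aligned-read data.frame) and `n_skipped`
#'   (breaks too close to a chromosome edge).
#' @export
breaks_to_reads <- function(truth, genome, config) {
  stopifnot(inherits(truth, "TruthSet"), inherits(genome, "Genome"),
            inherits(config, "SimulationConfig"))
  withr::with_seed(derive_seed(config$seed, 3L), {
    b <- truth$breaks
    n <- nrow(b)
    if (n == 0) {
      return(list(reads = data.frame(chrom = character(0), start = integer(0),
                                     end = integer(0), strand = character(0),
                                     umi = character(0), mapq = integer(0),
                                     stringsAsFactors = FALSE),
                  n_skipped = 0L))
    }
    lens <- genome_lengths(genome)[b$chrom]
    frag <- pmax(20L, as.integer(round(stats::rnorm(n, config$mean_fragment,
                                                    config$mean_fragment / 4))))
    avail <- ifelse(b$strand == "+", b$pos, lens - b$pos - 1L)
    L <- pmin(config$read_length, frag, avail)
    keep <- L >= 20L
    n_skipped <- sum(!keep)
    bk <- b[keep, , drop = FALSE]
    Lk <- L[keep]
    start <- ifelse(bk$strand == "+", bk$pos - Lk, bk$pos + 1L)
    end <- start + Lk
    reads <- data.frame(chrom = bk$chrom, start = as.integer(start),
                        end = as.integer(end),
                        strand = other_strand(bk$strand),
                        umi = random_umis(nrow(bk), config$umi_length),
                        mapq = sample(30:60, nrow(bk), replace = TRUE),
                        stringsAsFactors = FALSE)
    if (config$duplication_rate > 0 && nrow(reads) > 0) {
      n_extra <- stats::rgeom(nrow(reads), 1 - config$duplication_rate)
      idx <- rep(seq_len(nrow(reads)), n_extra)
      if (length(idx) > 0) {
        dup <- reads[idx, , drop = FALSE]
        dup$mapq <- sample(30:60, nrow(dup), replace = TRUE)
        reads <- rbind(reads, dup)
      }
    }
    reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
    rownames(reads) <- NULL
    list(reads = reads, n_skipped = n_skipped)
  })
}

#' Simulate a nicking-endonuclease control experiment
#'
#' For every occurrence of `motif` on either strand of the genome, a break is
#' planted with probability `efficiency`; its signal nucleotide is the first
#' base of the motif on that strand (the nick lies immediately 5' of the
#' motif). Uniform background breaks are added at `background_rate` per kb
#' per strand.
#'
#' @param genome A [Genome()] object.
#' @param motif Recognition sequence over A/C/G/T (length >= 4), e.g.
#'   `"CATTGC"` for Nb.BsrDI.
#' @param efficiency Per-site nicking probability in (0, 1].
#' @param background_rate Background breaks per kb per strand.
#' @param config A [sim_config()] object (seed, UMI/read parameters).
#' @return A `TruthSet` with labels `nickase`/`background` and a `sites`
#'   element holding all motif sites.
#' @export
simulate_nickase <- function(genome, motif, efficiency, background_rate,
                             config) {
  stopifnot(inherits(genome, "Genome"), inherits(config, "SimulationConfig"),
            efficiency > 0, efficiency <= 1, nchar(motif) >= 4,
            !grepl("[^ACGT]", motif))
  withr::with_seed(derive_seed(config$seed, 4L), {
    sites <- find_motif_sites(genome, motif)
    cut <- stats::runif(nrow(sites)) < efficiency
    nick <- sites[cut, , drop = FALSE]
    chrom <- nick$chrom; pos <- nick$pos; strand <- nick$strand
    label <- rep("nickase", nrow(nick))
    if (background_rate > 0) {
      per_base <- background_rate / 1000
      for (cn in names(genome)) {
        for (s in c("+", "-")) {
          bp <- draw_positions(rep(per_base, nchar(genome[[cn]])))
          chrom <- c(chrom, rep(cn, length(bp)))
          pos <- c(pos, bp)
          strand <- c(strand, rep(s, length(bp)))
          label <- c(label, rep("background", length(bp)))
        }
      }
    }
    breaks <- data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
                         mapq = 60L, label = label, stringsAsFactors = FALSE)
    o <- order(breaks$chrom, breaks$pos, breaks$strand)
    breaks <- breaks[o, , drop = FALSE]
    rownames(breaks) <- NULL
    structure(list(breaks = breaks, gene_expected = NULL, sites = sites,
                   config = config),
              class = "TruthSet")
  })
}
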