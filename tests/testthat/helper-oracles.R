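# Fixture builders and independent brute-force oracles. The oracles stay
# deliberately naive (per-record loops, string scans, full enumerations) so
# they share no code path with the implementation they check.

random_genome <- function(len, seed, gc = 0.5, chrom = "chr1") {
  withr::with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- paste(sample(names(p), len, replace = TRUE, prob = p),
                  collapse = "")
    Genome(stats::setNames(seqs, chrom))
  })
}

random_breaks <- function(n, genome, seed, margin = 0L) {
  withr::with_seed(seed, {
    lens <- genome_lengths(genome)
    chrom <- sample(names(genome), n, replace = TRUE)
    pos <- vapply(chrom, function(cn) {
      sample.int(lens[[cn]] - 2L * margin, 1L) - 1L + margin
    }, integer(1))
    data.frame(chrom = unname(chrom), pos = unname(pos),
               strand = sample(c("+", "-"), n, replace = TRUE),
               mapq = sample(0:60, n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

random_reads <- function(n, seed, n_positions = 50L, umi_pool = 8L) {
  withr::with_seed(seed, {
    umis <- replicate(umi_pool, paste(sample(c("A", "C", "G", "T"), 10,
                                             replace = TRUE), collapse = ""))
    start <- sample.int(n_positions, n, replace = TRUE) * 10L
    data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
               start = start, end = start + sample(50:150, n, replace = TRUE),
               strand = sample(c("+", "-"), n, replace = TRUE),
               umi = sample(umis, n, replace = TRUE),
               mapq = sample(0:60, n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

# Brute-force dedup oracle: hash-group on the (chrom, strand, 5'-end, UMI)
# key, keep max mapq (first in input order on ties).
oracle_dedup <- function(reads) {
  key <- sprintf("%s|%s|%d|%s", reads$chrom, reads$strand,
                 ifelse(reads$strand == "+", reads$start, reads$end - 1L),
                 reads$umi)
  groups <- split(seq_along(key), key)  # hash-group on the full key
  # which.max takes the first maximum: mapq winner, ties by input order
  winners <- vapply(groups, function(rows) rows[which.max(reads$mapq[rows])],
                    integer(1))
  first_occ <- vapply(groups, min, integer(1))
  out <- reads[winners[order(first_occ)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_dedup_keys <- function(reads) {
  sort(unique(sprintf("%s|%s|%d|%s", reads$chrom, reads$strand,
                      ifelse(reads$strand == "+", reads$start,
                             reads$end - 1L), reads$umi)))
}

# Quadratic interval-scan oracle for per-gene strand-class counts.
oracle_gene_counts <- function(breaks, genes) {
  res <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ts <- if (g$strand == "+") "-" else "+"
    inside <- breaks$chrom == g$chrom & breaks$pos >= g$start &
      breaks$pos < g$end
    res[[i]] <- data.frame(gene_id = g$gene_id,
                           N_ts = sum(inside & breaks$strand == ts),
                           N_nts = sum(inside & breaks$strand != ts))
  }
  do.call(rbind, res)
}

# Per-break substring oracle for sequence context extraction.
oracle_context <- function(brk, genome, up, down) {
  seq <- genome[[brk$chrom]]
  len <- nchar(seq)
  out <- character(up + down + 1L)
  for (k in seq_along(out)) {
    offset <- k - up - 1L
    gpos <- if (brk$strand == "+") brk$pos + offset else brk$pos - offset
    if (gpos < 0 || gpos >= len) return(NULL)
    base <- substr(seq, gpos + 1L, gpos + 1L)
    out[k] <- if (brk$strand == "+") base else
      c(A = "T", C = "G", G = "C", T = "A", N = "N")[[base]]
  }
  paste(out, collapse = "")
}

# Naive double-strand motif scan.
oracle_motif_sites <- function(genome, motif) {
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", motif), "")[[1]]),
              collapse = "")
  m <- nchar(motif)
  rows <- list()
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    for (p in seq_len(nchar(seq) - m + 1L)) {
      word <- substr(seq, p, p + m - 1L)
      if (word == motif) {
        rows[[length(rows) + 1L]] <- data.frame(chrom = chrom, pos = p - 1L,
                                                strand = "+")
      }
      if (word == rc) {
        rows[[length(rows) + 1L]] <- data.frame(chrom = chrom,
                                                pos = p - 1L + m - 1L,
                                                strand = "-")
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}

# Exact one-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mannwhitney_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  m <- length(x)
  u_obs <- sum(rank(pooled)[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(n, m)
  r <- rank(pooled)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mean(u_all >= u_obs)
}

# Sorted multiset of break coordinates for recovery comparisons.
break_multiset <- function(breaks) {
  x <- breaks[order(breaks$chrom, breaks$pos, breaks$strand),
              c("chrom", "pos", "strand")]
  rownames(x) <- NULL
  x
}

# Keep structured pipeline logs out of test output.
options(trabiseq.log_level = "warn")
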