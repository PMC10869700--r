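test_that("gene-anchored coordinates flip with the annotation strand", {
  gene <- trabiseq:::finalize_genes(data.frame(
    gene_id = "g1", chrom = "chr1", start = 100L, end = 300L, strand = "-",
    coding = TRUE, tpm = 1, stringsAsFactors = FALSE))
  expect_identical(gene$tss, 299L)
  b <- data.frame(chrom = "chr1", pos = c(199L, 299L), strand = c("+", "-"),
                  mapq = 1L)
  out <- to_gene_coordinates(b, gene)
  expect_identical(out$offset, c(100L, 0L))
  # "+" equals the template strand of this minus gene
  expect_identical(out$strand_class, c("transcribed", "non_transcribed"))
})

test_that("mirror-image genes give identical offsets and strand classes", {
  L <- 1000L
  glen <- 10000L
  plus <- trabiseq:::finalize_genes(data.frame(
    gene_id = "gp", chrom = "chr1", start = 2000L, end = 2000L + L,
    strand = "+", coding = TRUE, tpm = 1, stringsAsFactors = FALSE))
  minus <- trabiseq:::finalize_genes(data.frame(
    gene_id = "gm", chrom = "chr1", start = glen - 2000L - L,
    end = glen - 2000L, strand = "-", coding = TRUE, tpm = 1,
    stringsAsFactors = FALSE))
  withr::with_seed(141, {
    pos <- sample(0:(glen - 1L), 200, replace = TRUE)
    strand <- sample(c("+", "-"), 200, replace = TRUE)
  })
  bp <- data.frame(chrom = "chr1", pos = pos, strand = strand, mapq = 1L)
  # reflect: pos -> glen - 1 - pos, strand flipped
  bm <- data.frame(chrom = "chr1", pos = glen - 1L - pos,
                   strand = ifelse(strand == "+", "-", "+"), mapq = 1L)
  expect_identical(to_gene_coordinates(bp, plus), to_gene_coordinates(bm, minus))
})

flat_fixture <- function(seed, n_genes = 30, glen = 4000L, rate = 5) {
  genome <- random_genome(n_genes * (glen + 4000L) + 8000L, seed = seed)
  starts <- 4000L + (seq_len(n_genes) - 1L) * (glen + 4000L)
  genes <- trabiseq:::finalize_genes(data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)), chrom = "chr1",
    start = starts, end = starts + glen,
    strand = rep(c("+", "-"), length.out = n_genes), coding = TRUE, tpm = 10,
    stringsAsFactors = FALSE))
  cfg <- sim_config(seed = seed + 1L, background_rate = rate)
  truth <- plant_breaks(genome, genes, sim_config(
    seed = seed + 1L, background_rate = rate,
    breaks_per_kb_at_reference_tpm = 0))
  list(genome = genome, genes = genes, breaks = truth$breaks)
}

test_that("a uniform break field yields a flat metagene profile", {
  fx <- flat_fixture(151)
  spec <- profile_spec(upstream = 2000, downstream = 2000, flank_bin = 500,
                       body_bins = 8)
  prof <- metagene_profile(fx$breaks, fx$genes, fx$genome, spec, M = 5)
  # every bin mean should be ~ 1 (density 5/kb over M = 5)
  expect_true(all(abs(prof$mean - 1) < 0.6))
  expect_true(all(prof$ci_lo <= prof$mean & prof$mean <= prof$ci_hi))
  expect_identical(unique(prof$n_genes), 30L)
  # transcribed and non-transcribed profiles are statistically alike
  ts <- prof[prof$strand_class == "transcribed", ]
  nts <- prof[prof$strand_class == "non_transcribed", ]
  overlap <- pmin(ts$ci_hi, nts$ci_hi) >= pmax(ts$ci_lo, nts$ci_lo)
  expect_gte(mean(overlap), 0.9)
})

test_that("profile counts are conserved across bins for a single gene", {
  genome <- random_genome(30000, seed = 161)
  gene <- trabiseq:::finalize_genes(data.frame(
    gene_id = "g1", chrom = "chr1", start = 10000L, end = 15000L,
    strand = "+", coding = TRUE, tpm = 3, stringsAsFactors = FALSE))
  breaks <- random_breaks(400, genome, seed = 162)
  spec <- profile_spec(upstream = 1000, downstream = 1000, flank_bin = 250,
                       body_bins = 10)
  prof <- metagene_profile(breaks, gene, genome, spec, M = 1)
  for (sc in c("transcribed", "non_transcribed")) {
    p <- prof[prof$strand_class == sc, ]
    bin_kb <- ifelse(p$region == "body", 5000 / 10 / 1000, 0.25)
    total <- sum(p$mean * bin_kb)   # n_genes = 1: mean == per-gene C
    want_strand <- if (sc == "transcribed") "-" else "+"
    manual <- sum(breaks$pos >= 9000 & breaks$pos < 16000 &
                    breaks$strand == want_strand)
    expect_equal(total, manual)
  }
})

test_that("a break on a relative bin boundary goes to the higher bin", {
  genome <- Genome(c(chr1 = strrep("A", 20000)))
  gene <- trabiseq:::finalize_genes(data.frame(
    gene_id = "g1", chrom = "chr1", start = 5000L, end = 6000L, strand = "+",
    coding = TRUE, tpm = 1, stringsAsFactors = FALSE))
  # body of 1000 b, 10 bins of 100 b; offset 100 sits on the bin-1/bin-2 edge
  b <- data.frame(chrom = "chr1", pos = 5100L, strand = "-", mapq = 1L)
  spec <- profile_spec(upstream = 0, downstream = 0, flank_bin = 100,
                       body_bins = 10)
  prof <- metagene_profile(b, gene, genome, spec, M = 1)
  ts <- prof[prof$strand_class == "transcribed", ]
  expect_identical(ts$bin[ts$mean > 0], 2L)
})

test_that("genes with truncated windows are excluded and counted", {
  genome <- Genome(c(chr1 = strrep("A", 12000)))
  genes <- trabiseq:::finalize_genes(data.frame(
    gene_id = c("edge", "ok"), chrom = "chr1", start = c(500L, 6000L),
    end = c(2500L, 8000L), strand = "+", coding = TRUE, tpm = 1,
    stringsAsFactors = FALSE))
  b <- data.frame(chrom = "chr1", pos = 7000L, strand = "-", mapq = 1L)
  spec <- profile_spec(upstream = 1000, downstream = 1000, flank_bin = 500,
                       body_bins = 4)
  prof <- metagene_profile(b, genes, genome, spec, M = 1)
  expect_identical(attr(prof, "n_excluded"), 1L)
  expect_identical(unique(prof$n_genes), 1L)
})

test_that("TSS window profiles stratify by gene length and ignore the TES", {
  expect_identical(as.character(trabiseq:::gene_length_group(c(9, 10, 22, 22.0001, 50, 51))),
                   c("<=10kb", "<=10kb", "<=22kb", "<=50kb", "<=50kb", ">50kb"))
  genome <- Genome(c(chr1 = strrep("A", 40000)))
  # a short 2-kb gene: window reaches past its TES
  gene <- trabiseq:::finalize_genes(data.frame(
    gene_id = "g1", chrom = "chr1", start = 10000L, end = 12000L,
    strand = "+", coding = TRUE, tpm = 1, stringsAsFactors = FALSE))
  b <- data.frame(chrom = "chr1", pos = 14000L, strand = "-", mapq = 1L)
  prof <- suppressWarnings(  # three empty length groups are reported
    tss_profile_by_length(b, gene, genome, window = 5000, bin = 1000))
  ts <- prof[prof$strand_class == "transcribed", ]
  hit <- ts[ts$mean > 0, ]
  expect_identical(hit$bin_start, 4000L)  # 4 kb after TSS, beyond the TES
  expect_identical(as.character(unique(prof$length_group)), "<=10kb")
})

test_that("strand-specific G content is complementary and ~flat on iid DNA", {
  genome <- random_genome(2e5, seed = 171)
  starts <- 10000L + (0:9) * 18000L
  genes <- trabiseq:::finalize_genes(data.frame(
    gene_id = sprintf("g%d", 1:10), chrom = "chr1", start = starts,
    end = starts + 8000L, strand = rep(c("+", "-"), 5), coding = TRUE,
    tpm = 1, stringsAsFactors = FALSE))
  gcp <- gc_profile(genes, genome, window = 3000, bin = 500)
  expect_true(all(abs(gcp$g_fraction - 0.25) < 3 * sqrt(0.25 * 0.75 / (500 * 10))))
  # complementarity: transcribed-strand G == sense-strand C, checked manually
  sense_c <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    seq <- genome_subseq(genome, g$chrom, g$tss - 3000L, g$tss + 3000L)
    if (g$strand == "-") {
      seq <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]),
                   collapse = "")
    }
    mean(strsplit(substr(seq, 1, 500), "")[[1]] == "C")
  }, numeric(1))
  ts_bin1 <- gcp$g_fraction[gcp$strand_class == "transcribed" &
                              gcp$bin_start == -3000L]
  expect_equal(ts_bin1, mean(sense_c))
})

test_that("flank counts quantify the two divergent-transcription branches", {
  genome <- Genome(c(chr1 = strrep("A", 40000)))
  gene <- trabiseq:::finalize_genes(data.frame(
    gene_id = "g1", chrom = "chr1", start = 10000L, end = 20000L,
    strand = "+", coding = TRUE, tpm = 5, stringsAsFactors = FALSE))
  breaks <- data.frame(
    chrom = "chr1",
    pos = c(10100L, 11000L, 14999L,  # downstream, template strand
            9000L, 9900L,            # upstream, sense strand
            10500L,                  # downstream but sense strand
            9500L),                  # upstream but template strand
    strand = c("-", "-", "-", "+", "+", "+", "-"), mapq = 1L)
  fc <- flank_counts(breaks, gene, genome, flank = 5000, M = 2)
  expect_equal(fc$C_downstream_ts, 3 / (5 * 2))
  expect_equal(fc$C_upstream_nts, 2 / (5 * 2))

  near_edge <- gene; near_edge$start <- 2000L; near_edge$end <- 12000L
  near_edge <- trabiseq:::finalize_genes(near_edge)
  both <- rbind(gene, near_edge)
  both$gene_id <- c("g1", "g2")
  fc2 <- flank_counts(breaks, trabiseq:::finalize_genes(both), genome,
                      flank = 5000, M = 2)
  expect_identical(attr(fc2, "n_excluded"), 1L)
  expect_identical(fc2$gene_id, "g1")
})

test_that("background threshold is the unexpressed upper quartile", {
  flanks <- data.frame(gene_id = sprintf("g%d", 1:8),
                       C_downstream_ts = 1,
                       C_upstream_nts = c(0, 1, 2, 3, 10, 1, 0.5, 4))
  tiers <- assign_tiers(data.frame(gene_id = flanks$gene_id,
                                   tpm = c(0, 0, 0, 0, 9, 8, 2, 7)))
  res <- background_threshold(flanks, tiers)
  expect_equal(res$threshold, 2.25)  # quartile of {0,1,2,3}, interpolated
  expect_equal(unname(res$fraction_below["not_expressed"]), 0.75)
  # all-equal reference: threshold equals the value, nothing lies below it
  flanks$C_upstream_nts[1:4] <- 2
  res2 <- background_threshold(flanks, tiers)
  expect_equal(res2$threshold, 2)
  expect_equal(unname(res2$fraction_below["not_expressed"]), 0)
  expect_error(background_threshold(flanks[5:8, ], tiers[5:8, ]), "at least 4")
})

test_that("region selection keeps template-strand body and upstream sense breaks", {
  genome <- Genome(c(chr1 = strrep("A", 40000)))
  gene <- trabiseq:::finalize_genes(data.frame(
    gene_id = "g1", chrom = "chr1", start = 10000L, end = 20000L,
    strand = "+", coding = TRUE, tpm = 5, stringsAsFactors = FALSE))
  breaks <- data.frame(
    chrom = "chr1",
    pos = c(15000L,   # body, template ("-") strand -> kept (body)
            5001L,    # 4999 b upstream of TSS, sense strand -> kept
            9000L,    # upstream but template strand -> excluded
            15000L,   # body but sense strand -> excluded
            4999L),   # 5001 b upstream: outside the reach -> excluded
    strand = c("-", "+", "-", "+", "+"), mapq = 1L)
  sel <- select_breaks_in_regions(breaks, gene, upstream = 5000)
  expect_identical(nrow(sel), 2L)
  expect_identical(sel$region[order(sel$pos)], c("upstream", "body"))
})
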