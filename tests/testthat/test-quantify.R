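test_that("transcribed strand is the template strand and is involutive", {
  expect_identical(transcribed_strand("+"), "-")
  expect_identical(transcribed_strand("-"), "+")
  s <- c("+", "-", "-", "+")
  expect_identical(transcribed_strand(transcribed_strand(s)), s)
})

test_that("gene break counting matches the quadratic oracle", {
  g <- random_genome(50000, seed = 111)
  withr::with_seed(112, {
    starts <- sample.int(45000, 50) - 1L
    genes <- data.frame(gene_id = sprintf("g%02d", 1:50), chrom = "chr1",
                        start = starts,
                        end = starts + sample(500:5000, 50, replace = TRUE),
                        strand = sample(c("+", "-"), 50, replace = TRUE),
                        coding = TRUE, tpm = 1, stringsAsFactors = FALSE)
  })
  genes$end <- pmin(genes$end, 50000L)
  genes <- trabiseq:::finalize_genes(genes)
  breaks <- random_breaks(5000, g, seed = 113)
  ours <- count_gene_breaks(breaks, genes)
  oracle <- oracle_gene_counts(breaks, genes)
  got_ts <- ours$N[ours$strand_class == "transcribed"]
  got_nts <- ours$N[ours$strand_class == "non_transcribed"]
  expect_identical(got_ts, oracle$N_ts)
  expect_identical(got_nts, oracle$N_nts)
})

test_that("gene counting respects the half-open boundary and strand classes", {
  genes <- trabiseq:::finalize_genes(data.frame(
    gene_id = "g1", chrom = "chr1", start = 100L, end = 200L, strand = "+",
    coding = TRUE, tpm = 5, stringsAsFactors = FALSE))
  breaks <- data.frame(chrom = "chr1", pos = c(150L, 150L, 200L, 99L),
                       strand = c("-", "+", "-", "-"), mapq = 60L)
  cnt <- count_gene_breaks(breaks, genes)
  # the minus break at 150 is on the template strand of this + gene
  expect_identical(cnt$N[cnt$strand_class == "transcribed"], 1L)
  expect_identical(cnt$N[cnt$strand_class == "non_transcribed"], 1L)
  # pos 200 == end and pos 99 < start are outside the half-open body
  empty <- count_gene_breaks(breaks[0, ], genes)
  expect_identical(empty$N, c(0L, 0L))
  expect_identical(empty$L_kb, c(0.1, 0.1))
})

make_tiers <- function(gene_id, tpm) {
  assign_tiers(data.frame(gene_id = gene_id, tpm = tpm,
                          stringsAsFactors = FALSE))
}

test_that("normalization factor is the mean unexpressed template density", {
  gc <- data.frame(gene_id = rep(c("u1", "u2", "e1"), each = 2),
                   strand_class = rep(c("transcribed", "non_transcribed"), 3),
                   N = c(4L, 9L, 8L, 1L, 50L, 2L),
                   L_kb = c(2, 2, 2, 2, 5, 5), stringsAsFactors = FALSE)
  tiers <- make_tiers(c("u1", "u2", "e1"), c(0, 0, 10))
  expect_identical(normalization_factor(gc, tiers), 3)  # mean(2, 4)

  one <- make_tiers(c("u1", "u2", "e1"), c(0, 5, 10))
  gc1 <- gc; gc1$N[1] <- 5L
  expect_identical(normalization_factor(gc1, one), 2.5)  # 5 / 2 kb

  expect_error(normalization_factor(gc, make_tiers(c("u1", "u2", "e1"),
                                                   c(1, 2, 3))),
               "reference class empty")
  gc0 <- gc; gc0$N[c(1, 3)] <- 0L
  expect_error(normalization_factor(gc0, tiers), "pseudocount")
})

test_that("normalized counts follow C = N / (L_kb * M) and identities hold", {
  gc <- data.frame(gene_id = c("a", "b"), strand_class = "transcribed",
                   N = c(10L, 0L), L_kb = c(2, 3), stringsAsFactors = FALSE)
  out <- normalize_counts(gc, M = 5)
  expect_equal(out$C, c(1, 0))

  # reference-class mean C == 1 to machine precision; scale invariance in k
  g <- random_genome(3e5, seed = 121)
  cfg <- sim_config(seed = 122, genome_length = 3e5, n_genes = 20,
                    gene_length_bounds = c(2000, 6000),
                    unexpressed_fraction = 0.4)
  sim <- simulate_genome_and_genes(cfg)
  truth <- plant_breaks(sim$genome, sim$genes, cfg)
  tiers <- assign_tiers(sim$genes)
  cnt <- count_gene_breaks(truth$breaks, sim$genes)
  M <- normalization_factor(cnt, tiers)
  C1 <- normalize_counts(cnt, M)
  ref <- C1$C[C1$strand_class == "transcribed" &
                C1$gene_id %in% tiers$gene_id[tiers$tier == "not_expressed"]]
  expect_equal(mean(ref), 1, tolerance = 1e-12)

  tripled <- truth$breaks[rep(seq_len(nrow(truth$breaks)), 3), ]
  cnt3 <- count_gene_breaks(tripled, sim$genes)
  C3 <- normalize_counts(cnt3, normalization_factor(cnt3, tiers))
  expect_equal(C3$C, C1$C, tolerance = 1e-12)
})

test_that("expression tiers split percentiles 25/50/70/80/90/95/100", {
  tiers <- make_tiers(sprintf("g%03d", 1:100), sample(1:100))
  expect_identical(as.vector(table(tiers$tier)),
                   c(0L, 25L, 25L, 20L, 10L, 10L, 5L, 5L))
  all0 <- make_tiers(c("a", "b"), c(0, 0))
  expect_true(all(all0$tier == "not_expressed"))
  # equal TPMs at a boundary share the tier of their average rank
  tied <- make_tiers(sprintf("g%d", 1:4), c(1, 1, 5, 6))
  expect_identical(as.character(tied$tier[1]), as.character(tied$tier[2]))
})

test_that("tier summaries reproduce box-plot statistics", {
  gc <- data.frame(gene_id = sprintf("g%d", 1:5), strand_class = "transcribed",
                   N = 1L, L_kb = 1, C = c(1, 2, 3, 4, 100),
                   stringsAsFactors = FALSE)
  tiers <- make_tiers(gc$gene_id, c(0, 0, 0, 0, 0))
  s <- summarize_tiers(gc, tiers)
  row <- s[s$tier == "not_expressed" & s$strand_class == "transcribed", ]
  expect_identical(row$n, 5L)
  expect_equal(row$median, 3)
  expect_equal(c(row$q1, row$q3), c(2, 4))
  expect_equal(row$whisker_hi, 4)  # 100 lies beyond 1.5 x IQR
  expect_equal(row$whisker_lo, 1)
  expect_identical(s$n[s$tier == "<=25%" & s$strand_class == "transcribed"],
                   0L)

  single <- summarize_tiers(gc[3, ], tiers[3, ])
  srow <- single[single$n == 1 & single$strand_class == "transcribed", ]
  expect_equal(srow$mean, srow$median)
  expect_equal(srow$mean, 3)
})

test_that("Spearman correlation is rank-invariant and flags degeneracy", {
  genes <- data.frame(gene_id = sprintf("g%d", 1:20), tpm = exp(1:20 / 3))
  gc <- data.frame(gene_id = genes$gene_id, strand_class = "transcribed",
                   N = 1L, L_kb = 1, C = (1:20)^2, stringsAsFactors = FALSE)
  expect_equal(spearman_expression_correlation(gc, genes)$rho, 1)
  genes_rev <- genes; genes_rev$tpm <- rev(genes_rev$tpm)
  expect_equal(spearman_expression_correlation(gc, genes_rev)$rho, -1)
  gc$C <- 7
  expect_warning(res <- spearman_expression_correlation(gc, genes),
                 "undefined")
  expect_false(res$defined)
  expect_error(spearman_expression_correlation(gc[1:2, ], genes), "at least 3")
})

test_that("genome binning tiles chromosomes, conserves counts, normalizes", {
  g <- Genome(c(chr1 = strrep("A", 250000), chr2 = strrep("C", 90000)))
  b <- random_breaks(2000, g, seed = 131)
  bt <- bin_genome(b, g, width = 100000, M = 1)
  expect_identical(sum(bt$N), 2000L)                     # conservation
  expect_identical(nrow(bt), 4L)                         # 3 + 1 bins
  expect_identical(bt$end[3], 250000L)                   # short last bin
  # a break exactly at k * width belongs to bin k
  one <- data.frame(chrom = "chr1", pos = 100000L, strand = "+", mapq = 1L)
  bt1 <- bin_genome(one, g, width = 100000, M = 1)
  expect_identical(bt1$N[bt1$chrom == "chr1"], c(0L, 1L, 0L))
  # 3 breaks in a 100-kb bin with M = 1 -> C = 3 / 100
  three <- data.frame(chrom = "chr2", pos = c(1L, 2L, 3L), strand = "+",
                      mapq = 1L)
  bt3 <- bin_genome(three, g, width = 100000, M = 1)
  expect_equal(bt3$C[bt3$chrom == "chr2"], 3 / 90)  # short bin: 90 kb
  # strand-separate mode keeps per-strand counts that sum to the merged ones
  bts <- bin_genome(b, g, width = 100000, strand_mode = "separate", M = 1)
  expect_identical(sum(bts$N), 2000L)
  expect_identical(nrow(bts), 8L)
})

test_that("fold change vs median centres the track at 1", {
  bt <- data.frame(C = c(1, 2, 3))
  out <- fold_change_vs_median(bt)
  expect_equal(out$fold_change, c(0.5, 1, 1.5))
  expect_equal(stats::median(out$fold_change), 1)
  allsame <- data.frame(C = rep(2, 5))
  expect_equal(fold_change_vs_median(allsame)$fold_change, rep(1, 5))
  expect_error(fold_change_vs_median(data.frame(C = c(0, 0, 5))), "median")
})

test_that("top expressed gene selection keeps the requested fraction", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:100), tpm = c(1:100),
                      coding = c(rep(TRUE, 90), rep(FALSE, 10)))
  top <- top_expressed_genes(genes, 0.30)
  expect_identical(nrow(top), 27L)  # 30% of the 90 coding genes
  expect_true(all(top$tpm > 63))
})
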