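---
title: "Strand-resolved single-strand-break mapping: models and methods"
author: "trabiseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-resolved single-strand-break mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabiseq)
options(trabiseq.log_level = "warn")
```

## The measurement

3'-OH capture sequencing (the GLOE-seq family of protocols, including its
trabectedin application, TRABI-seq) maps DNA single-strand breaks (SSBs)
genome-wide at single-nucleotide, strand-resolved precision. A free 3'-OH at
a nick is ligated to an adapter, the fragment is captured, and the
sequencing read is the reverse complement of the captured strand. Two facts
fix the entire downstream coordinate arithmetic:

* the **signal nucleotide** of a read is the base immediately upstream of
  the read's 5' end on the reference, and
* its strand is the **opposite** of the read's mapping strand, so that the
  original break lies on the 5' side of the signal nucleotide *on the signal
  strand*.

Concretely, with 0-based half-open intervals (used everywhere in this
package): a read mapped to `+` over `[start, end)` yields a signal at
`(start - 1, "-")`; a read mapped to `-` yields `(end, "+")`. Signals
falling outside the chromosome are dropped and counted. A 10-nt unique
molecular identifier (UMI), carried in the read name after the final
underscore, identifies PCR duplicates: reads sharing (chromosome, mapping
strand, mapped 5'-end coordinate, exact UMI) are collapsed to their
highest-MAPQ representative. The 5' end — not the full interval — defines
the duplicate key because sonication makes 3' ends variable while the 5'
end is fixed by ligation; exact UMI matching mirrors unique-grouping
deduplication, with no edit-distance clustering.

## Normalization

Sequencing depth varies between samples, so raw counts are scaled by a
per-sample factor anchored on damage the treatment cannot have caused. For
sample $s$,

$$M(s) = \mathrm{mean}_f\left\{ \frac{N(s,f)}{L(f)} \right\},$$

where $f$ runs over the transcribed (template) strands of genes with TPM
exactly 0, $N$ is the raw break count of the feature and $L$ its length in
kb. Any feature's normalized count is then

$$C(s,f) = \frac{N(s,f)}{L(f)\,M(s)} \quad [\text{arb. unit}],$$

so the mean normalized count of the reference class is exactly 1 — a
machine-precision identity the tests assert — and multiplying all counts by
a constant (deeper sequencing) leaves every $C$ unchanged. A feature can be
a gene strand, a 100-kb genomic bin, a 5-kb promoter flank, or a profile
bin; the formula never changes. "Not expressed" means TPM exactly 0 by
default (`tpm_zero_threshold` is configurable); no minimum gene length is
imposed on the reference class.

Expressed genes are tiered by average-rank TPM percentiles at cut points
25/50/70/80/90/95/100; average ranks guarantee that equal TPMs never
straddle a tier boundary. Box summaries report quartiles with linear
interpolation and whiskers to the furthest point within 1.5 IQR.

## Profiles

Gene-anchored coordinates place the TSS at zero with transcription running
rightward; a break on the gene's template strand belongs to the
`transcribed` class, otherwise `non_transcribed`. The metagene profile uses
absolute bins (a base count) in the flanks and relative bins (a fraction
$\alpha$ of each gene's length, real-valued boundaries, boundary break to
the higher bin) across the body; per-bin densities $C(s,g,t,b) =
N/(L_g(b) M)$ are averaged over the gene set (by default the top 30%
expressed protein-coding genes) with a 95% CI of mean ± 1.96 SE. Genes
whose window would leave the chromosome are excluded and counted rather
than zero-padded, which would bias edge bins downward. TSS-anchored
profiles stratify genes at 10/22/50 kb (left-open, right-closed); the
window is not clipped at the TES. A G-content control computes per-bin
strand-specific G fractions from the reference sequence (template-strand G
equals sense-strand C by complementarity).

The divergent-transcription branch is quantified as per-gene normalized
counts in the 5-kb flank upstream of the TSS on the non-transcribed strand,
against the 5-kb downstream flank on the transcribed strand. The
endogenous-damage threshold is the upper quartile of the upstream flank
count among unexpressed genes; per tier, the fraction of genes below it
estimates how many show no treatment-induced upstream damage.

## Sequence context

Context windows are read in the 5'→3' orientation of the broken strand with
the break 5' of offset 0: offset 0 is the signal nucleotide ("+1 relative
to the break"), and conventional logo position 1 is offset +1 ("+2 relative
to the break") — the offset headers in all outputs state this mapping to
prevent off-by-one drift. Minus-strand contexts are reverse-complemented.
Information content per offset is $2 - H$ bits with $H$ the Shannon entropy
of the A/C/G/T fractions; all break records contribute with their
multiplicity (abundance), not one per unique position.

## The synthetic generator

All tests run against `plant_breaks()`, an inhomogeneous-Poisson generator
whose defaults encode the phenomenology the analysis is built to detect:

| parameter | default | meaning |
|---|---|---|
| `breaks_per_kb_at_reference_tpm` | 2 | template-strand rate at the TSS of a gene at `reference_tpm` |
| `reference_tpm` | 10 | TPM anchoring the rate |
| `tss_decay_length` | 1500 b | exponential decay of damage into the gene body (peak within the first 1–2 kb) |
| `divergent_ratio` | 0.5 | upstream antisense branch at half the downstream intensity |
| `divergent_extent` | 5000 b | reach of the divergent branch |
| `promoter_dead_zone` | 100 b | promoter region devoid of induced breaks on both strands |
| `background_rate` | 0.5 /kb/strand | uniform endogenous breakage |
| `g_plus2_weight` | 3 | multiplicative preference for G one base downstream of the signal nucleotide |
| `read_length`, `mean_fragment`, `umi_length` | 100 b, 300 b, 10 nt | library geometry |
| `duplication_rate` | 0.2 | P(a break gains ≥1 PCR copy); copy count is geometric |

Poisson with expression-proportional intensity is the minimal generative
law consistent with count data that scale with expression; it is what makes
parameter-recovery tests meaningful. The G preference multiplies the
intensity of *incision-derived* components only (transcribed + divergent),
not the endogenous background — the preference belongs to the nuclease —
which keeps the planted context fraction in closed form:
$w p_G / (w p_G + 1 - p_G)$ on an i.i.d. genome
(`g_weight_for_fraction()` inverts it). Read emission inverts the calling
convention exactly; UMIs are drawn uniformly (collisions possible in
principle, negligible at $4^{10}$, and logged rather than corrected). The
nickase control plants a break whose signal nucleotide is the first motif
base on either strand, with per-site Bernoulli efficiency.

What the generator does **not** model: sequencing errors and base
qualities, mappability and alignment artifacts, chromatin-state-dependent
background, transcriptional read-through past the TES, and antisense gene
bodies. Passing recovery tests therefore demonstrate the correctness of the
pipeline's arithmetic and statistics on data matching its assumptions, not
robustness to real-library artifacts.

## Numerical choices and scale

Deterministic seeding: every generator derives an independent substream
from one master seed, so outputs are byte-identical under a fixed
configuration. Quantiles use linear interpolation (R type 7). The
Mann-Whitney test is exact for tie-free groups up to 50 per side and
otherwise uses the normal approximation with average ranks, tie correction
and continuity correction; all-identical inputs return p = 1 with a
degeneracy flag instead of an error. Constant inputs to correlations are
flagged undefined rather than silently 0. Unknown chromosomes error by
default (`on_unknown = "skip"` downgrades to a warning) because silent
coordinate mismatches are the classic failure mode of this pipeline class.

Test problem sizes were chosen so that recovery statistics are decisive at
desk scale: round trips on 10,000 planted breaks; fold recovery on 1,000
genes over a 14-Mb genome with the top-tier/unexpressed fold calibrated to
9 from the drawn TPMs; geometry recovery on 250 genes with decay 1500 b,
dead zone 100 b and divergent ratio 0.5; context recovery on ~10,000
breaks with the weight set for a 60% G fraction; CI calibration over 200
background-only simulations with the true normalization factor supplied
(isolating the CI machinery from the correlated noise of estimating $M$
on the same draw).

## A small worked run

```{r example}
cfg <- sim_config(seed = 7, genome_length = 2e6, n_genes = 60,
                  gene_length_bounds = c(6000, 20000))
sim <- simulate_genome_and_genes(cfg)
truth <- plant_breaks(sim$genome, sim$genes, cfg)
rr <- breaks_to_reads(truth, sim$genome, cfg)
sample <- call_breaks(rr$reads, sim$genome, sample_id = "demo")

tiers <- assign_tiers(sim$genes)
cnt <- count_gene_breaks(sample$breaks, sim$genes)
M <- normalization_factor(cnt, tiers)
cnt <- normalize_counts(cnt, M)
mean(cnt$C[cnt$strand_class == "transcribed" &
             cnt$gene_id %in% tiers$gene_id[tiers$tier == "not_expressed"]])

spearman_expression_correlation(cnt, sim$genes, "transcribed")$rho
logo_summary(context_matrix(sample$breaks, sim$genome, up = 3,
                            down = 6))$g_plus1_fraction
```

## Known limitations

Relative-bin profiles of genes shorter than one body bin contribute their
actual bin length, but very short genes make single-gene bin densities
noisy; the CI is a normal approximation and is anti-conservative below a
few dozen genes (a bootstrap is the natural extension). Sensitivity of the
nickase validation requires exact coordinate coincidence (a `slop`
parameter exists for exploration); real libraries with resection or
imprecise nicking would need it. Overlapping genes both receive shared
breaks — counts are not partitioned — so summing $N$ over genes can exceed
the number of break records.
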