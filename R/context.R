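# Sequence context at break sites. Offset 0 is the signal nucleotide, the
# first base downstream of the break ("+1 relative to the break"); the
# conventional logo "position 1" is offset +1 here ("+2 relative to the
# break"). For a break on the "-" strand, offsets run leftward on the
# reference and bases are complemented, so contexts are always read in the
# 5'->3' orientation of the broken strand with the break 5' of offset 0.

#' Base composition around break signal nucleotides
#'
#' Extracts the window `[-up, +down]` (in broken-strand orientation) around
#' each break's signal nucleotide and tallies base counts and fractions per
#' offset. Breaks whose window leaves the chromosome are excluded and
#' counted; fractions are computed over non-N bases.
#'
#' @param breaks Break data.frame (row multiplicity counts).
#' @param genome A [Genome()] object.
#' @param up Bases upstream of the signal nucleotide (offsets `-up..-1`).
#' @param down Bases downstream (offsets `1..down`).
#' @return A `ContextMatrix`: list with `counts` and `fraction` (offset x
#'   base matrices over A/C/G/T plus an N count column in `counts`),
#'   `offsets`, `n` (contexts used) and `n_excluded`.
#' @export
context_matrix <- function(breaks, genome, up = 5L, down = 10L) {
  stopifnot(inherits(genome, "Genome"), up >= 0, down >= 0)
  offsets <- seq.int(-up, down)
  lens <- genome_lengths(genome)[breaks$chrom]
  plus <- breaks$strand == "+"
  # genomic span touched by the window, per break
  span_lo <- ifelse(plus, breaks$pos - up, breaks$pos - down)
  span_hi <- ifelse(plus, breaks$pos + down, breaks$pos + up)
  ok <- span_lo >= 0 & span_hi < lens
  n_excluded <- sum(!ok)
  b <- breaks[ok, , drop = FALSE]
  plus <- plus[ok]
  ctx <- character(nrow(b))
  if (nrow(b) > 0) {
    lo <- ifelse(plus, b$pos - up, b$pos - down)
    hi <- ifelse(plus, b$pos + down, b$pos + up)
    for (chrom in unique(b$chrom)) {
      i <- b$chrom == chrom
      ctx[i] <- substring(genome[[chrom]], lo[i] + 1L, hi[i] + 1L)
    }
    ctx[!plus] <- revcomp(ctx[!plus])
  }
  width <- up + down + 1L
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, width, 5L,
                   dimnames = list(offset = offsets, base = c(bases, "N")))
  if (length(ctx) > 0) {
    mat <- matrix(unlist(strsplit(ctx, "", fixed = TRUE), use.names = FALSE),
                  ncol = width, byrow = TRUE)
    for (j in seq_len(width)) {
      tab <- table(factor(mat[, j], levels = c(bases, "N")))
      counts[j, ] <- as.integer(tab)
    }
  }
  non_n <- counts[, bases, drop = FALSE]
  denom <- rowSums(non_n)
  fraction <- sweep(non_n, 1, pmax(denom, 1L), "/")
  structure(list(counts = counts, fraction = fraction, offsets = offsets,
                 n = nrow(b), n_excluded = n_excluded),
            class = "ContextMatrix")
}

#' @export
print.ContextMatrix <- function(x, ...) {
  cat(sprintf("ContextMatrix: %d contexts, offsets %d..%d (%d excluded)\n",
              x$n, min(x$offsets), max(x$offsets), x$n_excluded))
  print(round(x$fraction, 3))
  invisible(x)
}

#' Information content per offset and the G fraction at offset +1
#'
#' Information content is `2 - H` bits per offset, with `H` the Shannon
#' entropy (log2) of the A/C/G/T fractions. The G fraction at offset +1
#' (one base downstream of the signal nucleotide, i.e. logo position 1,
#' "+2 relative to the break") is returned explicitly because it carries the
#' incision sequence preference.
#'
#' @param matrix A `ContextMatrix` from [context_matrix()].
#' @return List with `information` (named numeric, bits per offset),
#'   `g_plus1_fraction` and `g_plus1_percent` (`NA` when offset +1 is not in
#'   the window).
#' @export
logo_summary <- function(matrix) {
  stopifnot(inherits(matrix, "ContextMatrix"), matrix$n >= 1)
  ent <- apply(matrix$fraction, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  info <- 2 - ent
  names(info) <- rownames(matrix$fraction)
  g1 <- if ("1" %in% rownames(matrix$fraction)) {
    unname(matrix$fraction["1", "G"])
  } else {
    NA_real_
  }
  list(information = info, g_plus1_fraction = g1,
       g_plus1_percent = 100 * g1)
}
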