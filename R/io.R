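# Readers/writers for the tabular formats the pipeline touches. All on-disk
# coordinates follow the 0-based half-open convention except where a reader
# flag declares a 1-based input.

#' Read gene models and join expression values
#'
#' The gene table is tab-separated with a header line and columns
#' `gene_id, chrom, start, end, strand, coding` (0-based half-open interval,
#' strand in `+`/`-`, coding as TRUE/FALSE or 1/0). The expression table has
#' columns `gene_id, tpm`. The transcription start site (TSS) and end site
#' (TES) are derived from the annotation strand: for a `+` gene TSS = start
#' and TES = end - 1; for a `-` gene TSS = end - 1 and TES = start.
#'
#' @param path Path to the gene table.
#' @param expression_path Path to the expression table (TPM). `NULL` to skip
#'   the join (all `tpm` set to `NA`).
#' @param missing_expression `"error"` (default) fails when a gene has no
#'   expression entry; `"allow"` leaves its `tpm` as `NA`.
#' @param one_based Set `TRUE` if the gene table uses 1-based inclusive
#'   coordinates; they are converted on read.
#' @return A data.frame of gene models with derived columns `tss`, `tes` and
#'   `length_kb`.
#' @export
read_genes <- function(path, expression_path = NULL,
                       missing_expression = c("error", "allow"),
                       one_based = FALSE) {
  missing_expression <- match.arg(missing_expression)
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "chrom", "start", "end", "strand", "coding")
  missing_cols <- setdiff(required, names(g))
  if (length(missing_cols) > 0) {
    stop("gene table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  g$start <- as.integer(g$start)
  g$end <- as.integer(g$end)
  if (one_based) g$start <- g$start - 1L
  if (anyNA(g$start) || anyNA(g$end)) stop("non-integer gene coordinates")
  if (any(g$start >= g$end)) {
    bad <- g$gene_id[g$start >= g$end]
    stop("start >= end for gene(s): ", paste(bad, collapse = ", "))
  }
  check_strand(g$strand, "gene strand")
  if (anyDuplicated(g$gene_id)) {
    stop("duplicate gene_id(s): ",
         paste(unique(g$gene_id[duplicated(g$gene_id)]), collapse = ", "))
  }
  g$coding <- as.logical(g$coding)
  if (anyNA(g$coding)) stop("coding column must be logical (TRUE/FALSE or 1/0)")

  if (!is.null(expression_path)) {
    e <- utils::read.delim(expression_path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "tpm") %in% names(e))) {
      stop("expression table must have columns gene_id, tpm")
    }
    e$tpm <- as.numeric(e$tpm)
    if (anyNA(e$tpm) || any(e$tpm < 0)) stop("tpm must be nonnegative numbers")
    idx <- match(g$gene_id, e$gene_id)
    if (missing_expression == "error" && anyNA(idx)) {
      stop("gene(s) missing from expression table: ",
           paste(utils::head(g$gene_id[is.na(idx)], 10), collapse = ", "))
    }
    g$tpm <- e$tpm[idx]
  } else {
    g$tpm <- NA_real_
  }
  finalize_genes(g)
}

# Derive TSS/TES/length from validated gene columns.
finalize_genes <- function(g) {
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g$tes <- ifelse(g$strand == "+", g$end - 1L, g$start)
  g$length_kb <- (g$end - g$start) / 1000
  rownames(g) <- NULL
  g
}

#' Write a gene table (with optional expression companion file)
#'
#' @param genes Gene model data.frame as returned by [read_genes()].
#' @param path Output path for the gene table.
#' @param expression_path Optional output path for a `gene_id`/`tpm` table.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path, expression_path = NULL) {
  cols <- c("gene_id", "chrom", "start", "end", "strand", "coding")
  utils::write.table(genes[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(expression_path)) {
    utils::write.table(data.frame(gene_id = genes$gene_id, tpm = genes$tpm),
                       expression_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read UMI-tagged alignments from a BED-like TSV
#'
#' Six tab-separated columns without header, in BED6 order:
#' `chrom, start, end, name, mapq, strand`. The UMI is the substring of the
#' read name after its final underscore (the convention produced by merging
#' the UMI read into the genomic read's name).
#'
#' @param path Input path.
#' @param umi_length Expected UMI length (default 10).
#' @return A data.frame of aligned reads with columns
#'   `chrom, start, end, strand, umi, mapq` in file order.
#' @export
read_alignments <- function(path, umi_length = 10L) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "mapq", "strand"))
  if (ncol(d) != 6) stop("alignment file must have exactly 6 columns")
  line <- seq_len(nrow(d))
  d$start <- suppressWarnings(as.integer(d$start))
  d$end <- suppressWarnings(as.integer(d$end))
  bad_coord <- is.na(d$start) | is.na(d$end) | d$start >= d$end | d$start < 0
  if (any(bad_coord)) {
    stop("invalid interval at line(s): ",
         paste(utils::head(line[bad_coord], 10), collapse = ", "))
  }
  d$mapq <- suppressWarnings(as.integer(d$mapq))
  if (anyNA(d$mapq) || any(d$mapq < 0)) {
    stop("mapq must be a nonnegative integer; first bad line: ",
         line[is.na(d$mapq) | d$mapq < 0][1])
  }
  check_strand(d$strand, "mapping strand")
  no_us <- !grepl("_", d$name)
  if (any(no_us)) {
    stop("read name without UMI suffix (no underscore) at line(s): ",
         paste(utils::head(line[no_us], 10), collapse = ", "))
  }
  umi <- sub(".*_", "", d$name)
  bad_umi <- nchar(umi) != umi_length | grepl("[^ACGTN]", umi)
  if (any(bad_umi)) {
    stop(sprintf("UMI must be %d bases over A/C/G/T/N; bad line(s): %s",
                 umi_length,
                 paste(utils::head(line[bad_umi], 10), collapse = ", ")))
  }
  data.frame(chrom = d$chrom, start = d$start, end = d$end,
             strand = d$strand, umi = umi, mapq = d$mapq,
             stringsAsFactors = FALSE)
}

#' Write UMI-tagged alignments to a BED-like TSV
#'
#' Inverse of [read_alignments()]: the UMI is appended to a generated read
#' name after an underscore.
#'
#' @param reads Aligned-read data.frame.
#' @param path Output path.
#' @param names Optional read names (without UMI suffix); defaults to
#'   `read<i>`.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(reads, path, names = NULL) {
  if (is.null(names)) names <- sprintf("read%d", seq_len(nrow(reads)))
  out <- data.frame(chrom = reads$chrom, start = reads$start, end = reads$end,
                    name = paste0(names, "_", reads$umi),
                    mapq = reads$mapq, strand = reads$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write called break signals (4-column TSV)
#'
#' The break TSV has exactly four columns and no header: chromosome, 0-based
#' coordinate of the signal nucleotide, strand of the signal nucleotide, and
#' MAPQ of the supporting read. Each line is one break revealed by one mapped
#' read; identical lines are legitimate (line multiplicity encodes break
#' abundance). The original break lies on the 5' side of the signal
#' nucleotide on its strand.
#'
#' @param path Input path.
#' @return Data.frame with columns `chrom, pos, strand, mapq`.
#' @export
read_breaks_tsv <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) != 4) {
    stop("break TSV must have exactly 4 columns, found ", ncol(d))
  }
  names(d) <- c("chrom", "pos", "strand", "mapq")
  d$pos <- suppressWarnings(as.integer(d$pos))
  if (anyNA(d$pos) || any(d$pos < 0)) stop("break pos must be a nonnegative integer")
  check_strand(d$strand, "break strand")
  d$mapq <- suppressWarnings(as.integer(d$mapq))
  if (anyNA(d$mapq) || any(d$mapq < 0)) stop("mapq must be a nonnegative integer")
  d
}

#' @rdname read_breaks_tsv
#' @param breaks Break data.frame (`chrom, pos, strand, mapq`).
#' @return For the writer, `path` invisibly.
#' @export
write_breaks_tsv <- function(breaks, path) {
  stopifnot(all(c("chrom", "pos", "strand", "mapq") %in% names(breaks)))
  utils::write.table(breaks[, c("chrom", "pos", "strand", "mapq")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a peak track (BED3+)
#'
#' The first three columns (chrom, start, end; 0-based half-open) are parsed;
#' any further columns are ignored.
#'
#' @param path Input path.
#' @return Data.frame with columns `chrom, start, end` (possibly 0 rows).
#' @export
read_peaks <- function(path) {
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character(0))
  if (length(first) == 0 || !nzchar(first)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop("peak file must have at least 3 columns (BED3)")
  p <- data.frame(chrom = as.character(d[[1]]),
                  start = suppressWarnings(as.integer(d[[2]])),
                  end = suppressWarnings(as.integer(d[[3]])),
                  stringsAsFactors = FALSE)
  if (anyNA(p$start) || anyNA(p$end)) stop("non-integer peak coordinates")
  if (any(p$start >= p$end)) {
    stop("peak start must be < end; first bad line: ",
         which(p$start >= p$end)[1])
  }
  p
}

#' Check that records live on chromosomes of a genome
#'
#' Coordinate-system mismatches between a genome and break/peak files are the
#' classic silent failure of this pipeline class; unknown chromosomes
#' therefore error by default.
#'
#' @param x Data.frame with a `chrom` column (and optionally `pos` or
#'   `start`/`end`).
#' @param genome A [Genome()] object.
#' @param on_unknown `"error"` (default) or `"skip"` (drop offending rows
#'   with a warning).
#' @return `x`, possibly with unknown-chromosome rows removed.
#' @export
check_chromosomes <- function(x, genome, on_unknown = c("error", "skip")) {
  on_unknown <- match.arg(on_unknown)
  known <- x$chrom %in% names(genome)
  if (all(known)) return(x)
  offending <- unique(x$chrom[!known])
  if (on_unknown == "error") {
    stop("record(s) on unknown chromosome(s): ",
         paste(offending, collapse = ", "))
  }
  warning(sprintf("skipping %d record(s) on unknown chromosome(s): %s",
                  sum(!known), paste(offending, collapse = ", ")))
  x[known, , drop = FALSE]
}
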