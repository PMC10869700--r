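#' Genome container
#'
#' A genome is stored as a named character vector of uppercase chromosome
#' sequences over the alphabet A/C/G/T/N. All coordinates in this package are
#' 0-based, half-open `[start, end)`; conversion to the 1-based conventions of
#' Biostrings/GenomicRanges happens only at call boundaries.
#'
#' @param sequences Named character vector, one element per chromosome.
#' @return An object of class `Genome`.
#' @export
Genome <- function(sequences) {
  if (length(sequences) == 0) stop("genome must contain at least one chromosome")
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("all chromosomes must have nonempty names")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sequences <- toupper(sequences)
  if (any(!nzchar(sequences))) {
    stop("empty sequence for chromosome(s): ",
         paste(nm[!nzchar(sequences)], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("sequence alphabet must be A/C/G/T/N; offending chromosome(s): ",
         paste(nm[bad], collapse = ", "))
  }
  structure(as.character(sequences), names = nm, class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("Genome with %d chromosome(s), %d bases total\n",
              length(x), sum(nchar(unclass(x)))))
  for (nm in utils::head(names(x), 10)) {
    cat(sprintf("  %s: %d bp\n", nm, nchar(x[[nm]])))
  }
  invisible(x)
}

#' Chromosome lengths of a genome
#'
#' @param genome A [Genome()] object.
#' @return Named integer vector of chromosome lengths in bases.
#' @export
genome_lengths <- function(genome) {
  stopifnot(inherits(genome, "Genome"))
  vapply(unclass(genome), nchar, integer(1))
}

#' Extract a subsequence in 0-based half-open coordinates
#'
#' @param genome A [Genome()] object.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval `[start, end)`.
#' @return Character scalar with the requested bases (plus strand).
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "Genome"))
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- nchar(genome[[chrom]])
  if (start < 0 || end > len || start >= end) {
    stop(sprintf("interval [%d, %d) out of range for %s (length %d)",
                 start, end, chrom, len))
  }
  substring(genome[[chrom]], start + 1L, end)
}

#' Read a genome from FASTA
#'
#' Sequences are uppercased on read and restricted to the A/C/G/T/N alphabet.
#' Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A [Genome()] object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0) stop("no FASTA records in ", path)
  widths <- Biostrings::width(seqs)
  if (any(widths == 0)) {
    stop("empty FASTA record(s) in ", path, ": ",
         paste(names(seqs)[widths == 0], collapse = ", "))
  }
  v <- as.character(seqs)
  # keep only the first whitespace-delimited token of each header
  names(v) <- sub("\\s.*$", "", names(v))
  Genome(v)
}

#' Write a genome to FASTA
#'
#' @param genome A [Genome()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "Genome"))
  x <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
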