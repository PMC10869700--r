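# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Opposite strand symbol
#'
#' Maps `"+"` to `"-"` and vice versa, vectorized.
#'
#' @param strand Character vector over `{"+", "-"}`.
#' @return Character vector of flipped strand symbols.
#' @keywords internal
other_strand <- function(strand) {
  stopifnot(all(strand %in% c("+", "-")))
  chartr("+-", "-+", strand)
}

# Reverse complement of plain character sequences (vectorized).
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# Complement without reversal.
complement_bases <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", x)
}

check_strand <- function(strand, what = "strand") {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    stop(sprintf("invalid %s symbol(s): %s", what,
                 paste(unique(strand[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(strand)
}

# Stable integer-safe seed derivation for sub-streams of one master seed.
derive_seed <- function(seed, salt) {
  (as.integer(seed) + as.integer(salt) * 10007L) %% .Machine$integer.max
}

# Structured logging to stderr; level gate is a package option.
ts_log <- function(level, fmt, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  gate <- getOption("trabiseq.log_level", "info")
  if (levels[[level]] >= levels[[gate]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}
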