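## Circular coordinate arithmetic. All public coordinates are 1-based
## inclusive; internally a 0-based shadow index is used for modular math.

#' Wrap a (possibly unwrapped) position onto the circle
#'
#' @param pos integer vector of positions; values outside `[1, L]` are wrapped.
#' @param L genome length.
#' @return positions in `[1, L]`.
#' @keywords internal
circ_pos <- function(pos, L) ((pos - 1L) %% L) + 1L

#' Positions covered by a circular interval
#'
#' @param start 1-based start (in `[1, L]`).
#' @param len interval length (`<= L`).
#' @param L genome length.
#' @keywords internal
circ_span <- function(start, len, L) {
  if (len <= 0L) return(integer(0))
  circ_pos(seq.int(start, length.out = len), L)
}

#' Circular gap from position a to position b walking forward
#'
#' Number of positions strictly between `a` and `b` going clockwise
#' (a -> a+1 -> ...). Zero when `b` immediately follows `a`.
#' @keywords internal
circ_gap <- function(a, b, L) (b - a - 1L) %% L

#' Length of a feature span on the circle
#' @keywords internal
circ_len <- function(start, end, L) ((end - start) %% L) + 1L

mitotx_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mitotx_error", "error", "condition")))
}

DNA_BASES <- c("A", "C", "G", "T")
DNA_IUPAC <- c(DNA_BASES, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract a circular subsequence as a character string
#'
#' @param genome a `circular_genome`.
#' @param start,end 1-based inclusive bounds; `end < start` means the segment
#'   wraps the origin.
#' @param strand `"H"` returns the sequence as stored, `"L"` its reverse
#'   complement (transcript sense for light-strand features).
#' @return character scalar.
#' @export
genome_segment <- function(genome, start, end, strand = "H") {
  L <- genome$length
  start <- circ_pos(start, L)
  end <- circ_pos(end, L)
  s <- if (end >= start) {
    substr(genome$sequence, start, end)
  } else {
    paste0(substr(genome$sequence, start, L), substr(genome$sequence, 1L, end))
  }
  if (strand == "L") revcomp(s) else s
}
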