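# Internal helpers shared across modules.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse-complement a DNA string
#'
#' Thin character-level wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character scalar over the IUPAC DNA alphabet.
#' @return character scalar.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# total spliced length of a transcript model
tx_length <- function(t) {
  sum(t$exons[, 2L] - t$exons[, 1L])
}

# introns as a 2-column matrix of 0-based half-open genomic intervals
# (gaps between consecutive exons); 0 rows for single-exon models
tx_introns <- function(t) {
  ex <- t$exons
  n <- nrow(ex)
  if (n < 2L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = ex[-n, 2L], end = ex[-1L, 1L])
}

# transcript coordinates (0-based) of exon-exon junctions, 5'->3'.
# A junction at position j separates spliced bases j-1 and j.
tx_junctions <- function(t) {
  lens <- t$exons[, 2L] - t$exons[, 1L]
  if (t$strand == "-") lens <- rev(lens)
  if (length(lens) < 2L) return(integer(0))
  cumsum(lens)[-length(lens)]
}

# map a transcript coordinate (0-based) to its genomic coordinate (0-based)
tx_to_genome <- function(t, pos) {
  lens <- t$exons[, 2L] - t$exons[, 1L]
  total <- sum(lens)
  stopifnot(all(pos >= 0L), all(pos < total))
  if (t$strand == "-") pos <- total - 1L - pos
  # now pos is in plus-orientation transcript coordinates
  ends <- cumsum(lens)
  starts <- c(0L, ends[-length(ends)])
  idx <- findInterval(pos, starts)
  t$exons[idx, 1L] + (pos - starts[idx])
}

# exonic membership over a genomic window [lo, hi): logical vector
exonic_mask <- function(exons, lo, hi) {
  m <- logical(hi - lo)
  for (i in seq_len(nrow(exons))) {
    a <- max(exons[i, 1L], lo)
    b <- min(exons[i, 2L], hi)
    if (b > a) m[(a - lo + 1L):(b - lo)] <- TRUE
  }
  m
}

# deterministic event identifier
event_id_string <- function(gene_id, event_type, contig, start, end) {
  sprintf("%s:%s:%s:%d-%d", gene_id, event_type, contig, start, end)
}

# split a logical vector into maximal TRUE runs; returns 2-col matrix of
# 0-based half-open offsets
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
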