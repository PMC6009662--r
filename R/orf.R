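# Main-ORF selection: candidate ORF enumeration and the lexicographic
# (homology > protein length > expression > 5'-most) choice of each gene's
# main ORF and reference isoform.

#' Enumerate candidate ORFs in a spliced sequence
#'
#' A candidate ORF is an ATG followed by the first in-frame stop codon
#' (TAA/TAG/TGA). Candidates whose span contains an N are discarded.
#' Non-ATG starts are not considered.
#'
#' @param seq spliced DNA string (5'->3').
#' @return data.frame with columns `start` (0-based ATG position), `stop`
#'   (0-based position just after the stop codon) and `length_nt`; zero rows
#'   if none.
#' @export
find_orfs <- function(seq) {
  n <- nchar(seq)
  empty <- data.frame(start = integer(0), stop = integer(0),
                      length_nt = integer(0))
  if (n < 6L) return(empty)
  codons_at <- function(pos) substring(seq, pos + 1L, pos + 3L)
  atg <- as.integer(gregexpr("ATG", seq, fixed = TRUE)[[1L]])
  atg <- atg[atg > 0L] - 1L
  if (!length(atg)) return(empty)
  res <- lapply(atg, function(a) {
    starts <- seq.int(a, n - 3L, by = 3L)
    if (length(starts) < 2L) return(NULL)
    cods <- codons_at(starts)
    stop_i <- which(cods %in% STOP_CODONS)[1L]
    if (is.na(stop_i) || stop_i == 1L) return(NULL)
    end <- starts[stop_i] + 3L
    if (grepl("N", substring(seq, a + 1L, end), fixed = TRUE)) return(NULL)
    data.frame(start = a, stop = end, length_nt = end - a)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) empty else res
}

#' Select each isoform's ORF and the gene's reference isoform
#'
#' Within each isoform, candidate ORFs are ranked lexicographically:
#' homology score (highest first, when available), then ORF length, then
#' isoform expression, then 5'-most start. The gene's reference isoform is
#' the isoform whose selected ORF wins the same comparison across isoforms.
#' The criteria ordering is configurable via `criteria`.
#'
#' @param isoforms list of [transcript_model()] for one gene.
#' @param sequences named character vector/list: `transcript_id` -> spliced
#'   sequence.
#' @param homology optional. Either a named numeric vector
#'   (`transcript_id` -> score) or a function taking a peptide string and
#'   returning a score (or `NA` for no hit), applied per candidate ORF.
#' @param expression optional named numeric vector (`transcript_id` -> CPM).
#' @param criteria character vector ordering the tie-break chain; a
#'   permutation of `c("homology", "length", "expression", "start")`.
#' @return list with `reference` (transcript_id of the reference isoform) and
#'   `orfs`, a data.frame (one row per coding isoform) with columns
#'   `transcript_id`, `orf_start`, `orf_stop`, `orf_length_nt`,
#'   `homology_score`, `isoform_expression`, `selection_basis`. Non-coding
#'   isoforms (no ATG..stop) are omitted from `orfs`.
#' @export
select_main_orf <- function(isoforms, sequences, homology = NULL,
                            expression = NULL,
                            criteria = c("homology", "length",
                                         "expression", "start")) {
  stopifnot(length(isoforms) >= 1L,
            setequal(criteria, c("homology", "length", "expression", "start")))
  ids <- vapply(isoforms, function(t) t$transcript_id, character(1L))
  if (!all(ids %in% names(sequences))) {
    stop("sequences missing for: ",
         paste(setdiff(ids, names(sequences)), collapse = ", "))
  }
  score_orf <- function(tx, orf_row, seq) {
    h <- NA_real_
    if (is.function(homology)) {
      pep <- as.character(Biostrings::translate(Biostrings::DNAString(
        substring(seq, orf_row$start + 1L, orf_row$stop)),
        if.fuzzy.codon = "X"))
      h <- suppressWarnings(as.numeric(homology(pep)))
    } else if (!is.null(homology) && tx %in% names(homology)) {
      h <- as.numeric(homology[[tx]])
    }
    e <- if (!is.null(expression) && tx %in% names(expression)) {
      as.numeric(expression[[tx]])
    } else NA_real_
    c(homology = h, length = orf_row$length_nt,
      expression = e, start = orf_row$start)
  }
  # lexicographic comparison; NA ranks below any value; start is minimized
  better <- function(a, b) {
    for (k in criteria) {
      av <- a[[k]]; bv <- b[[k]]
      if (k == "start") { av <- -av; bv <- -bv }
      if (is.na(av) && is.na(bv)) next
      if (is.na(bv)) return(TRUE)
      if (is.na(av)) return(FALSE)
      if (av > bv) return(TRUE)
      if (av < bv) return(FALSE)
    }
    FALSE
  }
  rows <- list()
  best_scores <- list()
  for (i in seq_along(isoforms)) {
    tx <- ids[i]
    seq <- as.character(sequences[[tx]])
    cand <- find_orfs(seq)
    if (!nrow(cand)) next
    scores <- lapply(seq_len(nrow(cand)), function(j)
      score_orf(tx, cand[j, ], seq))
    best <- 1L
    for (j in seq_len(nrow(cand))[-1L]) {
      if (better(scores[[j]], scores[[best]])) best <- j
    }
    sc <- scores[[best]]
    basis <- criteria[which(!is.na(sc[criteria]))[1L]]
    rows[[tx]] <- data.frame(
      transcript_id = tx,
      orf_start = cand$start[best], orf_stop = cand$stop[best],
      orf_length_nt = cand$length_nt[best],
      homology_score = unname(sc[["homology"]]),
      isoform_expression = unname(sc[["expression"]]),
      selection_basis = basis, stringsAsFactors = FALSE)
    best_scores[[tx]] <- sc
  }
  if (!length(rows)) {
    return(list(reference = NA_character_,
                orfs = data.frame(transcript_id = character(0))))
  }
  ref <- names(best_scores)[1L]
  for (tx in names(best_scores)[-1L]) {
    if (better(best_scores[[tx]], best_scores[[ref]])) ref <- tx
  }
  list(reference = ref,
       orfs = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Per-gene ORF selections for a model set
#'
#' Convenience wrapper running [select_main_orf()] over every gene.
#'
#' @param models named list `gene_id -> list of transcript_model`.
#' @param genome `DNAStringSet`; defaults to `attr(models, "genome")`.
#' @param homology,expression forwarded to [select_main_orf()].
#' @return named list of [select_main_orf()] results.
#' @export
compute_orf_selections <- function(models, genome = NULL, homology = NULL,
                                   expression = NULL) {
  genome <- genome %||% attr(models, "genome")
  lapply(models, function(iso) {
    seqs <- stats::setNames(
      lapply(iso, extract_transcript_sequence, genome = genome),
      vapply(iso, function(t) t$transcript_id, character(1L)))
    select_main_orf(iso, seqs, homology = homology, expression = expression)
  })
}

# ORF of `t` anchored at the gene's authentic start codon (the reference
# ORF's genomic ATG position); NULL when that ATG is absent from the
# isoform or yields no in-frame stop. Premature-stop evaluation of an
# alternative isoform asks where translation from the authentic start
# terminates, not where the isoform's longest ORF lies.
anchored_orf <- function(t, seq, ref_start_genomic) {
  cand <- find_orfs(seq)
  if (!nrow(cand)) return(NULL)
  g <- vapply(cand$start, function(p) tx_to_genome(t, p), numeric(1L))
  hit <- which(g == ref_start_genomic)
  if (!length(hit)) return(NULL)
  row <- cand[hit[1L], ]
  data.frame(transcript_id = t$transcript_id, orf_start = row$start,
             orf_stop = row$stop, orf_length_nt = row$length_nt,
             homology_score = NA_real_, isoform_expression = NA_real_,
             selection_basis = "anchored", stringsAsFactors = FALSE)
}
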