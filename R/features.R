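# NMD-targeting features: PTC calls under the 50-nt rule, 3' UTR junction
# features, uORF profiles, sequence composition, motif counts, methylation
# at splice sites, and assembly of the per-event feature matrix.

#' Call the ORF/PTC status of an isoform
#'
#' Derives exon-junction transcript positions from the exon chain and
#' evaluates the 50-nt rule: the transcript is flagged when some junction
#' lies at least 50 nt downstream of the stop codon (distance measured from
#' the first base after the stop codon). `is_ptc` additionally flags stops
#' lying strictly 5' of the gene's reference stop codon (mapped through the
#' genome), so early stops in last exons are still recognised as premature;
#' the two criteria are reported separately.
#'
#' @param t a [transcript_model()].
#' @param orf this isoform's row from [select_main_orf()]`$orfs` (or any list
#'   with `orf_start`/`orf_stop` transcript coordinates, 0-based, `orf_stop`
#'   just past the terminal stop codon).
#' @param gene_reference_stop optional genomic coordinate (0-based) of the
#'   last base of the gene's reference stop codon, as returned by
#'   [reference_stop_genomic()].
#' @param rule_50nt_min junction distance threshold in nt (default 50).
#' @return one-row data.frame: `transcript_id`, `stop_pos_tx`,
#'   `n_3utr_spliced_introns`, `dist_stop_to_first_downstream_junction_nt`
#'   (`NA` when no 3' UTR junction exists), `utr3_length_nt`,
#'   `utr5_length_nt`, `rule_50nt`, `stop_upstream_of_reference`, `is_ptc`.
#' @export
call_orf_and_ptc <- function(t, orf, gene_reference_stop = NULL,
                             rule_50nt_min = 50L) {
  if (is.null(orf) || !length(orf) || is.na(orf$orf_start)) {
    stop("non-coding isoform ", t$transcript_id, ": no ORF to evaluate")
  }
  total <- tx_length(t)
  jx <- tx_junctions(t)
  stop_end <- orf$orf_stop              # first base after the stop codon
  down <- jx[jx >= stop_end] - stop_end
  n_utr3_jx <- length(down)
  first_dist <- if (n_utr3_jx) min(down) else NA_integer_
  rule_50nt <- any(down >= rule_50nt_min)
  upstream <- FALSE
  if (!is.null(gene_reference_stop) && !is.na(gene_reference_stop)) {
    own_stop_g <- tx_to_genome(t, stop_end - 1L)
    upstream <- if (t$strand == "+") own_stop_g < gene_reference_stop
                else own_stop_g > gene_reference_stop
  }
  data.frame(transcript_id = t$transcript_id, stop_pos_tx = stop_end,
             n_3utr_spliced_introns = n_utr3_jx,
             dist_stop_to_first_downstream_junction_nt = first_dist,
             utr3_length_nt = total - stop_end,
             utr5_length_nt = orf$orf_start,
             rule_50nt = rule_50nt,
             stop_upstream_of_reference = upstream,
             is_ptc = rule_50nt || upstream,
             stringsAsFactors = FALSE)
}

#' Genomic coordinate of a transcript's stop codon
#'
#' Maps the last base of the selected ORF's stop codon to the genome; used
#' as the `gene_reference_stop` anchor in [call_orf_and_ptc()].
#'
#' @param t a [transcript_model()].
#' @param orf the isoform's ORF selection row.
#' @return 0-based genomic coordinate.
#' @export
reference_stop_genomic <- function(t, orf) {
  tx_to_genome(t, orf$orf_stop - 1L)
}

#' Detect upstream ORFs in a 5' leader
#'
#' A uORF is an ATG starting before the main ORF with an in-frame stop codon
#' (which may lie past the main start, in which case the uORF overlaps it);
#' minimum length two codons including the stop. Nested same-frame ATGs
#' count once per distinct start. Codon frequencies are tallied over all
#' codons of all uORFs (starts and stops included).
#'
#' @param seq full spliced transcript sequence (so that uORF stops past the
#'   main start can be found); the leader is `substring(seq, 1, main_start)`.
#' @param main_start_tx 0-based transcript coordinate of the main ATG.
#' @return list: `n_uorfs`, `uorf_lengths_nt`, `overlaps_main_start`
#'   (logical per uORF), `codon_freq` (named numeric, empty when no uORF).
#' @export
detect_uorfs <- function(seq, main_start_tx) {
  n <- nchar(seq)
  empty <- list(n_uorfs = 0L, uorf_lengths_nt = integer(0),
                overlaps_main_start = logical(0), codon_freq = numeric(0))
  if (main_start_tx < 3L) return(empty)
  leader <- substring(seq, 1L, main_start_tx)
  atg <- as.integer(gregexpr("ATG", leader, fixed = TRUE)[[1L]])
  atg <- atg[atg > 0L] - 1L
  if (!length(atg)) return(empty)
  lens <- integer(0); over <- logical(0); codons_all <- character(0)
  for (a in atg) {
    starts <- seq.int(a, n - 3L, by = 3L)
    if (length(starts) < 2L) next
    cods <- substring(seq, starts + 1L, starts + 3L)
    si <- which(cods %in% STOP_CODONS)[1L]
    if (is.na(si) || si == 1L) next
    stop_end <- starts[si] + 3L
    lens <- c(lens, stop_end - a)
    over <- c(over, stop_end > main_start_tx)
    codons_all <- c(codons_all, cods[seq_len(si)])
  }
  if (!length(lens)) return(empty)
  freq <- table(codons_all) / length(codons_all)
  list(n_uorfs = length(lens), uorf_lengths_nt = lens,
       overlaps_main_start = over,
       codon_freq = stats::setNames(as.numeric(freq), names(freq)))
}

#' K-mer composition of a sequence
#'
#' Overlapping k-mer counts normalized to frequencies, one block per k. A
#' sequence shorter than k yields an all-zero block (logged).
#'
#' @param seq DNA string.
#' @param k_values integer vector of k-mer sizes (default `1:3`).
#' @param prefix prepended to feature names (context window label).
#' @return named numeric vector, names `"<prefix>k<k>_<mer>"`.
#' @export
compute_composition <- function(seq, k_values = 1:3, prefix = "") {
  out <- numeric(0)
  dna <- Biostrings::DNAString(if (nchar(seq)) seq else "A")
  for (k in sort(k_values)) {
    counts <- Biostrings::oligonucleotideFrequency(dna, width = k)
    if (nchar(seq) < k) {
      message("sequence shorter than k=", k, "; zero composition block")
      counts[] <- 0L
    }
    tot <- sum(counts)
    freq <- if (tot > 0) counts / tot else counts
    names(freq) <- sprintf("%sk%d_%s", prefix, k, names(counts))
    out <- c(out, freq)
  }
  out
}

#' The six NMD-associated sequence motifs
#'
#' IUPAC motifs reported as over-represented (CAGTTGAAATTT, GTGAAAVTTTTC)
#' or under-represented (CCAACATCAT, CTTGGCTA, THTCAWGGGT) in NMD-targeted
#' transcripts, plus CTACAAGA from the importance ranking.
#'
#' @return character vector of IUPAC motifs.
#' @export
default_motif_set <- function() {
  c("CAGTTGAAATTT", "GTGAAAVTTTTC", "CCAACATCAT",
    "CTTGGCTA", "THTCAWGGGT", "CTACAAGA")
}

#' Count motif matches in a sequence
#'
#' Counts possibly-overlapping matches of IUPAC motifs (V = A/C/G,
#' H = A/C/T, W = A/T, ...) on the transcript's forward strand.
#'
#' @param seq DNA string.
#' @param motifs character vector of IUPAC motifs
#'   (default [default_motif_set()]).
#' @return named integer vector of counts.
#' @export
scan_motifs <- function(seq, motifs = default_motif_set()) {
  ok <- grepl("^[ACGTRYSWKMBDHVN]+$", motifs)
  if (!all(ok)) {
    stop("invalid IUPAC motif: ", paste(motifs[!ok], collapse = ", "))
  }
  if (!nchar(seq)) {
    return(stats::setNames(integer(length(motifs)), motifs))
  }
  subject <- Biostrings::DNAString(seq)
  counts <- vapply(motifs, function(m) {
    Biostrings::countPattern(m, subject, fixed = FALSE)
  }, integer(1L))
  stats::setNames(counts, motifs)
}

#' Read a per-site cytosine methylation table
#'
#' @param path TSV with columns `contig`, `pos` (0-based), `mC_fraction`,
#'   and optionally `coverage`.
#' @return data.frame.
#' @export
read_methylation_table <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("contig", "pos", "mC_fraction")
  if (!all(need %in% names(m))) {
    stop("methylation table must have columns: ",
         paste(need, collapse = ", "))
  }
  if (!"coverage" %in% names(m)) m$coverage <- 1L
  m
}

#' Methylation features at event splice sites
#'
#' Coverage-weighted mean mC fraction in +/-25 nt windows around the event's
#' donor site, acceptor site, and over the event interval. Donor/acceptor
#' are the event boundaries in transcript orientation (strand-aware). Sites
#' without data contribute nothing; a window with no covered site yields 0
#' plus a companion missingness flag.
#'
#' @param events event catalog data.frame.
#' @param meth methylation table (see [read_methylation_table()]).
#' @param window half-window width in nt (default 25).
#' @return data.frame keyed by `event_id` with `meth_donor`,
#'   `meth_acceptor`, `meth_event` and `*_missing` flags.
#' @export
join_methylation <- function(events, meth, window = 25L) {
  win_mean <- function(contig, lo, hi) {
    sel <- meth$contig == contig & meth$pos >= lo & meth$pos < hi
    if (!any(sel)) return(c(0, 1))
    w <- meth$coverage[sel]
    c(sum(meth$mC_fraction[sel] * w) / sum(w), 0)
  }
  res <- lapply(seq_len(nrow(events)), function(i) {
    s <- events$start[i]; e <- events$end[i]
    donor <- if (events$strand[i] == "+") s else e
    acceptor <- if (events$strand[i] == "+") e else s
    d <- win_mean(events$contig[i], donor - window, donor + window)
    a <- win_mean(events$contig[i], acceptor - window, acceptor + window)
    ev <- win_mean(events$contig[i], s, e)
    data.frame(event_id = events$event_id[i],
               meth_donor = d[1L], meth_acceptor = a[1L], meth_event = ev[1L],
               meth_donor_missing = d[2L], meth_acceptor_missing = a[2L],
               meth_event_missing = ev[2L], stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
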