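# Splice-event decomposition: diff an alternative isoform against the
# reference isoform and classify localized differences into the six-type
# AS typology (retained/spliced intron, included/skipped exon, alternative
# donor/acceptor), plus exitron sub-typing of retained introns.

#' Diff two isoforms into classified splicing events
#'
#' Compares the exon chains of an alternative and a reference isoform of the
#' same gene over the genomic intersection of their spans. Each maximal run
#' of bases exonic in exactly one of the two isoforms becomes one event,
#' typed from its flanking splice junctions:
#' \itemize{
#'   \item reference intron fully exonic in alt -> `retained_intron`
#'   \item alt intron fully exonic in reference -> `spliced_intron`
#'   \item introns sharing the 3' splice site but not the 5' -> `alt_donor`
#'     (the mirror case -> `alt_acceptor`); donor/acceptor assignment is
#'     strand-aware
#'   \item alt exon internal to a reference intron whose two flanking
#'     junctions pair with the intron boundaries -> `included_exon`
#'   \item reference exon spanned by a single alt intron -> `skipped_exon`
#' }
#' Runs whose junction context matches none of the patterns are typed
#' `retained_intron`/`spliced_intron` by direction, flagged `residual = TRUE`
#' and logged via `message()`. The union of event intervals equals, base for
#' base, the symmetric difference of the two exonic base sets within the
#' shared span.
#'
#' @param alt,ref [transcript_model()] objects on the same gene and strand.
#' @return data.frame with one row per event: `event_id`, `gene_id`,
#'   `alt_transcript_id`, `ref_transcript_id`, `event_type`, `contig`,
#'   `start`, `end`, `strand`, `residual`, and a list-column
#'   `diagnostic_junctions` (each a list with `ref` and `alt` 2-column
#'   matrices of intron intervals unique to that isoform).
#' @export
diff_isoforms <- function(alt, ref) {
  if (alt$contig != ref$contig || alt$strand != ref$strand) {
    stop("isoforms on different contigs/strands: ",
         alt$transcript_id, " vs ", ref$transcript_id)
  }
  if (!identical(alt$gene_id, ref$gene_id)) {
    stop("isoforms belong to different genes")
  }
  lo <- max(min(alt$exons), min(ref$exons))
  hi <- min(max(alt$exons), max(ref$exons))
  empty <- event_frame()
  if (hi <= lo) stop("isoform spans do not overlap")
  am <- exonic_mask(alt$exons, lo, hi)
  rm_ <- exonic_mask(ref$exons, lo, hi)
  diff <- am != rm_
  if (!any(diff)) return(empty)
  runs <- true_runs(diff)
  ri <- tx_introns(ref)
  ai <- tx_introns(alt)
  has_intron <- function(introns, s, e) {
    any(introns[, 1L] == s & introns[, 2L] == e)
  }
  containing_intron <- function(introns, u, v) {
    k <- which(introns[, 1L] <= u & v <= introns[, 2L])
    if (length(k)) introns[k[1L], ] else NULL
  }
  rows <- vector("list", nrow(runs))
  for (r in seq_len(nrow(runs))) {
    u <- lo + runs[r, 1L]; v <- lo + runs[r, 2L]
    alt_side <- am[runs[r, 1L] + 1L]  # TRUE: exonic in alt only
    own <- if (alt_side) ri else ai    # intron of the isoform lacking the run
    oth <- if (alt_side) ai else ri
    itr <- containing_intron(own, u, v)
    type <- NA_character_
    residual <- FALSE
    jx_own <- NULL; jx_oth <- NULL
    if (is.null(itr)) {
      # run abuts the shared-span edge without a containing intron
      type <- if (alt_side) "retained_intron" else "spliced_intron"
      residual <- TRUE
    } else {
      s <- itr[[1L]]; e <- itr[[2L]]
      if (u == s && v == e) {
        type <- if (alt_side) "retained_intron" else "spliced_intron"
        jx_own <- rbind(c(s, e))
      } else if (u == s && v < e && has_intron(oth, v, e)) {
        # shared genomic end, differing genomic start
        type <- splice_site_type(alt$strand, differing = "start")
        jx_own <- rbind(c(s, e)); jx_oth <- rbind(c(v, e))
      } else if (u > s && v == e && has_intron(oth, s, u)) {
        type <- splice_site_type(alt$strand, differing = "end")
        jx_own <- rbind(c(s, e)); jx_oth <- rbind(c(s, u))
      } else if (u > s && v < e && has_intron(oth, s, u) &&
                 has_intron(oth, v, e)) {
        type <- if (alt_side) "included_exon" else "skipped_exon"
        jx_own <- rbind(c(s, e)); jx_oth <- rbind(c(s, u), c(v, e))
      } else {
        type <- if (alt_side) "retained_intron" else "spliced_intron"
        residual <- TRUE
        jx_own <- rbind(c(s, e))
      }
    }
    if (residual) {
      message("residual event in ", ref$gene_id, " at ", alt$contig, ":",
              u, "-", v, " typed as ", type)
    }
    jx_ref <- if (alt_side) jx_own else jx_oth
    jx_alt <- if (alt_side) jx_oth else jx_own
    rows[[r]] <- data.frame(
      event_id = event_id_string(ref$gene_id, type, alt$contig, u, v),
      gene_id = ref$gene_id, alt_transcript_id = alt$transcript_id,
      ref_transcript_id = ref$transcript_id, event_type = type,
      contig = alt$contig, start = u, end = v, strand = alt$strand,
      residual = residual, stringsAsFactors = FALSE)
    rows[[r]]$diagnostic_junctions <- list(list(ref = jx_ref, alt = jx_alt))
  }
  do.call(rbind, rows)
}

# donor = transcript-5' end of the intron = genomic start on "+", genomic
# end on "-"; an intron pair differing at the donor is an alt_donor event
splice_site_type <- function(strand, differing) {
  if ((strand == "+") == (differing == "start")) "alt_donor" else "alt_acceptor"
}

event_frame <- function() {
  df <- data.frame(event_id = character(0), gene_id = character(0),
                   alt_transcript_id = character(0),
                   ref_transcript_id = character(0),
                   event_type = character(0), contig = character(0),
                   start = integer(0), end = integer(0),
                   strand = character(0), residual = logical(0),
                   stringsAsFactors = FALSE)
  df$diagnostic_junctions <- list()
  df
}

#' Test whether a retained intron is an exitron
#'
#' An exitron is a retained intron lying strictly within the reference coding
#' region whose retention preserves the reading frame (length a multiple of
#' 3) and introduces no stop codon when read in CDS frame — so the
#' alternative isoform terminates at the reference stop codon and carries no
#' premature termination codon.
#'
#' @param event one row of a [diff_isoforms()]/[build_event_catalog()] frame
#'   with `event_type == "retained_intron"`.
#' @param ref the reference [transcript_model()].
#' @param ref_orf the reference isoform's row from
#'   [select_main_orf()]`$orfs` (transcript-coordinate ORF), or `NULL` for a
#'   non-coding reference.
#' @param genome `DNAStringSet` holding the contig.
#' @return `TRUE` or `FALSE`.
#' @export
classify_exitron <- function(event, ref, ref_orf, genome) {
  stopifnot(event$event_type == "retained_intron")
  if (is.null(ref_orf) || !nrow(as.data.frame(ref_orf))) {
    message("exitron test on non-coding reference ", ref$transcript_id,
            ": FALSE")
    return(FALSE)
  }
  len <- event$end - event$start
  if (len %% 3L != 0L) return(FALSE)
  # insertion point of the intron in reference transcript coordinates
  ri <- tx_introns(ref)
  k <- which(ri[, 1L] == event$start & ri[, 2L] == event$end)
  if (!length(k)) return(FALSE)
  lens <- ref$exons[, 2L] - ref$exons[, 1L]
  p_plus <- cumsum(lens)[k]            # plus-orientation transcript coord
  p <- if (ref$strand == "+") p_plus else tx_length(ref) - p_plus
  if (p <= ref_orf$orf_start || p >= ref_orf$orf_stop) return(FALSE)
  # splice the intron into the CDS and require a clean translation
  ref_seq <- extract_transcript_sequence(ref, genome)
  cds <- substring(ref_seq, ref_orf$orf_start + 1L, ref_orf$orf_stop)
  intron_seq <- substring(as.character(genome[[event$contig]]),
                          event$start + 1L, event$end)
  if (ref$strand == "-") intron_seq <- revcomp(intron_seq)
  at <- p - ref_orf$orf_start
  mod <- paste0(substring(cds, 1L, at), intron_seq,
                substring(cds, at + 1L, nchar(cds)))
  starts <- seq.int(1L, nchar(mod) - 2L, by = 3L)
  codons <- substring(mod, starts, starts + 2L)
  stops <- which(codons %in% STOP_CODONS)
  length(stops) > 0L && stops[1L] == length(codons)
}

#' Build a deduplicated gene-set-wide event catalog
#'
#' Chooses (or accepts) each gene's reference isoform, diffs every other
#' isoform against it, merges events identical in (gene, type, interval,
#' junctions) across alternative isoforms, and sub-types retained introns as
#' exitrons. Event ids are deterministic and stable across runs.
#'
#' @param models named list `gene_id -> list of transcript_model` (as from
#'   [load_annotation()]).
#' @param genome `DNAStringSet`; defaults to `attr(models, "genome")`.
#' @param orf_selections optional named list `gene_id ->`
#'   [select_main_orf()] result; computed when absent.
#' @param homology,expression forwarded to [select_main_orf()] when
#'   `orf_selections` is computed here.
#' @return data.frame catalog: one row per distinct event, with
#'   `alt_transcript_id` a comma-separated list of supporting isoforms and an
#'   `is_exitron` flag (`NA` for non-retained types).
#' @export
build_event_catalog <- function(models, genome = NULL, orf_selections = NULL,
                                homology = NULL, expression = NULL) {
  genome <- genome %||% attr(models, "genome")
  if (is.null(genome)) stop("genome required")
  if (is.null(orf_selections)) {
    orf_selections <- compute_orf_selections(models, genome, homology,
                                             expression)
  }
  all_events <- list()
  for (gene in names(models)) {
    iso <- models[[gene]]
    if (length(iso) < 2L) next
    ids <- vapply(iso, function(t) t$transcript_id, character(1L))
    ref_id <- orf_selections[[gene]]$reference
    if (is.na(ref_id)) ref_id <- ids[1L]
    ref <- iso[[match(ref_id, ids)]]
    for (t in iso[ids != ref_id]) {
      ev <- diff_isoforms(t, ref)
      if (nrow(ev)) all_events[[length(all_events) + 1L]] <- ev
    }
  }
  if (!length(all_events)) return(event_frame())
  ev <- do.call(rbind, all_events)
  key <- vapply(seq_len(nrow(ev)), function(i) {
    j <- ev$diagnostic_junctions[[i]]
    paste(ev$event_id[i],
          paste(c(t(j$ref %||% matrix(0, 0, 2)),
                  t(j$alt %||% matrix(0, 0, 2))), collapse = ","))
  }, character(1L))
  merged <- lapply(split(seq_len(nrow(ev)), key), function(idx) {
    row <- ev[idx[1L], , drop = FALSE]
    row$alt_transcript_id <-
      paste(sort(unique(ev$alt_transcript_id[idx])), collapse = ",")
    row
  })
  cat <- do.call(rbind, merged)
  cat <- cat[order(cat$contig, cat$start, cat$end, cat$event_type), ,
             drop = FALSE]
  rownames(cat) <- NULL
  cat$is_exitron <- NA
  for (i in which(cat$event_type == "retained_intron")) {
    gene <- cat$gene_id[i]
    sel <- orf_selections[[gene]]
    ids <- vapply(models[[gene]], function(t) t$transcript_id, character(1L))
    ref <- models[[gene]][[match(cat$ref_transcript_id[i], ids)]]
    orf_row <- sel$orfs[sel$orfs$transcript_id == cat$ref_transcript_id[i], ,
                        drop = FALSE]
    cat$is_exitron[i] <- classify_exitron(
      cat[i, , drop = FALSE], ref,
      if (nrow(orf_row)) orf_row else NULL, genome)
  }
  cat
}

#' Write an event catalog as BED-like TSV
#'
#' @param catalog data.frame from [build_event_catalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_catalog <- function(catalog, path) {
  fmt_j <- function(m) {
    if (is.null(m) || !nrow(m)) return("")
    paste(sprintf("%d-%d", m[, 1L], m[, 2L]), collapse = ",")
  }
  out <- data.frame(
    contig = catalog$contig, start = catalog$start, end = catalog$end,
    event_id = catalog$event_id, event_type = catalog$event_type,
    strand = catalog$strand, gene_id = catalog$gene_id,
    ref_transcript_id = catalog$ref_transcript_id,
    alt_transcript_id = catalog$alt_transcript_id,
    is_exitron = catalog$is_exitron,
    ref_junctions = vapply(catalog$diagnostic_junctions, function(j)
      fmt_j(j$ref), character(1L)),
    alt_junctions = vapply(catalog$diagnostic_junctions, function(j)
      fmt_j(j$alt), character(1L)),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
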