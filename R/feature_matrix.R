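# Assembly and filtering of the per-event feature matrix.

#' Compute the full per-event feature matrix
#'
#' Orchestrates the feature extractors over an event catalog: one-hot AS-type
#' indicators, structural features (PTC call under the 50-nt rule, 3' UTR
#' junctions, uORF profile, exon/intron architecture, distances from TSS and
#' CDS), k-mer composition of transcript / 3' UTR / event-window contexts,
#' motif counts, methylation at splice sites, and (in EXP mode) expression
#' features from the differential tests.
#'
#' @param catalog event catalog from [build_event_catalog()].
#' @param models transcript models as from [load_annotation()].
#' @param genome `DNAStringSet`; defaults to `attr(models, "genome")`.
#' @param orf_selections optional per-gene [select_main_orf()] results.
#' @param methylation optional methylation table
#'   (see [read_methylation_table()]).
#' @param expression optional data.frame keyed by `event_id` with expression
#'   features, e.g. from [expression_feature_block()]. Required in EXP mode.
#' @param mode `"EXP"` (include expression features) or `"NOEXP"`.
#' @param k_values k-mer sizes for composition features.
#' @param flank nt of genomic flank added around the event interval for the
#'   event-context composition window.
#' @return numeric matrix, rows = events (rownames = `event_id`), columns in
#'   deterministic order; attribute `"schema"` lists column names by block.
#' @export
event_feature_matrix <- function(catalog, models, genome = NULL,
                                 orf_selections = NULL, methylation = NULL,
                                 expression = NULL, mode = c("EXP", "NOEXP"),
                                 k_values = 1:3, flank = 50L) {
  mode <- match.arg(mode)
  genome <- genome %||% attr(models, "genome")
  if (is.null(orf_selections)) {
    orf_selections <- compute_orf_selections(models, genome)
  }
  types <- c("retained_intron", "spliced_intron", "included_exon",
             "skipped_exon", "alt_acceptor", "alt_donor")
  struct <- vector("list", nrow(catalog))
  comp <- vector("list", nrow(catalog))
  motif <- vector("list", nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    gene <- catalog$gene_id[i]
    iso <- models[[gene]]
    ids <- vapply(iso, function(t) t$transcript_id, character(1L))
    alt_id <- strsplit(catalog$alt_transcript_id[i], ",", fixed = TRUE)[[1L]][1L]
    alt <- iso[[match(alt_id, ids)]]
    ref <- iso[[match(catalog$ref_transcript_id[i], ids)]]
    sel <- orf_selections[[gene]]
    alt_orf <- sel$orfs[sel$orfs$transcript_id == alt_id, , drop = FALSE]
    ref_orf <- sel$orfs[sel$orfs$transcript_id == ref$transcript_id, ,
                        drop = FALSE]
    alt_seq <- extract_transcript_sequence(alt, genome)
    ref_stop_g <- if (nrow(ref_orf)) {
      reference_stop_genomic(ref, ref_orf)
    } else NA_integer_
    # evaluate the alt isoform's stop relative to the gene's authentic
    # start codon when it is present in the isoform
    if (nrow(ref_orf) && alt_id != ref$transcript_id) {
      ref_start_g <- tx_to_genome(ref, ref_orf$orf_start)
      anch <- anchored_orf(alt, alt_seq, ref_start_g)
      if (!is.null(anch)) alt_orf <- anch
    }
    onehot <- stats::setNames(as.numeric(types == catalog$event_type[i]),
                              paste0("AS_type.", types))
    coding <- nrow(alt_orf) > 0L
    if (coding) {
      ptc <- call_orf_and_ptc(alt, alt_orf, ref_stop_g)
      uorf <- detect_uorfs(alt_seq, alt_orf$orf_start)
      utr3_seq <- substring(alt_seq, alt_orf$orf_stop + 1L, nchar(alt_seq))
    } else {
      ptc <- data.frame(n_3utr_spliced_introns = 0L,
                        dist_stop_to_first_downstream_junction_nt = NA,
                        utr3_length_nt = 0L, utr5_length_nt = 0L,
                        rule_50nt = FALSE, stop_upstream_of_reference = FALSE,
                        is_ptc = FALSE)
      uorf <- detect_uorfs("", 0L)
      utr3_seq <- ""
    }
    exlen <- alt$exons[, 2L] - alt$exons[, 1L]
    inlen <- tx_introns(alt)
    inlen <- if (nrow(inlen)) inlen[, 2L] - inlen[, 1L] else 0L
    # anchors as inter-base boundary coordinates so distances are invariant
    # under a strand-flipped mirror of the locus
    plus <- alt$strand == "+"
    tss <- if (plus) min(alt$exons) else max(alt$exons)
    ev_mid <- (catalog$start[i] + catalog$end[i]) / 2
    cds_start_g <- if (coding) {
      tx_to_genome(alt, alt_orf$orf_start) + !plus
    } else tss
    cds_stop_g <- if (coding) {
      tx_to_genome(alt, alt_orf$orf_stop - 1L) + plus
    } else tss
    uorf_codon <- function(codon) {
      if (codon %in% names(uorf$codon_freq)) uorf$codon_freq[[codon]] else 0
    }
    struct[[i]] <- c(
      onehot,
      is_exitron = as.numeric(isTRUE(catalog$is_exitron[i])),
      is_coding = as.numeric(coding),
      n_3utr_spliced_introns = ptc$n_3utr_spliced_introns,
      dist_stop_to_first_downstream_junction_nt =
        ifelse(is.na(ptc$dist_stop_to_first_downstream_junction_nt), 0,
               ptc$dist_stop_to_first_downstream_junction_nt),
      has_3utr_junction = as.numeric(ptc$n_3utr_spliced_introns > 0),
      utr3_length_nt = ptc$utr3_length_nt,
      utr5_length_nt = ptc$utr5_length_nt,
      rule_50nt = as.numeric(ptc$rule_50nt),
      stop_upstream_of_reference =
        as.numeric(ptc$stop_upstream_of_reference),
      is_ptc = as.numeric(ptc$is_ptc),
      n_exons = nrow(alt$exons), n_introns = max(nrow(alt$exons) - 1L, 0L),
      tx_length_nt = tx_length(alt),
      mean_exon_length_nt = mean(exlen),
      mean_intron_length_nt = mean(inlen),
      cds_length_nt = if (coding) alt_orf$orf_length_nt else 0,
      event_length_nt = catalog$end[i] - catalog$start[i],
      event_dist_tss_nt = abs(ev_mid - tss),
      event_dist_cds_start_nt = abs(ev_mid - cds_start_g),
      event_dist_cds_stop_nt = abs(ev_mid - cds_stop_g),
      n_uorfs = uorf$n_uorfs,
      uorf_total_length_nt = sum(uorf$uorf_lengths_nt),
      uorf_overlaps_main_start = as.numeric(any(uorf$overlaps_main_start)),
      uorf_codon_ATC = uorf_codon("ATC"),
      uorf_codon_AAC = uorf_codon("AAC"),
      uorf_codon_GGT = uorf_codon("GGT"))
    ev_lo <- max(catalog$start[i] - flank, 0L)
    ev_hi <- min(catalog$end[i] + flank,
                 length(genome[[catalog$contig[i]]]))
    ev_seq <- substring(as.character(genome[[catalog$contig[i]]]),
                        ev_lo + 1L, ev_hi)
    if (catalog$strand[i] == "-") ev_seq <- revcomp(ev_seq)
    comp[[i]] <- c(compute_composition(alt_seq, k_values, prefix = "tx_"),
                   compute_composition(utr3_seq, k_values, prefix = "utr3_"),
                   compute_composition(ev_seq, k_values, prefix = "event_"))
    motif[[i]] <- scan_motifs(alt_seq)
  }
  to_df <- function(lst) {
    df <- as.data.frame(do.call(rbind, lst))
    df <- cbind(event_id = catalog$event_id, df, stringsAsFactors = FALSE)
    df
  }
  meth_block <- if (!is.null(methylation)) {
    join_methylation(catalog, methylation)
  } else NULL
  assemble_features(catalog, ptc_calls = to_df(struct),
                    composition = to_df(comp),
                    motifs = {
                      m <- to_df(motif)
                      names(m)[-1L] <- paste0("motif_", names(m)[-1L])
                      m
                    },
                    methylation = meth_block, expression = expression,
                    mode = mode)
}

#' Assemble feature blocks into one matrix
#'
#' Joins per-event feature blocks (each a data.frame with an `event_id`
#' column) in a fixed block order; absent values become 0 after the join
#' (methylation blocks carry explicit missingness flags). In NOEXP mode the
#' expression block is dropped entirely, so NOEXP columns are a strict
#' subset of EXP columns.
#'
#' @param catalog event catalog (defines row order).
#' @param ptc_calls,composition,motifs,methylation,expression feature blocks.
#' @param mode `"EXP"` or `"NOEXP"`.
#' @return numeric matrix with `event_id` rownames and a `"schema"`
#'   attribute naming each block's columns.
#' @export
assemble_features <- function(catalog, ptc_calls = NULL, composition = NULL,
                              motifs = NULL, methylation = NULL,
                              expression = NULL, mode = c("EXP", "NOEXP")) {
  mode <- match.arg(mode)
  if (anyDuplicated(catalog$event_id)) {
    stop("duplicate event_id in catalog: ",
         catalog$event_id[duplicated(catalog$event_id)][1L])
  }
  blocks <- list(structural = ptc_calls, composition = composition,
                 motifs = motifs, methylation = methylation)
  if (mode == "EXP") {
    if (is.null(expression)) {
      stop("EXP mode requires an expression block; ",
           "use mode = \"NOEXP\" without expression data")
    }
    blocks$expression <- expression
  }
  blocks <- Filter(Negate(is.null), blocks)
  out <- data.frame(event_id = catalog$event_id, stringsAsFactors = FALSE)
  schema <- list()
  for (b in names(blocks)) {
    blk <- blocks[[b]]
    if (anyDuplicated(blk$event_id)) {
      stop("duplicate event_id in ", b, " block")
    }
    schema[[b]] <- setdiff(names(blk), "event_id")
    out <- merge(out, blk, by = "event_id", all.x = TRUE, sort = FALSE)
  }
  out <- out[match(catalog$event_id, out$event_id), , drop = FALSE]
  m <- as.matrix(out[, setdiff(names(out), "event_id"), drop = FALSE])
  mode(m) <- "numeric"
  m[is.na(m)] <- 0
  rownames(m) <- catalog$event_id
  attr(m, "schema") <- schema
  m
}

#' Expression feature block from differential results
#'
#' Reshapes [differential_events()] output into per-event expression
#' features (log2 fold change, FDR per mutant contrast, mean CPM) for the
#' EXP-mode feature matrix.
#'
#' @param results data.frame from [differential_events()].
#' @return data.frame keyed by `event_id`.
#' @export
expression_feature_block <- function(results) {
  wide <- NULL
  for (ct in unique(results$contrast)) {
    sub <- results[results$contrast == ct,
                   c("event_id", "log2fc", "fdr", "cpm_mean")]
    names(sub)[-1L] <- paste0(c("log2fc_", "fdr_", "cpm_"), ct)
    wide <- if (is.null(wide)) sub else merge(wide, sub, by = "event_id")
  }
  wide
}

#' Feature filter configuration
#'
#' Defaults follow the conventional near-zero-variance definition
#' (most-frequent / second-most-frequent ratio > 95/5, distinct values
#' < 10% of rows) and the >75% correlation cutoff.
#'
#' @param nzv_freq_ratio frequency ratio above which a column is
#'   near-zero-variance (jointly with `nzv_unique_pct`).
#' @param nzv_unique_pct distinct-value percentage below which a column is
#'   near-zero-variance.
#' @param correlation_cutoff absolute pairwise Pearson correlation above
#'   which one member of a pair is dropped; in (0, 1].
#' @return list of class `feature_filter_config`.
#' @export
feature_filter_config <- function(nzv_freq_ratio = 19,
                                  nzv_unique_pct = 10,
                                  correlation_cutoff = 0.75) {
  stopifnot(correlation_cutoff > 0, correlation_cutoff <= 1)
  structure(list(nzv_freq_ratio = nzv_freq_ratio,
                 nzv_unique_pct = nzv_unique_pct,
                 correlation_cutoff = correlation_cutoff),
            class = "feature_filter_config")
}

#' Filter near-zero-variance and highly correlated features
#'
#' Drops near-zero-variance columns, then iteratively removes, from every
#' pair with |Pearson r| above the cutoff, the member with the larger mean
#' absolute correlation to all remaining columns (ties broken by column
#' order), until the maximum pairwise |r| is at or below the cutoff.
#' Filtering is idempotent.
#'
#' @param m numeric feature matrix (events x features).
#' @param cfg a [feature_filter_config()].
#' @return filtered matrix; attribute `"removed"` records dropped column
#'   names by reason.
#' @export
filter_features <- function(m, cfg = feature_filter_config()) {
  m <- as.matrix(m)
  nzv <- caret::nearZeroVar(m, freqCut = cfg$nzv_freq_ratio,
                            uniqueCut = cfg$nzv_unique_pct)
  removed_nzv <- colnames(m)[nzv]
  keep <- if (length(nzv)) m[, -nzv, drop = FALSE] else m
  if (!ncol(keep)) stop("all features removed as near-zero variance")
  removed_cor <- character(0)
  if (ncol(keep) > 1L) {
    cm <- suppressWarnings(stats::cor(keep))
    cm[is.na(cm)] <- 0
    drop <- caret::findCorrelation(cm, cutoff = cfg$correlation_cutoff,
                                   exact = TRUE)
    removed_cor <- colnames(keep)[drop]
    if (length(drop)) keep <- keep[, -drop, drop = FALSE]
  }
  if (!ncol(keep)) stop("all features removed by correlation filter")
  sch <- attr(m, "schema")
  if (!is.null(sch)) {
    attr(keep, "schema") <- lapply(sch, intersect, y = colnames(keep))
  }
  attr(keep, "removed") <- list(near_zero_variance = removed_nzv,
                                correlated = removed_cor)
  keep
}

#' Write a feature matrix with its JSON schema sidecar
#'
#' @param m feature matrix from [event_feature_matrix()].
#' @param path output TSV path; the schema is written to `<path>.schema.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path) {
  df <- data.frame(event_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  schema <- attr(m, "schema") %||% list(all = colnames(m))
  jsonlite::write_json(schema, paste0(path, ".schema.json"), pretty = TRUE)
  invisible(path)
}
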