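# Shared helpers: hand-built transcript models, a naive per-base sequence
# oracle, random isoform-pair generation for the event-classification
# oracle, and model comparison utilities.

make_tm <- function(exons, strand = "+", contig = "chr1", tx = "t1",
                    gene = "g1", cds = NULL) {
  transcript_model(tx, gene, contig, strand, exons, cds)
}

random_genome <- function(n, contig = "chr1") {
  Biostrings::DNAStringSet(stats::setNames(
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    contig))
}

# naive per-base extraction oracle (character-by-character)
naive_extract <- function(t, genome) {
  s <- strsplit(as.character(genome[[t$contig]]), "")[[1L]]
  bases <- unlist(lapply(seq_len(nrow(t$exons)), function(i)
    s[(t$exons[i, 1L] + 1L):t$exons[i, 2L]]))
  if (t$strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    bases <- rev(unname(comp[bases]))
  }
  paste(bases, collapse = "")
}

# random multi-exon reference model
random_ref_model <- function(contig = "chr1", strand = NULL) {
  n_ex <- sample(2:6, 1L)
  lens <- sample(30:120, n_ex, replace = TRUE)
  introns <- sample(30:80, n_ex - 1L, replace = TRUE)
  starts <- integer(n_ex)
  pos <- sample(5:50, 1L)
  for (i in seq_len(n_ex)) {
    starts[i] <- pos
    pos <- pos + lens[i]
    if (i < n_ex) pos <- pos + introns[i]
  }
  if (is.null(strand)) strand <- sample(c("+", "-"), 1L)
  make_tm(cbind(starts, starts + lens), strand = strand, contig = contig)
}

# perturb a reference model with 1-2 random splicing changes, keeping the
# span fixed; returns NULL when no feasible op was found
random_alt_model <- function(ref) {
  exons <- ref$exons
  n_ops <- sample(1:2, 1L)
  changed <- FALSE
  for (op in sample(c("retain", "splice", "shift", "skip", "include"),
                    n_ops, replace = TRUE)) {
    introns <- if (nrow(exons) > 1L) {
      cbind(exons[-nrow(exons), 2L], exons[-1L, 1L])
    } else matrix(integer(0), ncol = 2L)
    if (op == "retain" && nrow(introns) > 0L) {
      k <- sample(nrow(introns), 1L)
      exons <- rbind(exons[seq_len(k - 1L), , drop = FALSE],
                     c(exons[k, 1L], exons[k + 1L, 2L]),
                     exons[-seq_len(k + 1L), , drop = FALSE])
      changed <- TRUE
    } else if (op == "splice") {
      k <- which(exons[, 2L] - exons[, 1L] >= 20L)
      if (!length(k)) next
      k <- sample(rep(k, 2L), 1L)
      w <- exons[k, 2L] - exons[k, 1L]
      a <- exons[k, 1L] + sample(2:(w - 12L), 1L)
      b <- a + sample(3:min(w - (a - exons[k, 1L]) - 2L, 40L), 1L)
      exons <- rbind(exons[seq_len(k - 1L), , drop = FALSE],
                     c(exons[k, 1L], a), c(b, exons[k, 2L]),
                     exons[-seq_len(k), , drop = FALSE])
      changed <- TRUE
    } else if (op == "shift" && nrow(introns) > 0L) {
      k <- sample(rep(seq_len(nrow(introns)), 2L), 1L)
      side <- sample(c("start", "end"), 1L)
      d <- sample(1:10, 1L)
      if (side == "start" &&
          exons[k, 2L] - exons[k, 1L] > d + 2L) {
        exons[k, 2L] <- exons[k, 2L] - d
        changed <- TRUE
      } else if (side == "end" &&
                 exons[k + 1L, 2L] - exons[k + 1L, 1L] > d + 2L) {
        exons[k + 1L, 1L] <- exons[k + 1L, 1L] + d
        changed <- TRUE
      }
    } else if (op == "skip" && nrow(exons) >= 3L) {
      k <- sample(rep(2:(nrow(exons) - 1L), 2L), 1L)
      exons <- exons[-k, , drop = FALSE]
      changed <- TRUE
    } else if (op == "include" && nrow(introns) > 0L) {
      w <- introns[, 2L] - introns[, 1L]
      k <- which(w >= 15L)
      if (!length(k)) next
      k <- sample(rep(k, 2L), 1L)
      a <- introns[k, 1L] + sample(2:5, 1L)
      b <- min(a + sample(5:20, 1L), introns[k, 2L] - 2L)
      exons <- rbind(exons, c(a, b))
      exons <- exons[order(exons[, 1L]), , drop = FALSE]
      changed <- TRUE
    }
  }
  if (!changed) return(NULL)
  make_tm(exons, strand = ref$strand, contig = ref$contig, tx = "t2",
          gene = ref$gene_id)
}

# per-base exon-membership diff oracle over the shared span: returns sorted
# 0-based positions exonic in exactly one isoform
membership_diff <- function(a, b) {
  lo <- max(min(a$exons), min(b$exons))
  hi <- min(max(a$exons), max(b$exons))
  in_a <- in_b <- logical(hi - lo)
  for (i in seq_len(nrow(a$exons))) {
    s <- max(a$exons[i, 1L], lo); e <- min(a$exons[i, 2L], hi)
    if (e > s) in_a[(s - lo + 1L):(e - lo)] <- TRUE
  }
  for (i in seq_len(nrow(b$exons))) {
    s <- max(b$exons[i, 1L], lo); e <- min(b$exons[i, 2L], hi)
    if (e > s) in_b[(s - lo + 1L):(e - lo)] <- TRUE
  }
  lo + which(in_a != in_b) - 1L
}

# check diff_isoforms against the oracle; TRUE when the event intervals
# tile the symmetric difference exactly and disjointly
events_match_oracle <- function(alt, ref) {
  ev <- suppressMessages(diff_isoforms(alt, ref))
  covered <- as.integer(unlist(lapply(seq_len(nrow(ev)), function(i)
    seq.int(ev$start[i], ev$end[i] - 1L))))
  expected <- membership_diff(alt, ref)
  !anyDuplicated(covered) && identical(sort(covered), expected)
}

# mirror a model onto the reverse-complemented contig
flip_model <- function(t, contig_len) {
  flip <- function(m) cbind(contig_len - m[, 2L], contig_len - m[, 1L])
  make_tm(flip(t$exons), strand = if (t$strand == "+") "-" else "+",
          contig = t$contig, tx = t$transcript_id, gene = t$gene_id,
          cds = if (!is.null(t$cds)) flip(t$cds))
}

models_equal <- function(a, b) {
  isTRUE(all.equal(unname(a$exons), unname(b$exons))) &&
    identical(a$strand, b$strand) && identical(a$contig, b$contig) &&
    ((is.null(a$cds) && is.null(b$cds)) ||
       isTRUE(all.equal(unname(a$cds), unname(b$cds))))
}

# small cached fixture shared across tests (computed once per run)
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_genes = 40L, seed = 424L)
      fx <- generate_fixture(cfg)
      orfs <- compute_orf_selections(fx$models, fx$genome,
                                     homology = fx$homology)
      catal <- build_event_catalog(fx$models, fx$genome,
                                   orf_selections = orfs)
      cache <<- list(cfg = cfg, fx = fx, orfs = orfs, catalog = catal)
    }
    cache
  }
})
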