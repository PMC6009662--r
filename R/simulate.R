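# Synthetic fixtures emulating an NMD-inhibition RNA-seq study: multi-exon
# genes with one planted splicing event per gene, golden NMD labels,
# negative-binomial count tables (wild type + two mutant lines, two
# replicates each) and optional read-level evidence.
#
# Genes are laid out in transcript orientation ("plus layout") with all
# exon-exon junctions codon-aligned, so frame-preserving events can be
# planted from stop-free codons and premature stops can be planted exactly
# at a junction; minus-strand genes are produced by reverse-complementing
# the finished contig. Each planted isoform's PTC/50-nt status is verified
# by a small string-level codon scanner (independent of the package's
# ORF caller) and the gene is re-drawn on the rare mismatch.

#' Simulation configuration
#'
#' Defaults emulate the study design the generator stands in for: two
#' biological replicates for wild type and each of two NMD-deficient mutant
#' lines; NMD-target isoforms up-regulated in both mutants with log2 fold
#' changes from Uniform(1, 3); negative-binomial counts at dispersion 0.1;
#' a secondary-change class (shifted in one mutant only) planted to exercise
#' the both-mutants logic.
#'
#' @param n_genes number of genes (one planted event each).
#' @param event_type_mix named proportions over the six event types.
#' @param nmd_fraction fraction of events planted as NMD targets.
#' @param secondary_fraction fraction planted as secondary changes.
#' @param lfc_nmd range of planted log2 fold changes (uniform).
#' @param dispersion negative-binomial dispersion.
#' @param mean_expression list with `meanlog`, `sdlog` of the log-normal
#'   baseline mean.
#' @param replicates replicates per genotype.
#' @param uorf_fraction fraction of genes given a planted 5' leader uORF.
#' @param flank nt of intergenic flank on each side of a gene.
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 200L,
                              event_type_mix = c(retained_intron = 0.30,
                                                 spliced_intron = 0.10,
                                                 included_exon = 0.15,
                                                 skipped_exon = 0.10,
                                                 alt_acceptor = 0.175,
                                                 alt_donor = 0.175),
                              nmd_fraction = 0.30,
                              secondary_fraction = 0.10,
                              lfc_nmd = c(1, 3),
                              dispersion = 0.1,
                              mean_expression = list(meanlog = log(100),
                                                     sdlog = 0.6),
                              replicates = 2L,
                              uorf_fraction = 0.3,
                              flank = 100L,
                              seed = 1L) {
  stopifnot(abs(sum(event_type_mix) - 1) < 1e-8,
            nmd_fraction >= 0, nmd_fraction <= 1,
            nmd_fraction + secondary_fraction <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 event_type_mix = event_type_mix,
                 nmd_fraction = nmd_fraction,
                 secondary_fraction = secondary_fraction,
                 lfc_nmd = lfc_nmd, dispersion = dispersion,
                 mean_expression = mean_expression,
                 replicates = as.integer(replicates),
                 uorf_fraction = uorf_fraction,
                 flank = as.integer(flank), seed = as.integer(seed)),
            class = "simulation_config")
}

BODY_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T"), paste0)),
                  c("A", "C", "G", "T"), paste0)),
  c("TAA", "TAG", "TGA", "ATG"))

rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ATG-free random sequence (so the planted main ATG stays the 5'-most)
rand_noncoding <- function(n) {
  s <- rand_dna(n)
  s <- gsub("ATG", "ATC", s, fixed = TRUE)
  gsub("ATG", "ATC", s, fixed = TRUE)
}

# stop-free, ATG-free codon run of n_codons codons
rand_codons <- function(n_codons) {
  if (n_codons <= 0L) return("")
  paste(sample(BODY_CODONS, n_codons, replace = TRUE), collapse = "")
}

# independent string-level scanner: first in-frame stop from orf_start and
# the 50-nt rule against the given junction positions
scan_stop <- function(tx, orf_start, junctions, rule_min = 50L) {
  n <- nchar(tx)
  starts <- seq.int(orf_start, n - 3L, by = 3L)
  cods <- substring(tx, starts + 1L, starts + 3L)
  si <- which(cods %in% STOP_CODONS)[1L]
  if (is.na(si)) return(NULL)
  stop_end <- starts[si] + 3L
  list(stop_end = stop_end,
       rule_50nt = any(junctions - stop_end >= rule_min))
}

# one gene with its reference isoform and one alternative isoform realizing
# `event_type` with intended NMD status; returns NULL when the random draw
# fails verification (caller retries)
build_gene <- function(gene_id, contig_id, event_type, planted_class,
                       strand, uorf = FALSE, flank = 100L) {
  nmd <- planted_class == "nmd"
  n_ex <- sample(4:6, 1L)
  u5 <- sample(60:120, 1L)
  c1 <- 3L * sample(40:70, 1L)
  internal <- 3L * sample(50:90, n_ex - 2L)
  if (event_type == "skipped_exon" && nmd) {
    internal[1L] <- internal[1L] + sample(1:2, 1L)  # frameshifting skip
  }
  if (event_type == "spliced_intron") {
    internal[1L] <- max(internal[1L], 180L)  # room for junction reads
  }
  cL <- 3L * sample(20:40, 1L)
  cL <- cL + (3L - (c1 + sum(internal) + cL) %% 3L) %% 3L
  u3 <- sample(100:180, 1L)
  exon_lens <- c(u5 + c1, internal, cL + 3L + u3)
  intron_lens <- 3L * sample(27:60, n_ex - 1L, replace = TRUE)
  if (event_type == "included_exon") {
    intron_lens[2L] <- 240L + 3L * sample(0:20, 1L)
  }
  cds_len <- c1 + sum(internal) + cL + 3L
  tx_len <- sum(exon_lens)

  u5_seq <- rand_noncoding(u5)
  if (uorf && u5 >= 40L) {
    ustart <- sample(5:(u5 - 25L), 1L)
    ubody <- paste0("ATG", rand_codons(sample(1:3, 1L)), "TAA")
    substr(u5_seq, ustart, ustart + nchar(ubody) - 1L) <- ubody
  }
  cds_seq <- paste0("ATG", rand_codons((cds_len - 6L) %/% 3L), "TAA")
  u3_seq <- rand_noncoding(u3)
  tx_seq <- paste0(u5_seq, cds_seq, u3_seq)

  # intron sequences; the planted event may prescribe one
  intron_seqs <- vapply(intron_lens, rand_noncoding, character(1L))
  ev <- list()          # interval offsets relative to the gene layout
  inc_exon <- NULL
  if (event_type == "retained_intron") {
    if (nmd) {
      intron_seqs[2L] <- paste0("TAA", rand_noncoding(intron_lens[2L] - 3L))
    } else {
      intron_seqs[2L] <- rand_codons(intron_lens[2L] %/% 3L)
      ev$is_exitron <- TRUE
    }
  } else if (event_type == "included_exon") {
    m <- if (nmd) 57L + 3L * sample(0:4, 1L) else 60L
    exon_seq <- if (nmd) paste0("TAA", rand_noncoding(m - 3L))
                else rand_codons(m %/% 3L)
    g <- 90L
    rest <- intron_lens[2L] - g - m
    intron_seqs[2L] <- paste0(rand_noncoding(g), exon_seq,
                              rand_noncoding(rest))
    inc_exon <- c(g, g + m)
  }

  # genomic layout (plus orientation)
  exon_starts <- integer(n_ex)
  pos <- flank
  gene_seq_parts <- character(0)
  tx_off <- c(0L, cumsum(exon_lens))
  for (i in seq_len(n_ex)) {
    exon_starts[i] <- pos
    gene_seq_parts <- c(gene_seq_parts,
                        substring(tx_seq, tx_off[i] + 1L, tx_off[i + 1L]))
    pos <- pos + exon_lens[i]
    if (i < n_ex) {
      gene_seq_parts <- c(gene_seq_parts, intron_seqs[i])
      pos <- pos + intron_lens[i]
    }
  }
  contig_len <- pos + flank
  contig_seq <- paste0(rand_noncoding(flank),
                       paste(gene_seq_parts, collapse = ""),
                       rand_noncoding(flank))
  exons <- cbind(exon_starts, exon_starts + exon_lens)
  i2 <- c(exons[2L, 2L], exons[3L, 1L])   # intron 2 interval

  # alternative isoform exon chain + event interval (plus layout)
  alt <- exons
  if (event_type == "retained_intron") {
    alt <- rbind(exons[1L, ], c(exons[2L, 1L], exons[3L, 2L]),
                 exons[-(1:3), , drop = FALSE])
    interval <- i2
  } else if (event_type == "spliced_intron") {
    a <- 3L * sample(17:20, 1L)
    L <- 3L * sample(15:18, 1L) + if (nmd) sample(1:2, 1L) else 0L
    s <- exons[2L, 1L] + a
    alt <- rbind(exons[1L, ], c(exons[2L, 1L], s), c(s + L, exons[2L, 2L]),
                 exons[-(1:2), , drop = FALSE])
    interval <- c(s, s + L)
  } else if (event_type == "included_exon") {
    ne <- i2[1L] + inc_exon
    alt <- rbind(exons[1:2, ], ne, exons[-(1:2), , drop = FALSE])
    interval <- ne
  } else if (event_type == "skipped_exon") {
    alt <- exons[-2L, , drop = FALSE]
    interval <- exons[2L, ]
  } else if (event_type == "alt_donor") {
    d <- 3L * sample(4:10, 1L) + if (nmd) sample(1:2, 1L) else 0L
    alt[2L, 2L] <- alt[2L, 2L] - d
    interval <- c(i2[1L] - d, i2[1L])
  } else if (event_type == "alt_acceptor") {
    d <- 3L * sample(4:10, 1L) + if (nmd) sample(1:2, 1L) else 0L
    alt[3L, 1L] <- alt[3L, 1L] + d
    interval <- c(i2[2L], i2[2L] + d)
  } else stop("unknown event type: ", event_type)

  # verify intended PTC / 50-nt status with the string scanner
  alt_lens <- alt[, 2L] - alt[, 1L]
  alt_tx <- paste(substring(contig_seq, alt[, 1L] + 1L, alt[, 2L]),
                  collapse = "")
  alt_jx <- cumsum(alt_lens)[-length(alt_lens)]
  sc <- scan_stop(alt_tx, u5, alt_jx)
  if (is.null(sc)) return(NULL)
  has_ptc <- sc$stop_end < nchar(alt_tx) - u3
  if (nmd && !(has_ptc && sc$rule_50nt)) return(NULL)
  if (!nmd && has_ptc) return(NULL)
  ref_sc <- scan_stop(tx_seq, u5, cumsum(exon_lens)[-n_ex])
  if (is.null(ref_sc) || ref_sc$stop_end != u5 + cds_len) return(NULL)

  # CDS genomic intervals of the reference isoform
  cds_tx <- c(u5, u5 + cds_len)
  cds <- NULL
  for (i in seq_len(n_ex)) {
    a <- max(cds_tx[1L], tx_off[i]); b <- min(cds_tx[2L], tx_off[i + 1L])
    if (b > a) {
      cds <- rbind(cds, exons[i, 1L] + c(a, b) - tx_off[i])
    }
  }

  flip <- function(m, L) cbind(L - m[, 2L], L - m[, 1L])
  if (strand == "-") {
    contig_seq <- revcomp(contig_seq)
    exons <- flip(exons, contig_len)
    alt <- flip(alt, contig_len)
    cds <- flip(cds, contig_len)
    interval <- c(contig_len - interval[2L], contig_len - interval[1L])
  }
  ref_id <- paste0(gene_id, ".t1")
  alt_id <- paste0(gene_id, ".t2")
  list(
    contig_seq = contig_seq,
    ref = transcript_model(ref_id, gene_id, contig_id, strand, exons, cds),
    alt = transcript_model(alt_id, gene_id, contig_id, strand, alt),
    event = data.frame(
      event_id = event_id_string(gene_id, event_type, contig_id,
                                 interval[1L], interval[2L]),
      gene_id = gene_id, alt_transcript_id = alt_id,
      ref_transcript_id = ref_id, event_type = event_type,
      contig = contig_id, start = interval[1L], end = interval[2L],
      strand = strand, is_nmd = nmd,
      is_exitron = isTRUE(ev$is_exitron),
      planted_class = planted_class, stringsAsFactors = FALSE),
    transcripts = data.frame(
      transcript_id = c(ref_id, alt_id),
      has_ptc = c(FALSE, has_ptc),
      rule_50nt = c(FALSE, sc$rule_50nt), stringsAsFactors = FALSE))
}

#' Generate a synthetic fixture with golden labels
#'
#' Builds a genome, a multi-isoform annotation realizing the configured
#' event-type mix and NMD fractions, and the golden label tables. Planted
#' NMD events create a premature stop with an exon-exon junction at least
#' 50 nt downstream; planted non-NMD retained introns are exitrons
#' (in-frame, stop-free, within the CDS). Deterministic under
#' `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return list of class `asnmd_fixture`: `genome` (`DNAStringSet`),
#'   `models` (as from [load_annotation()], genome attached), `labels`
#'   (list with `events` and `transcripts` data.frames), `homology` (named
#'   scores pinning each gene's reference isoform, emulating the homology
#'   criterion of main-ORF selection), `config`.
#' @export
generate_fixture <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_genes
  # deterministic census honouring the mix
  type_counts <- floor(cfg$event_type_mix * n)
  rem <- n - sum(type_counts)
  if (rem > 0) {
    frac <- cfg$event_type_mix * n - type_counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    type_counts[add] <- type_counts[add] + 1L
  }
  types <- sample(rep(names(type_counts), type_counts))
  n_nmd <- round(cfg$nmd_fraction * n)
  n_sec <- round(cfg$secondary_fraction * n)
  classes <- sample(rep(c("nmd", "secondary", "stable"),
                        c(n_nmd, n_sec, n - n_nmd - n_sec)))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  uorfs <- stats::runif(n) < cfg$uorf_fraction

  genomes <- character(n)
  models <- vector("list", n)
  events <- vector("list", n)
  txs <- vector("list", n)
  contigs <- sprintf("chr%03d", seq_len(n))
  gene_ids <- sprintf("g%03d", seq_len(n))
  for (i in seq_len(n)) {
    g <- NULL
    for (try in 1:50) {
      g <- build_gene(gene_ids[i], contigs[i], types[i], classes[i],
                      strands[i], uorf = uorfs[i], flank = cfg$flank)
      if (!is.null(g)) break
    }
    if (is.null(g)) {
      stop("could not realize a ", classes[i], " ", types[i],
           " event for gene ", gene_ids[i])
    }
    genomes[i] <- g$contig_seq
    models[[i]] <- list(g$ref, g$alt)
    events[[i]] <- g$event
    txs[[i]] <- g$transcripts
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(genomes, contigs))
  names(models) <- gene_ids
  ev <- do.call(rbind, events)
  # planted log2 fold changes (both mutants for NMD, one for secondary)
  ev$planted_lfc_mut1 <- 0
  ev$planted_lfc_mut2 <- 0
  is_n <- ev$planted_class == "nmd"
  lfc <- stats::runif(sum(is_n), cfg$lfc_nmd[1L], cfg$lfc_nmd[2L])
  ev$planted_lfc_mut1[is_n] <- lfc
  ev$planted_lfc_mut2[is_n] <- lfc
  is_s <- ev$planted_class == "secondary"
  which_mut <- sample(1:2, sum(is_s), replace = TRUE)
  lfc_s <- stats::runif(sum(is_s), cfg$lfc_nmd[1L], cfg$lfc_nmd[2L])
  ev$planted_lfc_mut1[is_s][which_mut == 1L] <- lfc_s[which_mut == 1L]
  ev$planted_lfc_mut2[is_s][which_mut == 2L] <- lfc_s[which_mut == 2L]
  attr(models, "genome") <- genome
  structure(list(
    genome = genome, models = models,
    labels = list(events = ev, transcripts = do.call(rbind, txs)),
    homology = stats::setNames(
      rep(1, n), vapply(models, function(m) m[[1L]]$transcript_id,
                        character(1L))),
    config = cfg), class = "asnmd_fixture")
}

#' Write a fixture to disk
#'
#' Emits `genome.fasta`, `annotation.gff3`, `labels.json` and
#' `homology.tsv`; byte-identical across runs with the same seed.
#'
#' @param fixture an [generate_fixture()] result.
#' @param dir output directory (created if needed).
#' @return named vector of paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fasta"),
             gff3 = file.path(dir, "annotation.gff3"),
             labels = file.path(dir, "labels.json"),
             homology = file.path(dir, "homology.tsv"))
  Biostrings::writeXStringSet(fixture$genome, paths["fasta"])
  write_gff3(fixture$models, paths["gff3"])
  jsonlite::write_json(fixture$labels, paths["labels"], digits = NA,
                       dataframe = "columns")
  utils::write.table(
    data.frame(transcript_id = names(fixture$homology),
               score = unname(fixture$homology)),
    paths["homology"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Simulate an event count table from golden labels
#'
#' Wild-type means are log-normal; NMD events get mean
#' `mu * 2^planted_lfc` in both mutant lines (secondary events in one);
#' counts are negative-binomial at the configured dispersion (Poisson at
#' dispersion 0).
#'
#' @param labels golden labels (`fixture$labels`).
#' @param cfg the fixture's [simulation_config()].
#' @return an [event_count_table()] with columns
#'   `WT_*`, `mut1_*`, `mut2_*`.
#' @export
simulate_counts <- function(labels, cfg = simulation_config()) {
  set.seed(cfg$seed + 104729L)
  ev <- labels$events
  reps <- cfg$replicates
  mu <- stats::rlnorm(nrow(ev), cfg$mean_expression$meanlog,
                      cfg$mean_expression$sdlog)
  draw <- function(mean_vec) {
    if (cfg$dispersion <= 0) {
      matrix(stats::rpois(length(mean_vec) * reps, rep(mean_vec, reps)),
             ncol = reps)
    } else {
      matrix(stats::rnbinom(length(mean_vec) * reps,
                            mu = rep(mean_vec, reps),
                            size = 1 / cfg$dispersion), ncol = reps)
    }
  }
  counts <- cbind(draw(mu), draw(mu * 2^ev$planted_lfc_mut1),
                  draw(mu * 2^ev$planted_lfc_mut2))
  colnames(counts) <- c(paste0("WT_", seq_len(reps)),
                        paste0("mut1_", seq_len(reps)),
                        paste0("mut2_", seq_len(reps)))
  rownames(counts) <- ev$event_id
  # libraries are sequenced to equal depth: the event table is a small
  # window on the transcriptome, so per-library depth is not the event-table
  # column sum (between-library normalization beyond CPM is out of scope)
  event_count_table(counts,
                    library_sizes = rep(round(mean(colSums(counts))),
                                        ncol(counts)))
}

#' Simulate read-level evidence as SAM files
#'
#' Emits, per library, gapped reads supporting the alternative side of each
#' event (junction-spanning or retention-crossing), with known per-event
#' provenance equal to `planted`, plus deliberately uninformative exonic
#' reads that match no event. Written as plain-text SAM.
#'
#' @param fixture an [generate_fixture()] result.
#' @param catalog the event catalog built from the fixture (defines the
#'   diagnostic junctions used for read construction).
#' @param planted integer matrix of planted read counts
#'   (events x libraries), rownames = `event_id`.
#' @param dir output directory.
#' @param read_length read length in nt (default 100, single-end).
#' @param ambiguous_per_gene uninformative exonic reads added per gene per
#'   library.
#' @return list with `paths` (named SAM paths), `planted` (the matrix,
#'   reordered to the catalog) and `ambiguous` (reads per library that must
#'   stay unassigned).
#' @export
simulate_read_evidence <- function(fixture, catalog, planted, dir,
                                   read_length = 100L,
                                   ambiguous_per_gene = 2L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  planted <- planted[catalog$event_id, , drop = FALSE]
  genome <- fixture$genome
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                      Biostrings::width(genome)))
  seq_of <- function(contig, blocks) {
    paste(substring(as.character(genome[[contig]]),
                    blocks[, 1L] + 1L, blocks[, 2L]), collapse = "")
  }
  # per event: POS (1-based), CIGAR and aligned blocks of its template read
  templates <- lapply(seq_len(nrow(catalog)), function(i) {
    ctg <- catalog$contig[i]
    if (catalog$event_type[i] == "retained_intron") {
      s <- catalog$diagnostic_junctions[[i]]$ref[1L, 1L]
      start <- s - 30L
      blocks <- cbind(start, start + read_length)
      list(pos = start + 1L, cigar = sprintf("%dM", read_length),
           blocks = blocks, contig = ctg)
    } else {
      j <- catalog$diagnostic_junctions[[i]]$alt[1L, ]
      half <- 50L
      blocks <- rbind(c(j[1L] - half, j[1L]), c(j[2L], j[2L] + half))
      list(pos = j[1L] - half + 1L,
           cigar = sprintf("%dM%dN%dM", half, j[2L] - j[1L], half),
           blocks = blocks, contig = ctg)
    }
  })
  libs <- colnames(planted)
  paths <- stats::setNames(file.path(dir, paste0(libs, ".sam")), libs)
  genes <- unique(catalog$gene_id)
  first_exon <- lapply(stats::setNames(genes, genes), function(g) {
    t1 <- fixture$models[[g]][[1L]]
    ex <- if (t1$strand == "+") t1$exons[1L, ] else
      t1$exons[nrow(t1$exons), ]
    list(contig = t1$contig, start = ex[1L])
  })
  ambiguous <- stats::setNames(integer(length(libs)), libs)
  for (lib in libs) {
    lines <- header
    rid <- 0L
    for (i in seq_len(nrow(catalog))) {
      tp <- templates[[i]]
      n <- planted[i, lib]
      if (n <= 0L) next
      sq <- seq_of(tp$contig, tp$blocks)
      ql <- strrep("I", nchar(sq))
      for (k in seq_len(n)) {
        rid <- rid + 1L
        lines <- c(lines, paste(sprintf("r_%s_%06d", lib, rid), 0L,
                                tp$contig, tp$pos, 60L, tp$cigar, "*", 0L,
                                0L, sq, ql, sep = "\t"))
      }
    }
    for (g in genes) {
      fe <- first_exon[[g]]
      for (k in seq_len(ambiguous_per_gene)) {
        rid <- rid + 1L
        blocks <- cbind(fe$start + 5L, fe$start + 5L + read_length)
        sq <- seq_of(fe$contig, blocks)
        lines <- c(lines, paste(sprintf("r_%s_%06d", lib, rid), 0L,
                                fe$contig, fe$start + 6L, 60L,
                                sprintf("%dM", read_length), "*", 0L, 0L,
                                sq, strrep("I", nchar(sq)), sep = "\t"))
        ambiguous[lib] <- ambiguous[lib] + 1L
      }
    }
    writeLines(lines, paths[[lib]])
  }
  list(paths = paths, planted = planted, ambiguous = ambiguous)
}
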