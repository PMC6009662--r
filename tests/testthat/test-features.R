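# NMD feature extraction: 50-nt rule, uORFs, composition, motifs,
# methylation, matrix assembly and filtering.

# two-exon model with the junction at transcript position `jpos` and a stop
# codon ending at transcript position `stop_end`
two_exon_ptc <- function(jpos, total = 400L) {
  make_tm(cbind(c(0L, jpos + 50L), c(jpos, jpos + 50L + (total - jpos))))
}

test_that("the 50-nt rule flips exactly at 50 nt downstream of the stop", {
  t <- two_exon_ptc(200L)
  orf <- list(orf_start = 30L, orf_stop = 150L)
  # junction at 200; stop_end 150 -> distance 50
  call50 <- call_orf_and_ptc(t, orf)
  expect_true(call50$rule_50nt)
  expect_true(call50$is_ptc)
  expect_equal(call50$dist_stop_to_first_downstream_junction_nt, 50L)
  # stop one base later -> distance 49
  call49 <- call_orf_and_ptc(t, list(orf_start = 31L, orf_stop = 151L))
  expect_false(call49$rule_50nt)
  expect_equal(call49$dist_stop_to_first_downstream_junction_nt, 49L)
  expect_equal(call49$n_3utr_spliced_introns, 1L)
})

test_that("single-exon transcripts never satisfy the junction rule", {
  t <- make_tm(cbind(0L, 400L))
  res <- call_orf_and_ptc(t, list(orf_start = 30L, orf_stop = 150L))
  expect_equal(res$n_3utr_spliced_introns, 0L)
  expect_false(res$rule_50nt)
  expect_true(is.na(res$dist_stop_to_first_downstream_junction_nt))
  expect_equal(res$utr3_length_nt, 250L)
})

test_that("adding a farther downstream junction never un-flags the rule", {
  set.seed(5)
  for (i in 1:50) {
    jpos <- sample(160:260, 1L)
    t1 <- two_exon_ptc(jpos)
    orf <- list(orf_start = 30L, orf_stop = sample(60:150, 1L))
    r1 <- call_orf_and_ptc(t1, orf)
    # add another exon far downstream (one extra junction)
    ex <- t1$exons
    t2 <- make_tm(rbind(ex, c(max(ex) + 80L, max(ex) + 160L)))
    r2 <- call_orf_and_ptc(t2, orf)
    expect_true(!r1$rule_50nt || r2$rule_50nt)
  }
})

test_that("a stop upstream of the reference stop is premature even in the last exon", {
  t <- make_tm(cbind(c(0L, 100L), c(80L, 300L)))
  # stop at transcript 150 (genomic 170+20=...), junction at 80 is upstream
  res <- call_orf_and_ptc(t, list(orf_start = 10L, orf_stop = 150L),
                          gene_reference_stop = 280L)
  expect_false(res$rule_50nt)
  expect_true(res$stop_upstream_of_reference)
  expect_true(res$is_ptc)
})

test_that("uORF detection matches hand-built leaders", {
  res <- detect_uorfs("CCATGAAATAACC", 11L)
  expect_equal(res$n_uorfs, 1L)
  expect_equal(res$uorf_lengths_nt, 9L)
  expect_false(any(res$overlaps_main_start))
  expect_equal(unname(res$codon_freq[c("ATG", "AAA", "TAA")]),
               rep(1 / 3, 3L))
  # no ATG in the leader
  empty <- detect_uorfs("CCCCCCCCCCCC", 10L)
  expect_equal(empty$n_uorfs, 0L)
  expect_length(empty$codon_freq, 0L)
})

test_that("uORFs may overlap the main start and codons tally correctly", {
  # leader of 12 nt; uORF ATG ATC AAC GGT TAA runs past the main start
  seq <- paste0("CC", "ATGATCAACGGTTAA", "ATGCCCCCC")
  res <- detect_uorfs(seq, 8L)
  expect_equal(res$n_uorfs, 1L)
  expect_true(res$overlaps_main_start)
  expect_equal(unname(res$codon_freq[c("ATC", "AAC", "GGT")]),
               rep(0.2, 3L))
  expect_equal(sum(res$codon_freq), 1)
})

test_that("composition frequencies are normalized sliding-window counts", {
  c1 <- compute_composition("ACGT", k_values = 1L)
  expect_equal(unname(c1), rep(0.25, 4L))
  set.seed(3)
  seq <- paste(sample(c("A", "C", "G", "T"), 30L, replace = TRUE),
               collapse = "")
  c3 <- compute_composition(seq, k_values = 3L)
  # naive window oracle
  wins <- substring(seq, 1:28, 3:30)
  for (mer in names(c3)) {
    expect_equal(unname(c3[mer]),
                 sum(wins == sub("k3_", "", mer)) / 28)
  }
  expect_equal(sum(c3), 1)
  expect_message(cz <- compute_composition("AC", k_values = 3L), "shorter")
  expect_equal(sum(cz), 0)
})

test_that("motif scanning expands IUPAC codes like a regex oracle", {
  expect_equal(unname(scan_motifs("AAGTGAAACTTTTCAA")["GTGAAAVTTTTC"]), 1L)
  expect_equal(sum(scan_motifs("")), 0L)
  expect_error(scan_motifs("ACGT", motifs = "AC-GT"), "IUPAC")
  expect_setequal(default_motif_set(),
                  c("CAGTTGAAATTT", "GTGAAAVTTTTC", "CCAACATCAT",
                    "CTTGGCTA", "THTCAWGGGT", "CTACAAGA"))
  # random sequences vs regex expansion, overlapping matches included
  iupac <- c(V = "[ACG]", H = "[ACT]", W = "[AT]", T = "T", A = "A",
             C = "C", G = "G")
  set.seed(11)
  for (i in 1:30) {
    seq <- paste(sample(c("A", "C", "G", "T"), 400L, replace = TRUE),
                 collapse = "")
    for (motif in c("THTCAWGGGT", "CTACAAGA", "TWT")) {
      rx <- paste0("(?=", paste(iupac[strsplit(motif, "")[[1L]]],
                                collapse = ""), ")")
      hits <- gregexpr(rx, seq, perl = TRUE)[[1L]]
      want <- if (hits[1L] == -1L) 0L else length(hits)
      expect_equal(unname(scan_motifs(seq, motif)), want)
    }
  }
})

test_that("methylation features average coverage-weighted windows", {
  ev <- data.frame(event_id = "e1", contig = "chr1", start = 100L,
                   end = 160L, strand = "+")
  zero <- join_methylation(ev, data.frame(contig = "chr1", pos = 1L,
                                          mC_fraction = 0, coverage = 10L))
  expect_equal(unlist(zero[c("meth_donor", "meth_acceptor", "meth_event")]),
               c(meth_donor = 0, meth_acceptor = 0, meth_event = 0))
  uniform <- join_methylation(ev, data.frame(
    contig = "chr1", pos = 0:300, mC_fraction = 0.5, coverage = 5L))
  expect_equal(unname(unlist(
    uniform[c("meth_donor", "meth_acceptor", "meth_event")])),
    rep(0.5, 3L))
  # hand-built 5-site window around the donor (positions 75..124)
  meth <- data.frame(contig = "chr1", pos = c(80L, 90L, 100L, 110L, 120L),
                     mC_fraction = c(0.1, 0.2, 0.3, 0.4, 0.5),
                     coverage = c(1L, 1L, 2L, 1L, 1L))
  out <- join_methylation(ev, meth)
  expect_equal(out$meth_donor,
               sum(c(0.1, 0.2, 0.3 * 2, 0.4, 0.5)) / 6)
  expect_equal(out$meth_acceptor_missing, 1)
  expect_equal(out$meth_acceptor, 0)
})

test_that("assembled matrices have one-hot types, no gaps, and nested modes", {
  fxc <- small_fixture()
  tab <- simulate_counts(fxc$fx$labels, fxc$cfg)
  tab$counts <- tab$counts[fxc$catalog$event_id, , drop = FALSE]
  res <- differential_events(tab)
  expr <- expression_feature_block(res)
  meth <- data.frame(contig = rep(names(fxc$fx$genome)[1L], 50L),
                     pos = seq(10L, 500L, by = 10L),
                     mC_fraction = stats::runif(50L), coverage = 3L)
  m_exp <- event_feature_matrix(fxc$catalog, fxc$fx$models, fxc$fx$genome,
                                orf_selections = fxc$orfs,
                                methylation = meth, expression = expr,
                                mode = "EXP")
  m_noexp <- event_feature_matrix(fxc$catalog, fxc$fx$models, fxc$fx$genome,
                                  orf_selections = fxc$orfs,
                                  methylation = meth, mode = "NOEXP")
  expect_true(all(colnames(m_noexp) %in% colnames(m_exp)))
  expect_gt(ncol(m_exp), ncol(m_noexp))
  expect_false(anyNA(m_exp))
  onehot <- m_exp[, grep("^AS_type\\.", colnames(m_exp)), drop = FALSE]
  expect_equal(unname(rowSums(onehot)), rep(1, nrow(m_exp)))
  expect_equal(nrow(m_exp), nrow(fxc$catalog))
  expect_named(attr(m_exp, "schema"),
               c("structural", "composition", "motifs", "methylation",
                 "expression"))
  expect_error(event_feature_matrix(
    fxc$catalog, fxc$fx$models, fxc$fx$genome, orf_selections = fxc$orfs,
    mode = "EXP"), "EXP mode requires")
})

test_that("feature assembly rejects duplicate event ids", {
  catal <- data.frame(event_id = c("e1", "e1"))
  expect_error(assemble_features(catal, mode = "NOEXP"), "duplicate")
})

test_that("near-zero-variance and duplicated columns are filtered", {
  set.seed(8)
  m <- cbind(a = rnorm(50L), b = rnorm(50L), const = rep(1, 50L))
  m <- cbind(m, dup = m[, "a"])
  out <- filter_features(m)
  removed <- attr(out, "removed")
  expect_equal(removed$near_zero_variance, "const")
  expect_length(intersect(c("a", "dup"), colnames(out)), 1L)
})

test_that("every feature survives a genome mirror of the fixture", {
  # reverse-complement two loci and flip their models: features unchanged
  fxc <- small_fixture()
  genes <- names(fxc$fx$models)[1:4]
  catal <- fxc$catalog[fxc$catalog$gene_id %in% genes, , drop = FALSE]
  models <- fxc$fx$models[genes]
  attr(models, "genome") <- fxc$fx$genome
  m1 <- event_feature_matrix(catal, models, fxc$fx$genome,
                             orf_selections = fxc$orfs[genes],
                             mode = "NOEXP")
  flip_models <- models
  contig_len <- stats::setNames(Biostrings::width(fxc$fx$genome),
                                names(fxc$fx$genome))
  genome2 <- fxc$fx$genome
  catal2 <- catal
  for (g in genes) {
    L <- contig_len[[models[[g]][[1L]]$contig]]
    flip_models[[g]] <- lapply(models[[g]], flip_model, contig_len = L)
    ctg <- models[[g]][[1L]]$contig
    genome2[[ctg]] <- Biostrings::reverseComplement(fxc$fx$genome[[ctg]])
    sel <- catal2$gene_id == g
    s <- catal2$start[sel]
    catal2$start[sel] <- L - catal2$end[sel]
    catal2$end[sel] <- L - s
    catal2$strand[sel] <- ifelse(catal2$strand[sel] == "+", "-", "+")
  }
  attr(flip_models, "genome") <- genome2
  m2 <- event_feature_matrix(catal2, flip_models, genome2,
                             orf_selections = NULL, mode = "NOEXP")
  expect_equal(unname(m2), unname(m1), tolerance = 1e-12)
})
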