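# Annotation model: GFF3/FASTA loading, coordinate conventions, spliced
# sequence extraction, and main-ORF selection.

test_that("GFF3 loading converts 1-based coordinates and builds models", {
  dir <- withr::local_tempdir()
  fasta <- file.path(dir, "g.fa")
  writeLines(c(">chr1", strrep("ACGT", 30)), fasta)
  gff <- file.path(dir, "a.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\tx\tmRNA\t1\t100\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tx\texon\t1\t30\t.\t+\t.\tParent=g1.t1",
    "chr1\tx\texon\t61\t100\t.\t+\t.\tParent=g1.t1"), gff)
  models <- load_annotation(gff, fasta)
  expect_length(models, 1L)
  t1 <- models[["g1"]][[1L]]
  expect_equal(unname(t1$exons), cbind(c(0L, 60L), c(30L, 100L)))
  expect_equal(nrow(asnmd:::tx_introns(t1)), 1L)
  expect_true(attr(models[["g1"]], "single_isoform"))
})

test_that("malformed GFF3 lines are reported with their line number", {
  dir <- withr::local_tempdir()
  fasta <- file.path(dir, "g.fa")
  writeLines(c(">chr1", strrep("ACGT", 30)), fasta)
  gff <- file.path(dir, "bad.gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chr1\tx\tmRNA\t1\t100"), gff)
  expect_error(load_annotation(gff, fasta), "line 3")
})

test_that("CDS with length not a multiple of 3 is dropped with a warning", {
  dir <- withr::local_tempdir()
  fasta <- file.path(dir, "g.fa")
  writeLines(c(">chr1", strrep("ACGT", 30)), fasta)
  gff <- file.path(dir, "a.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\tx\tmRNA\t1\t100\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tx\texon\t1\t100\t.\t+\t.\tParent=g1.t1",
    "chr1\tx\tCDS\t10\t30\t.\t+\t0\tParent=g1.t1",
    "chr1\tx\tCDS\t50\t60\t.\t+\t0\tParent=g1.t1"), gff)
  expect_warning(models <- load_annotation(gff, fasta), "CDS")
  expect_null(models[["g1"]][[1L]]$cds)
})

test_that("load -> write -> load round-trips synthetic gene models", {
  fx <- generate_fixture(simulation_config(n_genes = 50L, seed = 17L))
  dir <- withr::local_tempdir()
  p1 <- write_fixture(fx, dir)
  reloaded <- load_annotation(p1[["gff3"]], p1[["fasta"]])
  expect_setequal(names(reloaded), names(fx$models))
  for (g in names(fx$models)) {
    for (i in seq_along(fx$models[[g]])) {
      expect_true(models_equal(fx$models[[g]][[i]], reloaded[[g]][[i]]),
                  label = paste("model", g, i))
    }
  }
  # writing the reloaded models reproduces the file byte-for-byte
  gff2 <- file.path(dir, "again.gff3")
  write_gff3(reloaded, gff2)
  expect_identical(readLines(gff2), readLines(p1[["gff3"]]))
})

test_that("spliced sequence extraction is strand-aware", {
  g <- Biostrings::DNAStringSet(c(chr1 = "AAATTTGGG"))
  t_plus <- make_tm(cbind(c(0L, 6L), c(3L, 9L)), strand = "+")
  t_minus <- make_tm(cbind(c(0L, 6L), c(3L, 9L)), strand = "-")
  expect_equal(extract_transcript_sequence(t_plus, g), "AAAGGG")
  expect_equal(extract_transcript_sequence(t_minus, g), "CCCTTT")
  expect_error(extract_transcript_sequence(
    make_tm(cbind(0L, 3L), contig = "nope"), g), "contig")
})

test_that("extraction agrees with a naive per-base oracle on random models", {
  set.seed(101)
  genome <- random_genome(1600L)
  for (i in 1:300) {
    t <- random_ref_model()
    expect_identical(extract_transcript_sequence(t, genome),
                     naive_extract(t, genome))
  }
})

test_that("ORF selection prefers homology, then length, then 5'-most start", {
  # one isoform: long ORF (30 codons) and short ORF (5 codons)
  long_orf <- paste0("ATG", strrep("GCA", 28L), "TAA")
  short_orf <- paste0("ATG", strrep("GCT", 3L), "TGA")
  seq <- paste0("CC", long_orf, "AT", short_orf, "CC")
  t <- make_tm(cbind(0L, nchar(seq)))
  sel <- select_main_orf(list(t), stats::setNames(list(seq), "t1"))
  expect_equal(sel$orfs$orf_length_nt, nchar(long_orf))
  # homology scoring only the shorter peptide wins over length
  sel_h <- select_main_orf(
    list(t), stats::setNames(list(seq), "t1"),
    homology = function(pep) if (nchar(pep) < 10L) 50 else NA)
  expect_equal(sel_h$orfs$orf_length_nt, nchar(short_orf))
  expect_equal(sel_h$orfs$selection_basis, "homology")
})

test_that("equal-length candidate ORFs fall back to the 5'-most start", {
  orf <- paste0("ATG", strrep("GCA", 10L), "TAA")
  seq <- paste0("C", orf, "TT", orf, "C")
  t <- make_tm(cbind(0L, nchar(seq)))
  sel <- select_main_orf(list(t), stats::setNames(list(seq), "t1"))
  expect_equal(sel$orfs$orf_start, 1L)
})

test_that("selected ORFs start with ATG and end at an in-frame stop", {
  fx <- small_fixture()
  for (g in names(fx$fx$models)[1:10]) {
    sel <- fx$orfs[[g]]
    for (i in seq_len(nrow(sel$orfs))) {
      row <- sel$orfs[i, ]
      iso <- fx$fx$models[[g]]
      ids <- vapply(iso, function(t) t$transcript_id, character(1L))
      seq <- extract_transcript_sequence(iso[[match(row$transcript_id, ids)]],
                                         fx$fx$genome)
      expect_equal(substring(seq, row$orf_start + 1L, row$orf_start + 3L),
                   "ATG")
      expect_true(substring(seq, row$orf_stop - 2L, row$orf_stop) %in%
                    c("TAA", "TAG", "TGA"))
      expect_equal(row$orf_length_nt %% 3L, 0L)
    }
  }
})

test_that("non-coding isoforms are tolerated and genes remain usable", {
  t <- make_tm(cbind(0L, 12L))
  sel <- select_main_orf(list(t), stats::setNames(list("CCCCCCCCCCCC"), "t1"))
  expect_true(is.na(sel$reference))
  expect_equal(nrow(sel$orfs), 0L)
})

test_that("reverse-complementing the genome leaves spliced sequences fixed", {
  fx <- small_fixture()
  genome <- fx$fx$genome
  for (g in names(fx$fx$models)[1:8]) {
    for (t in fx$fx$models[[g]]) {
      L <- length(genome[[t$contig]])
      flipped_genome <- Biostrings::DNAStringSet(stats::setNames(
        as.character(Biostrings::reverseComplement(genome[[t$contig]])),
        t$contig))
      t2 <- flip_model(t, L)
      expect_identical(extract_transcript_sequence(t2, flipped_genome),
                       extract_transcript_sequence(t, genome))
    }
  }
})
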