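# Differential statistics: CPM, exact NB test, FDR, the two-mutant rule,
# consensus calls and hypergeometric enrichment.

test_that("CPM is count over library size times a million", {
  tab <- event_count_table(matrix(c(10L, 0L), 2L, 1L,
                                  dimnames = list(c("e1", "e2"), "WT_1")),
                           library_sizes = 1e6)
  expect_equal(unname(cpm(tab)[, 1L]), c(10, 0))
  expect_error(cpm(event_count_table(matrix(1L), library_sizes = 0)),
               "library size")
  # with library sizes at column sums, columns sum to 1e6
  m <- matrix(rpois(20L, 40L), 5L, 4L,
              dimnames = list(NULL, paste0("WT_", 1:4)))
  expect_equal(unname(colSums(cpm(event_count_table(m)))), rep(1e6, 4L))
})

test_that("identical groups give p = 1 and swapping groups flips the sign", {
  res <- nb_exact_test(c(5L, 5L), c(5L, 5L), dispersion = 0.1)
  expect_equal(res$p, 1)
  expect_equal(res$log2fc, 0)
  set.seed(21)
  for (i in 1:50) {
    a <- rpois(2L, 30L); b <- rpois(2L, 60L)
    r1 <- nb_exact_test(a, b, 0.1)
    r2 <- nb_exact_test(b, a, 0.1)
    expect_equal(r1$p, r2$p, tolerance = 1e-12)
    expect_equal(r1$log2fc, -r2$log2fc)
  }
  expect_error(nb_exact_test(c(-1L, 2L), c(1L, 1L), 0.1), "negative")
})

test_that("at dispersion 0 the test matches exhaustive binomial enumeration", {
  # independent oracle: enumerate all splits of the total, two-sided by
  # summing outcomes no more probable than the observed one
  enum_p <- function(sa, s, na, nb) {
    probs <- vapply(0:s, function(x) {
      choose(s, x) * (na / (na + nb))^x * (nb / (na + nb))^(s - x)
    }, numeric(1L))
    sum(probs[probs <= probs[sa + 1L] * (1 + 1e-10)])
  }
  set.seed(9)
  for (i in 1:60) {
    a <- rpois(2L, 8L); b <- rpois(2L, 8L)
    if (sum(a, b) > 50L || sum(a, b) == 0L) next
    expect_equal(nb_exact_test(a, b, 0)$p,
                 enum_p(sum(a), sum(a) + sum(b), 2L, 2L),
                 tolerance = 1e-10)
  }
  # unequal group sizes
  expect_equal(nb_exact_test(c(3L), c(5L, 6L), 0)$p,
               enum_p(3L, 14L, 1L, 2L), tolerance = 1e-10)
})

test_that("BH adjustment reproduces the hand-computed step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(bh_fdr(0.2), 0.2)
  p <- sort(runif(20L))
  expect_true(all(diff(bh_fdr(p)) >= 0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("method-of-moments dispersion recovers the simulated value", {
  set.seed(33)
  counts <- matrix(rnbinom(4000L * 4L, mu = 80, size = 1 / 0.15), ncol = 4L)
  est <- estimate_dispersion(counts, c("a", "a", "b", "b"))
  expect_equal(est, 0.15, tolerance = 0.05)
  # Poisson data estimates to (near) zero
  pois <- matrix(rpois(4000L * 4L, 80L), ncol = 4L)
  expect_lt(estimate_dispersion(pois, c("a", "a", "b", "b")), 0.02)
})

test_that("responsiveness requires the same direction in both mutants", {
  base <- c(50L, 55L)
  up <- c(400L, 420L)
  counts <- rbind(both = c(base, up, up),
                  one_mutant = c(base, up, base),
                  none = c(base, base, base))
  colnames(counts) <- c("WT_1", "WT_2", "mut1_1", "mut1_2",
                        "mut2_1", "mut2_2")
  res <- differential_events(
    event_count_table(counts, library_sizes = rep(1e6, 6L)),
    dispersion = 0.01)
  resp <- unique(res$event_id[res$responsive])
  expect_equal(resp, "both")
  both_rows <- res[res$event_id == "both", ]
  expect_equal(both_rows$direction, c("up", "up"))
})

test_that("planted up-events are recovered with controlled error", {
  # 500 events, 100 planted 8-fold up in both mutants
  ev <- data.frame(event_id = sprintf("e%03d", 1:500),
                   planted_lfc_mut1 = rep(c(3, 0), c(100L, 400L)),
                   planted_lfc_mut2 = rep(c(3, 0), c(100L, 400L)))
  cfg <- simulation_config(n_genes = 10L, seed = 61L)
  tab <- simulate_counts(list(events = ev), cfg)
  res <- differential_events(tab)
  hits <- unique(res$event_id[res$responsive])
  up_dir <- unique(res$event_id[res$responsive & res$direction == "up"])
  planted <- ev$event_id[ev$planted_lfc_mut1 > 0]
  expect_gte(mean(planted %in% hits), 0.9)
  expect_lte(sum(!(hits %in% planted)) / max(length(hits), 1L), 0.05)
  expect_setequal(hits, up_dir)
})

test_that("shuffling library labels across genotypes silences the calls", {
  fxc <- small_fixture()
  tab <- simulate_counts(fxc$fx$labels, fxc$cfg)
  # mix genotypes within every pseudo-group
  perm <- c("WT_1", "mut1_1", "WT_2", "mut2_1", "mut1_2", "mut2_2")
  shuffled <- tab$counts[, perm]
  colnames(shuffled) <- c("WT_1", "WT_2", "mut1_1", "mut1_2",
                          "mut2_1", "mut2_2")
  res <- differential_events(event_count_table(shuffled))
  expect_lte(mean(unique(res$event_id) %in%
                    res$event_id[res$responsive]), 0.01)
})

test_that("the 2-of-3 both-mutants consensus matches its truth table", {
  # states per mutant: how many methods call the gene up/down significantly
  states <- list(up2 = c(up = 2L, down = 0L), up1 = c(up = 1L, down = 0L),
                 dn2 = c(up = 0L, down = 2L), ns = c(up = 0L, down = 0L))
  expected <- function(m1, m2) {
    lab <- function(s) if (s == "up2") "up" else if (s == "dn2") "down"
                       else "ns"
    a <- lab(m1); b <- lab(m2)
    if (a == "up" && b == "up") "up"
    else if (a == "down" && b == "down") "down"
    else "not_de"
  }
  rows <- list()
  for (m1 in names(states)) for (m2 in names(states)) {
    gene <- paste(m1, m2, sep = "_")
    for (mut in c("mut1", "mut2")) {
      st <- states[[if (mut == "mut1") m1 else m2]]
      for (meth in c("edger", "deseq", "noiseq")) {
        i <- match(meth, c("edger", "deseq", "noiseq"))
        dir <- if (st["up"] >= i) "up" else if (st["down"] >= i) "down"
               else "unchanged"
        rows[[length(rows) + 1L]] <- data.frame(
          method = meth, mutant = mut, gene_id = gene,
          direction = dir, padj = if (dir == "unchanged") 0.9 else 0.001)
      }
    }
  }
  per_method <- do.call(rbind, rows)
  calls <- consensus_calls(per_method)
  for (m1 in names(states)) for (m2 in names(states)) {
    gene <- paste(m1, m2, sep = "_")
    expect_equal(calls$consensus[calls$gene_id == gene], expected(m1, m2),
                 label = gene)
  }
})

test_that("disjoint method universes trigger a warning and intersection", {
  pm <- rbind(
    data.frame(method = "a", mutant = c("mut1", "mut2"), gene_id = "g1",
               direction = "up", padj = 0.001),
    data.frame(method = "b", mutant = c("mut1", "mut2"),
               gene_id = c("g1"), direction = "up", padj = 0.001),
    data.frame(method = "b", mutant = c("mut1", "mut2"),
               gene_id = c("g2"), direction = "up", padj = 0.001))
  expect_warning(calls <- consensus_calls(pm), "intersection")
  expect_equal(calls$gene_id, "g1")
  expect_equal(calls$consensus, "up")
  expect_error(consensus_calls(pm[pm$method == "a", ]), "two methods")
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  universe <- paste0("g", 1:10)
  annotated <- universe[1:5]
  hits <- universe[1:4]
  res <- hypergeom_enrichment(hits, annotated, universe)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_enrichment(character(0), annotated, universe)$p, 1)
  # p decreases as overlap k grows with N, K, n fixed
  ps <- vapply(0:4, function(k) {
    h <- c(universe[seq_len(k)], universe[6:(9 - k + 1)])[1:4]
    hypergeom_enrichment(h, annotated, universe)$p
  }, numeric(1L))
  expect_true(all(diff(ps) < 0))
  expect_error(hypergeom_enrichment("x", annotated, universe), "subsets")
  expect_error(hypergeom_enrichment("g1", "g1", character(0)), "universe")
})
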