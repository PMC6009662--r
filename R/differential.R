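# Event-level differential testing: event-specific read counting lives in
# counting.R; here are CPM, the exact conditional negative-binomial test,
# BH FDR, the per-event two-mutant analysis, the 2-of-3 / both-mutants
# gene-level consensus rule, and hypergeometric enrichment.

#' Construct an event count table
#'
#' @param counts integer matrix, rows = events, columns = libraries (the
#'   conventional layout is `WT_1, WT_2, mut1_1, mut1_2, mut2_1, mut2_2`).
#' @param library_sizes optional named numeric vector of per-library totals;
#'   defaults to column sums.
#' @return list of class `event_count_table` with `counts` and
#'   `library_sizes`.
#' @export
event_count_table <- function(counts, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  library_sizes <- library_sizes %||% colSums(counts)
  stopifnot(length(library_sizes) == ncol(counts))
  structure(list(counts = counts,
                 library_sizes = stats::setNames(as.numeric(library_sizes),
                                                 colnames(counts))),
            class = "event_count_table")
}

#' Counts per million
#'
#' @param table an [event_count_table()].
#' @return numeric matrix of CPM values.
#' @export
cpm <- function(table) {
  if (any(table$library_sizes <= 0)) stop("zero or negative library size")
  sweep(table$counts, 2L, table$library_sizes, `/`) * 1e6
}

#' Exact conditional negative-binomial test for one event
#'
#' Two-sided test of equal means between two small count groups. Counts are
#' library-size-adjusted by scaling to the geometric mean library size, then
#' the group-A total is compared with its conditional distribution given the
#' overall total under a negative binomial with common mean and the supplied
#' dispersion; the p-value sums the probabilities of all outcomes at most as
#' likely as the observed one. At `dispersion = 0` this reduces to the exact
#' conditional binomial test. The log2 fold change uses a 0.5-count prior on
#' each group mean.
#'
#' @param group_a,group_b non-negative integer count vectors (e.g. WT and
#'   mutant replicates).
#' @param dispersion negative-binomial dispersion (>= 0).
#' @param lib_sizes optional numeric vector of library sizes, ordered as
#'   `c(group_a, group_b)`; equal sizes assumed when omitted.
#' @return list with `p` and `log2fc` (group B over group A).
#' @export
nb_exact_test <- function(group_a, group_b, dispersion,
                          lib_sizes = NULL) {
  if (any(c(group_a, group_b) < 0)) stop("negative counts")
  stopifnot(dispersion >= 0, length(group_a) >= 1L, length(group_b) >= 1L)
  na <- length(group_a); nb <- length(group_b)
  if (!is.null(lib_sizes)) {
    stopifnot(length(lib_sizes) == na + nb, all(lib_sizes > 0))
    geo <- exp(mean(log(lib_sizes)))
    adj <- c(group_a, group_b) * geo / lib_sizes
    group_a <- round(adj[seq_len(na)])
    group_b <- round(adj[na + seq_len(nb)])
  }
  sa <- sum(group_a); sb <- sum(group_b); s <- sa + sb
  log2fc <- log2((sb / nb + 0.5) / (sa / na + 0.5))
  if (s == 0L) return(list(p = 1, log2fc = log2fc))
  mu <- s / (na + nb)
  x <- 0:s
  if (dispersion < 1e-12) {
    probs <- stats::dbinom(x, s, na / (na + nb))
  } else {
    la <- stats::dnbinom(x, size = na / dispersion, mu = na * mu, log = TRUE)
    lb <- stats::dnbinom(s - x, size = nb / dispersion, mu = nb * mu,
                         log = TRUE)
    lp <- la + lb
    probs <- exp(lp - max(lp))
    probs <- probs / sum(probs)
  }
  p_obs <- probs[sa + 1L]
  p <- sum(probs[probs <= p_obs * (1 + 1e-10)])
  list(p = min(p, 1), log2fc = log2fc)
}

#' Pooled method-of-moments dispersion estimate
#'
#' Common negative-binomial dispersion across all event-by-group cells with
#' at least two replicates: `sum(v - m) / sum(m^2 - v/n)` over cells with
#' sample mean `m`, sample variance `v` and `n` replicates, clamped at 0.
#'
#' @param counts count matrix (events x libraries).
#' @param groups factor/character vector of library group labels.
#' @return non-negative scalar dispersion.
#' @export
estimate_dispersion <- function(counts, groups) {
  groups <- as.character(groups)
  num <- 0; den <- 0
  for (g in unique(groups)) {
    sub <- counts[, groups == g, drop = FALSE]
    n <- ncol(sub)
    if (n < 2L) next
    m <- rowMeans(sub)
    v <- apply(sub, 1L, stats::var)
    num <- num + sum(v - m)
    den <- den + sum(m^2 - v / n)
  }
  if (den <= 0) return(0)
  max(num / den, 0)
}

#' Benjamini-Hochberg FDR
#'
#' Step-up BH adjustment (via [stats::p.adjust()]) with input validation.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return q-values in \[0, 1\], same order as input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-event differential tests against both mutants
#'
#' Tests every event in each mutant-vs-WT contrast with the exact
#' conditional NB test, BH-adjusts p-values within each contrast, and calls
#' an event NMD-responsive when its FDR is below the threshold with the same
#' fold-change sign in both mutant contrasts.
#'
#' @param table an [event_count_table()]; column names must start with the
#'   group labels in `groups` (e.g. `WT_1`, `mut1_2`).
#' @param fdr_threshold FDR threshold for direction calls (default 0.01).
#' @param dispersion common NB dispersion; estimated by
#'   [estimate_dispersion()] when `NULL`.
#' @param groups the WT label followed by the mutant labels.
#' @return data.frame with one row per event per contrast (`event_id`,
#'   `contrast`, `cpm_mean`, `log2fc`, `p`, `fdr`, `direction`) plus a
#'   `responsive` column (same value across an event's rows); the dispersion
#'   used is attached as `attr(x, "dispersion")`.
#' @export
differential_events <- function(table, fdr_threshold = 0.01,
                                dispersion = NULL,
                                groups = c("WT", "mut1", "mut2")) {
  counts <- table$counts
  lib_group <- sub("_[0-9]+$", "", colnames(counts))
  if (!all(groups %in% lib_group)) {
    stop("missing library group(s): ",
         paste(setdiff(groups, lib_group), collapse = ", "))
  }
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(counts, lib_group)
  }
  cpm_mat <- cpm(table)
  wt_idx <- which(lib_group == groups[1L])
  out <- list()
  for (mut in groups[-1L]) {
    mut_idx <- which(lib_group == mut)
    contrast <- paste0(mut, "_vs_", groups[1L])
    res <- lapply(seq_len(nrow(counts)), function(i) {
      nb_exact_test(counts[i, wt_idx], counts[i, mut_idx], dispersion,
                    lib_sizes = table$library_sizes[c(wt_idx, mut_idx)])
    })
    p <- vapply(res, `[[`, numeric(1L), "p")
    fdr <- bh_fdr(p)
    lfc <- vapply(res, `[[`, numeric(1L), "log2fc")
    out[[contrast]] <- data.frame(
      event_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
      contrast = contrast,
      cpm_mean = rowMeans(cpm_mat[, c(wt_idx, mut_idx), drop = FALSE]),
      log2fc = lfc, p = p, fdr = fdr,
      direction = ifelse(fdr >= fdr_threshold, "unchanged",
                         ifelse(lfc > 0, "up", "down")),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  dir_by_event <- split(res$direction, res$event_id)
  responsive_ids <- names(dir_by_event)[vapply(dir_by_event, function(d) {
    all(d != "unchanged") && length(unique(d)) == 1L
  }, logical(1L))]
  res$responsive <- res$event_id %in% responsive_ids
  attr(res, "dispersion") <- dispersion
  res
}

#' Gene-level 2-of-3 / both-mutants consensus
#'
#' A gene is called up (down) when at least `min_methods` differential
#' methods call it up (down) at adjusted p below `alpha` in mutant 1 AND in
#' mutant 2; conflicting consensus directions across mutants (or within one
#' mutant) yield `not_de`.
#'
#' @param per_method data.frame with columns `method`, `mutant`, `gene_id`,
#'   `direction` (`"up"`/`"down"`/`"unchanged"`) and `padj`.
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param min_methods methods required to agree (default 2).
#' @return data.frame `gene_id`, `consensus` in `{up, down, not_de}`.
#' @export
consensus_calls <- function(per_method, alpha = 0.05, min_methods = 2L) {
  need <- c("method", "mutant", "gene_id", "direction", "padj")
  if (!all(need %in% names(per_method))) {
    stop("per_method must have columns: ", paste(need, collapse = ", "))
  }
  if (length(unique(per_method$method)) < 2L) {
    stop("at least two methods required for a consensus")
  }
  universes <- lapply(split(per_method$gene_id, per_method$method), unique)
  genes <- Reduce(intersect, universes)
  if (length(unique(lengths(universes))) > 1L ||
      length(genes) < max(lengths(universes))) {
    warning("method tables cover different gene universes; ",
            "using their intersection (", length(genes), " genes)")
  }
  mutants <- sort(unique(per_method$mutant))
  sig <- per_method[per_method$padj < alpha &
                      per_method$direction %in% c("up", "down") &
                      per_method$gene_id %in% genes, ]
  call_dir <- function(gene) {
    per_mut <- vapply(mutants, function(m) {
      sub <- sig[sig$gene_id == gene & sig$mutant == m, ]
      n_up <- length(unique(sub$method[sub$direction == "up"]))
      n_dn <- length(unique(sub$method[sub$direction == "down"]))
      up_ok <- n_up >= min_methods
      dn_ok <- n_dn >= min_methods
      if (up_ok && dn_ok) "conflict"
      else if (up_ok) "up" else if (dn_ok) "down" else "ns"
    }, character(1L))
    if (all(per_mut == "up")) "up"
    else if (all(per_mut == "down")) "down"
    else "not_de"
  }
  data.frame(gene_id = genes,
             consensus = vapply(genes, call_dir, character(1L)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric enrichment test
#'
#' Upper-tail probability `P(X >= k)` of drawing `k = |hits ∩ annotated|`
#' annotated genes in `|hits|` draws from a universe containing
#' `|annotated|` annotated genes.
#'
#' @param hits,annotated,universe character vectors of gene ids;
#'   `hits` and `annotated` must be subsets of `universe`.
#' @return list with `p`, `k`, `n_hits`, `n_annotated`, `n_universe`.
#' @export
hypergeom_enrichment <- function(hits, annotated, universe) {
  universe <- unique(universe)
  hits <- unique(hits); annotated <- unique(annotated)
  if (!length(universe)) stop("empty universe")
  if (!all(hits %in% universe) || !all(annotated %in% universe)) {
    stop("hits and annotated must be subsets of the universe")
  }
  N <- length(universe); K <- length(annotated); n <- length(hits)
  k <- length(intersect(hits, annotated))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(p = p, k = k, n_hits = n, n_annotated = K, n_universe = N)
}
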