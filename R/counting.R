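# Event-specific read counting from SAM/BAM alignments.
#
# A read supports the alternative side of an event when its gapped alignment
# spans one of the event's alt-unique diagnostic junctions, or (for retained
# introns) aligns contiguously across an intron boundary. Reads supporting
# no event, or more than one, are left unassigned; no read is ever counted
# twice and counts are never fractional.

#' Count event-specific reads per library
#'
#' @param alignments named character vector of SAM or BAM paths, one per
#'   library; names become column names.
#' @param catalog event catalog from [build_event_catalog()].
#' @return an [event_count_table()]; per-library unassigned-read tallies are
#'   attached as `attr(x, "unassigned")` and total reads as
#'   `attr(x, "total_reads")`.
#' @export
count_event_reads <- function(alignments, catalog) {
  if (is.null(names(alignments)) || any(!nzchar(names(alignments)))) {
    stop("alignments must be a named vector of file paths")
  }
  idx <- build_event_index(catalog)
  counts <- matrix(0L, nrow = nrow(catalog), ncol = length(alignments),
                   dimnames = list(catalog$event_id, names(alignments)))
  unassigned <- stats::setNames(integer(length(alignments)),
                                names(alignments))
  totals <- unassigned
  for (lib in names(alignments)) {
    ga <- read_alignments(alignments[[lib]])
    totals[lib] <- length(ga)
    if (!length(ga)) next
    contig <- as.character(GenomicAlignments::seqnames(ga))
    jx <- GenomicAlignments::junctions(ga)             # introns, 1-based
    blocks <- GenomicAlignments::grglist(ga)           # aligned blocks
    for (r in seq_along(ga)) {
      hits <- integer(0)
      j <- jx[[r]]
      if (length(j)) {
        keys <- sprintf("%s:%d-%d", contig[r],
                        BiocGenerics::start(j) - 1L, BiocGenerics::end(j))
        hits <- c(hits, unlist(idx$junction[keys], use.names = FALSE))
      }
      b <- blocks[[r]]
      if (length(b)) {
        # contiguous coverage across a retained-intron boundary: the block
        # contains both the last exonic base and the first intronic base
        bs <- BiocGenerics::start(b); be <- BiocGenerics::end(b)
        for (bound in idx$boundary_list[[contig[r]]] %||% integer(0)) {
          if (any(bs <= bound & bound + 1L <= be)) {
            key <- sprintf("%s:%d", contig[r], bound)
            hits <- c(hits, idx$boundary[[key]])
          }
        }
      }
      hits <- unique(hits)
      if (length(hits) == 1L) {
        counts[hits, lib] <- counts[hits, lib] + 1L
      } else {
        unassigned[lib] <- unassigned[lib] + 1L
      }
    }
  }
  tab <- event_count_table(counts)
  attr(tab, "unassigned") <- unassigned
  attr(tab, "total_reads") <- totals
  tab
}

# Index alt-side diagnostic signatures:
#  * junction: "contig:start-end" (0-based half-open intron) -> event rows
#  * boundary: "contig:b" -> event rows, where a contiguous alignment
#    covering 1-based positions b and b+1 crosses a retained intron boundary
build_event_index <- function(catalog) {
  junction <- new.env(parent = emptyenv())
  boundary <- new.env(parent = emptyenv())
  boundary_list <- list()
  add <- function(env, key, i) {
    assign(key, c(if (exists(key, envir = env)) get(key, envir = env),
                  i), envir = env)
  }
  for (i in seq_len(nrow(catalog))) {
    ctg <- catalog$contig[i]
    if (catalog$event_type[i] == "retained_intron") {
      jr <- catalog$diagnostic_junctions[[i]]$ref
      for (row in seq_len(nrow(jr %||% matrix(0, 0, 2)))) {
        s <- jr[row, 1L]; e <- jr[row, 2L]
        # crossing the donor-side boundary: covers 1-based s and s+1;
        # acceptor side: covers e and e+1
        for (b in c(s, e)) {
          add(boundary, sprintf("%s:%d", ctg, b), i)
          boundary_list[[ctg]] <- c(boundary_list[[ctg]], b)
        }
      }
    } else {
      ja <- catalog$diagnostic_junctions[[i]]$alt
      for (row in seq_len(nrow(ja %||% matrix(0, 0, 2)))) {
        add(junction,
            sprintf("%s:%d-%d", ctg, ja[row, 1L], ja[row, 2L]), i)
      }
    }
  }
  list(junction = as.list(junction), boundary = as.list(boundary),
       boundary_list = lapply(boundary_list, unique))
}

# read a SAM or BAM file into a GAlignments object
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, destination = tempfile(),
                            overwrite = TRUE, indexDestination = FALSE)
    path <- bam
  }
  GenomicAlignments::readGAlignments(path)
}
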