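# Annotation model: genome + GFF3 -> strand-aware transcript models.
#
# Internal coordinates are 0-based half-open throughout the package; GFF3 is
# 1-based inclusive and converted exactly once, at load/write time.

#' Construct a transcript model
#'
#' A `transcript_model` bundles one isoform's exon (and optionally CDS) chain
#' on a genome. Exons are stored as a 2-column integer matrix of 0-based
#' half-open genomic intervals, sorted by start and non-overlapping.
#'
#' @param transcript_id,gene_id identifiers.
#' @param contig contig (chromosome/scaffold) name.
#' @param strand `"+"` or `"-"`.
#' @param exons 2-column matrix (start, end), 0-based half-open.
#' @param cds optional 2-column matrix of CDS intervals, each contained in an
#'   exon; spliced CDS length must be a positive multiple of 3.
#' @param attributes named list of extra annotation fields.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand, exons,
                             cds = NULL, attributes = list()) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L])) {
    stop("transcript ", transcript_id, ": exon with non-positive length")
  }
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
    stop("transcript ", transcript_id, ": overlapping exons")
  }
  if (nrow(exons) > 1L && any(exons[-1L, 1L] == exons[-nrow(exons), 2L])) {
    stop("transcript ", transcript_id, ": zero-length intron")
  }
  if (!is.null(cds)) {
    cds <- matrix(as.integer(cds), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
    cds <- cds[order(cds[, 1L]), , drop = FALSE]
    contained <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons[, 1L] <= cds[i, 1L] & cds[i, 2L] <= exons[, 2L])
    }, logical(1L))
    if (!all(contained)) {
      stop("transcript ", transcript_id, ": CDS interval outside exons")
    }
    clen <- sum(cds[, 2L] - cds[, 1L])
    if (clen < 3L || clen %% 3L != 0L) {
      stop("transcript ", transcript_id,
           ": spliced CDS length not a positive multiple of 3")
    }
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 contig = contig, strand = strand, exons = exons, cds = cds,
                 attributes = attributes),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (gene %s) %s%s, %d exon(s), %d nt%s\n",
              x$transcript_id, x$gene_id, x$contig, x$strand,
              nrow(x$exons), tx_length(x),
              if (is.null(x$cds)) "" else ", with CDS"))
  invisible(x)
}

#' Load a genome FASTA
#'
#' Reads a (multi-record) FASTA into a named [Biostrings::DNAStringSet],
#' upper-cased, and checks the alphabet is restricted to A, C, G, T, N.
#'
#' @param fasta_path path to a FASTA file.
#' @return `DNAStringSet` named by contig id (first whitespace token).
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
  g <- Biostrings::readDNAStringSet(fasta_path)
  names(g) <- sub("\\s.*$", "", names(g))
  g <- Biostrings::DNAStringSet(toupper(as.character(g)))
  if (any(Biostrings::width(g) == 0L)) stop("empty sequence in FASTA")
  freq <- Biostrings::alphabetFrequency(g, baseOnly = FALSE)
  bad <- setdiff(colnames(freq)[colSums(freq) > 0], c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop("genome contains characters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ", "))
  }
  g
}

#' Load transcript models from GFF3 + FASTA
#'
#' Parses a GFF3 annotation (gene/mRNA/exon/CDS features linked by
#' `ID`/`Parent`) against a genome FASTA into per-gene lists of
#' [transcript_model()] objects. GFF3 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention here and nowhere
#' else.
#'
#' Isoforms whose annotated CDS length is not a positive multiple of 3 keep
#' their exon chain but have the CDS dropped, with a warning. Single-isoform
#' genes are retained and flagged (`attr(gene, "single_isoform")`).
#'
#' @param gff3_path path to GFF3 annotation.
#' @param fasta_path path to the genome FASTA.
#' @return named list: `gene_id` -> list of `transcript_model`. The genome is
#'   attached as `attr(x, "genome")`.
#' @export
load_annotation <- function(gff3_path, fasta_path) {
  if (!file.exists(gff3_path)) stop("GFF3 not found: ", gff3_path)
  genome <- load_genome(fasta_path)
  validate_gff3_lines(gff3_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID %||% rep(NA_character_, length(gr)))
  parents <- md$Parent

  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  if (!length(mrna_idx)) stop("GFF3 contains no mRNA/transcript features")
  mrna_parent <- vapply(parents[mrna_idx], function(p)
    if (length(p)) as.character(p)[1L] else NA_character_, character(1L))
  tx2gene <- stats::setNames(mrna_parent, ids[mrna_idx])
  tx2gene[is.na(tx2gene)] <- names(tx2gene)[is.na(tx2gene)]

  part_idx <- which(type %in% c("exon", "CDS"))
  part_parent <- vapply(parents[part_idx], function(p)
    if (length(p)) as.character(p)[1L] else NA_character_, character(1L))

  models <- list()
  for (tx in ids[mrna_idx]) {
    sel <- part_idx[part_parent == tx & !is.na(part_parent)]
    ex <- sel[type[sel] == "exon"]
    cd <- sel[type[sel] == "CDS"]
    if (!length(ex)) next
    contig <- as.character(GenomicRanges::seqnames(gr[ex[1L]]))
    if (!contig %in% names(genome)) {
      stop("contig ", contig, " in GFF3 absent from FASTA")
    }
    strand <- as.character(BiocGenerics::strand(gr[ex[1L]]))
    # 1-based inclusive -> 0-based half-open
    exons <- cbind(BiocGenerics::start(gr[ex]) - 1L, BiocGenerics::end(gr[ex]))
    if (any(exons[, 1L] < 0L) ||
        any(exons[, 2L] > length(genome[[contig]]))) {
      stop("transcript ", tx, ": exon outside contig bounds on ", contig)
    }
    cds <- NULL
    if (length(cd)) {
      cds <- cbind(BiocGenerics::start(gr[cd]) - 1L, BiocGenerics::end(gr[cd]))
      clen <- sum(cds[, 2L] - cds[, 1L])
      if (clen < 3L || clen %% 3L != 0L) {
        warning("transcript ", tx,
                ": CDS length not a multiple of 3; CDS dropped")
        cds <- NULL
      }
    }
    gene <- unname(tx2gene[tx])
    models[[gene]] <- c(models[[gene]], list(
      transcript_model(tx, gene, contig, strand, exons, cds)))
  }
  models <- lapply(models, function(iso) {
    attr(iso, "single_isoform") <- length(iso) == 1L
    iso
  })
  attr(models, "genome") <- genome
  models
}

# cheap structural validation so malformed lines are reported with their
# line number (rtracklayer's own errors do not carry one)
validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nf != 9L]
  if (length(bad)) {
    stop("malformed GFF3 line ", bad[1L], ": expected 9 tab-separated fields")
  }
  invisible(TRUE)
}

#' Write transcript models to GFF3
#'
#' Inverse of [load_annotation()]: emits gene/mRNA/exon/CDS records with
#' 1-based inclusive coordinates. `load_annotation(write_gff3(x))` is the
#' identity on valid models.
#'
#' @param models named list `gene_id -> list of transcript_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  out <- c("##gff-version 3")
  for (gene in names(models)) {
    isoforms <- models[[gene]]
    span <- range(unlist(lapply(isoforms, function(t) t$exons)))
    t1 <- isoforms[[1L]]
    out <- c(out, paste(t1$contig, "asnmd", "gene", span[1L] + 1L, span[2L],
                        ".", t1$strand, ".", sprintf("ID=%s", gene),
                        sep = "\t"))
    for (t in isoforms) {
      tspan <- range(t$exons)
      out <- c(out, paste(t$contig, "asnmd", "mRNA", tspan[1L] + 1L,
                          tspan[2L], ".", t$strand, ".",
                          sprintf("ID=%s;Parent=%s", t$transcript_id, gene),
                          sep = "\t"))
      for (i in seq_len(nrow(t$exons))) {
        out <- c(out, paste(t$contig, "asnmd", "exon",
                            t$exons[i, 1L] + 1L, t$exons[i, 2L], ".",
                            t$strand, ".",
                            sprintf("Parent=%s", t$transcript_id),
                            sep = "\t"))
      }
      if (!is.null(t$cds)) {
        for (i in seq_len(nrow(t$cds))) {
          out <- c(out, paste(t$contig, "asnmd", "CDS",
                              t$cds[i, 1L] + 1L, t$cds[i, 2L], ".",
                              t$strand, "0",
                              sprintf("Parent=%s", t$transcript_id),
                              sep = "\t"))
        }
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Extract the spliced transcript sequence
#'
#' Concatenates exon substrings of the contig; on the minus strand the
#' concatenation is reverse-complemented so the result always reads 5'->3'
#' in transcript orientation.
#'
#' @param t a [transcript_model()].
#' @param genome `DNAStringSet` (or single contig string) holding `t$contig`.
#' @return character scalar of length `sum(exon lengths)`.
#' @export
extract_transcript_sequence <- function(t, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!t$contig %in% names(genome)) {
    stop("contig not found in genome: ", t$contig)
  }
  contig <- genome[[t$contig]]
  if (max(t$exons[, 2L]) > length(contig)) {
    stop("transcript ", t$transcript_id, ": exon outside contig bounds")
  }
  pieces <- substring(as.character(contig),
                      t$exons[, 1L] + 1L, t$exons[, 2L])
  s <- paste(pieces, collapse = "")
  if (t$strand == "-") s <- revcomp(s)
  s
}
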