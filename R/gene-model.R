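## Gene models: plain-list representation of a gene and its transcripts.
## Coordinates are 1-based inclusive genomic nucleotide positions throughout
## (the GFF3 convention); conversion to 0-based half-open happens only at the
## BED boundary.

#' Construct a transcript
#'
#' @param transcript_id character scalar.
#' @param exons two-column matrix or data frame of 1-based inclusive
#'   `[start, end]` exon intervals. Rows are sorted by start; overlapping
#'   exons within a transcript are an error.
#' @return a `transcript` object (list with `transcript_id` and an integer
#'   exon matrix).
#' @export
transcript <- function(transcript_id, exons) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L)
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L || nrow(exons) < 1L) {
    stop("'exons' must have >= 1 row and exactly 2 columns (start, end)")
  }
  storage.mode(exons) <- "integer"
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] < exons[, 1L])) {
    stop("exon end < start in transcript ", transcript_id)
  }
  if (nrow(exons) > 1L && any(exons[-1L, 1L] <= exons[-nrow(exons), 2L])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  dimnames(exons) <- list(NULL, c("start", "end"))
  structure(list(transcript_id = transcript_id, exons = exons),
            class = "transcript")
}

#' Construct a gene model
#'
#' A gene model is a gene identifier, a chromosome, a strand, and one or more
#' transcripts sharing that chromosome and strand. The gene span is the hull
#' of all exon intervals.
#'
#' @param gene_id,chrom character scalars.
#' @param strand `"+"` or `"-"`.
#' @param transcripts list of [transcript()] objects (>= 1).
#' @return a `gene_model` object.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            is.character(chrom), length(chrom) == 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!is.list(transcripts) || length(transcripts) < 1L) {
    stop("gene ", gene_id, " needs >= 1 transcript")
  }
  if (!all(vapply(transcripts, inherits, logical(1), "transcript"))) {
    stop("all elements of 'transcripts' must be transcript objects")
  }
  ids <- vapply(transcripts, `[[`, character(1), "transcript_id")
  if (anyDuplicated(ids)) stop("duplicate transcript ids in gene ", gene_id)
  names(transcripts) <- ids
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  sp <- gene_span(x)
  cat(sprintf("<gene_model> %s %s:%d-%d(%s), %d transcript(s)\n",
              x$gene_id, x$chrom, sp[1L], sp[2L], x$strand,
              length(x$transcripts)))
  for (tr in x$transcripts) {
    cat(sprintf("  %s: %s\n", tr$transcript_id,
                paste(sprintf("[%d,%d]", tr$exons[, 1L], tr$exons[, 2L]),
                      collapse = " ")))
  }
  invisible(x)
}

#' Gene span (hull of all exons)
#' @param gene a `gene_model`.
#' @return integer vector `c(start, end)`.
#' @export
gene_span <- function(gene) {
  ex <- do.call(rbind, lapply(gene$transcripts, `[[`, "exons"))
  c(min(ex[, 1L]), max(ex[, 2L]))
}

#' Number of transcripts of a gene
#' @param gene a `gene_model`.
#' @export
n_transcripts <- function(gene) length(gene$transcripts)

## ---- interval helpers (1-based inclusive, two-column matrices) ----

## Merge overlapping or book-ended intervals into a sorted disjoint union.
ivl_union <- function(m) {
  if (nrow(m) == 0L) return(m)
  m <- m[order(m[, 1L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  if (nrow(m) > 1L) for (i in 2L:nrow(m)) {
    k <- nrow(out)
    if (m[i, 1L] <= out[k, 2L] + 1L) {
      out[k, 2L] <- max(out[k, 2L], m[i, 2L])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  out
}

## Clip an interval set to [lo, hi]; drops emptied intervals.
ivl_clip <- function(m, lo, hi) {
  s <- pmax(m[, 1L], lo)
  e <- pmin(m[, 2L], hi)
  keep <- s <= e
  cbind(start = s[keep], end = e[keep])
}

## Is position p exonic under interval set m?
ivl_covers <- function(m, p) {
  any(m[, 1L] <= p & m[, 2L] >= p)
}

## Exonic union of all transcripts of a gene.
gene_exon_union <- function(gene) {
  ivl_union(do.call(rbind, lapply(gene$transcripts, `[[`, "exons")))
}

## Introns of a transcript as (donor_end, acceptor_start) pairs, i.e. the
## coordinates of the flanking exon end and next exon start.
transcript_introns <- function(tr) {
  ex <- tr$exons
  if (nrow(ex) < 2L) {
    return(cbind(donor_end = integer(0), acceptor_start = integer(0)))
  }
  cbind(donor_end = ex[-nrow(ex), 2L], acceptor_start = ex[-1L, 1L])
}
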