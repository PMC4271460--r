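## Annotation I/O. Parsing and serialization of GFF3/GTF go through
## rtracklayer; this file only maps between GRanges feature tables and the
## package's plain gene_model lists. Coordinates are 1-based inclusive on
## both sides of the boundary; BED export converts to 0-based half-open.

#' Parse a GFF3 or GTF annotation into gene models
#'
#' GFF3 input requires `gene`, `mRNA` (or `transcript`) and `exon` features
#' linked by `ID`/`Parent`; GTF input requires `exon` features carrying
#' `gene_id` and `transcript_id` attributes. Exon order within a transcript
#' is normalized to genomic start order.
#'
#' @param path file path.
#' @param dialect `"GFF3"` or `"GTF"`.
#' @return named list of [gene_model()] objects.
#' @export
parse_annotation <- function(path, dialect = c("GFF3", "GTF")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  check_annotation_syntax(path)
  gr <- tryCatch(
    rtracklayer::import(path, format = if (dialect == "GFF3") "gff3" else "gtf"),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (dialect == "GFF3") genes_from_gff3(df, path) else genes_from_gtf(df, path)
}

## Cheap structural pre-check so malformed records are reported with their
## line number before the full parser runs.
check_annotation_syntax <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1L]]
    stop("parse error in ", path, " at line ", bad,
         ": expected 9 tab-separated fields, found ", nf[nf != 9L][1L],
         call. = FALSE)
  }
  invisible(TRUE)
}

genes_from_gff3 <- function(df, path) {
  type <- as.character(df$type)
  tx_rows <- df[type %in% c("mRNA", "transcript"), , drop = FALSE]
  ex_rows <- df[type == "exon", , drop = FALSE]
  if (nrow(ex_rows) == 0L) stop("no exon features in ", path)
  first_parent <- function(p) {
    vapply(p, function(v) if (length(v)) as.character(v[[1L]]) else NA_character_,
           character(1))
  }
  if (is.null(ex_rows$Parent)) {
    stop("structural error in ", path, ": exon without parent transcript")
  }
  tx_parent <- first_parent(tx_rows$Parent)
  ex_parent <- first_parent(ex_rows$Parent)
  if (anyNA(ex_parent) || length(ex_parent) != nrow(ex_rows)) {
    stop("structural error in ", path, ": exon without parent transcript")
  }
  tx_gene <- stats::setNames(tx_parent, tx_rows$ID)
  if (anyNA(tx_gene) || any(!ex_parent %in% names(tx_gene))) {
    stop("structural error in ", path,
         ": exon parent does not resolve to an mRNA with a gene parent")
  }
  build_genes(
    gene_id = unname(tx_gene[ex_parent]),
    tx_id = ex_parent,
    chrom = as.character(ex_rows$seqnames),
    strand = as.character(ex_rows$strand),
    start = ex_rows$start, end = ex_rows$end
  )
}

genes_from_gtf <- function(df, path) {
  ex_rows <- df[as.character(df$type) == "exon", , drop = FALSE]
  if (nrow(ex_rows) == 0L) stop("no exon features in ", path)
  if (is.null(ex_rows$gene_id) || is.null(ex_rows$transcript_id) ||
      anyNA(ex_rows$gene_id) || anyNA(ex_rows$transcript_id)) {
    stop("structural error in ", path,
         ": exon lacking gene_id/transcript_id attributes")
  }
  build_genes(
    gene_id = as.character(ex_rows$gene_id),
    tx_id = as.character(ex_rows$transcript_id),
    chrom = as.character(ex_rows$seqnames),
    strand = as.character(ex_rows$strand),
    start = ex_rows$start, end = ex_rows$end
  )
}

build_genes <- function(gene_id, tx_id, chrom, strand, start, end) {
  out <- list()
  for (gid in unique(gene_id)) {
    sel <- gene_id == gid
    g_chrom <- unique(chrom[sel])
    g_strand <- unique(strand[sel])
    if (length(g_chrom) != 1L || length(g_strand) != 1L) {
      stop("gene ", gid, " has transcripts on multiple chromosomes/strands")
    }
    if (!g_strand %in% c("+", "-")) {
      stop("gene ", gid, " has unstranded features")
    }
    trs <- lapply(unique(tx_id[sel]), function(tid) {
      ts <- sel & tx_id == tid
      transcript(tid, cbind(start[ts], end[ts]))
    })
    out[[gid]] <- gene_model(gid, g_chrom, g_strand, trs)
  }
  out
}

#' Write gene models as GFF3 or GTF
#'
#' @param genes list of [gene_model()] objects.
#' @param path output file.
#' @param dialect `"GFF3"` or `"GTF"`.
#' @param comment optional provenance string appended as a header comment.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path, dialect = c("GFF3", "GTF"),
                             comment = NULL) {
  dialect <- match.arg(dialect)
  rows <- list()
  for (g in genes) {
    sp <- gene_span(g)
    if (dialect == "GFF3") {
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = g$chrom, start = sp[1L], end = sp[2L], strand = g$strand,
        type = "gene", ID = g$gene_id, Parent = NA_character_,
        gene_id = NA_character_, transcript_id = NA_character_,
        stringsAsFactors = FALSE)
    }
    for (tr in g$transcripts) {
      if (dialect == "GFF3") {
        rows[[length(rows) + 1L]] <- data.frame(
          seqnames = g$chrom, start = min(tr$exons[, 1L]),
          end = max(tr$exons[, 2L]), strand = g$strand,
          type = "mRNA", ID = tr$transcript_id, Parent = g$gene_id,
          gene_id = NA_character_, transcript_id = NA_character_,
          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = g$chrom, start = tr$exons[, 1L], end = tr$exons[, 2L],
        strand = g$strand, type = "exon", ID = NA_character_,
        Parent = if (dialect == "GFF3") tr$transcript_id else NA_character_,
        gene_id = g$gene_id, transcript_id = tr$transcript_id,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand
  )
  if (dialect == "GFF3") {
    S4Vectors::mcols(gr)$type <- df$type
    S4Vectors::mcols(gr)$ID <- df$ID
    S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), NA, df$Parent)
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    S4Vectors::mcols(gr)$type <- df$type
    S4Vectors::mcols(gr)$gene_id <- df$gene_id
    S4Vectors::mcols(gr)$transcript_id <- df$transcript_id
    rtracklayer::export(gr, path, format = "gtf")
  }
  if (!is.null(comment)) {
    lines <- readLines(path, warn = FALSE)
    hdr <- startsWith(lines, "#")
    writeLines(c(lines[hdr], paste0("## ", comment), lines[!hdr]), path)
  }
  invisible(path)
}

#' Write counting units as BED
#'
#' Exonic bins become their interval; junction units become the spanned
#' intron `(donor_end, acceptor_start)`. Conversion to BED's 0-based
#' half-open convention happens here.
#'
#' @param units counting-unit table from [flatten_gene()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
units_to_bed <- function(units, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = if (is.null(units$chrom)) "units" else units$chrom,
    ranges = IRanges::IRanges(units$start, units$end),
    name = units$unit_id
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
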