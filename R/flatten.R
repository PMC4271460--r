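## Flattening a gene into counting units: disjoint exonic bins cut at every
## splice boundary observed in any transcript, plus one junction unit per
## distinct intron. This is the counting granularity used by count-based
## differential-splicing statistics.

#' Flatten a gene into counting units
#'
#' Exonic bins are the maximal intervals between consecutive distinct exon
#' boundaries over all transcripts, so no bin interior contains a splice
#' boundary of any transcript; their disjoint union equals the exonic union
#' of the gene. One junction unit is emitted per distinct intron
#' `(donor_end, acceptor_start)`. Exonic effective length is the bin width in
#' nucleotides; junction effective length is `read_length - 1`, the number of
#' read start positions that span the junction.
#'
#' @param gene a [gene_model()].
#' @param read_length read length in nt (>= 2); sets junction effective
#'   length.
#' @return data frame with one row per counting unit: `unit_id`, `gene_id`,
#'   `kind` (`"exonic_bin"` or `"junction"`), `start`, `end` (for junctions:
#'   donor end and acceptor start), `effective_length`, and a list-column
#'   `members` of transcript ids containing the unit.
#' @export
flatten_gene <- function(gene, read_length = 100L) {
  stopifnot(inherits(gene, "gene_model"))
  if (!is.numeric(read_length) || length(read_length) != 1L || read_length < 2) {
    stop("'read_length' must be a single number >= 2")
  }
  read_length <- as.integer(read_length)
  trs <- gene$transcripts
  tids <- names(trs)

  ## exonic bins: cut the exon union at every distinct start or end+1
  exon_union <- gene_exon_union(gene)
  all_ex <- do.call(rbind, lapply(trs, `[[`, "exons"))
  cuts <- sort(unique(c(all_ex[, 1L], all_ex[, 2L] + 1L)))
  bins <- NULL
  for (i in seq_len(nrow(exon_union))) {
    lo <- exon_union[i, 1L]; hi <- exon_union[i, 2L]
    inner <- cuts[cuts > lo & cuts <= hi]
    starts <- c(lo, inner)
    ends <- c(inner - 1L, hi)
    bins <- rbind(bins, cbind(starts, ends))
  }
  bin_members <- lapply(seq_len(nrow(bins)), function(i) {
    p <- bins[i, 1L]
    tids[vapply(trs, function(tr) ivl_covers(tr$exons, p), logical(1))]
  })

  ## junction units: distinct introns over all transcripts
  introns <- lapply(trs, transcript_introns)
  jn <- do.call(rbind, introns)
  out_bins <- data.frame(
    unit_id = sprintf("%s:E:%d-%d", gene$gene_id, bins[, 1L], bins[, 2L]),
    gene_id = gene$gene_id,
    chrom = gene$chrom,
    kind = "exonic_bin",
    start = as.integer(bins[, 1L]),
    end = as.integer(bins[, 2L]),
    effective_length = as.numeric(bins[, 2L] - bins[, 1L] + 1L),
    stringsAsFactors = FALSE
  )
  out_bins$members <- bin_members

  if (!is.null(jn) && nrow(jn) > 0L) {
    key <- paste(jn[, 1L], jn[, 2L])
    uniq <- !duplicated(key)
    ujn <- jn[uniq, , drop = FALSE]
    ukey <- key[uniq]
    jn_members <- lapply(ukey, function(k) {
      tids[vapply(introns, function(m) {
        nrow(m) > 0L && any(paste(m[, 1L], m[, 2L]) == k)
      }, logical(1))]
    })
    ord <- order(ujn[, 1L], ujn[, 2L])
    out_jn <- data.frame(
      unit_id = sprintf("%s:J:%d-%d", gene$gene_id, ujn[ord, 1L], ujn[ord, 2L]),
      gene_id = gene$gene_id,
      chrom = gene$chrom,
      kind = "junction",
      start = as.integer(ujn[ord, 1L]),
      end = as.integer(ujn[ord, 2L]),
      effective_length = as.numeric(read_length - 1L),
      stringsAsFactors = FALSE
    )
    out_jn$members <- jn_members[ord]
    out <- rbind(out_bins, out_jn)
  } else {
    out <- out_bins
  }
  rownames(out) <- NULL
  out
}

#' Flatten a list of genes into one counting-unit table
#'
#' @param genes list of [gene_model()] objects.
#' @inheritParams flatten_gene
#' @return row-bound data frame of [flatten_gene()] results.
#' @export
flatten_genes <- function(genes, read_length = 100L) {
  out <- do.call(rbind, lapply(genes, flatten_gene, read_length = read_length))
  rownames(out) <- NULL
  out
}
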