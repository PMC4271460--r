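## Gene-level alternative-splicing class assignment. Two-transcript genes
## with exactly one simple event get that event's class, with alternative
## donor and acceptor sites merged into a single A3A5SS class (the two are
## computationally indistinguishable targets). MXE is detected but, like any
## non-simple pattern, does not enter the three-class partition used for
## per-type evaluation.

GENE_CLASSES <- c("A3A5SS", "IR", "SE", "MXE", "complex", "multi_event",
                  "single_isoform")

#' Classify a gene by its alternative-splicing structure
#'
#' Single-transcript genes (or multi-transcript genes whose transcripts have
#' identical splice structure, e.g. UTR-only variants) are `single_isoform`.
#' A gene whose transcripts yield exactly one simple event across all
#' pairwise comparisons gets that event's class (`SE`, `IR`, `MXE`, or
#' `A3A5SS` for either alternative splice-site type). Genes with more than
#' one distinct event are `multi_event`; genes with any complex event (or
#' disagreeing pairs) are `complex`.
#'
#' @param gene a [gene_model()].
#' @return a `gene_as_class` object: list with `gene_id`, `n_transcripts`,
#'   `class`.
#' @export
classify_gene <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  n_tr <- n_transcripts(gene)
  cls <- if (n_tr == 1L) {
    "single_isoform"
  } else {
    trs <- gene$transcripts
    cmb <- utils::combn(n_tr, 2L)
    all_events <- list()
    pair_counts <- integer(0)
    for (j in seq_len(ncol(cmb))) {
      evs <- extract_events(trs[[cmb[1L, j]]], trs[[cmb[2L, j]]],
                            strand = gene$strand, gene_id = gene$gene_id)
      pair_counts <- c(pair_counts, length(evs))
      all_events <- c(all_events, evs)
    }
    if (length(all_events) == 0L) {
      "single_isoform"
    } else {
      keys <- vapply(all_events, function(e)
        paste(e$type, e$region[1L], e$region[2L]), character(1))
      types <- vapply(all_events, `[[`, character(1), "type")
      distinct <- !duplicated(keys)
      if (any(types == "complex")) {
        "complex"
      } else if (sum(distinct) > 1L || any(pair_counts > 1L)) {
        "multi_event"
      } else {
        tp <- types[1L]
        if (tp %in% c("A3SS", "A5SS")) "A3A5SS" else tp
      }
    }
  }
  structure(list(gene_id = gene$gene_id, n_transcripts = n_tr, class = cls),
            class = "gene_as_class")
}

#' @export
print.gene_as_class <- function(x, ...) {
  cat(sprintf("<gene_as_class> %s: %s (%d transcript(s))\n",
              x$gene_id, x$class, x$n_transcripts))
  invisible(x)
}

#' Summarize an annotation: multi-isoform counts and event-class partition
#'
#' Computes the headline structural counts of an annotation: total genes,
#' genes with at least two transcripts, the partition of two-transcript
#' single-event genes into the three simple classes (alternative
#' donor/acceptor, intron retention, exon skipping), and the longest gene
#' span.
#'
#' @param genes list of [gene_model()] objects.
#' @return list with `n_genes`, `n_multi_isoform`, `n_two_tx_single_event`,
#'   `partition` (named counts for A3A5SS/IR/SE), `longest_gene_nt`.
#' @export
annotation_summary <- function(genes) {
  n_tr <- vapply(genes, n_transcripts, integer(1))
  cls <- vapply(genes, function(g) classify_gene(g)$class, character(1))
  simple <- cls %in% c("A3A5SS", "IR", "SE") & n_tr == 2L
  spans <- vapply(genes, function(g) diff(gene_span(g)) + 1L, integer(1))
  list(
    n_genes = length(genes),
    n_multi_isoform = sum(n_tr >= 2L),
    n_two_tx_single_event = sum(simple),
    partition = c(A3A5SS = sum(cls == "A3A5SS" & simple),
                  IR = sum(cls == "IR" & simple),
                  SE = sum(cls == "SE" & simple)),
    longest_gene_nt = if (length(spans)) max(spans) else NA_integer_
  )
}

#' Remove the alternative transcript of each true AS gene from an annotation
#'
#' Emulates incomplete annotation: for every gene flagged as truly
#' differentially spliced in `truth`, the named alternative transcript is
#' deleted from a copy of the gene model. All other genes are returned
#' untouched. No gene is left without transcripts.
#'
#' @param genes named or unnamed list of [gene_model()] objects.
#' @param truth a truth table (see [choose_true_as_genes()]) with columns
#'   `gene_id`, `is_true_as`, `alt_transcript_id`.
#' @param strict if `TRUE`, an alternative transcript id missing from its
#'   gene is a consistency error; the default silently skips
#'   already-removed transcripts, which makes the transform idempotent.
#' @return list of gene models with alternative transcripts removed.
#' @export
make_incomplete_annotation <- function(genes, truth, strict = FALSE) {
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  names(genes) <- ids
  tr <- truth[truth$is_true_as, , drop = FALSE]
  for (i in seq_len(nrow(tr))) {
    gid <- tr$gene_id[i]
    alt <- tr$alt_transcript_id[i]
    if (!gid %in% ids) stop("true AS gene ", gid, " absent from annotation")
    g <- genes[[gid]]
    if (!alt %in% names(g$transcripts)) {
      if (strict) {
        stop("alternative transcript ", alt, " absent from gene ", gid)
      }
      next
    }
    if (length(g$transcripts) < 2L) {
      stop("removing ", alt, " would leave gene ", gid, " with no transcripts")
    }
    g$transcripts <- g$transcripts[names(g$transcripts) != alt]
    genes[[gid]] <- g
  }
  genes
}
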