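## Pairwise splice-event extraction. Two transcripts of a gene are compared
## by their exonic coverage over the span both of them reach; each maximal
## region where coverage differs, grouped between shared exonic blocks, is
## classified into one of the five simple event types or "complex".
##
## Differences at the outer transcription start/end (alternative first/last
## exon outer boundaries) are not splice events and are ignored: coverage is
## compared only over the shared span, and differing regions touching the
## shared-span edges are dropped.

EVENT_TYPES <- c("SE", "IR", "A3SS", "A5SS", "MXE", "complex")

#' Extract splice events between two transcripts
#'
#' The exonic coverage of the two transcripts is compared over their shared
#' span. Maximal differing regions are grouped between shared exonic blocks
#' and classified: an internal exon present in one transcript inside the
#' other's intron with shared flanking introns is a skipped exon (SE); an
#' intron of one transcript fully exonic in the other is intron retention
#' (IR); a single differing exon boundary with the other intron boundary
#' shared is an alternative 5' splice site (A5SS) when the differing boundary
#' is the donor side (strand-aware) and A3SS when it is the acceptor side;
#' two non-overlapping internal exons used exclusively by either transcript
#' are mutually exclusive exons (MXE); anything else is "complex".
#'
#' @param t1,t2 [transcript()] objects from the same gene.
#' @param strand `"+"` or `"-"`; decides donor vs acceptor roles.
#' @param gene_id optional gene id used in event ids.
#' @return list of `splice_event` objects (possibly empty), each a list with
#'   `event_id`, `gene_id`, `type`, `region` (`c(start, end)` hull of the
#'   differing runs), `runs` (matrix `start`, `end`, `in_t1` flag),
#'   `transcripts` (the ordered pair of ids compared).
#' @export
extract_events <- function(t1, t2, strand, gene_id = NA_character_) {
  stopifnot(inherits(t1, "transcript"), inherits(t2, "transcript"))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  ex1 <- t1$exons
  ex2 <- t2$exons

  lo <- max(min(ex1[, 1L]), min(ex2[, 1L]))
  hi <- min(max(ex1[, 2L]), max(ex2[, 2L]))
  if (lo > hi) return(list())
  c1 <- ivl_clip(ex1, lo, hi)
  c2 <- ivl_clip(ex2, lo, hi)
  if (nrow(c1) == 0L || nrow(c2) == 0L) return(list())

  ## elementary segments between consecutive boundaries of either set
  b <- sort(unique(c(lo, hi + 1L, c1[, 1L], c1[, 2L] + 1L,
                     c2[, 1L], c2[, 2L] + 1L)))
  b <- b[b >= lo & b <= hi + 1L]
  seg_start <- b[-length(b)]
  seg_end <- b[-1L] - 1L
  cov1 <- vapply(seg_start, function(p) ivl_covers(c1, p), logical(1))
  cov2 <- vapply(seg_start, function(p) ivl_covers(c2, p), logical(1))

  state <- ifelse(cov1 & cov2, "B", ifelse(cov1, "1", ifelse(cov2, "2", "0")))
  r <- rle(state)
  k <- length(r$values)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  runs <- data.frame(
    state = r$values,
    start = seg_start[idx_start],
    end = seg_end[idx_end],
    stringsAsFactors = FALSE
  )

  ## group differing runs ("1"/"2") by the number of shared exonic blocks
  ## ("B") seen before them; drop runs touching the shared-span edges
  ## (alternative first/last exon differences, not splicing).
  runs$block <- cumsum(runs$state == "B")
  diff_runs <- runs[runs$state %in% c("1", "2"), , drop = FALSE]
  diff_runs <- diff_runs[diff_runs$start > lo & diff_runs$end < hi, ,
                         drop = FALSE]
  if (nrow(diff_runs) == 0L) return(list())

  state_at <- function(p) {
    i <- which(runs$start <= p & runs$end >= p)
    if (length(i) == 0L) "edge" else runs$state[i[1L]]
  }

  events <- list()
  for (g in unique(diff_runs$block)) {
    grp <- diff_runs[diff_runs$block == g, , drop = FALSE]
    type <- classify_event_group(grp, state_at, strand)
    region <- c(min(grp$start), max(grp$end))
    ev <- structure(list(
      event_id = sprintf("%s:%s:%d-%d", gene_id, type, region[1L], region[2L]),
      gene_id = gene_id,
      type = type,
      region = region,
      runs = cbind(start = grp$start, end = grp$end, in_t1 = grp$state == "1"),
      transcripts = c(t1$transcript_id, t2$transcript_id)
    ), class = "splice_event")
    events[[length(events) + 1L]] <- ev
  }
  events
}

## Classify one group of differing runs lying between two shared exonic
## blocks. `grp` rows carry state "1" (exonic in t1 only) or "2".
classify_event_group <- function(grp, state_at, strand) {
  n <- nrow(grp)
  if (n == 1L) {
    left <- state_at(grp$start[1L] - 1L)
    right <- state_at(grp$end[1L] + 1L)
    if (left == "B" && right == "B") return("IR")
    if (left == "0" && right == "0") return("SE")
    if (left == "B" && right == "0") {
      ## differing exon END (right) boundary: donor side on +, acceptor on -
      return(if (strand == "+") "A5SS" else "A3SS")
    }
    if (left == "0" && right == "B") {
      ## differing exon START (left) boundary: acceptor side on +, donor on -
      return(if (strand == "+") "A3SS" else "A5SS")
    }
    return("complex")
  }
  if (n == 2L) {
    ## mutually exclusive exons: opposite signs, both complete internal
    ## exons, separated by a region intronic in both transcripts
    flanks <- c(state_at(grp$start[1L] - 1L), state_at(grp$end[1L] + 1L),
                state_at(grp$start[2L] - 1L), state_at(grp$end[2L] + 1L))
    if (grp$state[1L] != grp$state[2L] &&
        grp$end[1L] + 1L < grp$start[2L] &&
        all(flanks == "0")) {
      return("MXE")
    }
  }
  "complex"
}

#' @export
print.splice_event <- function(x, ...) {
  cat(sprintf("<splice_event> %s [%s] %d-%d (%s vs %s)\n",
              x$type, x$gene_id, x$region[1L], x$region[2L],
              x$transcripts[1L], x$transcripts[2L]))
  invisible(x)
}

#' Attach inclusion/exclusion counting units to a splice event
#'
#' Given a gene's counting-unit table, the inclusion side of an event is the
#' set of units (exonic bins and junctions) specific to the transcript with
#' more exonic sequence in the event region, restricted to units overlapping
#' the region; the exclusion side is the units specific to the other
#' transcript. "Specific" means the unit's member set contains one transcript
#' of the compared pair but not the other.
#'
#' @param event a `splice_event` from [extract_events()].
#' @param units counting-unit table from [flatten_gene()] for the same gene.
#' @return the event with `inclusion_units` and `exclusion_units` character
#'   vectors of unit ids filled in.
#' @export
event_units <- function(event, units) {
  stopifnot(inherits(event, "splice_event"))
  tx <- event$transcripts
  rn <- event$runs
  len1 <- sum((rn[, "end"] - rn[, "start"] + 1L)[rn[, "in_t1"] == 1])
  len2 <- sum((rn[, "end"] - rn[, "start"] + 1L)[rn[, "in_t1"] == 0])
  incl_tx <- if (len1 >= len2) tx[1L] else tx[2L]
  excl_tx <- setdiff(tx, incl_tx)

  lo <- event$region[1L] - 1L
  hi <- event$region[2L] + 1L
  overlaps <- units$start <= hi & units$end >= lo
  has <- function(m, id) vapply(m, function(v) id %in% v, logical(1))
  only_incl <- has(units$members, incl_tx) & !has(units$members, excl_tx)
  only_excl <- has(units$members, excl_tx) & !has(units$members, incl_tx)
  event$inclusion_units <- units$unit_id[overlaps & only_incl]
  event$exclusion_units <- units$unit_id[overlaps & only_excl]
  event$inclusion_transcript <- incl_tx
  event$exclusion_transcript <- excl_tx
  event
}

#' Extract all pairwise splice events of a gene, with counting units
#'
#' @param gene a [gene_model()].
#' @param read_length passed to [flatten_gene()] for junction units.
#' @return list of `splice_event` objects over all transcript pairs, each
#'   with inclusion/exclusion units attached.
#' @export
gene_events <- function(gene, read_length = 100L) {
  trs <- gene$transcripts
  if (length(trs) < 2L) return(list())
  units <- flatten_gene(gene, read_length = read_length)
  out <- list()
  cmb <- utils::combn(length(trs), 2L)
  for (j in seq_len(ncol(cmb))) {
    evs <- extract_events(trs[[cmb[1L, j]]], trs[[cmb[2L, j]]],
                          strand = gene$strand, gene_id = gene$gene_id)
    out <- c(out, lapply(evs, event_units, units = units))
  }
  out
}

#' Write splice events as TSV
#'
#' Columns: event_id, gene_id, type, start, end, transcripts (comma-joined),
#' inclusion_units, exclusion_units (comma-joined, empty when not attached).
#'
#' @param events list of `splice_event` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
events_to_tsv <- function(events, path) {
  df <- data.frame(
    event_id = vapply(events, `[[`, character(1), "event_id"),
    gene_id = vapply(events, `[[`, character(1), "gene_id"),
    type = vapply(events, `[[`, character(1), "type"),
    start = vapply(events, function(e) e$region[1L], integer(1)),
    end = vapply(events, function(e) e$region[2L], integer(1)),
    transcripts = vapply(events, function(e)
      paste(e$transcripts, collapse = ","), character(1)),
    inclusion_units = vapply(events, function(e)
      paste(e$inclusion_units %||% character(0), collapse = ","), character(1)),
    exclusion_units = vapply(events, function(e)
      paste(e$exclusion_units %||% character(0), collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
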