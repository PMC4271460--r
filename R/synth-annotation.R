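## Synthetic annotation generator: builds non-overlapping genes on a
## synthetic chromosome, each realizing a requested alternative-splicing
## class. This removes any dependency on downloaded reference annotation
## while keeping the structural features (short plant-like introns, two
## transcripts per AS gene) that the event classifier and simulator exercise.

#' Generate a synthetic annotation with a controlled class composition
#'
#' Genes are laid end-to-end (separated by `gap`) on one synthetic
#' chromosome. The number of genes per class is allocated
#' deterministically: `floor(fraction * n_genes)` per class, remainders
#' assigned by largest fractional part (ties broken by class order). Each
#' gene is built to realize its class and verified with [classify_gene()];
#' generation is deterministic under `seed`.
#'
#' Supported classes: `SE`, `IR`, `A3A5SS`, `MXE`, `complex` (a multi-exon
#' skip), `multi_event` (two separate skipped exons), `single_isoform`.
#'
#' @param n_genes number of genes.
#' @param class_mix named numeric vector of class fractions summing to 1.
#' @param length_params list with elements `exon = c(min, max)`,
#'   `intron = c(min, max)` and scalar `gap`, all in nt. Defaults emulate
#'   compact plant genes (exons 50-300 nt, introns 80-200 nt).
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @return list of [gene_model()] objects, names = gene ids.
#' @export
synth_annotation <- function(n_genes,
                             class_mix = c(SE = 0.25, IR = 0.25,
                                           A3A5SS = 0.25, complex = 0.25),
                             length_params = list(exon = c(50, 300),
                                                  intron = c(80, 200),
                                                  gap = 500),
                             seed = 1L,
                             chrom = "chrS") {
  stopifnot(n_genes >= 1L, length(class_mix) >= 1L)
  if (is.null(names(class_mix)) || any(names(class_mix) == "")) {
    stop("'class_mix' must be a named vector")
  }
  bad <- setdiff(names(class_mix), GENE_CLASSES)
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
  if (abs(sum(class_mix) - 1) > 1e-8) stop("'class_mix' must sum to 1")
  ex_rg <- length_params$exon
  in_rg <- length_params$intron
  gap <- length_params$gap
  if (is.null(ex_rg) || is.null(in_rg) || is.null(gap) ||
      ex_rg[1L] > ex_rg[2L] || in_rg[1L] > in_rg[2L] ||
      ex_rg[1L] < 10 || in_rg[1L] < 40 || gap < 1) {
    stop("infeasible length ranges: need exon >= 10, intron >= 40, gap >= 1")
  }

  ## deterministic allocation of genes to classes
  base <- floor(class_mix * n_genes)
  rem <- n_genes - sum(base)
  frac <- class_mix * n_genes - base
  if (rem > 0L) {
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  classes <- rep(names(base), times = base)

  with_seed(seed, {
    genes <- vector("list", n_genes)
    pos <- 1L
    for (i in seq_len(n_genes)) {
      gid <- sprintf("SG%05d", i)
      cls <- classes[i]
      strand <- sample(c("+", "-"), 1L)
      g <- build_class_gene(gid, chrom, strand, cls, pos, ex_rg, in_rg)
      got <- classify_gene(g)$class
      if (got != cls) {
        stop("generation error: gene ", gid, " built for class ", cls,
             " classified as ", got)
      }
      genes[[i]] <- g
      pos <- gene_span(g)[2L] + as.integer(gap)
    }
    names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
    genes
  })
}

## Draw a run of exon/intron lengths and return cumulative exon intervals
## starting at `pos`. n exons, n-1 introns.
draw_exons <- function(pos, n, ex_rg, in_rg) {
  el <- as.integer(round(stats::runif(n, ex_rg[1L], ex_rg[2L])))
  il <- if (n > 1L) as.integer(round(stats::runif(n - 1L, in_rg[1L], in_rg[2L])))
        else integer(0)
  starts <- integer(n)
  ends <- integer(n)
  p <- as.integer(pos)
  for (i in seq_len(n)) {
    starts[i] <- p
    ends[i] <- p + el[i] - 1L
    p <- ends[i] + (if (i < n) il[i] else 0L) + 1L
  }
  cbind(start = starts, end = ends)
}

build_class_gene <- function(gid, chrom, strand, cls, pos, ex_rg, in_rg) {
  t_id <- function(k) sprintf("%s.%d", gid, k)
  mk <- function(...) gene_model(gid, chrom, strand, list(...))
  switch(cls,
    single_isoform = {
      ex <- draw_exons(pos, 3L, ex_rg, in_rg)
      mk(transcript(t_id(1), ex))
    },
    SE = {
      ex <- draw_exons(pos, 3L, ex_rg, in_rg)
      mk(transcript(t_id(1), ex),
         transcript(t_id(2), ex[c(1L, 3L), , drop = FALSE]))
    },
    IR = {
      ex <- draw_exons(pos, 2L, ex_rg, in_rg)
      mk(transcript(t_id(1), ex),
         transcript(t_id(2), cbind(ex[1L, 1L], ex[2L, 2L])))
    },
    A3A5SS = {
      ex <- draw_exons(pos, 2L, ex_rg, in_rg)
      intron_len <- ex[2L, 1L] - ex[1L, 2L] - 1L
      delta <- as.integer(round(stats::runif(1L, 10, min(30, intron_len - 20))))
      alt <- ex
      if (stats::runif(1L) < 0.5) {
        alt[1L, 2L] <- alt[1L, 2L] + delta   # shifted exon end
      } else {
        alt[2L, 1L] <- alt[2L, 1L] - delta   # shifted exon start
      }
      mk(transcript(t_id(1), ex), transcript(t_id(2), alt))
    },
    MXE = {
      ex <- draw_exons(pos, 4L, ex_rg, in_rg)
      mk(transcript(t_id(1), ex[c(1L, 2L, 4L), , drop = FALSE]),
         transcript(t_id(2), ex[c(1L, 3L, 4L), , drop = FALSE]))
    },
    complex = {
      ## two adjacent exons skipped together: a single non-simple region
      ex <- draw_exons(pos, 4L, ex_rg, in_rg)
      mk(transcript(t_id(1), ex),
         transcript(t_id(2), ex[c(1L, 4L), , drop = FALSE]))
    },
    multi_event = {
      ## two separate skipped exons, split by a shared exon
      ex <- draw_exons(pos, 5L, ex_rg, in_rg)
      mk(transcript(t_id(1), ex),
         transcript(t_id(2), ex[c(1L, 3L, 5L), , drop = FALSE]))
    },
    stop("unsupported class: ", cls)
  )
}
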