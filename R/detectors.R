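## Reference count-based DAS detectors. These implement the families of
## statistics that count-based differential-splicing methods use — a
## variance-adjusted unit-fraction statistic with label-permutation
## p-values, a Jensen-Shannon divergence statistic on mean unit-fraction
## vectors, and a percent-spliced-in (psi) bootstrap test on
## inclusion/exclusion counts — as reference detectors for exercising the
## benchmarking harness, not as re-implementations of any published tool.

#' Gene-wise unit-fraction statistic
#'
#' Per counting unit `i` and condition `j`, `p_hat[i, j]` is the mean over
#' replicates of the unit's fraction of the gene total in that sample, and
#' `var_hat[i, j]` the across-replicate variance of those fractions. The
#' gene statistic is the variance-adjusted mean squared difference
#' `T = (1/U) * sum_i (p_hat[i,1] - p_hat[i,2])^2 / (var[i,1] + var[i,2] + eps)`.
#' Samples whose gene total is zero are dropped; the statistic is `NA`
#' (flagged, not scored) when fewer than two usable replicates remain in a
#' condition.
#'
#' @param counts unit x sample count matrix for one gene (>= 2 units).
#' @param design two-level factor/character of conditions per column.
#' @param eps variance floor (default 1e-8).
#' @return the statistic (numeric scalar, possibly `NA`).
#' @export
unit_fraction_stat <- function(counts, design, eps = 1e-8) {
  if (nrow(counts) < 2L) stop("gene needs >= 2 counting units")
  gene_ids <- rep("g", nrow(counts))
  res <- ufs_by_gene(counts, gene_ids, design, eps = eps)
  unname(res["g"])
}

## Vectorized unit-fraction statistic for all genes at once.
## counts: unit x sample; gene_ids: per row. Returns named vector per gene.
ufs_by_gene <- function(counts, gene_ids, design, eps = 1e-8) {
  design <- as.factor(design)
  stopifnot(nlevels(design) == 2L, length(design) == ncol(counts))
  totals <- rowsum(counts, gene_ids, reorder = FALSE)
  gidx <- match(gene_ids, rownames(totals))
  frac <- counts / totals[gidx, , drop = FALSE]
  frac[!is.finite(frac)] <- NA_real_  # samples with gene total 0 are dropped

  grp_stats <- function(x) {
    n <- rowSums(!is.na(x))
    m <- rowMeans(x, na.rm = TRUE)
    ss <- rowSums((x - m)^2, na.rm = TRUE)
    v <- ifelse(n > 1L, ss / (n - 1L), NA_real_)
    list(n = n, m = m, v = v)
  }
  s1 <- grp_stats(frac[, design == levels(design)[1L], drop = FALSE])
  s2 <- grp_stats(frac[, design == levels(design)[2L], drop = FALSE])

  d2 <- (s1$m - s2$m)^2 / (s1$v + s2$v + eps)
  ok_unit <- s1$n >= 2L & s2$n >= 2L
  d2[!ok_unit] <- NA_real_
  t_sum <- rowsum(ifelse(is.na(d2), 0, d2), gene_ids, reorder = FALSE)[, 1L]
  n_ok <- rowsum(as.numeric(ok_unit), gene_ids, reorder = FALSE)[, 1L]
  n_units <- rowsum(rep(1, length(gene_ids)), gene_ids, reorder = FALSE)[, 1L]
  out <- ifelse(n_ok == n_units & n_units >= 1L, t_sum / n_units, NA_real_)
  names(out) <- rownames(totals)
  out
}

## sqrt Jensen-Shannon divergence between the two conditions' mean
## unit-fraction vectors, per gene. Genes with any zero-total condition
## (degenerate mean vector) come back NA.
jsd_by_gene <- function(counts, gene_ids, design) {
  design <- as.factor(design)
  totals <- rowsum(counts, gene_ids, reorder = FALSE)
  gidx <- match(gene_ids, rownames(totals))
  frac <- counts / totals[gidx, , drop = FALSE]
  frac[!is.finite(frac)] <- NA_real_
  p1 <- rowMeans(frac[, design == levels(design)[1L], drop = FALSE], na.rm = TRUE)
  p2 <- rowMeans(frac[, design == levels(design)[2L], drop = FALSE], na.rm = TRUE)
  xlx <- function(x) ifelse(is.na(x) | x <= 0, 0, x * log2(x))
  m <- (p1 + p2) / 2
  contrib <- xlx(p1) / 2 + xlx(p2) / 2 - xlx(m)
  js <- rowsum(contrib, gene_ids, reorder = FALSE)[, 1L]
  bad <- rowsum(as.numeric(is.na(p1) | is.na(p2)), gene_ids,
                reorder = FALSE)[, 1L] > 0
  js[bad] <- NA_real_
  out <- sqrt(pmax(js, 0))
  names(out) <- rownames(totals)
  out
}

## Enumerate or sample label permutations. Returns a list of logical
## vectors (TRUE = sample assigned to condition 1) and a flag `exact`.
perm_splits <- function(design, n_perm, seed) {
  design <- as.factor(design)
  n <- length(design)
  n1 <- sum(design == levels(design)[1L])
  k_distinct <- choose(n, n1)
  if (k_distinct <= n_perm) {
    cmb <- utils::combn(n, n1)
    splits <- lapply(seq_len(ncol(cmb)), function(j) {
      v <- rep(FALSE, n); v[cmb[, j]] <- TRUE; v
    })
    list(splits = splits, exact = TRUE)
  } else {
    obs <- design == levels(design)[1L]
    splits <- with_seed(seed, {
      lapply(seq_len(n_perm), function(i) sample(obs))
    })
    list(splits = splits, exact = FALSE)
  }
}

#' Permutation p-values for a gene-wise statistic
#'
#' Condition labels are permuted jointly across all genes per iteration.
#' With the add-one convention, `p = (1 + #\{permuted T >= observed T\}) /
#' (n_perm + 1)`. When the design admits fewer distinct label splits than
#' `n_perm`, all distinct splits are enumerated instead and the p-value is
#' the exact tail fraction (the observed labeling included). Deterministic
#' under `seed`.
#'
#' @param counts unit x sample count matrix (all genes).
#' @param units counting-unit table ([flatten_genes()]) matching the rows,
#'   or a character vector of gene ids per row.
#' @param design two-level condition factor per column.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param statistic `"unit_fraction"` or `"jsd"` (sqrt Jensen-Shannon
#'   divergence of mean unit-fraction vectors).
#' @param eps variance floor for the unit-fraction statistic.
#' @return a `das_scores` data frame: `target_id`, `statistic`, `p_value`,
#'   `p_adj` (Benjamini-Hochberg), `ranking_score = 1 - p_adj`.
#' @export
permutation_pvalues <- function(counts, units, design, n_perm = 1000L,
                                seed = 1L,
                                statistic = c("unit_fraction", "jsd"),
                                eps = 1e-8) {
  statistic <- match.arg(statistic)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  gene_ids <- if (is.character(units)) units else units$gene_id
  stopifnot(length(gene_ids) == nrow(counts))
  design <- as.factor(design)
  if (any(table(design) == 0L)) stop("both conditions must be non-empty")

  stat_fun <- if (statistic == "unit_fraction") {
    function(labels) ufs_by_gene(counts, gene_ids,
                                 factor(ifelse(labels, "a", "b")), eps = eps)
  } else {
    function(labels) jsd_by_gene(counts, gene_ids,
                                 factor(ifelse(labels, "a", "b")))
  }
  obs_labels <- design == levels(design)[1L]
  t_obs <- stat_fun(obs_labels)

  ps <- perm_splits(design, n_perm, seed)
  exceed <- rep(0, length(t_obs))
  n_valid <- rep(0, length(t_obs))
  for (sp in ps$splits) {
    t_perm <- stat_fun(sp)
    hit <- !is.na(t_perm) & !is.na(t_obs) & t_perm >= t_obs
    exceed <- exceed + hit
    n_valid <- n_valid + !is.na(t_perm)
  }
  p <- if (ps$exact) {
    exceed / length(ps$splits)
  } else {
    (1 + exceed) / (length(ps$splits) + 1)
  }
  p[is.na(t_obs)] <- NA_real_
  p_adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_adj[ok] <- adjust_pvalues(p[ok], "BH")
  score_table(target_id = names(t_obs), statistic = unname(t_obs),
              p_value = unname(p), p_adj = unname(p_adj))
}

#' Jensen-Shannon divergence between two proportion vectors
#'
#' `JSD(p, q) = H((p + q)/2) - (H(p) + H(q))/2` with base-2 entropy, so the
#' value lies in `[0, 1]`; `sqrt(JSD)` is a metric.
#'
#' @param p,q non-negative vectors of equal length, each summing to 1
#'   (within 1e-6).
#' @param sqrt return the metric form `sqrt(JSD)`.
#' @return divergence in bits (or its square root).
#' @export
jsd <- function(p, q, sqrt = FALSE) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (any(p < 0) || any(q < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("input error: proportions must sum to 1 (tolerance 1e-6)")
  }
  xlx <- function(x) ifelse(x <= 0, 0, x * log2(x))
  m <- (p + q) / 2
  v <- sum(xlx(p)) / 2 + sum(xlx(q)) / 2 - sum(xlx(m))
  v <- max(v, 0)
  if (sqrt) base::sqrt(v) else v
}

#' JSD-based gene-level proportion test
#'
#' Statistic: `sqrt(JSD)` between the two conditions' mean unit-fraction
#' vectors; p-values by the same joint label-permutation scheme as
#' [permutation_pvalues()].
#'
#' @inheritParams permutation_pvalues
#' @return a `das_scores` data frame.
#' @export
jsd_proportion_test <- function(counts, units, design, n_perm = 1000L,
                                seed = 1L) {
  permutation_pvalues(counts, units, design, n_perm = n_perm, seed = seed,
                      statistic = "jsd")
}

#' Percent-spliced-in (psi) bootstrap test for one splice event
#'
#' Per sample, `psi = inclusion / (inclusion + exclusion)` after dividing
#' each side by its summed effective length (length normalization is the
#' default and can be switched off). The reported score is the bootstrap
#' probability that the absolute difference of condition mean psi exceeds
#' the cutoff `c`, resampling replicates within each condition.
#'
#' @param counts unit x sample count matrix.
#' @param event a `splice_event` with inclusion/exclusion units attached.
#' @param design two-level condition factor per column.
#' @param units counting-unit table (for effective lengths).
#' @param c difference cutoff in `[0, 1)` (default 0.1).
#' @param n_boot bootstrap draws (default 1000).
#' @param seed integer seed.
#' @param length_normalize divide each side by summed effective length.
#' @return a `psi_result` list: `event_id`, per-sample `psi`, `c`, `score`.
#'   Samples with zero inclusion + exclusion get `NA` psi; a condition with
#'   no usable sample flags the result as undefined (`score = NA`).
#' @export
psi_test <- function(counts, event, design, units, c = 0.1, n_boot = 1000L,
                     seed = 1L, length_normalize = TRUE) {
  if (!event$type %in% c("SE", "IR", "A3SS", "A5SS", "MXE")) {
    stop("psi_test requires a simple event; got ", event$type)
  }
  if (c < 0 || c >= 1) stop("'c' must be in [0, 1)")
  ec <- event_counts(counts, event)
  if (length_normalize) {
    il <- sum(units$effective_length[match(event$inclusion_units,
                                           units$unit_id)])
    el <- sum(units$effective_length[match(event$exclusion_units,
                                           units$unit_id)])
  } else {
    il <- el <- 1
  }
  inc <- ec["inclusion", ] / il
  exc <- ec["exclusion", ] / el
  psi <- ifelse(inc + exc > 0, inc / (inc + exc), NA_real_)
  design <- as.factor(design)
  i1 <- which(design == levels(design)[1L])
  i2 <- which(design == levels(design)[2L])
  ok1 <- i1[!is.na(psi[i1])]
  ok2 <- i2[!is.na(psi[i2])]
  score <- if (length(ok1) == 0L || length(ok2) == 0L) {
    NA_real_  # undefined: a condition has no reads on the event
  } else {
    with_seed(seed, {
      hits <- vapply(seq_len(n_boot), function(b) {
        m1 <- mean(psi[sample(ok1, length(ok1), replace = TRUE)])
        m2 <- mean(psi[sample(ok2, length(ok2), replace = TRUE)])
        abs(m1 - m2) > c
      }, logical(1))
      mean(hits)
    })
  }
  structure(list(event_id = event$event_id, psi = psi, c = c, score = score),
            class = "psi_result")
}

#' @export
print.psi_result <- function(x, ...) {
  cat(sprintf("<psi_result> %s: score %.3f (c = %.2g)\n  psi: %s\n",
              x$event_id, x$score, x$c,
              paste(sprintf("%.3f", x$psi), collapse = " ")))
  invisible(x)
}

#' Gene-level Bonferroni combination of unit p-values
#'
#' `min(1, k * min(p))` for `k` unit-level p-values.
#'
#' @param p numeric vector of p-values in `[0, 1]` (non-empty).
#' @return gene-level p-value.
#' @export
gene_level_bonferroni <- function(p) {
  if (length(p) == 0L) stop("empty p-value list is undefined")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  min(1, length(p) * min(p, na.rm = TRUE))
}

#' Construct a score table
#'
#' The common output schema of internal detectors and the input schema the
#' evaluator accepts from external tools: one row per gene or event with a
#' statistic, optional (adjusted) p-values, and a ranking score (higher =
#' more evidence for differential splicing).
#'
#' @param target_id character vector of gene/event ids.
#' @param statistic numeric statistic per target.
#' @param p_value,p_adj optional p-values in `[0, 1]`.
#' @param ranking_score optional explicit ranking score; defaults to
#'   `1 - p_adj` when adjusted p-values are present, else the statistic.
#' @return a `das_scores` data frame.
#' @export
score_table <- function(target_id, statistic, p_value = NA_real_,
                        p_adj = NA_real_, ranking_score = NULL) {
  df <- data.frame(target_id = as.character(target_id),
                   statistic = statistic,
                   p_value = p_value, p_adj = p_adj,
                   stringsAsFactors = FALSE)
  df$ranking_score <- if (!is.null(ranking_score)) {
    ranking_score
  } else if (any(!is.na(df$p_adj))) {
    1 - df$p_adj
  } else {
    df$statistic
  }
  class(df) <- c("das_scores", "data.frame")
  df
}

#' @export
print.das_scores <- function(x, ...) {
  cat(sprintf("<das_scores> %d targets; %d with p-values\n",
              nrow(x), sum(!is.na(x$p_value))))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' Write / read score tables as TSV
#'
#' @param scores a `das_scores` data frame.
#' @param path file path.
#' @param comment optional provenance header comment.
#' @return `path` (writer) or a `das_scores` data frame (reader).
#' @export
write_score_table <- function(scores, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(as.data.frame(scores), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("target_id")
  if (!all(need %in% names(df))) stop("score table missing target_id column")
  score_table(target_id = df$target_id,
              statistic = df$statistic %||% NA_real_,
              p_value = df$p_value %||% NA_real_,
              p_adj = df$p_adj %||% NA_real_,
              ranking_score = df$ranking_score)
}
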