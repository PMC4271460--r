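## Evaluation harness: ranking scores, restricted ROC / partial AUC,
## recall/precision at an FDR cutoff, rank concordance, overlap tables.
## ROC construction and partial-AUC integration are implemented here with
## explicit tie handling (one step per tie group, i.e. a diagonal segment),
## because the restricted-AUC conventions are the point of the harness.

#' Ranking scores from a score table
#'
#' `1 - p_adj` when adjusted p-values are present; otherwise the raw
#' statistic. Higher means more evidence for differential splicing.
#'
#' @param table a `das_scores` data frame (or anything with `target_id` plus
#'   `p_adj` and/or `statistic`).
#' @return named numeric vector of scores (names = target ids).
#' @export
ranking_scores <- function(table) {
  if (!is.null(table$p_adj) && any(!is.na(table$p_adj))) {
    stats::setNames(1 - table$p_adj, table$target_id)
  } else if (!is.null(table$statistic)) {
    stats::setNames(as.numeric(table$statistic), table$target_id)
  } else {
    stop("schema error: score table has neither p_adj nor statistic")
  }
}

#' ROC points from scores and truth
#'
#' Thresholds sweep the distinct score values in descending order; targets
#' tied at one score enter as a single step (a diagonal ROC segment).
#' Truth targets missing from `scores` are treated as scored `-Inf` (called
#' last). `NA` scores are likewise ranked last.
#'
#' @param scores named numeric vector (names = target ids).
#' @param truth truth table with `gene_id` and `is_true_as` columns, or a
#'   logical vector named by target id.
#' @return a `das_roc` data frame of `(fpr, tpr)` points from `(0, 0)` to
#'   `(1, 1)`, both coordinates non-decreasing.
#' @export
roc_points <- function(scores, truth) {
  lab <- truth_labels(truth)
  if (!any(lab) || all(lab)) {
    stop("undefined curve: need >= 1 positive and >= 1 negative target")
  }
  s <- scores[names(lab)]
  s[is.na(s)] <- -Inf
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]
  lab <- lab[ord]
  grp <- cumsum(!duplicated(s))            # tie groups in descending order
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  last <- !duplicated(grp, fromLast = TRUE) # last index of each tie group
  pts <- data.frame(fpr = c(0, unname(fp[last]) / sum(!lab)),
                    tpr = c(0, unname(tp[last]) / sum(lab)))
  rownames(pts) <- NULL
  class(pts) <- c("das_roc", "data.frame")
  pts
}

truth_labels <- function(truth) {
  if (is.logical(truth)) {
    if (is.null(names(truth))) stop("logical truth must be named")
    return(truth)
  }
  stats::setNames(as.logical(truth$is_true_as), truth$gene_id)
}

#' Restricted (partial) AUC of an ROC curve
#'
#' Trapezoidal area under the curve over `FPR` in `[0, fpr_max]`, linearly
#' interpolating the curve at `fpr_max`. The standardized (McClish) form is
#' `0.5 * (1 + (pAUC - pAUC_min) / (pAUC_max - pAUC_min))` with
#' `pAUC_max = fpr_max` and `pAUC_min = fpr_max^2 / 2`, so a random ranking
#' scores about 0.5 and a perfect one exactly 1.
#'
#' @param curve a `das_roc` from [roc_points()].
#' @param fpr_max right edge of the restricted FPR range (default 0.2).
#' @param standardized return the McClish-standardized value (default);
#'   `FALSE` returns the raw trapezoidal area.
#' @return the (standardized) partial AUC. The raw area is attached as
#'   attribute `"raw"`.
#' @export
restricted_auc <- function(curve, fpr_max = 0.2, standardized = TRUE) {
  if (!(fpr_max > 0 && fpr_max <= 1)) stop("fpr_max must be in (0, 1]")
  fpr <- curve$fpr
  tpr <- curve$tpr
  ## interpolate at fpr_max and drop points beyond it
  if (max(fpr) < fpr_max) stop("curve does not reach fpr_max")
  keep <- fpr < fpr_max
  x <- fpr[keep]
  y <- tpr[keep]
  i <- which(!keep)[1L]
  if (fpr[i] == fpr_max) {
    x <- c(x, fpr_max); y <- c(y, tpr[i])
  } else {
    x0 <- fpr[i - 1L]; y0 <- tpr[i - 1L]
    f <- (fpr_max - x0) / (fpr[i] - x0)
    x <- c(x, fpr_max); y <- c(y, y0 + f * (tpr[i] - y0))
  }
  raw <- sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
  out <- if (standardized) {
    pmin_ <- fpr_max^2 / 2
    pmax_ <- fpr_max
    0.5 * (1 + (raw - pmin_) / (pmax_ - pmin_))
  } else raw
  attr(out, "raw") <- raw
  out
}

#' Recall and precision at an adjusted-p cutoff
#'
#' Calls are targets with `p_adj <= alpha`. Recall is TP / positives (the
#' true-positive rate); precision is TP / calls, `NA` (flagged undefined)
#' when nothing is called.
#'
#' @param table a `das_scores` data frame with `p_adj`.
#' @param truth truth table (see [roc_points()]).
#' @param alpha cutoff on the adjusted p-value (default 0.05).
#' @return list with `recall`, `precision`, `n_called`.
#' @export
recall_precision <- function(table, truth, alpha = 0.05) {
  if (is.null(table$p_adj) || all(is.na(table$p_adj))) {
    stop("schema error: recall_precision requires p_adj")
  }
  lab <- truth_labels(truth)
  called <- table$target_id[!is.na(table$p_adj) & table$p_adj <= alpha]
  tp <- sum(lab[called], na.rm = TRUE)
  n_pos <- sum(lab)
  list(recall = if (n_pos > 0) tp / n_pos else NA_real_,
       precision = if (length(called) > 0) tp / length(called) else NA_real_,
       n_called = length(called))
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up or Bonferroni, via [stats::p.adjust()].
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param method `"BH"` or `"Bonferroni"`.
#' @return adjusted p-values, order-preserving.
#' @export
adjust_pvalues <- function(p, method = c("BH", "Bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("input error: p-values must be in [0, 1]")
  }
  stats::p.adjust(p, method = if (method == "BH") "BH" else "bonferroni")
}

#' Pairwise Spearman correlation of ranking scores
#'
#' Restricts all tables to the intersection of their target ids and
#' computes Spearman's rho (average ranks for ties) between every pair of
#' ranking-score vectors.
#'
#' @param tables named list of >= 2 score tables.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(tables) {
  if (length(tables) < 2L) stop("need >= 2 score tables")
  if (is.null(names(tables))) names(tables) <- paste0("m", seq_along(tables))
  ids <- lapply(tables, function(t) t$target_id)
  common <- Reduce(intersect, ids)
  if (length(common) == 0L) {
    ## name the first offending pair for the error message
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i < j && length(intersect(ids[[i]], ids[[j]])) == 0L) {
        stop("empty target intersection between ", names(tables)[i],
             " and ", names(tables)[j])
      }
    }
    stop("empty common target intersection across all tables")
  }
  m <- vapply(tables, function(t) {
    sc <- ranking_scores(t)
    unname(sc[common])
  }, numeric(length(common)))
  stats::cor(m, method = "spearman", use = "pairwise.complete.obs")
}

#' Overlap table of significant-call sets
#'
#' Diagonal: set sizes; off-diagonal: pairwise intersection sizes.
#'
#' @param call_sets named list of character vectors of significant targets.
#' @return symmetric integer matrix.
#' @export
overlap_table <- function(call_sets) {
  n <- length(call_sets)
  nm <- names(call_sets) %||% paste0("m", seq_len(n))
  out <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[i, j] <- if (i == j) length(unique(call_sets[[i]]))
                 else length(intersect(call_sets[[i]], call_sets[[j]]))
  }
  out
}

#' Full evaluation report for one or more methods
#'
#' Computes, per method: restricted AUC (standardized and raw), recall,
#' precision and number of calls at the `alpha` cutoff (where adjusted
#' p-values exist); plus the pairwise Spearman matrix and the overlap table
#' of significant calls when several methods are given.
#'
#' @param tables named list of score tables.
#' @param truth truth table.
#' @param fpr_max restricted-ROC right edge (default 0.2).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return a `das_eval` object.
#' @export
eval_report <- function(tables, truth, fpr_max = 0.2, alpha = 0.05) {
  if (inherits(tables, "das_scores")) tables <- list(method = tables)
  if (is.null(names(tables))) names(tables) <- paste0("m", seq_along(tables))
  per_method <- lapply(names(tables), function(nm) {
    tab <- tables[[nm]]
    sc <- ranking_scores(tab)
    curve <- roc_points(sc, truth)
    pauc <- restricted_auc(curve, fpr_max, standardized = TRUE)
    rp <- if (!is.null(tab$p_adj) && any(!is.na(tab$p_adj))) {
      recall_precision(tab, truth, alpha)
    } else list(recall = NA_real_, precision = NA_real_, n_called = NA_integer_)
    list(method = nm, pauc_std = as.numeric(pauc), pauc_raw = attr(pauc, "raw"),
         recall = rp$recall, precision = rp$precision, n_called = rp$n_called,
         roc = curve)
  })
  names(per_method) <- names(tables)
  spearman <- if (length(tables) >= 2L) spearman_matrix(tables) else NULL
  calls <- lapply(tables, function(tab) {
    if (is.null(tab$p_adj) || all(is.na(tab$p_adj))) return(character(0))
    tab$target_id[!is.na(tab$p_adj) & tab$p_adj <= alpha]
  })
  overlaps <- if (length(tables) >= 2L) overlap_table(calls) else NULL
  structure(list(per_method = per_method, spearman = spearman,
                 overlaps = overlaps, fpr_max = fpr_max, alpha = alpha),
            class = "das_eval")
}

#' @export
print.das_eval <- function(x, ...) {
  cat(sprintf("<das_eval> restricted ROC over FPR [0, %.2g], cutoff alpha = %.2g\n",
              x$fpr_max, x$alpha))
  df <- do.call(rbind, lapply(x$per_method, function(m) {
    data.frame(method = m$method, pauc_std = round(m$pauc_std, 4),
               pauc_raw = round(m$pauc_raw, 4),
               recall = round(m$recall, 4), precision = round(m$precision, 4),
               n_called = m$n_called, stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  print(df)
  invisible(x)
}

#' Serialize an evaluation report to JSON (plus optional ROC-point TSV)
#'
#' @param report a `das_eval` object.
#' @param path output JSON file.
#' @param roc_dir optional directory for per-method ROC-point TSVs.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, roc_dir = NULL) {
  out <- list(fpr_max = report$fpr_max, alpha = report$alpha,
              methods = lapply(report$per_method, function(m) {
                m[c("pauc_std", "pauc_raw", "recall", "precision", "n_called")]
              }))
  if (!is.null(report$spearman)) out$spearman <- report$spearman
  if (!is.null(report$overlaps)) out$overlaps <- report$overlaps
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", pretty = TRUE, na = "null")
  if (!is.null(roc_dir)) {
    dir.create(roc_dir, showWarnings = FALSE, recursive = TRUE)
    for (m in report$per_method) {
      utils::write.table(as.data.frame(m$roc),
                         file.path(roc_dir, paste0(m$method, "_roc.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}
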