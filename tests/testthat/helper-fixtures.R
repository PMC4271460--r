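## Fixture builders and independent brute-force oracles used across tests.

## -- gene fixtures ---------------------------------------------------------

se_gene <- function(id = "Gse") {
  gene_model(id, "chr1", "+", list(
    transcript(paste0(id, ".1"), rbind(c(1, 100), c(201, 300), c(401, 500))),
    transcript(paste0(id, ".2"), rbind(c(1, 100), c(401, 500)))
  ))
}

ir_gene <- function(id = "Gir") {
  gene_model(id, "chr1", "+", list(
    transcript(paste0(id, ".1"), rbind(c(1, 100), c(201, 300))),
    transcript(paste0(id, ".2"), rbind(c(1, 300)))
  ))
}

a5ss_gene <- function(id = "Ga5", strand = "+") {
  gene_model(id, "chr1", strand, list(
    transcript(paste0(id, ".1"), rbind(c(1, 100), c(201, 300))),
    transcript(paste0(id, ".2"), rbind(c(1, 130), c(201, 300)))
  ))
}

## -- brute-force oracles ---------------------------------------------------

## Full/partial AUC by exhaustive threshold enumeration: for every distinct
## score t (descending), classify score >= t as positive, collect
## (FPR, TPR), integrate by trapezoid after clipping at fpr_max.
oracle_pauc <- function(scores, labels, fpr_max = 1) {
  s <- scores
  s[is.na(s)] <- -Inf
  th <- sort(unique(s), decreasing = TRUE)
  fpr <- c(0, vapply(th, function(t) mean(s[!labels] >= t), numeric(1)))
  tpr <- c(0, vapply(th, function(t) mean(s[labels] >= t), numeric(1)))
  ## clip at fpr_max with linear interpolation
  if (max(fpr) < fpr_max) stop("oracle: curve does not reach fpr_max")
  keep <- fpr < fpr_max
  x <- fpr[keep]; y <- tpr[keep]
  i <- which(!keep)[1L]
  if (fpr[i] == fpr_max) {
    x <- c(x, fpr_max); y <- c(y, tpr[i])
  } else {
    f <- (fpr_max - fpr[i - 1L]) / (fpr[i] - fpr[i - 1L])
    x <- c(x, fpr_max); y <- c(y, tpr[i - 1L] + f * (tpr[i] - tpr[i - 1L]))
  }
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

## Benjamini-Hochberg step-up computed literally from the definition:
## adjusted p = min over j >= rank of (m * p_(j) / j), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

## Spearman rho as Pearson correlation of average ranks.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

## A small simulated data set shared by detector/evaluation tests.
tiny_simulation <- function(n_genes = 40, n_true = 10, palt = 0.8,
                            n_rep = c(3L, 3L), seed = 7L) {
  genes <- synth_annotation(n_genes, c(SE = 0.5, IR = 0.5), seed = seed)
  units <- flatten_genes(genes)
  scen <- scenario_config(palt_treatment = palt, n_true_as = n_true,
                          n_replicates = n_rep, seed = seed + 1L)
  params <- default_nb_params(names(genes), "Diff", seed = seed + 2L)
  truth <- choose_true_as_genes(genes, params, n_true, seed = seed + 3L,
                                palt_control = 0.2, palt_treatment = palt)
  props <- assign_all_proportions(genes, truth, scen)
  sim <- simulate_counts(genes, units, params, props, scen)
  list(genes = genes, units = units, scen = scen, params = params,
       truth = truth, props = props, sim = sim)
}
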