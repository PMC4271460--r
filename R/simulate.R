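## Two-condition negative-binomial count simulator with controlled
## differential isoform proportions. Step 1 draws a per-gene total count
## from NB(mu * depth, alpha); step 2 partitions it into transcripts by the
## condition's isoform proportions and into counting units by effective
## length. The degree of differential splicing is set by PALT, the relative
## abundance of the designated alternative isoform of each true AS gene.

#' Scenario configuration for a simulation
#'
#' @param palt_treatment PALT (fraction of the alternative isoform) in the
#'   treatment condition; the canonical low/medium/high levels are 0.4, 0.6
#'   and 0.8.
#' @param palt_control PALT in the control condition (default 0.2).
#' @param dispersion_pattern `"Diff"` (conditions have separately drawn or
#'   estimated dispersions) or `"Same"` (one shared dispersion).
#' @param depth_factor multiplicative sequencing-depth factor; 1.0 is the
#'   baseline (100x) depth, 0.6 and 0.25 the reduced-depth settings.
#' @param n_replicates integer vector of length 2: replicates per condition.
#' @param n_true_as number of genes simulated as truly differentially
#'   spliced.
#' @param read_length read length in nt (junction effective length).
#' @param seed integer seed governing all randomness downstream.
#' @return a `scenario_config` object.
#' @export
scenario_config <- function(palt_treatment,
                            palt_control = 0.2,
                            dispersion_pattern = c("Diff", "Same"),
                            depth_factor = 1.0,
                            n_replicates = c(3L, 3L),
                            n_true_as = 200L,
                            read_length = 100L,
                            seed = 1L) {
  dispersion_pattern <- match.arg(dispersion_pattern)
  if (!(palt_control > 0 && palt_control < 1)) {
    stop("palt_control must be in (0, 1)")
  }
  if (!(palt_treatment > 0 && palt_treatment < 1)) {
    stop("palt_treatment must be in (0, 1)")
  }
  if (depth_factor < 0) stop("depth_factor must be >= 0")
  n_replicates <- as.integer(n_replicates)
  if (length(n_replicates) != 2L || any(n_replicates < 1L)) {
    stop("n_replicates must be two integers >= 1")
  }
  structure(list(palt_control = palt_control,
                 palt_treatment = palt_treatment,
                 dispersion_pattern = dispersion_pattern,
                 depth_factor = depth_factor,
                 n_replicates = n_replicates,
                 n_true_as = as.integer(n_true_as),
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> PALT %.2g -> %.2g, %s dispersion, depth %.2g, %d vs %d reps, %d true AS, seed %d\n",
    x$palt_control, x$palt_treatment, x$dispersion_pattern, x$depth_factor,
    x$n_replicates[1L], x$n_replicates[2L], x$n_true_as, x$seed))
  invisible(x)
}

#' Method-of-moments NB parameter estimation per gene
#'
#' For each gene and estimation group, `mu` is the sample mean `m` and the
#' dispersion is `alpha = max(0, (s^2 - m) / m^2)` (so variance
#' `= mu + alpha * mu^2`; negative estimates clamp to the Poisson limit).
#' In `pooled` mode a single alpha per gene is estimated from the
#' per-condition mean-centered residuals pooled across conditions, with the
#' grand mean as the scale.
#'
#' @param counts gene x sample numeric matrix with row names = gene ids.
#' @param design character/factor of length `ncol(counts)` with two levels
#'   giving each sample's condition.
#' @param pooling `"per_condition"` or `"pooled"`.
#' @return data frame with `gene_id`, `mu1`, `mu2`, `alpha1`, `alpha2`.
#'   Genes with zero mean in a group get `mu = 0, alpha = 0` there and are
#'   flagged in the `expressed` column.
#' @export
estimate_nb <- function(counts, design, pooling = c("per_condition", "pooled")) {
  pooling <- match.arg(pooling)
  design <- as.factor(design)
  if (nlevels(design) != 2L) stop("'design' must have exactly two levels")
  if (length(design) != ncol(counts)) {
    stop("'design' length must match ncol(counts)")
  }
  if (min(table(design)) < 2L) stop("need >= 2 samples per condition")
  g1 <- design == levels(design)[1L]
  g2 <- design == levels(design)[2L]
  m1 <- rowMeans(counts[, g1, drop = FALSE])
  m2 <- rowMeans(counts[, g2, drop = FALSE])
  v1 <- apply(counts[, g1, drop = FALSE], 1L, stats::var)
  v2 <- apply(counts[, g2, drop = FALSE], 1L, stats::var)
  mom_alpha <- function(m, v) ifelse(m > 0, pmax(0, (v - m) / m^2), 0)
  if (pooling == "per_condition") {
    a1 <- mom_alpha(m1, v1)
    a2 <- mom_alpha(m2, v2)
  } else {
    cent <- counts
    cent[, g1] <- counts[, g1, drop = FALSE] - m1
    cent[, g2] <- counts[, g2, drop = FALSE] - m2
    s2 <- rowSums(cent^2) / (ncol(counts) - 2L)
    mbar <- rowMeans(counts)
    a1 <- a2 <- mom_alpha(mbar, s2)
  }
  data.frame(gene_id = rownames(counts),
             mu1 = unname(m1), mu2 = unname(m2),
             alpha1 = unname(a1), alpha2 = unname(a2),
             expressed = unname(m1 > 0 & m2 > 0),
             stringsAsFactors = FALSE)
}

#' Default synthetic NB parameters
#'
#' Baseline per-gene parameters for simulations without a real calibration
#' matrix: gene means are log-normal (median 200 reads at baseline depth,
#' sdlog 1.5) and dispersions uniform on `[0.05, 0.5]`. These are synthetic
#' defaults emulating the spread seen in bulk RNA-seq calibration data, not
#' values estimated from any particular data set. Under the `Same` pattern
#' both conditions share one dispersion; under `Diff` each condition draws
#' its own.
#'
#' @param gene_ids character vector of gene ids.
#' @param dispersion_pattern `"Diff"` or `"Same"`.
#' @param seed integer seed.
#' @param mu_meanlog,mu_sdlog log-normal parameters for the mean.
#' @param alpha_range range of the uniform dispersion draw.
#' @return data frame as from [estimate_nb()].
#' @export
default_nb_params <- function(gene_ids,
                              dispersion_pattern = c("Diff", "Same"),
                              seed = 1L,
                              mu_meanlog = log(200), mu_sdlog = 1.5,
                              alpha_range = c(0.05, 0.5)) {
  dispersion_pattern <- match.arg(dispersion_pattern)
  n <- length(gene_ids)
  with_seed(seed, {
    mu <- stats::rlnorm(n, mu_meanlog, mu_sdlog)
    a1 <- stats::runif(n, alpha_range[1L], alpha_range[2L])
    a2 <- if (dispersion_pattern == "Diff") {
      stats::runif(n, alpha_range[1L], alpha_range[2L])
    } else a1
    data.frame(gene_id = gene_ids, mu1 = mu, mu2 = mu,
               alpha1 = a1, alpha2 = a2, expressed = mu > 0,
               stringsAsFactors = FALSE)
  })
}

#' Choose the true AS genes and their alternative isoforms
#'
#' Samples `n` genes uniformly without replacement from the eligible set
#' (genes with at least two transcripts and positive mean in both
#' conditions), and for each picks one transcript uniformly at random as the
#' alternative isoform. Deterministic under `seed`.
#'
#' @param genes list of [gene_model()] objects.
#' @param params NB parameter table ([estimate_nb()]/[default_nb_params()]).
#' @param n number of true AS genes.
#' @param seed integer seed.
#' @param palt_control,palt_treatment PALT levels recorded in the table.
#' @return truth table: data frame with one row per gene (`gene_id`,
#'   `is_true_as`, `alt_transcript_id`, `palt_control`, `palt_treatment`).
#' @export
choose_true_as_genes <- function(genes, params, n, seed = 1L,
                                 palt_control = NA_real_,
                                 palt_treatment = NA_real_) {
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  n_tr <- vapply(genes, n_transcripts, integer(1))
  expressed <- params$mu1[match(ids, params$gene_id)] > 0 &
    params$mu2[match(ids, params$gene_id)] > 0
  expressed[is.na(expressed)] <- FALSE
  eligible <- which(n_tr >= 2L & expressed)
  if (n > length(eligible)) {
    stop("sampling error: requested ", n, " true AS genes but only ",
         length(eligible), " eligible")
  }
  with_seed(seed, {
    chosen <- sort(sample(eligible, n))
    alt <- rep(NA_character_, length(genes))
    for (i in chosen) {
      alt[i] <- sample(names(genes[[i]]$transcripts), 1L)
    }
    data.frame(gene_id = ids,
               is_true_as = seq_along(genes) %in% chosen,
               alt_transcript_id = alt,
               palt_control = ifelse(seq_along(genes) %in% chosen,
                                     palt_control, NA_real_),
               palt_treatment = ifelse(seq_along(genes) %in% chosen,
                                       palt_treatment, NA_real_),
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Assign per-condition isoform proportions for one gene
#'
#' True AS genes give the alternative transcript `palt_control` of the mass
#' in condition 1 and `palt_treatment` in condition 2, splitting the
#' remaining `1 - PALT` equally among the standard isoforms. Non-AS
#' multi-isoform genes draw one proportion vector from a symmetric
#' Dirichlet(1) and use it identically in both conditions (so condition
#' labels are exchangeable for them). Single-isoform genes get theta = 1.
#'
#' @param gene a [gene_model()].
#' @param truth_row one-row slice of the truth table for this gene.
#' @param scenario a [scenario_config()].
#' @param seed integer seed for the null Dirichlet draw.
#' @return list with named numeric vectors `theta1`, `theta2` (one entry per
#'   transcript, each summing to 1).
#' @export
assign_proportions <- function(gene, truth_row, scenario, seed = 1L) {
  tids <- names(gene$transcripts)
  k <- length(tids)
  if (isTRUE(truth_row$is_true_as)) {
    if (k < 2L) stop("true AS gene ", gene$gene_id, " has < 2 transcripts")
    alt <- truth_row$alt_transcript_id
    if (!alt %in% tids) {
      stop("alternative transcript ", alt, " not in gene ", gene$gene_id)
    }
    mk <- function(palt) {
      th <- stats::setNames(rep((1 - palt) / (k - 1L), k), tids)
      th[alt] <- palt
      th
    }
    list(theta1 = mk(scenario$palt_control),
         theta2 = mk(scenario$palt_treatment))
  } else if (k == 1L) {
    th <- stats::setNames(1, tids)
    list(theta1 = th, theta2 = th)
  } else {
    th <- with_seed(seed, {
      x <- stats::rgamma(k, shape = 1)
      stats::setNames(x / sum(x), tids)
    })
    list(theta1 = th, theta2 = th)
  }
}

#' Assign proportions for every gene in an annotation
#'
#' Convenience wrapper applying [assign_proportions()] per gene with a
#' gene-specific child seed derived from `scenario$seed`.
#'
#' @param genes list of [gene_model()] objects.
#' @param truth truth table from [choose_true_as_genes()].
#' @param scenario a [scenario_config()].
#' @return named list (by gene id) of `theta1`/`theta2` pairs.
#' @export
assign_all_proportions <- function(genes, truth, scenario) {
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  out <- vector("list", length(genes))
  names(out) <- ids
  for (i in seq_along(genes)) {
    row <- truth[truth$gene_id == ids[i], , drop = FALSE]
    out[[i]] <- assign_proportions(genes[[i]], row, scenario,
                                   seed = child_seed(scenario$seed, i))
  }
  out
}

#' Simulate a two-condition counting-unit count matrix
#'
#' Per sample and gene, the gene total is drawn from a negative binomial
#' with mean `mu * depth_factor` and the condition's dispersion; transcript
#' counts are multinomial in the condition's isoform proportions; each
#' transcript's count is allocated to its member counting units by a
#' multinomial with effective-length weights; unit counts are summed over
#' transcripts sharing a unit. Deterministic under `scenario$seed`.
#'
#' @param genes list of [gene_model()] objects.
#' @param units counting-unit table from [flatten_genes()].
#' @param params NB parameter table covering all genes.
#' @param proportions named list (by gene id) of [assign_proportions()]
#'   results.
#' @param scenario a [scenario_config()].
#' @return list with `counts` (integer unit x sample matrix), `design`
#'   (condition factor per column) and `gene_totals` (gene x sample matrix
#'   of the drawn NB totals, for conservation checks).
#' @export
simulate_counts <- function(genes, units, params, proportions, scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  names(genes) <- ids
  miss <- setdiff(ids, params$gene_id)
  if (length(miss)) stop("params missing gene(s): ", paste(miss, collapse = ", "))
  n1 <- scenario$n_replicates[1L]
  n2 <- scenario$n_replicates[2L]
  sample_ids <- c(sprintf("ctrl_%d", seq_len(n1)), sprintf("trt_%d", seq_len(n2)))
  design <- factor(rep(c("control", "treatment"), c(n1, n2)),
                   levels = c("control", "treatment"))
  counts <- matrix(0L, nrow = nrow(units), ncol = n1 + n2,
                   dimnames = list(units$unit_id, sample_ids))
  gene_totals <- matrix(0L, nrow = length(ids), ncol = n1 + n2,
                        dimnames = list(ids, sample_ids))

  with_seed(scenario$seed, {
    for (gid in ids) {
      g <- genes[[gid]]
      gu <- units[units$gene_id == gid, , drop = FALSE]
      if (nrow(gu) == 0L) next
      bad <- !vapply(gu$members, function(m)
        all(m %in% names(g$transcripts)), logical(1))
      if (any(bad)) {
        stop("consistency error: unit ", gu$unit_id[which(bad)[1L]],
             " references transcripts absent from gene ", gid)
      }
      pr <- params[match(gid, params$gene_id), ]
      th <- proportions[[gid]]
      if (is.null(th)) stop("proportions missing gene ", gid)
      ## per-transcript unit membership and weights
      tx_units <- lapply(names(g$transcripts), function(tid) {
        which(vapply(gu$members, function(m) tid %in% m, logical(1)))
      })
      names(tx_units) <- names(g$transcripts)
      for (s in seq_len(n1 + n2)) {
        cond2 <- design[s] == "treatment"
        mu <- (if (cond2) pr$mu2 else pr$mu1) * scenario$depth_factor
        alpha <- if (cond2) pr$alpha2 else pr$alpha1
        theta <- if (cond2) th$theta2 else th$theta1
        total <- if (mu <= 0) 0L else if (alpha > 0) {
          stats::rnbinom(1L, mu = mu, size = 1 / alpha)
        } else {
          stats::rpois(1L, mu)
        }
        gene_totals[gid, s] <- as.integer(total)
        if (total == 0L) next
        tx_counts <- drop(stats::rmultinom(1L, total,
                                           theta[names(g$transcripts)]))
        for (ti in seq_along(tx_counts)) {
          nt <- tx_counts[ti]
          if (nt == 0L) next
          uidx <- tx_units[[ti]]
          w <- gu$effective_length[uidx]
          alloc <- drop(stats::rmultinom(1L, nt, w / sum(w)))
          counts[gu$unit_id[uidx], s] <- counts[gu$unit_id[uidx], s] + alloc
        }
      }
    }
    list(counts = counts, design = design, gene_totals = gene_totals)
  })
}

#' Per-sample inclusion/exclusion counts for a splice event
#'
#' @param counts unit x sample count matrix.
#' @param event a `splice_event` with units attached ([event_units()]).
#' @return 2 x sample matrix with rows `inclusion`, `exclusion`.
#' @export
event_counts <- function(counts, event) {
  stopifnot(inherits(event, "splice_event"))
  inc <- event$inclusion_units
  exc <- event$exclusion_units
  if (is.null(inc) || is.null(exc) || !length(inc) || !length(exc)) {
    stop("event ", event$event_id,
         " has empty inclusion or exclusion unit set")
  }
  miss <- setdiff(c(inc, exc), rownames(counts))
  if (length(miss)) {
    stop("lookup error: unit(s) not in count matrix: ",
         paste(miss, collapse = ", "))
  }
  rbind(
    inclusion = colSums(counts[inc, , drop = FALSE]),
    exclusion = colSums(counts[exc, , drop = FALSE])
  )
}

#' Write a count matrix (or truth table) as seed-stamped TSV
#'
#' @param counts unit x sample matrix.
#' @param design condition factor per column.
#' @param path output file.
#' @param comment provenance string for the header comment.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, design, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste0("# condition\t", paste(as.character(design), collapse = "\t")),
             con)
  df <- data.frame(unit_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param path TSV file.
#' @return list with `counts` matrix and `design` factor.
#' @export
read_count_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cond_line <- grep("^# condition\t", lines, value = TRUE)
  if (!length(cond_line)) stop("no condition header in ", path)
  design <- factor(strsplit(sub("^# condition\t", "", cond_line[1L]),
                            "\t")[[1L]])
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(counts) <- df[[1L]]
  list(counts = counts, design = design)
}
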