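test_that("ranking scores prefer adjusted p-values and fall back to statistics", {
  st <- score_table("g1", statistic = 2, p_value = 0.01, p_adj = 0.05)
  expect_equal(unname(ranking_scores(st)), 0.95)

  st2 <- score_table(c("g1", "g2"), statistic = c(2, 5))
  expect_equal(unname(ranking_scores(st2)), c(2, 5))

  ## order-isomorphic to -p_adj
  p_adj <- c(0.3, 0.01, 0.9, 0.2)
  st3 <- score_table(paste0("g", 1:4), statistic = 1:4,
                     p_value = p_adj, p_adj = p_adj)
  expect_equal(order(ranking_scores(st3)), order(-p_adj))

  expect_error(ranking_scores(data.frame(target_id = "g1")), "schema")
})

test_that("ROC points follow the hand-enumerated threshold sweep", {
  scores <- c(a = 4, b = 3, c = 2, d = 1)
  truth <- data.frame(gene_id = c("a", "b", "c", "d"),
                      is_true_as = c(TRUE, FALSE, TRUE, FALSE))
  pts <- roc_points(scores, truth)
  expect_equal(pts$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(pts$tpr, c(0, 0.5, 0.5, 1, 1))

  ## perfect separation passes through (0, 1)
  scores2 <- c(a = 4, b = 3, c = 2, d = 1)
  truth2 <- data.frame(gene_id = c("a", "b", "c", "d"),
                       is_true_as = c(TRUE, TRUE, FALSE, FALSE))
  pts2 <- roc_points(scores2, truth2)
  expect_true(any(pts2$fpr == 0 & pts2$tpr == 1))

  ## all scores tied -> single diagonal step
  pts3 <- roc_points(c(a = 1, b = 1, c = 1, d = 1), truth2)
  expect_equal(pts3, structure(data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                               class = c("das_roc", "data.frame")))

  ## targets missing from scores rank last
  pts4 <- roc_points(c(a = 4, c = 2), truth2)
  expect_equal(pts4$tpr[2], 0.5)

  expect_error(roc_points(scores, data.frame(gene_id = "a",
                                             is_true_as = TRUE)),
               "undefined curve")
})

test_that("restricted AUC has the stated closed-form anchors", {
  perfect <- roc_points(c(a = 4, b = 3, c = 2, d = 1),
                        data.frame(gene_id = c("a", "b", "c", "d"),
                                   is_true_as = c(TRUE, TRUE, FALSE, FALSE)))
  v <- restricted_auc(perfect, fpr_max = 0.2)
  expect_equal(as.numeric(v), 1)
  expect_equal(attr(v, "raw"), 0.2)

  diagonal <- structure(data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                        class = c("das_roc", "data.frame"))
  expect_equal(as.numeric(restricted_auc(diagonal, 0.2)), 0.5)
  expect_equal(attr(restricted_auc(diagonal, 0.2), "raw"), 0.02)

  ## fpr_max = 1, unstandardized equals the full trapezoidal AUC
  set.seed(10)
  sc <- stats::setNames(runif(30), paste0("g", 1:30))
  lab <- rep(c(TRUE, FALSE), 15)
  tr <- data.frame(gene_id = names(sc), is_true_as = lab)
  full <- restricted_auc(roc_points(sc, tr), fpr_max = 1,
                         standardized = FALSE)
  expect_equal(as.numeric(full), oracle_pauc(sc, lab, 1), tolerance = 1e-12)
})

test_that("ROC and partial AUC agree with brute-force enumeration", {
  set.seed(123)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    lab <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    sc <- stats::setNames(sample(1:4, n, replace = TRUE) + 0, paste0("t", 1:n))
    tr <- data.frame(gene_id = names(sc), is_true_as = lab)
    for (fm in c(0.2, 0.5, 1)) {
      mine <- restricted_auc(roc_points(sc, tr), fm, standardized = FALSE)
      expect_equal(as.numeric(mine), oracle_pauc(sc, lab, fm),
                   tolerance = 1e-12)
    }
  }
})

test_that("full AUC cross-checks against an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  sc <- stats::setNames(rnorm(100), paste0("g", 1:100))
  lab <- runif(100) < 0.4
  tr <- data.frame(gene_id = names(sc), is_true_as = lab)
  mine <- as.numeric(restricted_auc(roc_points(sc, tr), 1,
                                    standardized = FALSE))
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(9)
  sc <- stats::setNames(runif(50), paste0("g", 1:50))
  lab <- runif(50) < 0.5
  tr <- data.frame(gene_id = names(sc), is_true_as = lab)
  a1 <- as.numeric(restricted_auc(roc_points(sc, tr), 0.2))
  a2 <- as.numeric(restricted_auc(roc_points(exp(3 * sc) + 2, tr), 0.2))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("random rankings give standardized pAUC near one half", {
  set.seed(321)
  vals <- replicate(200, {
    sc <- stats::setNames(runif(2000), paste0("g", 1:2000))
    lab <- rep(c(TRUE, FALSE), 1000)
    tr <- data.frame(gene_id = names(sc), is_true_as = lab)
    as.numeric(restricted_auc(roc_points(sc, tr), 0.2))
  })
  expect_lt(abs(mean(vals) - 0.5), 0.02)
})

test_that("recall and precision follow confusion-count arithmetic", {
  ## 20 positives, 10 calls of which 8 true -> recall 0.4, precision 0.8
  ids <- paste0("g", 1:100)
  truth <- data.frame(gene_id = ids, is_true_as = c(rep(TRUE, 20),
                                                    rep(FALSE, 80)))
  p_adj <- rep(1, 100)
  p_adj[c(1:8, 90:91)] <- 0.01   # 8 true + 2 false calls
  st <- score_table(ids, statistic = 1, p_value = p_adj, p_adj = p_adj)
  rp <- recall_precision(st, truth, alpha = 0.05)
  expect_equal(rp$recall, 0.4)
  expect_equal(rp$precision, 0.8)
  expect_equal(rp$n_called, 10L)

  ## nothing called: recall 0, precision flagged undefined
  st0 <- score_table(ids, statistic = 1, p_value = 1, p_adj = 1)
  rp0 <- recall_precision(st0, truth)
  expect_equal(rp0$recall, 0)
  expect_true(is.na(rp0$precision))

  expect_error(recall_precision(score_table(ids, statistic = 1), truth),
               "schema")
})

test_that("p-value adjustment matches the step-up oracle", {
  expect_equal(adjust_pvalues(c(0.01, 0.04), "Bonferroni"), c(0.02, 0.08))
  expect_equal(adjust_pvalues(0.3, "BH"), 0.3)
  expect_equal(adjust_pvalues(0.3, "Bonferroni"), 0.3)
  set.seed(14)
  for (i in 1:20) {
    p <- round(runif(sample(2:8, 1)), 3)
    expect_equal(adjust_pvalues(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), "input error")
})

test_that("Spearman matrix uses common targets and average ranks", {
  t1 <- score_table(paste0("g", 1:5), statistic = c(3, 1, 4, 1, 5))
  t2 <- score_table(paste0("g", 1:5), statistic = c(2, 7, 1, 8, 2))
  m <- spearman_matrix(list(a = t1, b = t2))
  expect_equal(diag(m), c(a = 1, b = 1))
  expect_equal(m["a", "b"],
               oracle_spearman(c(3, 1, 4, 1, 5), c(2, 7, 1, 8, 2)),
               tolerance = 1e-12)

  ## reversed ranking -> rho = -1
  t3 <- score_table(paste0("g", 1:5), statistic = 5:1)
  t4 <- score_table(paste0("g", 1:5), statistic = 1:5)
  expect_equal(spearman_matrix(list(t3, t4))[1, 2], -1)

  ## intersection restriction: extra targets in one table are ignored
  t5 <- score_table(paste0("g", 1:8), statistic = c(5:1, 9, 9, 9))
  expect_equal(spearman_matrix(list(t3, t5))[1, 2], 1)

  ## empty intersection names the offending pair
  t6 <- score_table(paste0("h", 1:3), statistic = 1:3)
  expect_error(spearman_matrix(list(x = t3, y = t6)), "x.*y|empty")
})

test_that("overlap tables count shared significant targets", {
  m <- overlap_table(list(a = c("x", "y", "z"), b = c("y", "z", "w")))
  expect_equal(unname(diag(m)), c(3L, 3L))
  expect_equal(m["a", "b"], 2L)
  m2 <- overlap_table(list(a = c("x"), b = c("y")))
  expect_equal(m2["a", "b"], 0L)
  m3 <- overlap_table(list(a = c("x", "y"), b = c("x", "y")))
  expect_true(all(m3 == 2L))
})

test_that("evaluation reports aggregate methods and serialize to JSON", {
  fx <- tiny_simulation(n_genes = 20, n_true = 6, seed = 91)
  st1 <- permutation_pvalues(fx$sim$counts, fx$units, fx$sim$design,
                             n_perm = 100, seed = 1)
  st2 <- jsd_proportion_test(fx$sim$counts, fx$units, fx$sim$design,
                             n_perm = 100, seed = 1)
  rep <- eval_report(list(ufs = st1, jsd = st2), fx$truth)
  expect_named(rep$per_method, c("ufs", "jsd"))
  expect_true(all(vapply(rep$per_method, function(m)
    m$pauc_std >= 0 && m$pauc_std <= 1, logical(1))))
  expect_equal(dim(rep$spearman), c(2L, 2L))

  f <- tempfile(fileext = ".json")
  write_eval_report(rep, f, roc_dir = tempfile())
  parsed <- jsonlite::read_json(f)
  expect_equal(names(parsed$methods), c("ufs", "jsd"))
  expect_equal(parsed$fpr_max, 0.2)
})
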