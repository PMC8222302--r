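# Exhaustive pairwise Mann-Whitney AUC oracle with half-weighted ties.
pair_auc <- function(scores, truth, positive = "EXT") {
  p <- scores[truth == positive]; n <- scores[truth != positive]
  wins <- 0
  for (a in p) for (b in n) wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(p) * length(n))
}

panel_fixture <- function(n_train = 20, n_test = 10, n_genes = 10, seed = 21) {
  set.seed(seed)
  genes <- c("PTGIS", "THBS4", "SRGN", "FERMT2", "NR4A3", "TIMP1", "SAMSN1",
             "HGF", "VCAN", "C3")[seq_len(n_genes)]
  train <- matrix(rnorm(n_genes * n_train, 100, 10), n_genes,
                  dimnames = list(genes, sprintf("CTRL-%d", seq_len(n_train))))
  test <- matrix(rnorm(n_genes * n_test, 100, 10), n_genes,
                 dimnames = list(genes, sprintf("T-%d", seq_len(n_test))))
  x <- toy_nanoset(cbind(train, test))
  tab <- data.frame(gene = genes, log2fc = rep(1, n_genes),
                    p_adj = seq_len(n_genes) / 1e5)
  list(x = x, tab = tab, train_ids = colnames(train), test_ids = colnames(test))
}

test_that("panel selection takes the top genes by rank with type-7 centile thresholds", {
  fx <- panel_fixture()
  panel <- score_panel(fx$tab, fx$x, training = fx$train_ids)
  expect_equal(panel$genes, fx$tab$gene)              # top 10 in table order
  # 20 training values 1..20: 95th centile interpolates to 19.05
  v <- ns_values(fx$x)
  v["PTGIS", fx$train_ids] <- 1:20
  x2 <- toy_nanoset(v)
  p2 <- score_panel(fx$tab, x2, training = fx$train_ids)
  expect_equal(unname(p2$threshold["PTGIS"]), 19.05)
  expect_error(score_panel(fx$tab[1:4, ], fx$x, training = fx$train_ids),
               "fewer than")
  expect_error(score_panel(fx$tab, fx$x, training = "CTRL-1"), "training")
})

test_that("scoring is a strict exceedance count with boundary values scoring zero", {
  fx <- panel_fixture()
  panel <- score_panel(fx$tab, fx$x, training = fx$train_ids)
  v <- ns_values(fx$x)
  hi <- v; hi[, "T-1"] <- apply(v[, fx$train_ids], 1, max) + 1
  lo <- hi; lo[, "T-2"] <- 0
  at <- lo; at[panel$genes, "T-3"] <- panel$threshold[panel$genes]
  res <- predict(panel, toy_nanoset(at))
  scores <- setNames(res$score, res$sample_id)
  expect_equal(unname(scores["T-1"]), 10)             # above every threshold
  expect_equal(unname(scores["T-2"]), 0)              # below every threshold
  expect_equal(unname(scores["T-3"]), 0)              # exactly at threshold: strict
  ind <- attr(res, "indicators")
  expect_equal(unname(colSums(ind)), unname(res$score))
  expect_true(all(res$score >= 0 & res$score <= 10))
  expect_error(predict(panel, ns_subset(fx$x, probes = setdiff(rownames(v), "HGF"))),
               "HGF")
})

test_that("exactly one of twenty training values exceeds its gene threshold", {
  fx <- panel_fixture(n_train = 20)
  panel <- score_panel(fx$tab, fx$x, training = fx$train_ids)
  ind <- attr(predict(panel, ns_subset(fx$x, samples = fx$train_ids)), "indicators")
  expect_equal(unname(rowSums(ind)), rep(1, 10))
})

test_that("scores are invariant under monotone transforms and monotone in the centile", {
  fx <- panel_fixture()
  panel <- score_panel(fx$tab, fx$x, training = fx$train_ids)
  s1 <- predict(panel, fx$x)$score
  # strictly monotone per-gene transform applied to training and test alike
  v <- ns_values(fx$x)
  xf <- toy_nanoset(exp(v / 50))
  pf <- score_panel(fx$tab, xf, training = fx$train_ids)
  expect_equal(predict(pf, xf)$score, s1)
  # raising the centile never increases any score
  p99 <- score_panel(fx$tab, fx$x, training = fx$train_ids, centile = 0.99)
  expect_true(all(predict(p99, fx$x)$score <= s1))
})

test_that("direction-aware mode scores the lower tail for down-regulated genes", {
  fx <- panel_fixture()
  tab <- fx$tab
  tab$log2fc[1] <- -2
  panel <- score_panel(tab, fx$x, training = fx$train_ids, direction = "auto")
  expect_equal(unname(panel$direction[1]), "lower")
  v <- ns_values(fx$x)
  v[1, "T-1"] <- 0                                    # deeply down
  res <- predict(panel, toy_nanoset(v))
  expect_equal(attr(res, "indicators")[1, "T-1"], 1L)
})

test_that("classification and confusion metrics follow the published conventions", {
  res <- data.frame(sample_id = c("a", "b", "c"), score = c(3, 2, 7))
  cl <- classify_scores(res, cutoff = 2.5)
  expect_equal(cl$predicted_ext, c(TRUE, FALSE, TRUE))   # 3 > 2.5, 2 <= 2.5
  expect_false(any(classify_scores(res, cutoff = 10)$predicted_ext))
  m <- suppressWarnings(confusion_metrics(c(rep(TRUE, 24), FALSE), rep("EXT", 25)))
  expect_equal(m$sensitivity, 0.96)
  m2 <- suppressWarnings(confusion_metrics(c(rep(FALSE, 18), TRUE, TRUE), rep("NON", 20)))
  expect_equal(m2$specificity, 0.90)
  perfect <- confusion_metrics(c(TRUE, TRUE, FALSE), c("EXT", "EXT", "NON"))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))
  expect_warning(und <- confusion_metrics(c(TRUE, FALSE), c("NON", "NON")),
                 "sensitivity undefined")
  expect_true(is.na(und$sensitivity))
})

test_that("ROC/AUC equals exhaustive Mann-Whitney pair counting", {
  # perfectly separated
  r1 <- roc_curve(c(1, 2, 8, 9), c("N", "N", "EXT", "EXT"))
  expect_equal(r1$auc, 1)
  # pure ties
  r2 <- roc_curve(rep(5, 6), rep(c("EXT", "N"), 3))
  expect_equal(r2$auc, 0.5)
  # integer-score fixture, n = 30
  set.seed(30)
  sc <- sample(0:10, 30, replace = TRUE)
  truth <- rep(c("EXT", "NON"), c(14, 16))
  sc[truth == "EXT"] <- sc[truth == "EXT"] + sample(0:3, 14, replace = TRUE)
  r3 <- roc_curve(sc, truth)
  expect_equal(r3$auc, pair_auc(sc, truth), tolerance = 1e-12)
  # monotone sensitivity/specificity along the cutoff grid
  expect_true(all(diff(r3$points$sensitivity) <= 1e-12))
  expect_true(all(diff(r3$points$specificity) >= -1e-12))
  # random continuous fixtures up to 200 samples
  for (i in 1:3) {
    n <- sample(20:200, 1)
    s <- round(rnorm(n), 1)
    t <- sample(c("EXT", "NON"), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(t)) < 2) next
    expect_equal(roc_curve(s, t)$auc, pair_auc(s, t), tolerance = 1e-12)
  }
  expect_error(roc_curve(1:3, rep("EXT", 3)), "both classes")
})

test_that("null calibration reports exceedance against the binomial reference", {
  fx <- panel_fixture(n_train = 500, n_test = 400, seed = 33)
  panel <- score_panel(fx$tab, fx$x, training = fx$train_ids)
  cal <- null_score_calibration(panel, ns_subset(fx$x, samples = fx$test_ids))
  expect_equal(cal$expected_mean, 0.5)
  expect_equal(mean(cal$exceedance), 0.05, tolerance = 0.4)   # right scale
  expect_equal(cal$mean_score, sum(as.numeric(names(cal$score_table)) *
                                     as.vector(cal$score_table)) / 400)
})
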