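test_that("log transform is the documented log2(x + offset)", {
  expect_equal(log_transform(matrix(0, 1, 1, dimnames = list("g", "s")))[1, 1], 0)
  expect_equal(log_transform(matrix(7, 1, 1, dimnames = list("g", "s")))[1, 1], 3)
  v <- matrix(c(3, 1, 8, 2), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(order(log_transform(v)[, 1]), order(v[, 1]))
  expect_error(log_transform(matrix(-1, 1, 1)), "nonnegative")
})

test_that("two-group fit matches textbook pooled statistics", {
  set.seed(5)
  mat <- matrix(rnorm(10 * 8, 7, 1), 10,
                dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:8)))
  grp <- rep(c("A", "B"), each = 4)
  fit <- fit_two_group(mat, grp)
  # brute-force oracle per gene
  for (g in 1:10) {
    a <- mat[g, 1:4]; b <- mat[g, 5:8]
    expect_equal(fit$log2fc[g], mean(b) - mean(a))
    s2_pool <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 6
    expect_equal(fit$s2[g], s2_pool)
  }
  expect_equal(attr(fit, "df_residual"), 6)
  expect_equal(attr(fit, "stdev_unscaled"), sqrt(1 / 4 + 1 / 4))
  # forced examples
  m2 <- rbind(g1 = c(5, 5, 8, 8))
  colnames(m2) <- sprintf("s%d", 1:4)
  f2 <- fit_two_group(rbind(m2, m2), rep(c("A", "B"), each = 2))
  expect_equal(f2$log2fc, c(3, 3))
  expect_error(fit_two_group(mat, rep("A", 8)), "two group")
  expect_error(fit_two_group(mat, c("A", rep("B", 7))), ">= 2 samples")
  # identical groups give log2fc 0 everywhere
  f0 <- fit_two_group(cbind(mat[, 1:4], mat[, 1:4]), rep(c("A", "B"), each = 4))
  expect_equal(f0$log2fc, rep(0, 10))
})

test_that("empirical-Bayes moderation matches limma and its limits", {
  set.seed(6)
  G <- 200
  # heterogeneous true variances so the prior df is finite
  sd_g <- sqrt(1 / rgamma(G, 4, 4))
  mat <- matrix(rnorm(G * 9, 8, 1), G,
                dimnames = list(sprintf("g%03d", 1:G), sprintf("s%d", 1:9))) * sd_g
  grp <- rep(c("A", "B"), c(4, 5))
  fit <- fit_two_group(mat, grp)
  mod <- ebayes_moderate(fit$s2, attr(fit, "df_residual"), fit$log2fc,
                         attr(fit, "stdev_unscaled"))
  # independent oracle: limma's implementation of the same closed form
  lf <- limma::eBayes(limma::lmFit(mat, stats::model.matrix(~factor(grp))))
  expect_equal(mod$fit$d0, unname(lf$df.prior), tolerance = 1e-6)
  expect_equal(mod$fit$s0_sq, unname(lf$s2.prior), tolerance = 1e-6)
  expect_equal(mod$table$t_mod, unname(lf$t[, 2]), tolerance = 1e-6)
  expect_equal(mod$table$p_raw, unname(lf$p.value[, 2]), tolerance = 1e-6)
  # d0 = 0: ordinary pooled t for every gene
  mod0 <- ebayes_moderate(fit$s2, 7, fit$log2fc, attr(fit, "stdev_unscaled"), d0 = 0)
  t_ord <- vapply(1:G, function(g)
    unname(stats::t.test(mat[g, grp == "B"], mat[g, grp == "A"],
                         var.equal = TRUE)$statistic), numeric(1))
  expect_equal(mod0$table$t_mod, t_ord, tolerance = 1e-10)
  # posterior variance always lies between the observed and prior variance
  st <- mod$fit$s_tilde_sq
  expect_true(all(st >= pmin(fit$s2, mod$fit$s0_sq) - 1e-12))
  expect_true(all(st <= pmax(fit$s2, mod$fit$s0_sq) + 1e-12))
  # moderation shrinks: moderated t less dispersed than ordinary t on nulls
  expect_lte(var(mod$table$t_mod), var(mod0$table$t_mod))
})

test_that("degenerate variance inputs follow the closed form", {
  # all variances identical: unbounded prior df, posterior variances all
  # equal to the common value (fixed point of the shrinkage)
  s2 <- rep(0.8, 50)
  mod <- ebayes_moderate(s2, 8, rnorm(50), 0.5)
  expect_true(is.infinite(mod$fit$d0))
  expect_equal(unique(mod$fit$s_tilde_sq), 0.8, tolerance = 1e-12)
  expect_equal(mod$table$df_total[1], Inf)
  # zero-variance genes are flagged and given the smallest positive s2
  s2z <- c(0, 0.5, 0.7, 0.9)
  modz <- ebayes_moderate(s2z, 6, c(1, 1, 1, 1), 0.5)
  expect_true(modz$fit$zero_variance[1])
  expect_true(is.finite(modz$table$t_mod[1]))
  # single gene: warning, ordinary t
  expect_warning(m1 <- ebayes_moderate(0.5, 6, 2, 0.5), "single gene")
  expect_equal(m1$table$t_mod, 2 / (sqrt(0.5) * 0.5))
})

test_that("Benjamini-Hochberg step-up matches hand computation and p.adjust", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (n in c(3, 17, 1000)) {
    p <- runif(n)^1.7
    q <- adjust_bh(p)
    expect_equal(q, p.adjust(p, "BH"))
    expect_true(all(q >= p) && all(q <= 1))
  }
})

test_that("DEG selection applies strict linear fold-change and p thresholds", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(1.59, 1.0, -1.7, 2.5),
                    p_adj = c(0.001, 0.02, 0.001, 0.02))
  sel <- select_degs(tab, fc_cut = 3, p_cut = 0.01)
  expect_equal(sel$up, "a")            # 2^1.59 = 3.01 > 3
  expect_equal(sel$down, "c")          # 2^-1.7 = 0.31 < 1/3
  sel2 <- select_degs(tab, fc_cut = 2, p_cut = 0.01)
  expect_false("b" %in% sel2$up)       # 2^1.0 = 2 is not > 2 (strict)
  expect_false("d" %in% sel2$up)       # p_adj 0.02 >= 0.01 excluded regardless of FC
})

test_that("DEG set comparison is exact set algebra", {
  cmp <- compare_deg_sets(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
  expect_setequal(cmp$shared, c("g2", "g3"))
  expect_equal(cmp$unique_to_a, "g1")
  expect_equal(cmp$unique_to_b, "g4")
  expect_equal(unname(cmp$counts), c(2, 1, 1))
  same <- compare_deg_sets(c("x", "y"), c("y", "x"))
  expect_equal(unname(same$counts), c(2, 0, 0))
  disj <- compare_deg_sets("x", "y")
  expect_equal(unname(disj$counts["shared"]), 0)
})

test_that("the assembled DEG table respects its ordering and sign invariants", {
  run <- full_run(1)
  tab <- run$de$table
  expect_true(all(tab$p_adj >= tab$p_raw - 1e-15))
  expect_true(all(tab$p_adj <= 1))
  expect_true(all(sign(tab$t_mod) == sign(tab$log2fc) | tab$log2fc == 0))
  expect_false(is.unsorted(tab$p_adj))
  expect_equal(tab$log2fc, tab$mean_g2 - tab$mean_g1)
})
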