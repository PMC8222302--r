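mk_norm_fixture <- function(endo, hk, pos, neg) {
  values <- rbind(endo, hk, pos, neg)
  rownames(values) <- c(sprintf("g%02d", seq_len(nrow(endo))),
                        sprintf("hk%02d", seq_len(nrow(hk))),
                        sprintf("pos%02d", seq_len(nrow(pos))),
                        sprintf("neg%02d", seq_len(nrow(neg))))
  colnames(values) <- sprintf("s%02d", seq_len(ncol(endo)))
  nanoset(values, rep(c("Endogenous", "Housekeeping", "Positive", "Negative"),
                      c(nrow(endo), nrow(hk), nrow(pos), nrow(neg))))
}

test_that("background correction subtracts the negative-control statistic, floored at zero", {
  x <- mk_norm_fixture(endo = rbind(c(100, 4), c(25, 50)),
                       hk = rbind(c(40, 40)),
                       pos = rbind(c(1000, 1000)),
                       neg = rbind(c(8, 10), c(10, 10), c(12, 10)))
  out <- background_correct(x, "mean")
  expect_equal(unname(out$background), c(10, 10))
  expect_equal(unname(ns_values(out$x)["g01", ]), c(90, 0))   # 4 - 10 floors at 0
  expect_equal(unname(ns_values(out$x)["g02", ]), c(15, 40))
  # control rows retained unchanged for audit
  expect_equal(ns_values(out$x)["pos01", ], ns_values(x)["pos01", ])
  expect_equal(ns_values(out$x)["neg01", ], ns_values(x)["neg01", ])
  # all-zero negatives leave the matrix unchanged
  x0 <- mk_norm_fixture(rbind(c(7, 7)), rbind(c(5, 5)), rbind(c(9, 9)),
                        rbind(c(0, 0)))
  expect_equal(ns_values(background_correct(x0, "mean")$x), ns_values(x0))
  expect_error(background_correct(x, "median"))
  x_noneg <- toy_nanoset(matrix(1:4, 2))
  expect_error(background_correct(x_noneg), "no Negative probes")
})

test_that("positive-control normalization equalizes positive geometric means", {
  base <- rbind(c(100, 100, 100), c(50, 50, 50))
  x <- mk_norm_fixture(endo = base, hk = rbind(c(30, 30, 30)),
                       pos = rbind(c(8, 8, 8), c(32, 32, 32)),
                       neg = rbind(c(0, 0, 0)))
  out <- positive_control_normalize(x)
  expect_equal(unname(out$factors), c(1, 1, 1))
  expect_equal(ns_values(out$x), ns_values(x))
  # doubling one sample's counts halves it back to the common scale
  v <- ns_values(x); v[, 2] <- v[, 2] * 2
  x2 <- nanoset(v, as.character(probe_class(x)))
  out2 <- positive_control_normalize(x2)
  expect_equal(unname(out2$factors[2] / out2$factors[1]), 0.5)
  expect_equal(ns_values(out2$x)["g01", 2], ns_values(out2$x)["g01", 1] * 1,
               tolerance = 1e-12, ignore_attr = TRUE)
  # random fixture: factors equalize the positive geometric means exactly
  set.seed(4)
  xr <- mk_norm_fixture(endo = matrix(rpois(40, 200), 8),
                        hk = matrix(rpois(10, 300), 2),
                        pos = matrix(rpois(20, 500), 4),
                        neg = matrix(rpois(5, 10), 1))
  outr <- positive_control_normalize(xr)
  gm <- exp(colMeans(log(ns_values(xr, "Positive")))) * outr$factors
  expect_equal(max(gm) - min(gm), 0, tolerance = 1e-9)
})

test_that("zero control counts error unless a pseudocount is requested", {
  x <- mk_norm_fixture(endo = rbind(c(10, 10)), hk = rbind(c(0, 5), c(5, 5)),
                       pos = rbind(c(0, 4)), neg = rbind(c(1, 1)))
  expect_error(positive_control_normalize(x), "pseudocount")
  expect_error(housekeeping_normalize(x), "pseudocount")
  expect_silent(positive_control_normalize(x, pseudocount = 0.5))
  expect_silent(housekeeping_normalize(x, pseudocount = 0.5))
})

test_that("housekeeping normalization recovers planted lane factors", {
  # single sample: its own mean is the reference, factor 1
  x1 <- mk_norm_fixture(endo = matrix(10, 1), hk = rbind(matrix(20, 1), matrix(30, 1)),
                        pos = matrix(40, 1), neg = matrix(1, 1))
  expect_equal(unname(housekeeping_normalize(x1)$factors), 1)
  # low-dispersion cohort: the combined applied correction tracks the
  # planted per-sample lane factor almost perfectly
  cfg <- small_config(seed = 11, nb_dispersion = 0.005)
  cohort <- generate_cohort(cfg)
  nm <- normalize_nanostring(cohort$counts)
  total <- nm$factors$positive_factor * nm$factors$housekeeping_factor
  expect_gt(cor(log(1 / total), log(cohort$truth$lane_factors)), 0.99)
  # housekeeping geometric means are exactly equalized by their factors
  hk_v <- ns_values(positive_control_normalize(background_correct(cohort$counts)$x)$x,
                    "Housekeeping")
  gm <- exp(colMeans(log(hk_v))) * nm$factors$housekeeping_factor
  expect_equal(max(gm) - min(gm), 0, tolerance = 1e-8 * mean(gm))
})

test_that("the full chain keeps dimensions, is deterministic, and flags wild factors", {
  cohort <- generate_cohort(small_config(seed = 2))
  a <- normalize_nanostring(cohort$counts)
  b <- normalize_nanostring(cohort$counts)
  expect_identical(ns_values(a$x), ns_values(b$x))
  expect_equal(dim(a$x), dim(cohort$counts))
  expect_true(all(a$factors$positive_factor > 0))
  expect_true(all(a$factors$housekeeping_factor > 0))
  # a sample with a grossly inflated lane is flagged, not dropped
  v <- ns_values(cohort$counts)
  v[, 1] <- as.integer(pmin(v[, 1] * 8, .Machine$integer.max / 2))
  inflated <- nanoset(v, as.character(probe_class(cohort$counts)))
  f <- normalize_nanostring(inflated)$factors
  expect_true(f$positive_flagged[1] || f$housekeeping_flagged[1])
  expect_equal(nrow(f), ncol(v))
})
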