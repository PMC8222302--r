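# Shared fixtures, built in code at test time.

# Small generator configuration for fast unit tests.
small_config <- function(seed = 1L, ...) {
  cohort_config(n_non = 5L, n_focal = 5L, n_ext = 8L,
                n_endogenous = 120L, n_housekeeping = 10L,
                n_de_strong = 8L, n_de_moderate = 8L, seed = seed, ...)
}

# Hand-built nanoset from a plain matrix (default all-endogenous plus
# optional controls appended by class).
toy_nanoset <- function(values, classes = rep("Endogenous", nrow(values))) {
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  nanoset(values, classes)
}

# Session-level cache so expensive simulation suites are shared between
# test files (notably the 20-seed full-cohort experiment).
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# One full default-conditions pipeline pass: generate, normalize,
# differential expression (EXT vs combined Focal/Non, and Focal vs Non),
# panel, scores, metrics. Used by the acceptance suite and by the
# clustering/pipeline property tests.
full_run <- function(seed) cached(paste0("run_", seed), {
  cfg <- cohort_config(seed = seed)
  cohort <- generate_cohort(cfg)
  nm <- normalize_nanostring(cohort$counts)
  grp <- factor(ifelse(cohort$annotation$cohort == "EXT", "EXT", "FOCAL_NON"),
                levels = c("FOCAL_NON", "EXT"))
  de <- moderated_de(nm$x, grp)
  de_fn <- moderated_de(
    ns_subset(nm$x, samples = cohort$annotation$sample_id[grp == "FOCAL_NON"]),
    droplevels(cohort$annotation$cohort[grp == "FOCAL_NON"]))
  panel <- score_panel(de, nm$x, cohort$annotation)
  scores <- classify_scores(predict(panel, nm$x, cohort$annotation))
  metrics <- confusion_metrics(scores$predicted_ext, scores$cohort)
  roc <- roc_curve(scores$score, scores$cohort)
  sel2 <- select_degs(de, fc_cut = 2, p_cut = 0.01)
  sel3 <- select_degs(de, fc_cut = 3, p_cut = 0.01)
  list(cohort = cohort, norm = nm, de = de, de_focal_non = de_fn,
       panel = panel, scores = scores, metrics = metrics, auc = roc$auc,
       n_fc2 = length(sel2$up) + length(sel2$down),
       n_fc3 = length(sel3$up) + length(sel3$down),
       deg2 = c(sel2$up, sel2$down))
})

acceptance_seeds <- 1:20

# Brute-force agglomeration oracle: recomputes every inter-cluster
# distance from scratch at each step (O(n^3)); used by the clustering and
# acceptance suites.
oracle_agglomerate <- function(mat, linkage = "average") {
  items <- lapply(seq_len(nrow(mat)), identity)
  cluster_dist <- function(a, b) {
    pd <- outer(a, b, Vectorize(function(i, j) sqrt(sum((mat[i, ] - mat[j, ])^2))))
    switch(linkage, average = mean(pd), complete = max(pd), single = min(pd))
  }
  heights <- numeric(0)
  while (length(items) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(items)) for (j in seq_along(items)) if (i < j) {
      d <- cluster_dist(items[[i]], items[[j]])
      if (d < best - 1e-12) { best <- d; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    items[[bi]] <- c(items[[bi]], items[[bj]])
    items[[bj]] <- NULL
  }
  heights
}
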