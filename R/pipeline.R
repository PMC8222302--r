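#' Pipeline configuration
#'
#' Bundles the options of every stage of the end-to-end analysis. Inputs
#' are either file paths (`counts_path` + `annotation_path`) or the
#' synthetic generator (`generator`, the default when no paths are
#' given).
#'
#' @param counts_path,annotation_path optional on-disk inputs (counts TSV
#'   per [read_counts_table()], annotation CSV per [read_annotation()]).
#' @param generator a [cohort_config()] used when no paths are given.
#' @param background_method,pseudocount normalization options.
#' @param fc_cuts linear fold-change thresholds reported by the DEG stage
#'   (default `c(2, 3)`).
#' @param p_cut adjusted-p threshold for DEG selection (default 0.01).
#' @param top_n number of top DEGs fed to clustering (default 70).
#' @param k clusters for the segregation check (default 2).
#' @param linkage clustering linkage (default `"average"`).
#' @param panel_size,centile,cutoff score-panel options (defaults 10,
#'   0.95, 2.5).
#' @param gmt_path optional GMT file enabling the enrichment stage.
#' @param nerve_cutoff nerve-fraction split point for the confounder
#'   stratification (default 0.10; "low" means fraction <= cutoff).
#' @param outdir output directory.
#' @param seed master seed; overrides `generator$seed` when inputs are
#'   generated.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_path = NULL, annotation_path = NULL,
                            generator = cohort_config(),
                            background_method = "mean", pseudocount = 0,
                            fc_cuts = c(2, 3), p_cut = 0.01,
                            top_n = 70L, k = 2L, linkage = "average",
                            panel_size = 10L, centile = 0.95, cutoff = 2.5,
                            gmt_path = NULL, nerve_cutoff = 0.10,
                            outdir = tempfile("pni_run_"), seed = NULL) {
  stopifnot(all(fc_cuts > 1), p_cut > 0, p_cut < 1, panel_size >= 1)
  if (!is.null(seed)) generator$seed <- seed
  structure(list(counts_path = counts_path, annotation_path = annotation_path,
                 generator = generator, background_method = background_method,
                 pseudocount = pseudocount, fc_cuts = fc_cuts, p_cut = p_cut,
                 top_n = top_n, k = k, linkage = linkage,
                 panel_size = panel_size, centile = centile, cutoff = cutoff,
                 gmt_path = gmt_path, nerve_cutoff = nerve_cutoff,
                 outdir = outdir, seed = generator$seed),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full PNI expression analysis end-to-end
#'
#' Stages: load or simulate the cohort; normalize; moderated differential
#' expression for the EXT vs NON, EXT vs FOCAL, FOCAL vs NON and EXT vs
#' combined Focal/Non contrasts; DEG selection and Venn comparison of the
#' two EXT contrasts; hierarchical clustering of samples over the top
#' DEGs with a cohort-segregation check; the percentile gene-score panel
#' with confusion metrics and ROC; optional gene-set enrichment; cohort
#' statistics; and the nerve-fraction confounder stratification within
#' EXT. Every stage's artifact is written under `config$outdir` and a run
#' manifest (config snapshot, package version, input checksums, per-stage
#' outputs and accumulated warnings) is written even when a stage fails —
#' downstream stages are then skipped but completed outputs are kept.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `results` (per-stage in-memory objects)
#'   and `manifest`.
#' @export
run_pni_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config[setdiff(names(config), "")],
                   package_version = as.character(utils::packageVersion("pniscore")),
                   created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   inputs = list(), stages = list(), warnings = character(0))
  results <- list()
  failed <- FALSE
  note <- function(w) manifest$warnings <<- c(manifest$warnings, w)
  run_stage <- function(name, expr) {
    if (failed) return(NULL)
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(withCallingHandlers(expr, warning = function(w) {
      note(paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      failed <<- TRUE
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      NULL
    })
    if (!failed)
      manifest$stages[[name]] <<- list(status = "ok",
                                       seconds = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }

  ## input
  results$input <- run_stage("input", {
    if (!is.null(config$counts_path)) {
      x <- read_counts_table(config$counts_path)
      ann <- sample_annotation(read_annotation(config$annotation_path), x)
      manifest$inputs <- as.list(tools::md5sum(c(config$counts_path,
                                                  config$annotation_path)))
      list(counts = x, annotation = ann, truth = NULL)
    } else {
      cohort <- generate_cohort(config$generator)
      cp <- write_counts_table(cohort$counts, file.path(config$outdir, "counts.tsv"))
      ap <- write_annotation(cohort$annotation, file.path(config$outdir, "annotation.csv"))
      manifest$inputs <- as.list(tools::md5sum(c(cp, ap)))
      cohort
    }
  })

  ## normalization
  results$normalized <- run_stage("normalize", {
    nm <- normalize_nanostring(results$input$counts, config$background_method,
                               config$pseudocount)
    write_tsv(nm$factors, file.path(config$outdir, "normalization_factors.tsv"))
    write_counts_table(nm$x, file.path(config$outdir, "normalized.tsv"))
    nm
  })

  ## differential expression, all contrasts
  results$de <- run_stage("deg", {
    ann <- results$input$annotation
    x <- results$normalized$x
    contrast <- function(g1, g2) {
      ids1 <- ann$sample_id[ann$cohort %in% g1]
      ids2 <- ann$sample_id[ann$cohort %in% g2]
      sub <- ns_subset(x, samples = c(ids1, ids2))
      grp <- factor(rep(c("A", "B"), c(length(ids1), length(ids2))),
                    levels = c("A", "B"))
      moderated_de(sub, grp)
    }
    de <- list(EXT_vs_NON = contrast("NON", "EXT"),
               EXT_vs_FOCAL = contrast("FOCAL", "EXT"),
               FOCAL_vs_NON = contrast("NON", "FOCAL"),
               EXT_vs_FOCAL_NON = contrast(c("NON", "FOCAL"), "EXT"))
    for (nm in names(de))
      write_tsv(de[[nm]]$table, file.path(config$outdir, paste0("deg_", nm, ".tsv")))
    de
  })

  ## DEG selection + Venn comparisons
  results$deg_sets <- run_stage("deg_sets", {
    sets <- list()
    for (fc in config$fc_cuts) {
      key <- paste0("fc", fc)
      sets[[key]] <- lapply(results$de, select_degs, fc_cut = fc, p_cut = config$p_cut)
    }
    fckey <- paste0("fc", max(config$fc_cuts))
    venn <- list(
      up = compare_deg_sets(sets[[fckey]]$EXT_vs_FOCAL$up,
                            sets[[fckey]]$EXT_vs_NON$up),
      down = compare_deg_sets(sets[[fckey]]$EXT_vs_FOCAL$down,
                              sets[[fckey]]$EXT_vs_NON$down))
    counts <- data.frame(
      contrast = rep(names(results$de), times = length(config$fc_cuts)),
      fc_cut = rep(config$fc_cuts, each = length(results$de)),
      n_up = unlist(lapply(sets, function(s) vapply(s, function(d) length(d$up), 1L))),
      n_down = unlist(lapply(sets, function(s) vapply(s, function(d) length(d$down), 1L))))
    write_tsv(counts, file.path(config$outdir, "deg_counts.tsv"))
    list(sets = sets, venn = venn, counts = counts)
  })

  ## clustering over top DEGs of the combined contrast
  results$clustering <- run_stage("cluster", {
    de <- results$de$EXT_vs_FOCAL_NON
    top <- utils::head(de$table$gene, config$top_n)
    x <- results$normalized$x
    mat <- log_transform(ns_values(x)[top, , drop = FALSE])
    hc <- hierarchical_cluster(scale_genes(mat), axis = "samples",
                               linkage = config$linkage)
    ann <- results$input$annotation
    seg <- evaluate_segregation(hc, stats::setNames(
      ifelse(ann$cohort == "EXT", "EXT", "FOCAL_NON"), ann$sample_id), k = config$k)
    write_tsv(data.frame(sample_id = names(seg$assignment),
                         cluster = unname(seg$assignment)),
              file.path(config$outdir, "clusters.tsv"))
    list(hclust = hc, segregation = seg, genes = top)
  })

  ## score panel, classification, ROC
  results$panel <- run_stage("panel", {
    ann <- results$input$annotation
    panel <- score_panel(results$de$EXT_vs_FOCAL_NON, results$normalized$x, ann,
                         size = config$panel_size, centile = config$centile)
    scores <- classify_scores(predict(panel, results$normalized$x, ann),
                              cutoff = config$cutoff)
    metrics <- confusion_metrics(scores$predicted_ext, scores$cohort)
    roc <- roc_curve(scores$score, scores$cohort)
    write_tsv(data.frame(gene = panel$genes, threshold = unname(panel$threshold)),
              file.path(config$outdir, "panel.tsv"))
    write_tsv(scores, file.path(config$outdir, "scores.tsv"))
    write_tsv(roc$points, file.path(config$outdir, "roc_points.tsv"))
    jsonlite::write_json(list(auc = roc$auc, sensitivity = metrics$sensitivity,
                              specificity = metrics$specificity,
                              counts = as.list(metrics$counts)),
                         file.path(config$outdir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    list(panel = panel, scores = scores, metrics = metrics, roc = roc)
  })

  ## enrichment (optional)
  if (!is.null(config$gmt_path))
    results$enrichment <- run_stage("enrich", {
      sets <- read_gmt(config$gmt_path)
      degs <- results$deg_sets$sets[[paste0("fc", min(config$fc_cuts))]]$EXT_vs_FOCAL_NON
      res <- hypergeometric_ora(c(degs$up, degs$down), sets,
                                probe_ids(results$normalized$x, "Endogenous"))
      write_tsv(utils::head(res[, setdiff(names(res), "genes")], 20L),
                file.path(config$outdir, "enrichment_top20.tsv"))
      res
    })

  ## cohort statistics
  results$cohort_stats <- run_stage("cohort_stats", {
    tab <- cohort_stat_table(results$input$annotation)
    write_tsv(tab, file.path(config$outdir, "cohort_stats.tsv"))
    tab
  })

  ## nerve-fraction confounder stratification within EXT
  results$confounder <- run_stage("confounder", {
    out <- stratify_confounder(results$normalized$x, results$input$annotation,
                               cutoff = config$nerve_cutoff)
    write_tsv(data.frame(n_low = out$n_low, n_high = out$n_high,
                         n_significant = out$n_significant,
                         p_threshold = out$p_threshold),
              file.path(config$outdir, "confounder.tsv"))
    out
  })

  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(list(results = results, manifest = manifest,
                 manifest_path = manifest_path))
}

#' Confounder stratification within one cohort
#'
#' Splits a cohort's samples at a covariate cutoff (values exactly at the
#' cutoff go to the low stratum) and runs the moderated DE analysis
#' between the low and high strata; the summary reports how many genes
#' fall below the adjusted-p threshold. With nerve fraction as the
#' covariate this checks whether nerve-tissue content, rather than
#' biology, drives the cohort's expression signal.
#'
#' @param x normalized [nanoset()].
#' @param annotation [sample_annotation()] covering the samples of `x`.
#' @param cohort cohort to stratify (default `"EXT"`).
#' @param covariate annotation column to split on
#'   (default `"nerve_fraction"`).
#' @param cutoff split point (default 0.10); low stratum is
#'   `value <= cutoff`.
#' @param p_cut adjusted-p threshold for the significance count
#'   (default 0.05).
#' @return list with the stratified `de` fit, `n_low`, `n_high`,
#'   `n_significant` and `p_threshold`.
#' @export
stratify_confounder <- function(x, annotation, cohort = "EXT",
                                covariate = "nerve_fraction", cutoff = 0.10,
                                p_cut = 0.05) {
  annotation <- sample_annotation(annotation)
  ann <- annotation[annotation$cohort == cohort, , drop = FALSE]
  if (!covariate %in% names(ann)) stop("covariate not in annotation: ", covariate)
  if (anyNA(ann[[covariate]])) stop("covariate missing for some ", cohort, " samples")
  stratum <- ifelse(ann[[covariate]] <= cutoff, "low", "high")
  if (min(table(factor(stratum, levels = c("low", "high")))) < 2L)
    stop("a stratum has < 2 samples; choose a different cutoff")
  sub <- ns_subset(x, samples = ann$sample_id)
  de <- moderated_de(sub, factor(stratum, levels = c("low", "high")))
  list(de = de, n_low = sum(stratum == "low"), n_high = sum(stratum == "high"),
       n_significant = sum(de$table$p_adj < p_cut), p_threshold = p_cut)
}
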