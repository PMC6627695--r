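## End-to-end workflows writing plain CSV/JSON run directories; the thin
## command-line front end in inst/cli/mirgstab.R dispatches to these.

.writeManifest <- function(outDir, seed, stages, files) {
  manifest <- list(
    package = "miRGstab",
    version = as.character(utils::packageVersion("miRGstab")),
    seed = seed,
    stages = stages,
    files = files,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.loadInput <- function(ct, sampleSheet) {
  if (is(ct, "CtExperiment")) return(ct)
  readCtTable(ct, sampleSheet = sampleSheet)
}

#' Simulate a synthetic dataset into a run directory
#'
#' Writes \code{ct.csv} (wide Ct table), \code{samples.csv} (sample
#' sheet), \code{truth.csv} (per-gene generating parameters) and a run
#' manifest.
#'
#' @param config a [synthConfig()] object.
#' @param seed integer random seed.
#' @param outDir output directory (created if needed).
#' @return The output directory path, invisibly.
#' @export
simulateWorkflow <- function(config = synthConfig(), seed, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateCtExperiment(config, seed = seed)
  writeCtTable(sim$experiment, file.path(outDir, "ct.csv"))
  writeSampleSheet(sim$experiment, file.path(outDir, "samples.csv"))
  truth <- data.frame(
    gene = names(sim$truth$baseline),
    baseline = sim$truth$baseline,
    sigma = sim$truth$sigma,
    role = sim$truth$role,
    sim$truth$shift,
    row.names = NULL, check.names = FALSE, stringsAsFactors = FALSE
  )
  colnames(truth)[-(1:4)] <- paste0("shift_", colnames(sim$truth$shift))
  utils::write.table(truth, file.path(outDir, "truth.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  .writeManifest(outDir, seed,
                 stages = list(simulate = list(
                   n_genes = nrow(sim$experiment),
                   n_samples = ncol(sim$experiment))),
                 files = c("ct.csv", "samples.csv", "truth.csv"))
  invisible(outDir)
}

#' Rank candidate reference genes across datasets
#'
#' Runs the complete ranking workflow: detection filter, then for every
#' dataset (each sample group plus all samples pooled) the four stability
#' estimators and the geometric-mean consensus.  Writes one stability CSV
#' per dataset/method pair, one consensus CSV per dataset, a top-k
#' overlap JSON per dataset, and a manifest.
#'
#' @param ct a \linkS4class{CtExperiment} or path to a wide Ct table.
#' @param sampleSheet sample-sheet path (when \code{ct} is a path).
#' @param outDir output directory.
#' @param efficiency scalar or per-gene amplification efficiency in (0,1].
#' @param topK top-k size for the per-method overlap summary.
#' @return Invisibly, a list of per-dataset results (\code{tables},
#'   \code{consensus}, \code{overlap}).
#' @export
rankWorkflow <- function(ct, sampleSheet = NULL, outDir,
                         efficiency = 1, topK = 15L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  x <- .loadInput(ct, sampleSheet)
  nInput <- nrow(x)
  x <- suppressMessages(filterCompleteDetection(x))
  datasets <- c(levels(droplevels(x$group)), "pooled")
  files <- character()
  results <- list()
  for (ds in datasets) {
    tabs <- runAllStability(x, dataset = ds, efficiency = efficiency)
    for (m in names(tabs)) {
      f <- sprintf("stability_%s_%s.csv", ds, m)
      utils::write.table(tabs[[m]], file.path(outDir, f), sep = ",",
                         row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
    cons <- combineRankings(tabs)
    f <- sprintf("consensus_%s.csv", ds)
    utils::write.table(cons, file.path(outDir, f), sep = ",",
                       row.names = FALSE, quote = FALSE)
    files <- c(files, f)
    ov <- topKOverlap(tabs, k = min(topK, nrow(cons)))
    f <- sprintf("top%d_overlap_%s.json", min(topK, nrow(cons)), ds)
    jsonlite::write_json(as.list(ov$regions), file.path(outDir, f),
                         auto_unbox = TRUE, pretty = TRUE)
    files <- c(files, f)
    results[[ds]] <- list(tables = tabs, consensus = cons, overlap = ov)
  }
  .writeManifest(outDir, seed = NA,
                 stages = list(filter = list(
                   n_input = nInput, n_retained = nrow(x),
                   n_removed = nInput - nrow(x))),
                 files = files)
  invisible(results)
}

#' Quantify the impact of reference-gene choice on a target gene
#'
#' For each candidate reference gene: normalizes the target
#' (per-sample delta-Ct), tests all group pairs (unpaired pooled-variance
#' t-test with optional Grubbs screening), correlates the reference with
#' the target, and clusters the reference-normalized panel.  Writes per-
#' reference delta-Ct tables, a combined comparison report with
#' significance tiers side by side, correlation and clustering summaries,
#' and a manifest.
#'
#' @param ct a \linkS4class{CtExperiment} or path to a wide Ct table.
#' @param sampleSheet sample-sheet path (when \code{ct} is a path).
#' @param target target gene id.
#' @param references character vector of reference gene ids.
#' @param outDir output directory.
#' @param screenOutliers remove one Grubbs outlier per group before each
#'   t-test (flags are reported either way).
#' @return Invisibly, a list with per-reference results and the combined
#'   comparison table.
#' @export
impactWorkflow <- function(ct, sampleSheet = NULL, target, references,
                           outDir, screenOutliers = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  x <- .loadInput(ct, sampleSheet)
  x <- suppressMessages(filterCompleteDetection(x))
  for (g in c(target, references)) {
    if (!(g %in% rownames(x))) {
      stop("gene absent after detection filter: ", g)
    }
  }
  grp <- levels(droplevels(x$group))
  pairs <- utils::combn(grp, 2L, simplify = FALSE)
  files <- character()
  comparisons <- list()
  perRef <- list()
  for (ref in references) {
    ne <- normalizeToReference(x, target, ref)
    f <- sprintf("delta_ct_%s_vs_%s.csv", target, ref)
    utils::write.table(ne, file.path(outDir, f), sep = ",",
                       row.names = FALSE, quote = FALSE)
    files <- c(files, f)
    cors <- geneCorrelation(x, ref, target)
    clus <- clusterHeatmap(x, reference = ref)
    merges <- data.frame(step = seq_len(nrow(clus$rowDendrogram$merge)),
                         left = clus$rowDendrogram$merge[, 1L],
                         right = clus$rowDendrogram$merge[, 2L],
                         height = clus$rowDendrogram$height)
    f <- sprintf("row_dendrogram_%s.csv", ref)
    utils::write.table(merges, file.path(outDir, f), sep = ",",
                       row.names = FALSE, quote = FALSE)
    files <- c(files, f)
    for (pr in pairs) {
      cmp <- compareGroups(ne, pr[1L], pr[2L],
                           screenOutliers = screenOutliers)
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        target = target, reference = ref,
        group_a = pr[1L], group_b = pr[2L],
        t = cmp$t, df = cmp$df, p_value = cmp$p_value, tier = cmp$tier,
        n_outliers_flagged = sum(lengths(cmp$outliers)),
        stringsAsFactors = FALSE
      )
    }
    perRef[[ref]] <- list(normalized = ne, correlation = cors,
                          clustering = clus)
  }
  report <- do.call(rbind, comparisons)
  utils::write.table(report, file.path(outDir, "comparisons.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  files <- c(files, "comparisons.csv")
  .writeManifest(outDir, seed = NA,
                 stages = list(impact = list(
                   target = target, references = references,
                   n_samples = ncol(x))),
                 files = files)
  invisible(list(references = perRef, comparisons = report))
}
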