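# tiny FNV-1a hash of a string, for config fingerprints in manifests
.fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

#' Run the full REO workflow
#'
#' Executes the complete chain: stable-pair mining in each purified
#' leukocyte dataset, orientation-consistent intersection across datasets,
#' consistency filtering against healthy whole blood, reversal detection,
#' and iterative differential-miRNA extraction. Stage counts, thresholds
#' and a config fingerprint are collected in a manifest; with `out_dir`
#' set, every stage artifact plus `manifest.json` is written there.
#'
#' @param purified list of purified-leukocyte [MirnaExpressionSet-class]
#'   objects (subtype labels in `colData$group`); one or more datasets
#' @param blood whole-blood [MirnaExpressionSet-class] with groups
#'   `healthy` / `disease`
#' @param min_frac healthy consistency threshold (default 0.9)
#' @param p_healthy_min,delta_min,fdr_max reversal selection thresholds
#'   (defaults 0.9, 0.15, 0.05)
#' @param stable_method passed to [stablePairsWithin()]
#' @param count_universe passed to [extractDeMirnas()]
#' @param healthy,disease blood group labels
#' @param out_dir optional output directory for stage artifacts
#' @return list: `reference_pairs` (filtered [StablePairSet-class]),
#'   `reversal_stats`, `reversals`, `de` (`DataFrame`s), and `manifest`
#' @export
runPipeline <- function(purified, blood, min_frac = 0.9,
                        p_healthy_min = 0.9, delta_min = 0.15,
                        fdr_max = 0.05,
                        stable_method = c("per_sample", "subtype_mean"),
                        count_universe = c("reference", "reversal_only"),
                        healthy = "healthy", disease = "disease",
                        out_dir = NULL) {
  stable_method <- match.arg(stable_method)
  count_universe <- match.arg(count_universe)
  if (is(purified, "MirnaExpressionSet")) purified <- list(purified)
  stopifnot(length(purified) >= 1L)

  t0 <- proc.time()[["elapsed"]]
  stage <- function(nm) message(sprintf("[%6.1fs] %s",
                                        proc.time()[["elapsed"]] - t0, nm))
  stage("mining stable pairs")
  sets <- lapply(seq_along(purified), function(i)
    stablePairsWithin(purified[[i]], method = stable_method,
                      provenance = sprintf("purified_dataset_%d", i)))
  stage("intersecting datasets")
  common <- Reduce(intersectStable, sets)

  stage("consistency filter vs healthy blood")
  groups <- sampleGroups(blood)
  if (is.null(groups)) stop("blood needs group labels in colData")
  healthy_blood <- blood[, groups == healthy]
  reference <- filterByConsistency(common, healthy_blood,
                                   min_frac = min_frac)
  stage("reversal statistics")
  stats <- reversalStats(reference, blood, groups = groups,
                         healthy = healthy, disease = disease)
  reversals <- selectReversals(stats, p_healthy_min = p_healthy_min,
                               delta_min = delta_min, fdr_max = fdr_max)
  stage("extracting differential miRNAs")
  de <- extractDeMirnas(reference, reversals, blood, groups = groups,
                        healthy = healthy, disease = disease,
                        count_universe = count_universe)

  config <- list(min_frac = min_frac, p_healthy_min = p_healthy_min,
                 delta_min = delta_min, fdr_max = fdr_max,
                 stable_method = stable_method,
                 count_universe = count_universe)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE)
  manifest <- list(
    tool = "miREO",
    version = as.character(utils::packageVersion("miREO")),
    config = config,
    config_hash = .fnv1a(as.character(cfg_json)),
    counts = list(
      stable_pairs_per_dataset = vapply(sets, length, integer(1)),
      pairs_after_intersection = length(common),
      pairs_after_consistency_filter = length(reference),
      reversal_pairs = nrow(reversals),
      de_mirnas = nrow(de)),
    n_samples = list(
      purified = vapply(purified, ncol, integer(1)),
      healthy = sum(groups == healthy),
      disease = sum(groups == disease)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writePairs(reference, file.path(out_dir, "reference_pairs.tsv"))
    utils::write.table(as.data.frame(stats),
                       file.path(out_dir, "reversal_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(reversals),
                       file.path(out_dir, "reversal_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(de),
                       file.path(out_dir, "de_mirnas.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage("done")
  list(reference_pairs = reference, reversal_stats = stats,
       reversals = reversals, de = de, manifest = manifest)
}
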