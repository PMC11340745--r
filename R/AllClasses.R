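#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Container for a miRNA expression matrix
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one
#' features x samples assay named \code{"exprs"}, with the measurement scale
#' (\code{"linear"} or \code{"log2"}) recorded in \code{metadata()$scale}.
#' Relative-expression-ordering (REO) computations are invariant to any
#' strictly monotone transform, so the scale only matters where log2
#' fold changes are computed; those helpers convert as needed.
#'
#' Validity requires unique, non-empty feature and sample identifiers, a
#' numeric assay with no missing values, and a declared scale.
#'
#' @seealso [MirnaExpressionSet()] for construction, [readExpression()]
#' @export
setClass("MirnaExpressionSet", contains = "SummarizedExperiment")

setValidity("MirnaExpressionSet", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  x <- SummarizedExperiment::assay(object, "exprs")
  fid <- rownames(object)
  sid <- colnames(object)
  if (is.null(fid) || length(fid) == 0L || anyNA(fid) || any(fid == ""))
    msg <- c(msg, "feature ids must be present and non-empty")
  else if (anyDuplicated(fid))
    msg <- c(msg, paste0("duplicated feature ids: ",
                         paste(unique(fid[duplicated(fid)]), collapse = ", ")))
  if (is.null(sid) || length(sid) == 0L || anyNA(sid) || any(sid == ""))
    msg <- c(msg, "sample ids must be present and non-empty")
  else if (anyDuplicated(sid))
    msg <- c(msg, paste0("duplicated sample ids: ",
                         paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  if (!is.numeric(x))
    msg <- c(msg, "expression values must be numeric")
  else if (anyNA(x))
    msg <- c(msg, "expression values must not contain missing values")
  sc <- S4Vectors::metadata(object)$scale
  if (is.null(sc) || !sc %in% c("linear", "log2"))
    msg <- c(msg, "metadata()$scale must be 'linear' or 'log2'")
  if (length(msg)) msg else TRUE
})

#' Set of reference-oriented stable miRNA pairs
#'
#' Holds oriented miRNA pairs (upper, lower) whose within-sample ordering
#' expression(upper) > expression(lower) held strictly in every purified
#' leukocyte sample, i.e. the reference against which whole-blood reversals
#' are judged. After consistency filtering against healthy whole blood each
#' pair additionally carries \code{p_healthy}, the fraction of healthy
#' samples maintaining the reference orientation.
#'
#' Validity: no self pairs, each unordered pair present at most once (the
#' orientation is unique), and \code{p_healthy} (when present) in [0, 1].
#'
#' @slot pairs a \code{DataFrame} with character columns \code{upper},
#'   \code{lower} and optional numeric \code{p_healthy}
#' @slot provenance character vector recording the datasets and criteria
#'   that produced the set
#' @seealso [stablePairsWithin()], [intersectStable()], [filterByConsistency()]
#' @export
setClass("StablePairSet",
         representation(pairs = "DataFrame", provenance = "character"))

setValidity("StablePairSet", function(object) {
  p <- object@pairs
  msg <- character()
  if (!all(c("upper", "lower") %in% colnames(p)))
    return("pairs must have columns 'upper' and 'lower'")
  if (nrow(p)) {
    if (!is.character(p$upper) || !is.character(p$lower))
      msg <- c(msg, "'upper' and 'lower' must be character")
    if (any(p$upper == p$lower))
      msg <- c(msg, "self pairs (upper == lower) are not allowed")
    key <- .pairKey(p$upper, p$lower)
    if (anyDuplicated(key))
      msg <- c(msg, "an unordered pair may appear at most once")
    if ("p_healthy" %in% colnames(p)) {
      ph <- p$p_healthy
      if (anyNA(ph) || any(ph < 0) || any(ph > 1))
        msg <- c(msg, "p_healthy must lie in [0, 1]")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic whole-blood experiment
#'
#' Records everything the simulator knows and the analysis must rediscover:
#' per-subtype log2 base profiles, the marker features assigned to each
#' subtype, per-sample mixing proportions (filled in by
#' [generateWholeBlood()]), the intracellular spike set with log2 shifts,
#' and the seed.
#'
#' @slot profiles numeric matrix, features x subtypes, of log2 mean profiles
#' @slot markers named list of marker feature ids per subtype
#' @slot proportions numeric matrix, samples x subtypes, rows summing to 1
#'   (zero rows before blood generation)
#' @slot spikes \code{DataFrame} with columns \code{feature}, \code{subtype},
#'   \code{log2_shift}; one row per (feature, subtype) spike
#' @slot seed integer seed the profiles were drawn under
#' @seealso [generateLeukocyteProfiles()], [generateWholeBlood()],
#'   [evaluateRecovery()]
#' @export
setClass("SyntheticTruth",
         representation(profiles = "matrix", markers = "list",
                        proportions = "matrix", spikes = "DataFrame",
                        seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (nrow(object@proportions)) {
    s <- rowSums(object@proportions)
    if (any(object@proportions < 0) || any(abs(s - 1) > 1e-8))
      msg <- c(msg, "proportions must be non-negative and sum to 1 per sample")
  }
  if (nrow(object@spikes) &&
      !all(c("feature", "subtype", "log2_shift") %in% colnames(object@spikes)))
    msg <- c(msg, "spikes needs columns feature, subtype, log2_shift")
  if (length(msg)) msg else TRUE
})
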