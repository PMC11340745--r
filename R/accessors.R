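# canonical key for an unordered pair, independent of orientation
.pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Construct a MirnaExpressionSet
#'
#' @param values numeric matrix, features in rows (rownames = miRNA ids),
#'   samples in columns (colnames = sample ids)
#' @param scale measurement scale of `values`, `"log2"` or `"linear"`
#' @param group optional character vector of per-sample group labels
#'   (leukocyte subtype names, or `"healthy"` / `"disease"`)
#' @param datasetId optional dataset label, recycled across samples
#' @return a [MirnaExpressionSet-class]
#' @examples
#' m <- matrix(rnorm(6, 7), 3, 2,
#'             dimnames = list(c("miR-a", "miR-b", "miR-c"), c("s1", "s2")))
#' MirnaExpressionSet(m, scale = "log2")
#' @export
MirnaExpressionSet <- function(values, scale = c("log2", "linear"),
                               group = NULL, datasetId = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  cd <- S4Vectors::DataFrame(row.names = colnames(values))
  if (!is.null(group)) {
    stopifnot(length(group) == ncol(values))
    cd$group <- as.character(group)
  }
  if (!is.null(datasetId))
    cd$dataset_id <- rep_len(as.character(datasetId), ncol(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = cd,
    metadata = list(scale = scale))
  obj <- new("MirnaExpressionSet", se)
  validObject(obj)
  obj
}

#' @describeIn MirnaExpressionSet the expression matrix (features x samples)
#' @param x a `MirnaExpressionSet`
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn MirnaExpressionSet the declared scale, `"log2"` or `"linear"`
#' @export
exprScale <- function(x) S4Vectors::metadata(x)$scale

#' @describeIn MirnaExpressionSet per-sample group labels (NULL if unset)
#' @export
sampleGroups <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("group" %in% colnames(cd)) as.character(cd$group) else NULL
}

# expression matrix on log2 scale regardless of stored scale
.log2Values <- function(x) {
  v <- exprValues(x)
  if (exprScale(x) == "log2") return(v)
  if (any(v <= 0))
    stop("cannot log2-transform: matrix declared linear contains values <= 0")
  log2(v)
}

#' Construct a StablePairSet
#'
#' @param upper,lower character vectors of miRNA ids; the reference
#'   orientation is expression(upper) > expression(lower)
#' @param p_healthy optional numeric vector in [0,1], the fraction of
#'   healthy whole-blood samples maintaining the orientation
#' @param provenance character vector describing the origin of the set
#' @return a [StablePairSet-class], sorted lexicographically by (upper, lower)
#' @export
StablePairSet <- function(upper = character(), lower = character(),
                          p_healthy = NULL, provenance = character()) {
  df <- S4Vectors::DataFrame(upper = as.character(upper),
                             lower = as.character(lower))
  if (!is.null(p_healthy)) df$p_healthy <- as.numeric(p_healthy)
  if (nrow(df)) df <- df[order(df$upper, df$lower), , drop = FALSE]
  rownames(df) <- NULL
  obj <- new("StablePairSet", pairs = df, provenance = as.character(provenance))
  validObject(obj)
  obj
}

#' @describeIn StablePairSet the pairs as a `DataFrame`
#' @param x a `StablePairSet`
#' @export
stablePairs <- function(x) x@pairs

#' @describeIn StablePairSet provenance strings
#' @export
provenance <- function(x) x@provenance

#' @export
setMethod("length", "StablePairSet", function(x) nrow(x@pairs))

setMethod("show", "StablePairSet", function(object) {
  cat("StablePairSet with", nrow(object@pairs), "oriented pairs\n")
  if ("p_healthy" %in% colnames(object@pairs) && nrow(object@pairs))
    cat("  p_healthy range:",
        sprintf("[%.3f, %.3f]", min(object@pairs$p_healthy),
                max(object@pairs$p_healthy)), "\n")
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = " | "), "\n")
  if (nrow(object@pairs)) {
    n <- min(5L, nrow(object@pairs))
    show(utils::head(object@pairs, n))
    if (nrow(object@pairs) > n) cat("  ...\n")
  }
})

#' @export
setMethod("as.data.frame", "StablePairSet",
          function(x, ...) as.data.frame(x@pairs))

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@profiles), "features x",
      ncol(object@profiles), "subtypes\n")
  cat("  markers per subtype:",
      paste(vapply(object@markers, length, 1L), collapse = ", "), "\n")
  cat("  blood samples with proportions:", nrow(object@proportions), "\n")
  cat("  spikes:", nrow(object@spikes), "(feature, subtype) shifts\n")
})

#' @describeIn SyntheticTruth log2 base profiles, features x subtypes
#' @param x a `SyntheticTruth`
#' @export
truthProfiles <- function(x) x@profiles

#' @describeIn SyntheticTruth named list of marker features per subtype
#' @export
truthMarkers <- function(x) x@markers

#' @describeIn SyntheticTruth per-sample mixing proportions
#' @export
truthProportions <- function(x) x@proportions

#' @describeIn SyntheticTruth spike table (feature, subtype, log2_shift)
#' @export
truthSpikes <- function(x) x@spikes
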