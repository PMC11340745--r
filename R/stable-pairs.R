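# all unordered row-index pairs (i < j), as a 2-column integer matrix
.allPairIdx <- function(n) {
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i, j)
}

# per-pair counts of samples with x[i,] > x[j,] and x[i,] < x[j,],
# chunked so the intermediate comparison matrices stay modest
.pairCounts <- function(x, idx, chunk = 200000L) {
  n <- nrow(idx)
  gt <- integer(n); lt <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    a <- x[idx[s:e, 1L], , drop = FALSE]
    b <- x[idx[s:e, 2L], , drop = FALSE]
    gt[s:e] <- as.integer(rowSums(a > b))
    lt[s:e] <- as.integer(rowSums(a < b))
  }
  list(gt = gt, lt = lt)
}

#' Mine miRNA pairs with stable within-sample orderings
#'
#' A pair (i, j) is stable when one member has strictly higher expression
#' than the other in every sample of every leukocyte subtype
#' (`method = "per_sample"`, the default and the stringent reading standard
#' in the REO literature). Ties break stability. The alternative
#' `method = "subtype_mean"` requires the strict ordering only across the
#' per-subtype mean profiles. Because only within-sample ranks are used,
#' the result is invariant to any strictly monotone per-sample transform
#' of the expression values.
#'
#' @param expr a [MirnaExpressionSet-class]; all samples are used
#' @param groups optional per-sample subtype labels (defaults to the
#'   `group` column of `colData(expr)`); required for `"subtype_mean"`
#' @param method `"per_sample"` or `"subtype_mean"`
#' @param provenance provenance string recorded in the result
#' @return a [StablePairSet-class], oriented so expression(upper) >
#'   expression(lower), sorted lexicographically
#' @examples
#' m <- matrix(c(3, 2, 1, 5, 4, 3), 3, 2,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' stablePairsWithin(MirnaExpressionSet(m))
#' @export
stablePairsWithin <- function(expr, groups = sampleGroups(expr),
                              method = c("per_sample", "subtype_mean"),
                              provenance = "stablePairsWithin") {
  method <- match.arg(method)
  x <- exprValues(expr)
  if (nrow(x) < 2L) stop("need at least 2 features")
  if (ncol(x) < 1L) stop("empty expression matrix")
  if (method == "subtype_mean") {
    if (is.null(groups)) stop("subtype_mean method requires group labels")
    gs <- unique(groups)
    x <- vapply(gs, function(g)
      rowMeans(x[, groups == g, drop = FALSE]), numeric(nrow(x)))
  }
  idx <- .allPairIdx(nrow(x))
  cnt <- .pairCounts(x, idx)
  ns <- ncol(x)
  up <- cnt$gt == ns   # row i above row j everywhere
  dn <- cnt$lt == ns
  ids <- rownames(x)
  upper <- c(ids[idx[up, 1L]], ids[idx[dn, 2L]])
  lower <- c(ids[idx[up, 2L]], ids[idx[dn, 1L]])
  StablePairSet(upper, lower, provenance = provenance)
}

#' Intersect stable pair sets with consistent orientation
#'
#' Retains pairs present in both sets with the same orientation; a pair
#' oriented (A, B) in one set and (B, A) in the other is discarded.
#' Pairs commonly stable across independent purified-leukocyte datasets
#' form the reference stable pair set.
#'
#' @param a,b [StablePairSet-class] objects
#' @return a [StablePairSet-class]; provenance concatenated
#' @export
intersectStable <- function(a, b) {
  ka <- paste(stablePairs(a)$upper, stablePairs(a)$lower, sep = "\r")
  kb <- paste(stablePairs(b)$upper, stablePairs(b)$lower, sep = "\r")
  keep <- ka %in% kb
  StablePairSet(stablePairs(a)$upper[keep], stablePairs(a)$lower[keep],
                provenance = c(provenance(a), provenance(b)))
}

#' Filter reference pairs by consistency in healthy whole blood
#'
#' For each pair, computes `p_healthy`, the fraction of healthy whole-blood
#' samples in which the reference orientation expression(upper) >
#' expression(lower) holds strictly (ties count against), and retains
#' pairs with `p_healthy >= min_frac` (boundary inclusive).
#'
#' @param pairs a [StablePairSet-class]
#' @param healthy_expr [MirnaExpressionSet-class] of healthy whole-blood
#'   samples
#' @param min_frac minimum fraction of healthy samples maintaining the
#'   orientation; default 0.9
#' @return a [StablePairSet-class] annotated with `p_healthy`
#' @export
filterByConsistency <- function(pairs, healthy_expr, min_frac = 0.9) {
  df <- stablePairs(pairs)
  x <- exprValues(healthy_expr)
  feats <- unique(c(df$upper, df$lower))
  absent <- setdiff(feats, rownames(x))
  if (length(absent))
    stop("pair member(s) absent from healthy matrix: ",
         paste(absent, collapse = ", "))
  if (!nrow(df))
    return(StablePairSet(provenance = c(provenance(pairs),
                                        "filterByConsistency")))
  idx <- cbind(match(df$upper, rownames(x)), match(df$lower, rownames(x)))
  cnt <- .pairCounts(x, idx)
  ph <- cnt$gt / ncol(x)
  keep <- ph >= min_frac
  StablePairSet(df$upper[keep], df$lower[keep], p_healthy = ph[keep],
                provenance = c(provenance(pairs),
                               sprintf("filterByConsistency(min_frac=%g)",
                                       min_frac)))
}
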