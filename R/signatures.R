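# Row-wise Welch two-sample t-test on a log2 matrix.
# Constant features (zero variance in both groups, equal means) get p = 1;
# zero pooled SE with unequal means gets p = 0.
.rowWelch <- function(x, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  stopifnot(na >= 2L, nb >= 2L)
  xa <- x[, idx_a, drop = FALSE]; xb <- x[, idx_b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1L)
  vb <- rowSums((xb - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  diff <- ma - mb
  tt <- diff / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  zero <- se2 == 0
  p[zero] <- ifelse(diff[zero] == 0, 1, 0)
  list(log2fc = diff, t = tt, df = df, p_value = p)
}

#' Naive two-group differential expression
#'
#' Per-feature Welch's t-test on log2 values (converting from linear if
#' needed) with Benjamini-Hochberg FDR; features with
#' `log2fc >= lfc_min` in magnitude and `fdr <= fdr_max` are flagged. This
#' is the standard whole-blood contrast that is blind to cell-composition
#' shifts — the baseline the REO extraction is compared against.
#'
#' @param expr a [MirnaExpressionSet-class]
#' @param groups per-sample labels (defaults to `colData(expr)$group`)
#' @param group_a,group_b labels to contrast; `log2fc` is A minus B
#' @param lfc_min minimum |log2 fold change| (default 0.26, a 1.2-fold
#'   change)
#' @param fdr_max maximum BH-adjusted p (default 0.05)
#' @return `DataFrame`: `feature`, `log2fc`, `p_value`, `fdr`, `flagged`
#' @export
twoGroupDe <- function(expr, groups = sampleGroups(expr),
                       group_a = "disease", group_b = "healthy",
                       lfc_min = 0.26, fdr_max = 0.05) {
  if (is.null(groups)) stop("group labels are required")
  x <- .log2Values(expr)
  ia <- .groupIdx(groups, group_a); ib <- .groupIdx(groups, group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each group needs >= 2 samples")
  w <- .rowWelch(x, ia, ib)
  fdr <- stats::p.adjust(w$p_value, method = "BH")
  S4Vectors::DataFrame(feature = rownames(x), log2fc = w$log2fc,
                       p_value = w$p_value, fdr = fdr,
                       flagged = abs(w$log2fc) >= lfc_min & fdr <= fdr_max)
}

#' Derive leukocyte-subtype-specific miRNA signatures
#'
#' For each subtype, tests every feature one-vs-rest (Welch's t on log2
#' values, BH FDR across features within the subtype) and keeps features
#' showing differential upregulation: `log2fc >= lfc_min` and
#' `fdr <= fdr_max`. With `comparison = "pairwise"` the feature must pass
#' both gates against every other subtype individually. A feature may
#' qualify for more than one subtype; overlaps are reported via a message,
#' not forbidden.
#'
#' @param expr purified-leukocyte [MirnaExpressionSet-class]
#' @param groups per-sample subtype labels (defaults to
#'   `colData(expr)$group`)
#' @param lfc_min minimum log2 fold change over the rest (default 0.26)
#' @param fdr_max maximum BH-adjusted p (default 0.05)
#' @param comparison `"pooled"` (vs all other subtypes together, default)
#'   or `"pairwise"` (vs each other subtype, all must pass)
#' @return named list of character vectors, one signature per subtype
#'   (empty signatures are kept as empty vectors)
#' @export
subtypeSpecificMirnas <- function(expr, groups = sampleGroups(expr),
                                  lfc_min = 0.26, fdr_max = 0.05,
                                  comparison = c("pooled", "pairwise")) {
  comparison <- match.arg(comparison)
  if (is.null(groups)) stop("subtype labels are required")
  x <- .log2Values(expr)
  subtypes <- unique(groups)
  if (length(subtypes) < 2L) stop("need >= 2 subtypes")
  small <- subtypes[vapply(subtypes, function(s) sum(groups == s) < 2L,
                           logical(1))]
  if (length(small))
    stop("subtype(s) with < 2 samples: ", paste(small, collapse = ", "))
  sigs <- lapply(subtypes, function(s) {
    ia <- which(groups == s)
    if (comparison == "pooled") {
      w <- .rowWelch(x, ia, which(groups != s))
      fdr <- stats::p.adjust(w$p_value, method = "BH")
      rownames(x)[w$log2fc >= lfc_min & fdr <= fdr_max]
    } else {
      pass <- rep(TRUE, nrow(x))
      for (o in setdiff(subtypes, s)) {
        w <- .rowWelch(x, ia, which(groups == o))
        fdr <- stats::p.adjust(w$p_value, method = "BH")
        pass <- pass & w$log2fc >= lfc_min & fdr <= fdr_max
      }
      rownames(x)[pass]
    }
  })
  names(sigs) <- subtypes
  n_multi <- sum(table(unlist(sigs)) > 1L)
  if (n_multi)
    message(n_multi, " feature(s) qualified for more than one subtype")
  sigs
}

#' Cumulative hypergeometric overlap test
#'
#' Upper-tail probability of observing an overlap of at least `k` between
#' two sets of sizes `K` and `n` drawn from a universe of size `N`:
#' `P(X >= k) = sum_{x=k}^{min(K,n)} C(K,x) C(N-K,n-x) / C(N,n)`,
#' evaluated in log space via [stats::phyper()]. The universe size must be
#' given explicitly (e.g. the number of features measured in all
#' datasets); it is never inferred.
#'
#' @param N universe size
#' @param K,n sizes of the two sets (the test is symmetric in them)
#' @param k observed overlap
#' @return object of class `"htest"` with the overlap as statistic and the
#'   upper-tail p-value
#' @examples
#' hypergeometricOverlap(N = 777, K = 148, n = 136, k = 80)$p.value
#' @export
hypergeometricOverlap <- function(N, K, n, k) {
  stopifnot(N >= 1, K >= 0, n >= 0, k >= 0)
  if (K > N || n > N) stop("set sizes cannot exceed the universe size N")
  if (k > min(K, n))
    stop("overlap k cannot exceed min(K, n) = ", min(K, n))
  lp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  structure(list(
    statistic = c(overlap = k),
    parameter = c(N = N, K = K, n = n),
    p.value = exp(lp),
    method = "Cumulative hypergeometric overlap test (upper tail)",
    data.name = sprintf("overlap %d between sets of %d and %d in universe %d",
                        k, K, n, N),
    alternative = "overlap larger than expected by chance"),
    class = "htest")
}
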