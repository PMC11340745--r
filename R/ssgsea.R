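#' Single-sample gene set enrichment (ssGSEA) scores
#'
#' For each sample and signature: features are ranked by expression within
#' the sample (descending; ties get average ranks), in-set steps are
#' weighted by rank magnitude raised to `alpha` and normalized over the
#' set, out-of-set steps are uniform, and the score is the sum over the
#' ranked list of the difference between the weighted in-set ECDF and the
#' out-of-set ECDF. Raw enrichment scores are reported with no
#' cross-sample rescaling. Because only within-sample ranks enter, the
#' scores are invariant to strictly monotone per-sample transforms of the
#' expression values — the property that lets signature scores track
#' leukocyte proportions regardless of normalization.
#'
#' @param expr a [MirnaExpressionSet-class]
#' @param signatures named list of feature-id vectors (e.g. from
#'   [subtypeSpecificMirnas()] or [readGmt()]); features absent from
#'   `expr` are dropped with a warning, and a signature left empty is an
#'   error
#' @param alpha rank weighting exponent (default 0.25)
#' @return numeric matrix, samples x signatures, of enrichment scores
#' @export
ssgseaScores <- function(expr, signatures, alpha = 0.25) {
  stopifnot(is.list(signatures), length(signatures) > 0L,
            !is.null(names(signatures)))
  x <- exprValues(expr)
  n <- nrow(x)
  sig_idx <- lapply(names(signatures), function(nm) {
    feats <- unique(signatures[[nm]])
    hit <- feats %in% rownames(x)
    if (!all(hit))
      warning("signature '", nm, "': ", sum(!hit),
              " feature(s) absent from the matrix; dropped")
    idx <- match(feats[hit], rownames(x))
    if (!length(idx))
      stop("signature '", nm, "' has no feature in the matrix")
    if (length(idx) == n)
      stop("signature '", nm, "' covers every feature; no out-of-set steps")
    idx
  })
  names(sig_idx) <- names(signatures)

  scores <- matrix(NA_real_, ncol(x), length(sig_idx),
                   dimnames = list(colnames(x), names(sig_idx)))
  for (s in seq_len(ncol(x))) {
    r <- rank(x[, s], ties.method = "average")
    ord <- order(r, decreasing = TRUE)   # stable: ties resolved by index
    w_all <- r[ord]^alpha
    for (g in seq_along(sig_idx)) {
      inset <- ord %in% sig_idx[[g]]
      w <- w_all * inset
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!inset) / (n - sum(inset))
      scores[s, g] <- sum(p_in - p_out)
    }
  }
  scores
}
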