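# logical matrix (pairs x samples): strict expression(upper) > expression(lower)
.pairEvents <- function(pairs, expr) {
  df <- stablePairs(pairs)
  x <- exprValues(expr)
  absent <- setdiff(unique(c(df$upper, df$lower)), rownames(x))
  if (length(absent))
    stop("pair member(s) absent from matrix: ", paste(absent, collapse = ", "))
  x[df$upper, , drop = FALSE] > x[df$lower, , drop = FALSE]
}

# core reversal statistics from a precomputed event matrix
.reversalFromEvents <- function(ev, h_idx, d_idx) {
  n1 <- as.integer(rowSums(ev[, h_idx, drop = FALSE]))
  n2 <- as.integer(rowSums(ev[, d_idx, drop = FALSE]))
  m1 <- length(h_idx) - n1
  m2 <- length(d_idx) - n2
  p_healthy <- n1 / length(h_idx)
  p_disease <- n2 / length(d_idx)
  p <- .fisher2x2(n1, m1, n2, m2)
  list(n1 = n1, m1 = m1, n2 = n2, m2 = m2,
       p_healthy = p_healthy, p_disease = p_disease,
       delta_p = p_healthy - p_disease, p_value = p,
       fdr = stats::p.adjust(p, method = "BH"))
}

.groupIdx <- function(groups, label) {
  idx <- which(groups == label)
  if (!length(idx)) stop("no samples labelled '", label, "'")
  idx
}

#' Reversal statistics for reference stable pairs in whole blood
#'
#' For each reference pair, counts healthy and disease whole-blood samples
#' maintaining (`n1`, `n2`) or violating (`m1`, `m2`) the reference
#' orientation (ties count as violations), computes the maintained
#' fractions `p_healthy`, `p_disease` and their difference `delta_p`, a
#' two-sided Fisher exact p on the 2x2 table `[[n1, m1], [n2, m2]]`, and a
#' Benjamini-Hochberg FDR across all tested pairs. Directionality is not
#' imposed here; [selectReversals()] applies the one-sided `delta_p` gate.
#'
#' @param pairs a [StablePairSet-class] (typically after
#'   [filterByConsistency()])
#' @param expr whole-blood [MirnaExpressionSet-class]
#' @param groups per-sample labels (defaults to `colData(expr)$group`)
#' @param healthy,disease the two labels to contrast
#' @return a `DataFrame` with one row per pair: `upper`, `lower`, `n1`,
#'   `m1`, `n2`, `m2`, `p_healthy`, `p_disease`, `delta_p`, `p_value`, `fdr`
#' @export
reversalStats <- function(pairs, expr, groups = sampleGroups(expr),
                          healthy = "healthy", disease = "disease") {
  if (is.null(groups)) stop("group labels are required")
  st <- .reversalFromEvents(.pairEvents(pairs, expr),
                            .groupIdx(groups, healthy),
                            .groupIdx(groups, disease))
  df <- stablePairs(pairs)
  S4Vectors::DataFrame(upper = df$upper, lower = df$lower,
                       n1 = st$n1, m1 = st$m1, n2 = st$n2, m2 = st$m2,
                       p_healthy = st$p_healthy, p_disease = st$p_disease,
                       delta_p = st$delta_p, p_value = st$p_value,
                       fdr = st$fdr)
}

#' Select significant reversal pairs
#'
#' Retains pairs with `p_healthy >= p_healthy_min`, `delta_p >= delta_min`
#' and `fdr <= fdr_max` (all boundaries inclusive). `delta_p` is signed, so
#' only losses of the healthy reference orientation can pass. Output is
#' sorted by ascending p-value, then lexicographically by pair.
#'
#' @param stats `DataFrame` from [reversalStats()]
#' @param p_healthy_min minimum healthy maintained fraction (default 0.9)
#' @param delta_min minimum `p_healthy - p_disease` (default 0.15)
#' @param fdr_max maximum BH-adjusted p (default 0.05)
#' @return the selected subset, same columns as the input
#' @export
selectReversals <- function(stats, p_healthy_min = 0.9, delta_min = 0.15,
                            fdr_max = 0.05) {
  keep <- stats$p_healthy >= p_healthy_min &
    stats$delta_p >= delta_min & stats$fdr <= fdr_max
  out <- stats[keep, , drop = FALSE]
  out <- out[order(out$p_value, out$upper, out$lower), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label-permutation null for reversal pair counts
#'
#' Shuffles the healthy/disease labels uniformly at random (group sizes
#' preserved), reruns the full [reversalStats()] then [selectReversals()]
#' chain, and records the number of selected reversal pairs in each
#' permutation. With no true intracellular signal the counts should be
#' (almost always) zero, which is the method's negative control.
#'
#' @inheritParams reversalStats
#' @inheritParams selectReversals
#' @param n_perm number of permutations (>= 1)
#' @param seed integer seed; permutations are reproducible given the seed
#' @return integer vector of length `n_perm`: selected-pair counts
#' @export
permutationNull <- function(pairs, expr, groups = sampleGroups(expr),
                            healthy = "healthy", disease = "disease",
                            n_perm = 100L, seed = 1L,
                            p_healthy_min = 0.9, delta_min = 0.15,
                            fdr_max = 0.05) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (is.null(groups)) stop("group labels are required")
  h <- .groupIdx(groups, healthy)
  d <- .groupIdx(groups, disease)
  ev <- .pairEvents(pairs, expr)
  pool <- c(h, d)
  set.seed(as.integer(seed))
  vapply(seq_len(n_perm), function(i) {
    perm <- sample(pool)
    st <- .reversalFromEvents(ev, perm[seq_along(h)], perm[-seq_along(h)])
    sum(st$p_healthy >= p_healthy_min & st$delta_p >= delta_min &
          st$fdr <= fdr_max)
  }, integer(1))
}
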