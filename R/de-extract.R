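# partner lists per miRNA from an unordered view of a pair table
.partnerMap <- function(upper, lower) {
  split(c(lower, upper), c(upper, lower))
}

# aggregate REO event counts of one miRNA against a partner set
.contingencyCounts <- function(x, mirna, partners, h_idx, d_idx) {
  ev <- matrix(x[mirna, ], nrow = length(partners), ncol = ncol(x),
               byrow = TRUE) > x[partners, , drop = FALSE]
  n1 <- sum(ev[, h_idx]); n2 <- sum(ev[, d_idx])
  c(n1 = n1, m1 = length(h_idx) * length(partners) - n1,
    n2 = n2, m2 = length(d_idx) * length(partners) - n2)
}

#' Aggregate REO contingency table for one miRNA
#'
#' Over every (partner, sample) combination, counts the events
#' expression(mirna) > expression(partner) — `n1` in healthy and `n2` in
#' disease samples — and the complementary events (ties included) `m1`,
#' `m2`. Partners are all features paired with the miRNA in the pair
#' universe, regardless of orientation. Because the universe pairs are
#' maintained in nearly all healthy samples, `n1/(n1+m1)` acts as a
#' within-sample rank statistic for the miRNA among its partners.
#'
#' @param mirna feature id
#' @param pair_universe a [StablePairSet-class] (the filtered reference
#'   stable pairs)
#' @param expr whole-blood [MirnaExpressionSet-class]
#' @param groups per-sample labels (defaults to `colData(expr)$group`)
#' @param healthy,disease the two labels to contrast
#' @return list with `mirna`, `partners`, and integer counts `n1`, `m1`,
#'   `n2`, `m2`
#' @export
mirnaContingency <- function(mirna, pair_universe, expr,
                             groups = sampleGroups(expr),
                             healthy = "healthy", disease = "disease") {
  df <- stablePairs(pair_universe)
  partners <- unique(c(df$lower[df$upper == mirna],
                       df$upper[df$lower == mirna]))
  if (!length(partners))
    stop("'", mirna, "' participates in no pair of the universe")
  x <- exprValues(expr)
  cnt <- .contingencyCounts(x, mirna, partners,
                            .groupIdx(groups, healthy),
                            .groupIdx(groups, disease))
  list(mirna = mirna, partners = partners,
       n1 = unname(cnt["n1"]), m1 = unname(cnt["m1"]),
       n2 = unname(cnt["n2"]), m2 = unname(cnt["m2"]))
}

#' Iteratively extract differentially expressed miRNAs from reversal pairs
#'
#' The extraction loop: (a) for every miRNA in the current reversal set,
#' build its aggregate contingency table over the pair universe and compute
#' a two-sided Fisher exact p; (b) extract the minimum-p miRNA (ties broken
#' by more memberships in the current reversal set, then lexicographic id);
#' (c) assign its direction by cross-products — down in disease iff
#' `n1*m2 > n2*m1`, up iff `n1*m2 < n2*m1` (the ratio rule n1/m1 vs n2/m2
#' without division); exact equality leaves the direction undetermined and
#' the candidate is skipped for that iteration; (d) drop every reversal
#' pair containing the extracted miRNA; repeat until the reversal set is
#' empty. No significance floor is applied inside the loop; downstream
#' users filter on `q_value` (BH over the extracted miRNAs' p-values).
#'
#' @param reference_pairs a [StablePairSet-class]; the pair universe used
#'   for counting (reversal pairs must be a subset as unordered pairs)
#' @param reversal_pairs reversal pairs: output of [selectReversals()], or
#'   any data-frame-like with `upper`/`lower` columns, or a
#'   [StablePairSet-class]
#' @param expr whole-blood [MirnaExpressionSet-class]
#' @param groups per-sample labels (defaults to `colData(expr)$group`)
#' @param healthy,disease the two labels to contrast
#' @param count_universe `"reference"` (default) aggregates events over all
#'   reference pairs involving the candidate; `"reversal_only"` restricts
#'   counting to the current reversal pairs
#' @return a `DataFrame` ordered by extraction iteration: `mirna`,
#'   `direction` (+1 up / -1 down in disease), `p_value`, `q_value`,
#'   `iteration`, `n1`, `m1`, `n2`, `m2`
#' @export
extractDeMirnas <- function(reference_pairs, reversal_pairs, expr,
                            groups = sampleGroups(expr),
                            healthy = "healthy", disease = "disease",
                            count_universe = c("reference", "reversal_only")) {
  count_universe <- match.arg(count_universe)
  rev_df <- if (is(reversal_pairs, "StablePairSet"))
    as.data.frame(reversal_pairs)
  else as.data.frame(reversal_pairs)[, c("upper", "lower")]
  empty <- S4Vectors::DataFrame(
    mirna = character(), direction = integer(), p_value = numeric(),
    q_value = numeric(), iteration = integer(), n1 = integer(),
    m1 = integer(), n2 = integer(), m2 = integer())
  if (!nrow(rev_df)) return(empty)

  ref_df <- stablePairs(reference_pairs)
  miss <- setdiff(.pairKey(rev_df$upper, rev_df$lower),
                  .pairKey(ref_df$upper, ref_df$lower))
  if (length(miss))
    stop("reversal pairs must be a subset of the reference pairs (",
         length(miss), " are not)")

  x <- exprValues(expr)
  h_idx <- .groupIdx(groups, healthy)
  d_idx <- .groupIdx(groups, disease)
  ref_partners <- .partnerMap(ref_df$upper, ref_df$lower)

  # in reference mode the universe never shrinks, so each miRNA's counts
  # and p-value can be computed once up front
  statsFor <- function(mirnas, partner_map) {
    cnt <- t(vapply(mirnas, function(m)
      .contingencyCounts(x, m, unique(partner_map[[m]]), h_idx, d_idx),
      numeric(4)))
    p <- .fisher2x2(cnt[, "n1"], cnt[, "m1"], cnt[, "n2"], cnt[, "m2"])
    data.frame(mirna = mirnas, n1 = cnt[, "n1"], m1 = cnt[, "m1"],
               n2 = cnt[, "n2"], m2 = cnt[, "m2"], p_value = p,
               stringsAsFactors = FALSE, row.names = mirnas)
  }
  cache <- NULL
  if (count_universe == "reference")
    cache <- statsFor(sort(unique(c(rev_df$upper, rev_df$lower))),
                      ref_partners)

  out <- list()
  iter <- 0L
  cur <- rev_df
  while (nrow(cur)) {
    active <- sort(unique(c(cur$upper, cur$lower)))
    st <- if (count_universe == "reference") cache[active, , drop = FALSE]
    else statsFor(active, .partnerMap(cur$upper, cur$lower))
    membership <- table(factor(c(cur$upper, cur$lower), levels = active))
    dir <- sign(st$n2 * st$m1 - st$n1 * st$m2)   # +1 up, -1 down, 0 unknown
    ord <- order(st$p_value, -as.integer(membership), st$mirna)
    pick <- ord[dir[ord] != 0L][1L]
    if (is.na(pick)) {
      warning("direction undetermined for every remaining candidate; ",
              nrow(cur), " reversal pair(s) left unexplained")
      break
    }
    iter <- iter + 1L
    out[[iter]] <- data.frame(
      mirna = st$mirna[pick], direction = dir[pick],
      p_value = st$p_value[pick], iteration = iter,
      n1 = st$n1[pick], m1 = st$m1[pick], n2 = st$n2[pick],
      m2 = st$m2[pick], stringsAsFactors = FALSE)
    hit <- cur$upper == st$mirna[pick] | cur$lower == st$mirna[pick]
    cur <- cur[!hit, , drop = FALSE]
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  S4Vectors::DataFrame(
    mirna = res$mirna, direction = as.integer(res$direction),
    p_value = res$p_value,
    q_value = stats::p.adjust(res$p_value, method = "BH"),
    iteration = res$iteration, n1 = as.integer(res$n1),
    m1 = as.integer(res$m1), n2 = as.integer(res$n2),
    m2 = as.integer(res$m2))
}
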