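test_that("single-partner contingency counts match the obvious construction", {
  # mirna above its partner in all 5 healthy, below in all 5 disease samples
  m <- rbind(X = c(rep(5, 5), rep(3, 5)), P = 4)
  colnames(m) <- sprintf("s%02d", 1:10)
  x <- MirnaExpressionSet(m, group = rep(c("healthy", "disease"), each = 5))
  ps <- StablePairSet("X", "P")
  ct <- mirnaContingency("X", ps, x)
  expect_identical(ct$partners, "P")
  expect_equal(c(ct$n1, ct$m1, ct$n2, ct$m2), c(5, 0, 0, 5))
  expect_error(mirnaContingency("Q", ps, x), "no pair")
})

test_that("contingency counts equal a brute-force triple loop", {
  x <- randomExprSet(6, 10, groups = rep(c("healthy", "disease"), each = 5),
                     seed = 8)
  ps <- StablePairSet(c("f01", "f01", "f04", "f02"),
                      c("f02", "f03", "f01", "f05"))
  ct <- mirnaContingency("f01", ps, x)
  expect_setequal(ct$partners, c("f02", "f03", "f04"))
  v <- exprValues(x); g <- sampleGroups(x)
  n1 <- m1 <- n2 <- m2 <- 0
  for (p in ct$partners) for (s in seq_len(ncol(v))) {
    win <- v["f01", s] > v[p, s]
    if (g[s] == "healthy") { n1 <- n1 + win; m1 <- m1 + !win }
    else { n2 <- n2 + win; m2 <- m2 + !win }
  }
  expect_equal(c(ct$n1, ct$m1, ct$n2, ct$m2), c(n1, m1, n2, m2))
  expect_equal(ct$n1 + ct$m1, 5 * length(ct$partners))
  expect_equal(ct$n2 + ct$m2, 5 * length(ct$partners))
})

test_that("the cross-product rule fixes the direction", {
  # per partner, X wins 18/20 healthy and 5/20 disease samples; over the
  # two partners the aggregate is (36,4,10,30): n1*m2 = 1080 > n2*m1 = 40,
  # so the ratio rule (cross-product form) calls X down in disease
  nh <- 20; nd <- 20
  ev_h <- rep(c(5, 3), c(18, 2)); ev_d <- rep(c(5, 3), c(5, 15))
  m <- rbind(X = c(ev_h, ev_d), Z1 = 4, Z2 = 4)
  colnames(m) <- sprintf("s%02d", seq_len(nh + nd))
  x <- MirnaExpressionSet(m, group = rep(c("healthy", "disease"), c(nh, nd)))
  ref <- StablePairSet(c("X", "X"), c("Z1", "Z2"))
  de <- extractDeMirnas(ref, data.frame(upper = c("X", "X"),
                                        lower = c("Z1", "Z2")), x)
  expect_identical(de$mirna[1], "X")
  expect_identical(de$direction[1], -1L)
  expect_equal(c(de$n1[1], de$m1[1], de$n2[1], de$m2[1]),
               c(36L, 4L, 10L, 30L))
})

test_that("empty reversal set yields an empty result, not an error", {
  x <- randomExprSet(4, 6, groups = rep(c("healthy", "disease"), 3), seed = 9)
  ref <- StablePairSet(c("f01", "f02"), c("f02", "f03"))
  de <- extractDeMirnas(ref, data.frame(upper = character(),
                                        lower = character()), x)
  expect_equal(nrow(de), 0L)
})

test_that("reversal pairs must be a subset of the reference pairs", {
  x <- randomExprSet(4, 6, groups = rep(c("healthy", "disease"), 3), seed = 9)
  ref <- StablePairSet("f01", "f02")
  expect_error(extractDeMirnas(ref, data.frame(upper = "f03", lower = "f04"),
                               x), "subset")
})

test_that("a miRNA shifted below all its partners is extracted first, direction down", {
  # 20 + 20 samples; X sits above its 5 reference partners in every healthy
  # sample and below all of them in every disease sample
  set.seed(10)
  partners <- sprintf("P%d", 1:5)
  m <- matrix(rnorm(5 * 40, 5, 0.1), 5, 40,
              dimnames = list(partners, sprintf("s%02d", 1:40)))
  X <- c(rep(7, 20), rep(3, 20)) + rnorm(40, 0, 0.1)
  m <- rbind(X = X, m)
  x <- MirnaExpressionSet(m, group = rep(c("healthy", "disease"), each = 20))
  ref <- StablePairSet(rep("X", 5), partners)
  rev_pairs <- data.frame(upper = rep("X", 5), lower = partners)
  de <- extractDeMirnas(ref, rev_pairs, x)
  expect_identical(de$mirna[1], "X")
  expect_identical(de$direction[1], -1L)
  expect_identical(de$iteration, seq_len(nrow(de)))
  # X's aggregated Fisher p is minimal among all candidates (brute force)
  cands <- unique(c(rev_pairs$upper, rev_pairs$lower))
  ps <- vapply(cands, function(mi) {
    ct <- mirnaContingency(mi, ref, x)
    stats::fisher.test(matrix(c(ct$n1, ct$m1, ct$n2, ct$m2), 2,
                              byrow = TRUE))$p.value
  }, numeric(1))
  expect_identical(names(which.min(ps)), "X")
})

test_that("extraction terminates, never repeats a miRNA, and is deterministic", {
  x <- randomExprSet(12, 24, groups = rep(c("healthy", "disease"), 12),
                     seed = 12)
  ref <- stablePairsWithin(randomExprSet(12, 3, seed = 13))
  stats <- reversalStats(ref, x)
  # use a permissive selection so some pseudo-reversals exist
  rev_pairs <- stats[stats$delta_p > 0.2, c("upper", "lower")]
  de <- extractDeMirnas(ref, rev_pairs, x)
  expect_lte(nrow(de), nrow(rev_pairs))
  expect_false(anyDuplicated(de$mirna) > 0)
  expect_true(all(de$mirna %in% c(rev_pairs$upper, rev_pairs$lower)))
  expect_identical(de$iteration, seq_len(nrow(de)))
  expect_equal(as.data.frame(extractDeMirnas(ref, rev_pairs, x)),
               as.data.frame(de))
  # every reversal pair is accounted for by some extracted miRNA
  covered <- rev_pairs$upper %in% de$mirna | rev_pairs$lower %in% de$mirna
  expect_true(all(covered))
  # q-values are the BH adjustment of the extraction p-values
  expect_equal(de$q_value, stats::p.adjust(de$p_value, "BH"))
})

test_that("reversal_only counting restricts partners to the reversal set", {
  x <- randomExprSet(8, 10, groups = rep(c("healthy", "disease"), 5),
                     seed = 14)
  ref <- stablePairsWithin(randomExprSet(8, 2, seed = 15))
  df <- as.data.frame(ref)
  rev_pairs <- df[1:2, ]
  de_ref <- extractDeMirnas(ref, rev_pairs, x)
  de_rev <- extractDeMirnas(ref, rev_pairs, x,
                            count_universe = "reversal_only")
  expect_setequal(de_rev$mirna, de_ref$mirna)
  # counts in reversal_only mode aggregate over fewer partners
  expect_true(all(de_rev$n1 + de_rev$m1 <= de_ref$n1 + de_ref$m1))
})
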