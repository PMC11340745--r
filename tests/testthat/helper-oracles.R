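# shared fixtures and independent oracles, used across test files

# random log2-scale expression set with labelled groups
randomExprSet <- function(n_feat, n_samp, groups = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(n_feat * n_samp, 7, 2), n_feat, n_samp,
              dimnames = list(sprintf("f%02d", seq_len(n_feat)),
                              sprintf("s%02d", seq_len(n_samp))))
  MirnaExpressionSet(m, scale = "log2", group = groups)
}

# brute-force stable-pair mining: double loop over all unordered pairs,
# checking every sample individually
bruteStablePairs <- function(x) {
  ids <- rownames(x)
  up <- character(); lo <- character()
  for (i in seq_len(nrow(x) - 1L)) {
    for (j in (i + 1L):nrow(x)) {
      if (all(x[i, ] > x[j, ])) { up <- c(up, ids[i]); lo <- c(lo, ids[j]) }
      else if (all(x[j, ] > x[i, ])) { up <- c(up, ids[j]); lo <- c(lo, ids[i]) }
    }
  }
  df <- data.frame(upper = up, lower = lo, stringsAsFactors = FALSE)
  df[order(df$upper, df$lower), , drop = FALSE]
}

# two-sided Fisher exact p by exhaustive enumeration of all tables with the
# observed margins, summing probabilities <= the observed table's (computed
# from binomial coefficients, independent of the implementation's dhyper path)
enumFisher <- function(n1, m1, n2, m2) {
  Nh <- n1 + m1; Nd <- n2 + m2; k <- n1 + n2
  if (Nh == 0 || Nd == 0 || k == 0 || k == Nh + Nd) return(1)
  xs <- max(0, k - Nd):min(k, Nh)
  pr <- choose(Nh, xs) * choose(Nd, k - xs) / choose(Nh + Nd, k)
  obs <- pr[xs == n1]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# a strictly increasing transform applied per sample (different per column)
monotoneWarp <- function(expr) {
  v <- exprValues(expr)
  for (s in seq_len(ncol(v))) {
    v[, s] <- switch(1L + (s %% 3L),
                     exp(v[, s] / 4),
                     v[, s]^3,
                     2 * v[, s] + 10)
  }
  MirnaExpressionSet(v, scale = "linear", group = sampleGroups(expr))
}

pairString <- function(ps) {
  df <- as.data.frame(ps)
  if (!nrow(df)) return(character())
  paste(df$upper, df$lower, sep = ">")
}

# small two-dataset synthetic study used by several end-to-end tests
smallStudy <- function(seed, n_features = 300L, n_healthy = 100L,
                       n_disease = 100L, alpha_disease = NULL,
                       spike_set = NULL) {
  args <- list(n_features = n_features, n_healthy = n_healthy,
               n_disease = n_disease, spike_set = spike_set,
               seed = as.integer(seed))
  if (!is.null(alpha_disease)) args$dirichlet_alpha_disease <- alpha_disease
  cfg <- do.call(syntheticConfig, args)
  leuk <- generateLeukocyteProfiles(cfg, "train", seed = cfg$seed)
  blood <- generateWholeBlood(leuk$truth, cfg, seed = cfg$seed + 1L)
  list(cfg = cfg, leuk = leuk, blood = blood)
}

# the composition-shift disease prior used by the confound scenario:
# neutrophils -0.15, T cells +0.15 relative to the healthy means
shiftedAlpha <- function() 50 * c(0.08, 0.40, 0.03, 0.08, 0.35, 0.06)

# the spike table used by the recovery scenario: 10 features, log2 shift
# +/-1 within both subtypes whose mean proportion is >= 0.15
recoverySpikes <- function(seed) {
  set.seed(seed)
  feats <- sprintf("miR-%04d", sample(300, 10))
  dirs <- rep(c(1, -1), 5)
  data.frame(feature = rep(feats, each = 2),
             subtype = rep(c("Neutrophils", "Tcells"), 10),
             log2_shift = rep(dirs, each = 2),
             stringsAsFactors = FALSE)
}
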