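# Vectorized two-sided Fisher exact test for 2x2 tables [[n1, m1], [n2, m2]].
#
# Conditional on both margins, n1 follows a hypergeometric distribution;
# the two-sided p sums all outcome probabilities not exceeding the observed
# one (the same definition stats::fisher.test uses), with the customary
# (1 + 1e-7) relative tolerance for floating-point ties. Tables are
# deduplicated before evaluation: in REO pair screening thousands of pairs
# share identical counts, so this is the hot path's main saving.
.fisher2x2 <- function(n1, m1, n2, m2) {
  stopifnot(length(m1) == length(n1), length(n2) == length(n1),
            length(m2) == length(n1))
  if (!length(n1)) return(numeric())
  if (any(c(n1, m1, n2, m2) < 0)) stop("negative cell count")
  key <- paste(n1, m1, n2, m2)
  u <- !duplicated(key)
  pu <- vapply(which(u), function(i) {
    Nh <- n1[i] + m1[i]; Nd <- n2[i] + m2[i]; k <- n1[i] + n2[i]
    if (Nh == 0L || Nd == 0L || k == 0L || k == Nh + Nd) return(1)
    lo <- max(0L, k - Nd); hi <- min(k, Nh)
    d <- stats::dhyper(lo:hi, Nh, Nd, k)
    min(1, sum(d[d <= d[n1[i] - lo + 1L] * (1 + 1e-7)]))
  }, numeric(1))
  pu[match(key, key[u])]
}
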