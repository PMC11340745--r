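test_that("config validation rejects inconsistent settings", {
  expect_error(syntheticConfig(n_features = 20,
                               n_markers_per_subtype = 10), "exceeds")
  expect_error(syntheticConfig(dirichlet_alpha_healthy = c(1, 2)),
               "one entry per subtype")
  expect_error(syntheticConfig(
    spike_set = data.frame(feature = "miR-0001", subtype = "Platelets",
                           log2_shift = 1)), "unknown subtype")
})

test_that("purified profiles are deterministic and noise-free at noise_sd 0", {
  cfg <- syntheticConfig(n_features = 60, n_markers_per_subtype = 5,
                         noise_sd = 0, seed = 5L)
  a <- generateLeukocyteProfiles(cfg)
  b <- generateLeukocyteProfiles(cfg)
  expect_identical(exprValues(a$expr), exprValues(b$expr))
  # each sample equals its subtype's base profile exactly
  g <- sampleGroups(a$expr)
  prof <- truthProfiles(a$truth)
  for (s in unique(g))
    expect_true(all(exprValues(a$expr)[, g == s] == prof[, s]))
  # markers exceed every other subtype's mean by exactly the boost
  mk <- truthMarkers(a$truth)
  for (s in colnames(prof)) {
    others <- setdiff(colnames(prof), s)
    gap <- prof[mk[[s]], s] - apply(prof[mk[[s]], others, drop = FALSE],
                                    1, max)
    expect_true(all(abs(gap - cfg$marker_boost) < 1e-12))
  }
  # marker sets are disjoint across subtypes
  expect_equal(anyDuplicated(unlist(mk)), 0L)
})

test_that("whole blood is the convex combination of subtype profiles", {
  # one dominant subtype, zero noise: blood equals that subtype's profile
  cfg <- syntheticConfig(n_features = 40, n_markers_per_subtype = 4,
                         noise_sd = 0,
                         dirichlet_alpha_healthy = c(1e6, rep(1e-3, 5)),
                         dirichlet_alpha_disease = c(1e6, rep(1e-3, 5)),
                         n_healthy = 3, n_disease = 2, seed = 6L)
  leuk <- generateLeukocyteProfiles(cfg)
  blood <- generateWholeBlood(leuk$truth, cfg)
  prof <- truthProfiles(leuk$truth)
  expect_equal(exprValues(blood$expr)[, 1], prof[, 1], tolerance = 1e-6)

  # two subtypes at recorded proportions: linear scale mixes arithmetically
  props <- truthProportions(blood$truth)
  expect_equal(unname(rowSums(props)), rep(1, nrow(props)),
               tolerance = 1e-12)
  lin_expected <- 2^prof %*% t(props)
  expect_equal(2^exprValues(blood$expr), lin_expected,
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("Dirichlet proportions match their closed-form means", {
  alpha_d <- shiftedAlpha()
  cfg <- syntheticConfig(n_features = 30, n_markers_per_subtype = 3,
                         n_healthy = 200, n_disease = 200,
                         dirichlet_alpha_disease = alpha_d, seed = 7L)
  leuk <- generateLeukocyteProfiles(cfg)
  blood <- generateWholeBlood(leuk$truth, cfg)
  props <- truthProportions(blood$truth)
  g <- sampleGroups(blood$expr)
  mc_tol <- 4 / sqrt(200)   # ~4 sigma of a proportion's Monte-Carlo error
  expect_equal(unname(colMeans(props[g == "healthy", ])),
               cfg$dirichlet_alpha_healthy / sum(cfg$dirichlet_alpha_healthy),
               tolerance = mc_tol)
  expect_equal(unname(colMeans(props[g == "disease", ])),
               alpha_d / sum(alpha_d), tolerance = mc_tol)
  expect_gt(mean(props[g == "disease", "Tcells"]),
            mean(props[g == "healthy", "Tcells"]))
})

test_that("spikes shift the affected subtype's contribution before mixing", {
  spike <- data.frame(feature = "miR-0005", subtype = "Neutrophils",
                      log2_shift = 1)
  cfg <- syntheticConfig(n_features = 30, n_markers_per_subtype = 3,
                         noise_sd = 0, spike_set = spike,
                         n_healthy = 5, n_disease = 5, seed = 8L)
  leuk <- generateLeukocyteProfiles(cfg)
  blood <- generateWholeBlood(leuk$truth, cfg)
  v <- 2^exprValues(blood$expr)
  prof <- 2^truthProfiles(leuk$truth)
  props <- truthProportions(blood$truth)
  g <- sampleGroups(blood$expr)
  d1 <- which(g == "disease")[1]
  expected <- sum(prof["miR-0005", ] * props[d1, ] *
                    ifelse(colnames(prof) == "Neutrophils", 2, 1))
  expect_equal(v["miR-0005", d1], expected, tolerance = 1e-8)
  # healthy samples are unspiked
  h1 <- which(g == "healthy")[1]
  expect_equal(v["miR-0005", h1], sum(prof["miR-0005", ] * props[h1, ]),
               tolerance = 1e-8)
})

test_that("recovery metrics equal hand-counted values on a toy comparison", {
  truth <- new("SyntheticTruth",
               profiles = matrix(0, 2, 2,
                                 dimnames = list(c("a", "b"), c("X", "Y"))),
               markers = list(X = character(), Y = character()),
               proportions = matrix(numeric(), 0, 2),
               spikes = S4Vectors::DataFrame(
                 feature = c("a", "b"), subtype = "X",
                 log2_shift = c(1, -1)),
               seed = 1L)
  de <- S4Vectors::DataFrame(
    mirna = c("a", "c"), direction = c(1L, 1L),
    p_value = c(1e-5, 1e-4), q_value = c(1e-4, 1e-3),
    iteration = 1:2, n1 = 0L, m1 = 0L, n2 = 0L, m2 = 0L)
  rec <- evaluateRecovery(de, truth)
  expect_equal(rec$sensitivity, 0.5)          # a recovered, b missed
  expect_equal(rec$fdp, 0.5)                  # c is a false discovery
  expect_equal(rec$direction_accuracy, 1.0)   # a's direction is correct
  # empty extraction
  rec0 <- evaluateRecovery(de[0, ], truth)
  expect_equal(rec0$sensitivity, 0)
  expect_equal(rec0$fdp, 0)
})

test_that("generators are bit-reproducible under a fixed seed", {
  spike <- recoverySpikes(3)
  cfg <- syntheticConfig(spike_set = spike, seed = 9L)
  a <- generateLeukocyteProfiles(cfg)
  blood_a <- generateWholeBlood(a$truth, cfg)
  b <- generateLeukocyteProfiles(cfg)
  blood_b <- generateWholeBlood(b$truth, cfg)
  expect_identical(exprValues(blood_a$expr), exprValues(blood_b$expr))
  expect_identical(truthProportions(blood_a$truth),
                   truthProportions(blood_b$truth))
})
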