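#' Configuration for the synthetic whole-blood simulator
#'
#' Bundles every knob of the generative model: purified leukocyte subtype
#' profiles are drawn once as log2 means (baseline spread
#' `base_profile_sd` around `base_mean`), each subtype's markers are
#' boosted by `marker_boost` log2 units, measurement noise is Gaussian on
#' the log2 scale, and whole-blood samples are noisy convex combinations
#' of the subtype profiles on the linear scale with per-sample mixing
#' proportions drawn from group-specific Dirichlet priors. Disease samples
#' may additionally carry intracellular spikes: multiplicative log2 shifts
#' applied to specific features within specific subtypes before mixing, so
#' the whole-blood effect size of a spike is attenuated by the subtype's
#' proportion — the detection problem the REO method addresses.
#'
#' Default Dirichlet concentrations encode typical healthy leukocyte
#' proportions (neutrophils ~0.55, T cells ~0.20, monocytes and B cells
#' ~0.08, NK ~0.06, eosinophils ~0.03) at total concentration 50.
#'
#' @param n_features number of miRNA features (default 300)
#' @param subtypes named integer vector: purified samples per subtype
#' @param n_markers_per_subtype markers boosted per subtype (default 10)
#' @param marker_boost marker boost in log2 units (default 3, i.e. 8-fold)
#' @param base_mean baseline log2 mean intensity (default 7)
#' @param base_profile_sd spread of baseline feature means, log2 (default 2)
#' @param noise_sd log2 measurement noise SD (default 0.25)
#' @param dirichlet_alpha_healthy,dirichlet_alpha_disease positive vectors,
#'   one entry per subtype
#' @param spike_set `NULL`, or a data.frame with columns `feature`,
#'   `subtype`, `log2_shift` (one row per feature-subtype spike)
#' @param n_healthy,n_disease whole-blood sample counts (default 100 each)
#' @param seed integer seed
#' @return a validated config (list of class `"SyntheticConfig"`)
#' @export
syntheticConfig <- function(
    n_features = 300L,
    subtypes = c(Monocytes = 5L, Neutrophils = 5L, Eosinophils = 5L,
                 Bcells = 5L, Tcells = 5L, NKcells = 5L),
    n_markers_per_subtype = 10L,
    marker_boost = 3,
    base_mean = 7,
    base_profile_sd = 2,
    noise_sd = 0.25,
    dirichlet_alpha_healthy = 50 * c(0.08, 0.55, 0.03, 0.08, 0.20, 0.06),
    dirichlet_alpha_disease = dirichlet_alpha_healthy,
    spike_set = NULL,
    n_healthy = 100L,
    n_disease = 100L,
    seed = 1L) {
  stopifnot(n_features >= 2L, length(subtypes) >= 2L,
            !is.null(names(subtypes)), all(subtypes >= 1L),
            n_markers_per_subtype >= 0L, marker_boost > 0,
            base_profile_sd > 0, noise_sd >= 0,
            n_healthy >= 1L, n_disease >= 1L)
  if (length(dirichlet_alpha_healthy) != length(subtypes) ||
      length(dirichlet_alpha_disease) != length(subtypes))
    stop("Dirichlet alpha vectors need one entry per subtype")
  if (any(dirichlet_alpha_healthy <= 0) || any(dirichlet_alpha_disease <= 0))
    stop("Dirichlet alphas must be positive")
  if (n_markers_per_subtype * length(subtypes) > n_features)
    stop("markers per subtype x subtypes exceeds the feature count")
  if (!is.null(spike_set)) {
    spike_set <- as.data.frame(spike_set, stringsAsFactors = FALSE)
    if (!all(c("feature", "subtype", "log2_shift") %in% colnames(spike_set)))
      stop("spike_set needs columns feature, subtype, log2_shift")
    bad <- setdiff(spike_set$subtype, names(subtypes))
    if (length(bad))
      stop("spike_set references unknown subtype(s): ",
           paste(unique(bad), collapse = ", "))
  }
  structure(list(
    n_features = as.integer(n_features), subtypes = subtypes,
    n_markers_per_subtype = as.integer(n_markers_per_subtype),
    marker_boost = marker_boost, base_mean = base_mean,
    base_profile_sd = base_profile_sd, noise_sd = noise_sd,
    dirichlet_alpha_healthy = dirichlet_alpha_healthy,
    dirichlet_alpha_disease = dirichlet_alpha_disease,
    spike_set = spike_set, n_healthy = as.integer(n_healthy),
    n_disease = as.integer(n_disease), seed = as.integer(seed)),
    class = "SyntheticConfig")
}

.featureIds <- function(n) sprintf("miR-%04d", seq_len(n))

#' Generate purified leukocyte subtype profiles
#'
#' Draws one log2 base profile per subtype (shared baseline plus the
#' subtype's marker boost) and then per-sample Gaussian log2 noise. Marker
#' features are assigned to subtypes at random without overlap. Spiked
#' features named in `cfg$spike_set` are excluded from marker assignment
#' so intracellular disease effects never ride on composition markers.
#'
#' @param cfg a [syntheticConfig()]
#' @param datasetId dataset label for the annotation
#' @param seed seed for this draw (defaults to `cfg$seed`)
#' @param truth optional [SyntheticTruth-class] from a previous call: reuse
#'   its base profiles and marker assignment and draw only new measurement
#'   noise, emulating an independent purified-leukocyte dataset of the same
#'   underlying biology
#' @return list with `expr` (a [MirnaExpressionSet-class], log2 scale,
#'   subtype labels in `colData$group`) and `truth` (a
#'   [SyntheticTruth-class])
#' @export
generateLeukocyteProfiles <- function(cfg, datasetId = "synthetic_leukocytes",
                                      seed = cfg$seed, truth = NULL) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  set.seed(as.integer(seed))
  f <- cfg$n_features
  ids <- .featureIds(f)
  subtypes <- names(cfg$subtypes)
  if (!is.null(truth)) {
    stopifnot(is(truth, "SyntheticTruth"),
              identical(dim(truth@profiles),
                        c(f, length(subtypes))))
    profiles <- truth@profiles
    markers <- truth@markers
  } else {
    base <- stats::rnorm(f, cfg$base_mean, cfg$base_profile_sd)
    profiles <- matrix(base, f, length(subtypes),
                       dimnames = list(ids, subtypes))
    spiked <- if (!is.null(cfg$spike_set)) unique(cfg$spike_set$feature)
    else character()
    pool <- sample(setdiff(ids, spiked))
    n_mark <- cfg$n_markers_per_subtype
    if (n_mark * length(subtypes) > length(pool))
      stop("not enough non-spiked features to assign markers")
    markers <- lapply(seq_along(subtypes), function(i)
      pool[seq.int((i - 1L) * n_mark + 1L, length.out = n_mark)])
    names(markers) <- subtypes
    for (s in subtypes)
      profiles[markers[[s]], s] <- profiles[markers[[s]], s] +
        cfg$marker_boost
  }

  counts <- cfg$subtypes
  group <- rep(subtypes, counts)
  vals <- profiles[, group, drop = FALSE] +
    stats::rnorm(f * length(group), 0, cfg$noise_sd)
  colnames(vals) <- sprintf("%s_%s_%02d", datasetId, group,
                            sequence(unname(counts)))
  expr <- MirnaExpressionSet(vals, scale = "log2", group = group,
                             datasetId = datasetId)
  spikes <- if (!is.null(cfg$spike_set))
    S4Vectors::DataFrame(cfg$spike_set)
  else S4Vectors::DataFrame(feature = character(), subtype = character(),
                            log2_shift = numeric())
  truth <- new("SyntheticTruth", profiles = profiles, markers = markers,
               proportions = matrix(numeric(), 0, length(subtypes),
                                    dimnames = list(NULL, subtypes)),
               spikes = spikes, seed = as.integer(seed))
  list(expr = expr, truth = truth)
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  g / rowSums(g)
}

#' Generate whole-blood mixture samples
#'
#' Each sample draws mixing proportions from its group's Dirichlet prior;
#' linear-scale expression is the proportion-weighted sum of the
#' linear-scale subtype profiles. In disease samples, spike shifts are
#' applied multiplicatively to the affected subtypes' contributions
#' *before* mixing (so a spike's whole-blood effect is scaled by the
#' subtype's proportion). Gaussian log2 noise is added after mixing and
#' the result returned on the log2 scale.
#'
#' @param truth a [SyntheticTruth-class] from [generateLeukocyteProfiles()]
#' @param cfg the same [syntheticConfig()]
#' @param seed seed for this draw (defaults to `cfg$seed + 1`)
#' @return list with `expr` (log2 [MirnaExpressionSet-class], groups
#'   `healthy`/`disease`) and `truth` (input truth with proportions and
#'   spikes recorded)
#' @export
generateWholeBlood <- function(truth, cfg, seed = cfg$seed + 1L) {
  stopifnot(is(truth, "SyntheticTruth"), inherits(cfg, "SyntheticConfig"))
  set.seed(as.integer(seed))
  profiles <- truth@profiles
  subtypes <- colnames(profiles)
  lin <- 2^profiles
  lin_spiked <- lin
  if (!is.null(cfg$spike_set) && nrow(cfg$spike_set)) {
    sp <- cfg$spike_set
    bad <- setdiff(sp$feature, rownames(profiles))
    if (length(bad))
      stop("spike references unknown feature(s): ", paste(bad, collapse = ", "))
    for (i in seq_len(nrow(sp)))
      lin_spiked[sp$feature[i], sp$subtype[i]] <-
        lin_spiked[sp$feature[i], sp$subtype[i]] * 2^sp$log2_shift[i]
  }
  props_h <- .rdirichlet(cfg$n_healthy, cfg$dirichlet_alpha_healthy)
  props_d <- .rdirichlet(cfg$n_disease, cfg$dirichlet_alpha_disease)
  mix_h <- lin %*% t(props_h)
  mix_d <- lin_spiked %*% t(props_d)
  vals <- log2(cbind(mix_h, mix_d)) +
    stats::rnorm(nrow(profiles) * (cfg$n_healthy + cfg$n_disease),
                 0, cfg$noise_sd)
  rownames(vals) <- rownames(profiles)
  colnames(vals) <- c(sprintf("H_%03d", seq_len(cfg$n_healthy)),
                      sprintf("D_%03d", seq_len(cfg$n_disease)))
  group <- rep(c("healthy", "disease"), c(cfg$n_healthy, cfg$n_disease))
  expr <- MirnaExpressionSet(vals, scale = "log2", group = group,
                             datasetId = "synthetic_blood")
  props <- rbind(props_h, props_d)
  dimnames(props) <- list(colnames(vals), subtypes)
  truth@proportions <- props
  if (!is.null(cfg$spike_set))
    truth@spikes <- S4Vectors::DataFrame(cfg$spike_set)
  validObject(truth)
  list(expr = expr, truth = truth)
}

#' Score recovery of spiked miRNAs
#'
#' Compares an extracted differential-miRNA table against the simulator's
#' ground truth: sensitivity (spiked features extracted at
#' `q_value <= q_max`), false-discovery proportion (extracted features not
#' spiked), and direction accuracy among true positives (expected
#' direction = sign of the feature's total log2 spike shift).
#'
#' @param de `DataFrame` from [extractDeMirnas()]
#' @param truth a [SyntheticTruth-class]
#' @param q_max q-value cutoff defining the reported set (default 0.05)
#' @return list: `sensitivity`, `fdp`, `direction_accuracy`,
#'   `n_extracted`, `n_spiked`
#' @export
evaluateRecovery <- function(de, truth, q_max = 0.05) {
  sp <- truth@spikes
  spiked <- unique(sp$feature)
  expected <- vapply(spiked, function(f)
    sign(sum(sp$log2_shift[sp$feature == f])), numeric(1))
  hits <- de[de$q_value <= q_max, , drop = FALSE]
  tp <- intersect(hits$mirna, spiked)
  sens <- if (length(spiked)) length(tp) / length(spiked) else NA_real_
  fdp <- if (nrow(hits)) sum(!hits$mirna %in% spiked) / nrow(hits) else 0
  dir_acc <- if (length(tp))
    mean(hits$direction[match(tp, hits$mirna)] == expected[tp])
  else NA_real_
  list(sensitivity = sens, fdp = fdp, direction_accuracy = dir_acc,
       n_extracted = nrow(hits), n_spiked = length(spiked))
}
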