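# Shared fixtures. Everything is generated in code; the heavier cohort runs
# are cached per seed in an environment so several test files can reuse them.

# a small block-structured connectivity matrix: `nets` networks of size
# `per`, within-network correlation `w`, between `b`, plus optional noise
block_connectivity <- function(nets = 3L, per = 5L, w = 0.6, b = 0.05,
                               noise_dof = NULL, seed = 1L) {
  parc <- make_parcellation(setNames(rep(per, nets), LETTERS[seq_len(nets)]))
  P <- nets * per
  labs <- parc$network_labels
  sigma <- matrix(b, P, P)
  for (nw in unique(labs)) sigma[labs == nw, labs == nw] <- w
  diag(sigma) <- 1
  if (!is.null(noise_dof)) {
    set.seed(seed)
    s <- stats::rWishart(1L, noise_dof, sigma)[, , 1L] / noise_dof
    sigma <- stats::cov2cor(s)
  }
  connectivity_matrix(sigma, parc)
}

# a small noisy timeseries with planted correlation structure
toy_timeseries <- function(n = 200L, P = 6L, tr = 0.8, seed = 1L) {
  set.seed(seed)
  shared <- rnorm(n)
  x <- sapply(seq_len(P), function(j) 0.5 * shared + rnorm(n))
  colnames(x) <- paste0("p", seq_len(P))
  parcel_timeseries(x, tr = tr)
}

# embedding settings used by simulation-heavy tests: small dims, short walks
desk_embedding <- function(dims = 8L, seed = 1L)
  embedding_config(dims = dims, walk_length = 30L, walks_per_node = 4L,
                   window = 4L, negatives = 4L, epochs = 2L, seed = seed)

# reduced GBT candidate grid used by the simulation suites (the full
# 36-setting grid is exercised separately on its own contracts)
desk_gbt_grid <- function()
  expand.grid(nrounds = c(50, 100), eta = c(0.05, 0.10), max_depth = 3,
              lambda = 1, KEEP.OUT.ATTRS = FALSE)

# the study-condition synthetic cohort: n = 400 per arm, P = 90, d = 8, with
# one null facet, two planted linear couplings (population R^2 = 0.1, 0.25)
# and one facet whose coupling grows from baseline (r = 0.1) to year 2
# (r = 0.5). Prepared cohorts are cached per seed across test files.
.desk_cache <- new.env(parent = emptyenv())

desk_cohort <- function(seed) {
  key <- paste0("cohort", seed)
  if (!is.null(.desk_cache[[key]])) return(.desk_cache[[key]])
  cfg <- cohort_config(n_subjects = 800L, seed = seed)
  effs <- list(
    effect_spec("intent", "DMN", 0),
    effect_spec("access", "FP", sqrt(0.1)),
    effect_spec("fdhx", "CO", 0.5),
    effect_spec("upps", "SM", 0.1, multipliers = c(baseline = 1, year2 = 5)))
  coh <- generate_cohort(cfg, effs)
  cc <- prepare_cpm_cohort(coh, desk_embedding(seed = seed))
  .desk_cache[[key]] <- cc
  cc
}

# confirmation r for one facet/timing/family on the desk cohort; the boosted
# trees use coarse histogram splits and 2 inner folds at this scale
desk_confirmation_r <- function(seed, facet, timing = "baseline",
                                family = "RIDGE") {
  key <- paste0("r", seed, facet, timing, family)
  if (!is.null(.desk_cache[[key]])) return(.desk_cache[[key]])
  cc <- desk_cohort(seed)
  cand <- NULL
  cvc <- cv_config(seed = seed)
  if (family == "GBT") {
    cand <- desk_gbt_grid()
    cvc <- cv_config(inner_k = 2L, seed = seed)
    old <- options(neurocpm.gbt = list(tree_method = "hist", max_bin = 16L))
    on.exit(options(old))
  }
  sr <- suppressWarnings(run_specification(
    cc, facet, timing, confirmation_arm = 2L, family = family,
    cv_cfg = cvc, candidates = cand))
  .desk_cache[[key]] <- sr$result$r
  sr$result$r
}
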