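# From per-subject connectivity to a modeling-ready cohort: reference
# embedding, aligned per-subject embeddings, winsorized outcomes, covariates
# and the assembled feature matrix.

#' Embed every subject in a cohort
#'
#' Trains the group reference on the mean connectivity, then embeds every
#' subject warm-started from the reference and Procrustes-aligned to it.
#' Each subject gets its own seed stream derived from the config seed and the
#' subject id.
#'
#' @param conns named list of `connectivity_matrix` per subject.
#' @param cfg an `embedding_config`.
#' @param negative_policy passed to [to_walk_graph()].
#' @return list: `reference` (a `reference_embedding`), `embeddings` (named
#'   list of aligned `node_embedding`s).
#' @export
embed_cohort <- function(conns, cfg = embedding_config(),
                         negative_policy = "zero") {
  ref <- build_reference(group_mean_connectivity(conns), cfg)
  embeddings <- lapply(names(conns), function(s) {
    scfg <- cfg
    scfg$seed <- derive_seed(cfg$seed, paste0("embed:", s))
    embed_connectivity(conns[[s]], scfg, ref = ref,
                       negative_policy = negative_policy)
  })
  names(embeddings) <- names(conns)
  list(reference = ref, embeddings = embeddings)
}

#' Winsorized facet outcomes for a cohort
#'
#' Computes every facet composite (mean of items) and the impulsivity total
#' at both timepoints from the cohort's item tables and winsorizes each at
#' `winsor_z` standard deviations.
#'
#' @param items list with `$baseline` and `$year2` item tables.
#' @param spec a `composite_spec`.
#' @param facets facet names to compute (any of the spec's facets plus
#'   `"upps"` when the item tables carry the impulsivity items).
#' @return nested named list `outcomes[[facet]][[timepoint]]` of winsorized
#'   `phenotype_vector`s.
#' @export
compute_outcomes <- function(items, spec = load_composite_spec(),
                             facets = NULL) {
  if (is.null(facets)) {
    facets <- Filter(function(fac)
      all(facet_items(spec, fac) %in% names(items$baseline)),
      names(spec$facets))
    if (all(spec$upps_items %in% names(items$baseline)))
      facets <- c(facets, "upps")
  }
  out <- list()
  for (facet in facets) {
    out[[facet]] <- list()
    for (tp in c("baseline", "year2")) {
      tab <- items[[tp]]
      pv <- if (facet == "upps") upps_total(tab, spec, tp)
      else compute_composite(tab, spec, facet, tp)
      out[[facet]][[tp]] <- winsorize(pv, spec$winsor_z)
    }
  }
  out
}

#' Prepare a synthetic cohort for predictive modeling
#'
#' One call from generator output to `cpm_cohort`: embed all subjects
#' (reference + warm start + alignment), compute winsorized outcomes, encode
#' demographics, and assemble the requested feature set.
#'
#' @param cohort a `synthetic_cohort` in connectivity mode (or any list with
#'   `conns`, `items`, `demographics`, `arms`, `parcellation`).
#' @param emb_cfg an `embedding_config`.
#' @param feature_set passed to [assemble_features()].
#' @param spec a `composite_spec`.
#' @return a `cpm_cohort`.
#' @export
prepare_cpm_cohort <- function(cohort, emb_cfg = embedding_config(),
                               feature_set = "embeddings",
                               spec = load_composite_spec()) {
  if (is.null(cohort$conns))
    stop("cohort has no connectivity matrices; preprocess timeseries first")
  emb <- embed_cohort(cohort$conns, emb_cfg)
  facets <- if (!is.null(cohort$effects))
    vapply(cohort$effects, `[[`, "", "facet") else NULL
  outcomes <- compute_outcomes(cohort$items, spec, facets)
  covariates <- encode_demographics(cohort$demographics)
  features <- assemble_features(embeddings = emb$embeddings,
                                covariates = covariates,
                                feature_set = feature_set,
                                conns = cohort$conns,
                                parcellation = cohort$parcellation)
  cpm_cohort(features, outcomes, cohort$arms, cohort$parcellation)
}
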