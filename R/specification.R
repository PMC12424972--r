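# One modeling specification: outcome x timing x confirmation arm x family.

#' Train a connectome predictive model on a discovery sample
#'
#' Discovery-only pipeline: fit the robust scaler, select the top-k features
#' by univariate F statistic, run the nested cross-validated grid search, and
#' fit the final model with the averaged hyperparameters on the full
#' discovery sample. Nothing here sees confirmation rows.
#'
#' @param features a `feature_matrix` over all subjects.
#' @param outcome a `phenotype_vector` (winsorized scores).
#' @param discovery_subjects subject ids forming the discovery sample.
#' @param family `"PLSR"`, `"RIDGE"` or `"GBT"`.
#' @param k features to select (default 1000).
#' @param cfg a `cv_config`.
#' @param candidates optional hyperparameter grid override.
#' @return An object of class `cpm_model`: `family`, `hyper`, `fit`,
#'   `scaler`, `selected` (column indices), `meta` (selected-column
#'   provenance), `winners`, `discovery_subjects`.
#' @export
train_cpm_model <- function(features, outcome, discovery_subjects, family,
                            k = 1000L, cfg = cv_config(), candidates = NULL) {
  rows <- match(discovery_subjects, features$subject)
  if (anyNA(rows)) stop("discovery subjects missing from the feature matrix")
  y <- outcome$score[match(discovery_subjects, outcome$subject)]
  keep <- !is.na(y)
  X <- features$values[rows[keep], , drop = FALSE]
  y <- y[keep]
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(X, scaler)
  selected <- select_top_k(Xs, y, k)
  Xsel <- Xs[, selected, drop = FALSE]
  search <- nested_cv(Xsel, y, family, cfg, candidates)
  fit <- fit_final(Xsel, y, family, search$hyper)
  structure(list(family = family, hyper = search$hyper, fit = fit,
                 scaler = scaler, selected = as.integer(selected),
                 meta = features$meta[selected, , drop = FALSE],
                 winners = search$winners,
                 discovery_subjects = discovery_subjects[keep]),
            class = "cpm_model")
}

#' A cohort ready for the specification grid
#'
#' Bundles the assembled feature matrix, the winsorized outcomes (one
#' `phenotype_vector` per facet x timepoint), the arm assignment and the
#' parcellation.
#'
#' @param features a `feature_matrix`.
#' @param outcomes nested named list: `outcomes[[facet]][[timepoint]]` is a
#'   `phenotype_vector`.
#' @param arms named integer vector (1 or 2) over the feature-matrix subjects.
#' @param parcellation a `parcellation`.
#' @return An object of class `cpm_cohort`.
#' @export
cpm_cohort <- function(features, outcomes, arms, parcellation = NULL) {
  if (!all(features$subject %in% names(arms)))
    stop("every subject needs an arm label")
  if (!all(arms[features$subject] %in% c(1L, 2L)))
    stop("arm labels must be 1 or 2")
  structure(list(features = features, outcomes = outcomes,
                 arms = arms[features$subject], parcellation = parcellation),
            class = "cpm_cohort")
}

#' Run one modeling specification
#'
#' Executes scale -> select -> nested CV -> final fit on the discovery arm
#' (the arm that is not the confirmation arm) and evaluates on the
#' confirmation arm.
#'
#' @param cohort a `cpm_cohort`.
#' @param outcome facet name (must exist in `cohort$outcomes`).
#' @param timing `"baseline"` or `"year2"`.
#' @param confirmation_arm 1 or 2.
#' @param family model family.
#' @param k top-k features (default 1000).
#' @param cv_cfg a `cv_config`; its seed is combined with the specification id
#'   so every cell has its own reproducible stream.
#' @param candidates optional hyperparameter grid override.
#' @return An object of class `specification_result`: the design cell, a
#'   `prediction_result`, sample sizes, the network importance tally and the
#'   trained `cpm_model`.
#' @export
run_specification <- function(cohort, outcome, timing, confirmation_arm,
                              family, k = 1000L, cv_cfg = cv_config(),
                              candidates = NULL) {
  pv <- cohort$outcomes[[outcome]][[timing]]
  if (is.null(pv)) stop("no outcome '", outcome, "' at timepoint '", timing, "'")
  confirmation_arm <- as.integer(confirmation_arm)
  spec_id <- paste(outcome, timing, confirmation_arm, family, sep = "|")
  cv_cfg$seed <- derive_seed(cv_cfg$seed, spec_id)
  subjects <- cohort$features$subject
  disc <- subjects[cohort$arms != confirmation_arm]
  conf <- subjects[cohort$arms == confirmation_arm]
  model <- train_cpm_model(cohort$features, pv, disc, family, k, cv_cfg,
                           candidates)
  conf_rows <- match(conf, subjects)
  y_conf <- pv$score[match(conf, pv$subject)]
  res <- evaluate(model, cohort$features$values[conf_rows, , drop = FALSE],
                  y_conf)
  tally <- if (!is.null(cohort$parcellation))
    feature_importance_networks(model, cohort$parcellation) else NULL
  structure(list(outcome = outcome, timing = timing,
                 confirmation_arm = confirmation_arm, family = family,
                 result = res, n_discovery = length(model$discovery_subjects),
                 n_confirmation = res$n, network_importance = tally,
                 seed = cv_cfg$seed, model = model),
            class = "specification_result")
}

#' @export
print.specification_result <- function(x, ...) {
  cat(sprintf("%s @ %s, confirmation arm %d, %s: %s\n", x$outcome, x$timing,
              x$confirmation_arm, x$family,
              format_r_percent(x$result$r)))
  invisible(x)
}

#' Network-level feature importance
#'
#' Maps every selected feature back to the parcellation: embedding-dimension
#' features count toward the network of their parcel; connectivity-edge
#' features contribute half a count to each endpoint's network; demographic
#' covariates are tallied under `"covariate"`. Counts sum to the number of
#' selected features.
#'
#' @param model a `cpm_model`.
#' @param parcellation a `parcellation`.
#' @return named numeric vector of per-network counts (plus `covariate`).
#' @export
feature_importance_networks <- function(model, parcellation) {
  meta <- model$meta
  networks <- unique(parcellation$network_labels)
  counts <- setNames(numeric(length(networks) + 1L), c(networks, "covariate"))
  net_of <- setNames(parcellation$network_labels, parcellation$parcel_ids)
  for (row in seq_len(nrow(meta))) {
    type <- meta$type[row]
    if (type == "embedding") {
      counts[net_of[[meta$parcel[row]]]] <- counts[net_of[[meta$parcel[row]]]] + 1
    } else if (type %in% c("observed_edge", "implied_edge")) {
      ni <- parcellation$network_labels[meta$i[row]]
      nj <- parcellation$network_labels[meta$j[row]]
      counts[ni] <- counts[ni] + 0.5
      counts[nj] <- counts[nj] + 0.5
    } else {
      counts["covariate"] <- counts["covariate"] + 1
    }
  }
  counts
}
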