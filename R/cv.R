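# Nested cross-validation: inner grid search per outer fold, winners averaged
# into one final setting, final model fit on the full discovery sample.

#' Cross-validation configuration
#' @param outer_k outer folds (default 5).
#' @param inner_k inner folds (default 5).
#' @param seed integer seed for fold shuffling.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(outer_k = 5L, inner_k = 5L, seed = 1L) {
  if (outer_k < 2L || inner_k < 2L) stop("fold counts must be >= 2")
  structure(list(outer_k = as.integer(outer_k), inner_k = as.integer(inner_k),
                 seed = as.integer(seed)),
            class = "cv_config")
}

# run expr under a temporary RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# shuffled, balanced fold labels 1..k for n rows
.fold_labels <- function(n, k, seed) {
  .with_seed(seed, sample(rep_len(seq_len(k), n)))
}

.mse <- function(pred, obs) mean((pred - obs)^2)

# inner-fold mean MSE for every candidate; fast all-candidate paths for the
# linear families, per-candidate fits for GBT
.inner_search <- function(X, y, family, candidates, inner_k, seed) {
  folds <- .fold_labels(nrow(X), inner_k, seed)
  mse <- matrix(NA_real_, inner_k, nrow(candidates))
  for (f in seq_len(inner_k)) {
    tr <- folds != f; va <- !tr
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xva <- X[va, , drop = FALSE]; yva <- y[va]
    if (family == "RIDGE") {
      rp <- .ridge_path(Xtr, ytr, candidates$lambda)
      pred <- Xva %*% rp$coefs
      mse[f, ] <- colMeans((sweep(pred, 2, rp$intercepts, "+") - yva)^2)
    } else if (family == "PLSR") {
      s <- .simpls(Xtr, ytr, max(candidates$ncomp))
      pred <- Xva %*% s$coefs
      pred <- sweep(pred, 2, s$intercepts[seq_len(ncol(pred))], "+")
      avail <- pmin(pmax(candidates$ncomp, 1L), max(1L, s$ncomp))
      mse[f, ] <- vapply(seq_len(nrow(candidates)), function(ci)
        .mse(pred[, avail[ci]], yva), numeric(1))
    } else {
      # one booster per (eta, depth, lambda) group, evaluated at every
      # candidate tree count via iteration ranges
      key <- paste(candidates$eta, candidates$max_depth, candidates$lambda)
      dtrain <- xgboost::xgb.DMatrix(Xtr, label = ytr, nthread = 1L)
      dval <- xgboost::xgb.DMatrix(Xva, nthread = 1L)
      for (kg in unique(key)) {
        rows <- which(key == kg)
        h <- candidates[rows[1L], ]
        booster <- xgboost::xgb.train(
          params = c(list(objective = "reg:squarederror", eta = h$eta,
                          max_depth = as.integer(h$max_depth),
                          lambda = h$lambda, nthread = 1L, seed = 0),
                     .gbt_opts()),
          data = dtrain, nrounds = max(candidates$nrounds[rows]), verbose = 0)
        for (ci in rows) {
          pred <- predict(booster, dval,
                          iterationrange = c(1L, candidates$nrounds[ci]))
          mse[f, ci] <- .mse(pred, yva)
        }
      }
    }
  }
  colMeans(mse)
}

#' Nested cross-validated hyperparameter search
#'
#' For each outer fold, an inner K-fold grid search over the family's
#' candidates picks the setting minimizing mean inner-fold MSE on the outer
#' training portion; the winning settings from all outer folds are then
#' averaged into the final setting ([average_hyperparameters()]).
#'
#' @param X numeric matrix (scaled, selected discovery features).
#' @param y numeric outcome (no missing values; must vary within folds).
#' @param family `"PLSR"`, `"RIDGE"` or `"GBT"`.
#' @param cfg a `cv_config`.
#' @param candidates optional candidate grid; default [grid_candidates()] for
#'   the family.
#' @return list: `hyper` (final averaged setting), `winners` (per-outer-fold
#'   winning rows), `candidates`.
#' @export
nested_cv <- function(X, y, family, cfg = cv_config(), candidates = NULL) {
  if (anyNA(y)) stop("y must have no missing values")
  if (is.null(candidates)) candidates <- grid_candidates(family)
  n <- nrow(X)
  if (n < cfg$outer_k * cfg$inner_k)
    stop("too few rows for the requested nested fold structure")
  outer <- .fold_labels(n, cfg$outer_k, cfg$seed)
  winners <- vector("list", cfg$outer_k)
  for (f in seq_len(cfg$outer_k)) {
    tr <- outer != f
    ytr <- y[tr]
    if (sd(ytr) == 0) stop("outer training fold has zero-variance y")
    mean_mse <- .inner_search(X[tr, , drop = FALSE], ytr, family, candidates,
                              cfg$inner_k, cfg$seed + f)
    winners[[f]] <- candidates[which.min(mean_mse), , drop = FALSE]
  }
  winners <- do.call(rbind, winners)
  list(hyper = average_hyperparameters(winners, family, candidates),
       winners = winners, candidates = candidates)
}

# round half away from zero (R's round() is round-half-even)
.round_half_up <- function(x) trunc(x + 0.5 * sign(x))

#' Average per-fold winning hyperparameters into one final setting
#'
#' Integer-valued hyperparameters (components, depth, estimator count) are
#' averaged and rounded half away from zero; l2 penalties are averaged in
#' log10 space; the GBT learning rate is averaged then snapped to the nearest
#' grid value.
#'
#' @param winners data frame of winning settings, one row per outer fold.
#' @param family model family.
#' @param candidates the candidate grid (supplies snap targets).
#' @return named list: the final hyperparameter setting.
#' @export
average_hyperparameters <- function(winners, family, candidates = NULL) {
  if (is.null(candidates)) candidates <- grid_candidates(family)
  switch(family,
    PLSR = list(ncomp = .round_half_up(mean(winners$ncomp))),
    RIDGE = list(lambda = 10^mean(log10(winners$lambda))),
    GBT = {
      etas <- sort(unique(candidates$eta))
      eta_bar <- mean(winners$eta)
      list(nrounds = .round_half_up(mean(winners$nrounds)),
           eta = etas[which.min(abs(etas - eta_bar))],
           max_depth = .round_half_up(mean(winners$max_depth)),
           lambda = 10^mean(log10(winners$lambda)))
    },
    stop("unknown model family: ", family))
}

#' Fit the final model on the full discovery sample
#'
#' @param X scaled, selected discovery features.
#' @param y discovery outcome.
#' @param family model family.
#' @param hyper final hyperparameters (e.g. from [nested_cv()]).
#' @return a `fitted_family_model`.
#' @export
fit_final <- function(X, y, family, hyper) fit_model(X, y, family, hyper)

#' Evaluate a trained model on the confirmation arm
#'
#' Applies the scaler and feature selection stored with the model (both fit on
#' discovery only), predicts the confirmation outcomes, and reports the signed
#' Pearson correlation r between predictions and observations, r^2 and
#' 100 r^2. Subjects with missing outcomes are dropped pairwise; degenerate
#' (zero-variance) predictions are recorded as r = 0 with a flag.
#'
#' @param model a `cpm_model` (from [run_specification()] /
#'   [train_cpm_model()]).
#' @param X_raw unscaled confirmation feature matrix (all columns).
#' @param y confirmation outcomes (may contain NA).
#' @return An object of class `prediction_result`: `r`, `r2`, `percent`,
#'   `predictions`, `n`, `degenerate`.
#' @export
evaluate <- function(model, X_raw, y) {
  Xs <- apply_scaler(X_raw, model$scaler)[, model$selected, drop = FALSE]
  pred <- predict(model$fit, Xs)
  keep <- !is.na(y)
  n <- sum(keep)
  degenerate <- sd(pred[keep]) == 0 || sd(y[keep]) == 0
  r <- if (degenerate) 0 else cor(pred[keep], y[keep])
  structure(list(r = r, r2 = r * r, percent = 100 * r * r, predictions = pred,
                 n = n, n_dropped = sum(!keep), degenerate = degenerate),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result: r = %.3f (%.2f%%), n = %d%s\n", x$r,
              x$percent, x$n, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
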