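# Model families: partial least squares (SIMPLS), ridge with unpenalized
# intercept, and gradient boosted trees (xgboost). Each family exposes a
# hyperparameter grid, a fit and a predict path; linear families also expose
# fast all-candidates CV paths used by the nested search.

#' Hyperparameter grid for a model family
#'
#' PLSR: number of components 1..10. RIDGE: 20 l2 penalties spanning 1e-6 to
#' 1e6, spaced geometrically (linear in log10) by default; `ridge_spacing =
#' "linear"` gives literal linear spacing. GBT: estimators {100, 200} x
#' learning rate {0.01, 0.05, 0.10} x max depth {3, 5} x l2 penalty
#' {1, 10, 100} (36 settings).
#'
#' @param family `"PLSR"`, `"RIDGE"` or `"GBT"`.
#' @param ridge_spacing `"log"` (default) or `"linear"`.
#' @return data frame, one row per candidate setting.
#' @export
grid_candidates <- function(family = c("PLSR", "RIDGE", "GBT"),
                            ridge_spacing = c("log", "linear")) {
  family <- match.arg(family)
  ridge_spacing <- match.arg(ridge_spacing)
  switch(family,
    PLSR = data.frame(ncomp = 1:10),
    RIDGE = data.frame(lambda = if (ridge_spacing == "log")
      10^seq(-6, 6, length.out = 20) else seq(1e-6, 1e6, length.out = 20)),
    GBT = expand.grid(nrounds = c(100, 200), eta = c(0.01, 0.05, 0.10),
                      max_depth = c(3, 5), lambda = c(1, 10, 100),
                      KEEP.OUT.ATTRS = FALSE))
}

# ---- SIMPLS partial least squares ----------------------------------------

# de Jong's SIMPLS on centered data; returns coefficients for every component
# count 1..ncomp so one fit serves the whole candidate path.
.simpls <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm, "-"); yc <- y - ym
  ncomp <- min(ncomp, n - 1L, p)
  s <- crossprod(Xc, yc)            # p x 1
  R <- matrix(0, p, ncomp)          # weights
  P <- matrix(0, p, ncomp)          # loadings
  Q <- numeric(ncomp)
  V <- matrix(0, p, ncomp)          # orthonormalized loadings
  for (a in seq_len(ncomp)) {
    r <- s
    t_score <- Xc %*% r
    t_score <- t_score - mean(t_score)
    normt <- sqrt(sum(t_score^2))
    if (normt < 1e-12) { ncomp <- a - 1L; break }
    t_score <- t_score / normt
    r <- r / normt
    p_load <- crossprod(Xc, t_score)
    q_load <- sum(yc * t_score)
    v <- p_load
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p_load)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r; P[, a] <- p_load; Q[a] <- q_load; V[, a] <- v
  }
  if (ncomp == 0L)
    return(list(coefs = matrix(0, p, 1L), intercepts = ym, xmean = xm,
                ncomp = 0L))
  coefs <- vapply(seq_len(ncomp), function(a)
    as.numeric(R[, seq_len(a), drop = FALSE] %*% Q[seq_len(a)]),
    numeric(p))
  coefs <- matrix(coefs, nrow = p)
  intercepts <- ym - as.numeric(xm %*% coefs)
  list(coefs = coefs, intercepts = intercepts, xmean = xm, ncomp = ncomp)
}

# ---- ridge with unpenalized intercept ------------------------------------

# SVD path: coefficients for every lambda at once on centered data.
.ridge_path <- function(X, y, lambdas) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm, "-"); yc <- y - ym
  sv <- svd(Xc, nu = min(dim(Xc)), nv = min(dim(Xc)))
  uty <- crossprod(sv$u, yc)
  coefs <- vapply(lambdas, function(lam)
    as.numeric(sv$v %*% (sv$d / (sv$d^2 + lam) * uty)), numeric(ncol(X)))
  coefs <- matrix(coefs, nrow = ncol(X))
  intercepts <- ym - as.numeric(xm %*% coefs)
  list(coefs = coefs, intercepts = intercepts)
}

# booster engine settings (histogram splits); max_bin trades split
# resolution for speed and can be lowered via options(neurocpm.gbt = ...)
# for large simulation studies
.gbt_opts <- function() {
  opts <- getOption("neurocpm.gbt", NULL)
  if (is.null(opts)) opts <- list(tree_method = "hist", max_bin = 64L)
  opts
}

# ---- family fit / predict -------------------------------------------------

#' Fit one model with fixed hyperparameters
#'
#' @param X numeric matrix (scaled, selected discovery features).
#' @param y numeric outcome.
#' @param family `"PLSR"`, `"RIDGE"` or `"GBT"`.
#' @param hyper named list / one-row data frame of hyperparameters for the
#'   family (`ncomp`; `lambda`; `nrounds`, `eta`, `max_depth`, `lambda`).
#' @param nthread threads for GBT (default 1 for determinism).
#' @return An object of class `fitted_family_model`.
#' @export
fit_model <- function(X, y, family, hyper, nthread = 1L) {
  hyper <- as.list(hyper)
  fit <- switch(family,
    PLSR = {
      s <- .simpls(X, y, as.integer(hyper$ncomp))
      a <- max(1L, min(as.integer(hyper$ncomp), s$ncomp))
      if (s$ncomp == 0L) list(beta = s$coefs[, 1L], intercept = s$intercepts[1L])
      else list(beta = s$coefs[, a], intercept = s$intercepts[a])
    },
    RIDGE = {
      rp <- .ridge_path(X, y, hyper$lambda)
      list(beta = rp$coefs[, 1L], intercept = rp$intercepts[1L])
    },
    GBT = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = nthread)
      booster <- xgboost::xgb.train(
        params = c(list(objective = "reg:squarederror", eta = hyper$eta,
                        max_depth = as.integer(hyper$max_depth),
                        lambda = hyper$lambda, nthread = nthread, seed = 0),
                   .gbt_opts()),
        data = dtrain, nrounds = as.integer(hyper$nrounds), verbose = 0)
      list(booster_raw = xgboost::xgb.save.raw(booster))
    },
    stop("unknown model family: ", family))
  structure(list(family = family, hyper = hyper, fit = fit,
                 n_features = ncol(X)),
            class = "fitted_family_model")
}

#' Predict from a fitted family model
#' @param object a `fitted_family_model`.
#' @param newdata numeric matrix with the same columns as training.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.fitted_family_model <- function(object, newdata, ...) {
  if (ncol(newdata) != object$n_features)
    stop("newdata column count does not match the fitted model")
  if (object$family == "GBT") {
    booster <- xgboost::xgb.load.raw(object$fit$booster_raw)
    predict(booster, xgboost::xgb.DMatrix(newdata, nthread = 1L))
  } else {
    as.numeric(newdata %*% object$fit$beta) + object$fit$intercept
  }
}
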