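# Orchestration of the full specification grid and report formatting.

#' Enumerate the specification grid
#'
#' Full Cartesian product of outcomes x timings x confirmation arms x model
#' families in deterministic order (families fastest, outcomes slowest); the
#' reference design (4 outcomes x 2 timings x 2 arms x 3 families) gives 48
#' specifications.
#'
#' @param outcomes character vector of facet names.
#' @param timings character vector of timepoints.
#' @param arms integer vector of confirmation arms.
#' @param families character vector of model families.
#' @return data frame, one row per specification, with a `spec_id` column.
#' @export
enumerate_specifications <- function(outcomes = c("intent", "access", "fdhx", "upps"),
                                     timings = c("baseline", "year2"),
                                     arms = c(1L, 2L),
                                     families = c("PLSR", "RIDGE", "GBT")) {
  for (fac in list(outcomes, timings, arms, families)) {
    if (length(fac) == 0L) stop("every design factor must be non-empty")
    if (anyDuplicated(fac) > 0L) stop("duplicate entries in a design factor")
  }
  grid <- expand.grid(family = families, confirmation_arm = arms,
                      timing = timings, outcome = outcomes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("outcome", "timing", "confirmation_arm", "family")]
  grid$spec_id <- with(grid, paste(outcome, timing, confirmation_arm, family,
                                   sep = "|"))
  grid
}

# small stable polynomial hash of any R object (config fingerprinting);
# arithmetic kept below 2^31 so it stays exact in doubles
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261 %% 2147483647
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run every specification of the design grid
#'
#' Executes [run_specification()] for each cell. A failing cell records its
#' error and the run continues. When `out_dir` is given, per-spec results are
#' persisted and a rerun with an unchanged configuration reloads them instead
#' of recomputing (resumability keyed on a configuration hash).
#'
#' @param cohort a `cpm_cohort`.
#' @param specs specification grid (default [enumerate_specifications()]).
#' @param k top-k features.
#' @param cv_cfg a `cv_config` (global seed; per-spec streams are derived).
#' @param candidates optional named list of per-family grid overrides.
#' @param out_dir optional directory for per-spec result files and the
#'   summary CSV.
#' @return An object of class `results_table`: list of
#'   `specification_result`s (or error records) plus the summary data frame.
#' @export
run_all <- function(cohort, specs = enumerate_specifications(), k = 1000L,
                    cv_cfg = cv_config(), candidates = NULL, out_dir = NULL) {
  cfg_hash <- .config_hash(list(k = k, cv = unclass(cv_cfg),
                                candidates = candidates,
                                feature_set = cohort$features$feature_set))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  results <- vector("list", nrow(specs))
  names(results) <- specs$spec_id
  for (s in seq_len(nrow(specs))) {
    id <- specs$spec_id[s]
    cache <- if (!is.null(out_dir))
      file.path(out_dir, paste0(gsub("[^A-Za-z0-9]", "_", id), "_",
                                cfg_hash, ".rds")) else NULL
    if (!is.null(cache) && file.exists(cache)) {
      results[[s]] <- readRDS(cache)
      next
    }
    fam_cand <- if (!is.null(candidates)) candidates[[specs$family[s]]] else NULL
    results[[s]] <- tryCatch(
      run_specification(cohort, specs$outcome[s], specs$timing[s],
                        specs$confirmation_arm[s], specs$family[s],
                        k = k, cv_cfg = cv_cfg, candidates = fam_cand),
      error = function(e) structure(
        list(outcome = specs$outcome[s], timing = specs$timing[s],
             confirmation_arm = specs$confirmation_arm[s],
             family = specs$family[s], error = conditionMessage(e)),
        class = "specification_error"))
    if (!is.null(cache)) saveRDS(results[[s]], cache)
  }
  tab <- summarize_results(results, cv_cfg$seed)
  if (!is.null(out_dir))
    write.csv(tab, file.path(out_dir, "results.csv"), row.names = FALSE)
  structure(list(results = results, table = tab, config_hash = cfg_hash,
                 seed = cv_cfg$seed),
            class = "results_table")
}

#' Summarize specification results into one data frame
#' @param results list of `specification_result` / `specification_error`.
#' @param seed the global seed, recorded in every row.
#' @return data frame, one row per specification.
#' @export
summarize_results <- function(results, seed = NA_integer_) {
  do.call(rbind, lapply(results, function(x) {
    if (inherits(x, "specification_error"))
      data.frame(outcome = x$outcome, timing = x$timing,
                 confirmation_arm = x$confirmation_arm, family = x$family,
                 r = NA_real_, r2_percent = NA_real_,
                 n_discovery = NA_integer_, n_confirmation = NA_integer_,
                 seed = seed, status = paste("failed:", x$error))
    else
      data.frame(outcome = x$outcome, timing = x$timing,
                 confirmation_arm = x$confirmation_arm, family = x$family,
                 r = x$result$r, r2_percent = x$result$percent,
                 n_discovery = x$n_discovery, n_confirmation = x$n_confirmation,
                 seed = seed, status = "ok")
  }))
}

#' Format a correlation as "r (percent%)"
#'
#' The percent of variance is computed from the full-precision r and then
#' rounded for display, so e.g. r = 0.504 prints as "0.504 (25.40%)".
#'
#' @param r signed Pearson correlation.
#' @param digits_r decimals for r (default 3).
#' @param digits_pct decimals for the percent (default 2).
#' @return character scalar.
#' @export
format_r_percent <- function(r, digits_r = 3L, digits_pct = 2L) {
  sprintf(paste0("%.", digits_r, "f (%.", digits_pct, "f%%)"), r, 100 * r * r)
}

#' Render per-facet report blocks
#'
#' One block per outcome x timing with a family x confirmation-arm grid of
#' "r (percent%)" entries, mirroring the standard accuracy-table layout.
#'
#' @param tab results data frame (from [summarize_results()] or a
#'   `results_table`'s `$table`).
#' @param digits_r,digits_pct display precision.
#' @return character vector of report lines (also printed invisibly usable
#'   via `cat`).
#' @export
format_results <- function(tab, digits_r = 3L, digits_pct = 2L) {
  if (inherits(tab, "results_table")) tab <- tab$table
  lines <- character(0)
  for (oc in unique(tab$outcome)) for (tp in unique(tab$timing)) {
    sub <- tab[tab$outcome == oc & tab$timing == tp, , drop = FALSE]
    if (nrow(sub) == 0L) next
    lines <- c(lines, sprintf("== %s @ %s ==", oc, tp))
    for (fam in unique(sub$family)) {
      cells <- vapply(sort(unique(sub$confirmation_arm)), function(arm) {
        row <- sub[sub$family == fam & sub$confirmation_arm == arm, ]
        if (nrow(row) == 0L || is.na(row$r[1L])) "failed"
        else format_r_percent(row$r[1L], digits_r, digits_pct)
      }, character(1))
      lines <- c(lines, paste0(fam, "\t", paste(cells, collapse = "\t")))
    }
    lines <- c(lines, "")
  }
  lines
}

#' @export
print.results_table <- function(x, ...) {
  cat(format_results(x), sep = "\n")
  invisible(x)
}

#' Write network-importance companion tables
#' @param results a `results_table`.
#' @param path output CSV path (`network,count` rows per specification).
#' @export
write_network_importance <- function(results, path) {
  rows <- list()
  for (x in results$results) {
    if (!inherits(x, "specification_result") || is.null(x$network_importance))
      next
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = x$outcome, timing = x$timing,
      confirmation_arm = x$confirmation_arm, family = x$family,
      network = names(x$network_importance),
      count = as.numeric(x$network_importance))
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
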