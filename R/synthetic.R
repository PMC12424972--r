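# Synthetic cohorts with the statistical structure the pipeline assumes:
# block-covariance parcel signals with subject-level coupling deviations,
# framewise-displacement spike traces, two-timepoint item tables coupled to
# the planted brain signal, demographics and a matched two-arm split. The
# generator never reads pipeline outputs, so recovery tests are honest.

#' Synthetic cohort configuration
#'
#' Defaults emulate the reference acquisition (four 5-minute runs at TR
#' 0.8 s) at a desk-scale parcellation (6 networks x 15 parcels = 90), with
#' within-network correlation 0.35, between-network correlation 0.10,
#' subject-level within-network coupling SD 0.1, mild temporal
#' autocorrelation, and occasional FD spikes above the 0.3 mm censoring
#' threshold.
#'
#' @param n_subjects cohort size.
#' @param network_sizes named integer vector of parcels per network.
#' @param frames_per_run,runs,tr acquisition shape (TR in seconds).
#' @param w within-network base correlation (0 <= b < w < 1).
#' @param b between-network correlation.
#' @param ar1 AR(1) coefficient of the frame-to-frame signal.
#' @param coupling_sd SD of the per-subject within-network coupling deviation
#'   on an effect's target networks.
#' @param fd_spike_rate per-frame probability of a motion spike.
#' @param fd_spike_magnitude mm added to FD at spike frames.
#' @param item_loading latent-to-item loading for generated items.
#' @param item_levels response levels for composite items.
#' @param seed integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 800L,
                          network_sizes = c(DMN = 15L, FP = 15L, CO = 15L,
                                            SM = 15L, VIS = 15L, SUB = 15L),
                          frames_per_run = 375L, runs = 4L, tr = 0.8,
                          w = 0.35, b = 0.10, ar1 = 0.3, coupling_sd = 0.1,
                          fd_spike_rate = 0.05, fd_spike_magnitude = 0.8,
                          item_loading = 0.8, item_levels = 4L, seed = 1L) {
  if (!(0 <= b && b < w && w < 1)) stop("need 0 <= b < w < 1")
  if (fd_spike_rate < 0 || fd_spike_rate >= 1) stop("spike rate must be in [0, 1)")
  if (abs(ar1) >= 1) stop("ar1 must lie in (-1, 1)")
  structure(list(n_subjects = as.integer(n_subjects),
                 network_sizes = network_sizes,
                 frames_per_run = as.integer(frames_per_run),
                 runs = as.integer(runs), tr = tr, w = w, b = b, ar1 = ar1,
                 coupling_sd = coupling_sd, fd_spike_rate = fd_spike_rate,
                 fd_spike_magnitude = fd_spike_magnitude,
                 item_loading = item_loading,
                 item_levels = as.integer(item_levels),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Planted brain-phenotype effect
#'
#' Declares, for one facet, which networks carry the subject-level coupling
#' deviation and how strongly the facet's latent score correlates with it at
#' each timepoint (population correlation = `effect * multiplier`).
#'
#' @param facet facet name (e.g. `"intent"`, `"upps"`).
#' @param target_networks network labels carrying the deviation; required
#'   when the effect is nonzero.
#' @param effect standardized effect size: population correlation between the
#'   subject's coupling deviation and the latent facet score.
#' @param multipliers named numeric `c(baseline = ..., year2 = ...)` scaling
#'   the effect per timepoint.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(facet, target_networks = NULL, effect = 0,
                        multipliers = c(baseline = 1, year2 = 1)) {
  if (abs(effect) >= 1) stop("|effect| must be < 1")
  if (any(abs(effect * multipliers) >= 1)) stop("|effect * multiplier| must be < 1")
  if (effect != 0 && length(target_networks) == 0L)
    stop("a nonzero effect needs target networks")
  structure(list(facet = facet, target_networks = target_networks,
                 effect = effect, multipliers = multipliers),
            class = "effect_spec")
}

#' Draw subject coupling deviations and latent facet scores
#'
#' For each effect, every subject gets a coupling deviation
#' `delta ~ N(0, coupling_sd^2)` applied to that effect's target networks,
#' and per-timepoint latent facet scores
#' `eff * scale(delta) + sqrt(1 - eff^2) * noise`, so the population
#' correlation between deviation and score equals the stated effect.
#'
#' @param cfg a `cohort_config`.
#' @param effects list of `effect_spec`s.
#' @param seed integer seed.
#' @return list: `deltas` (subjects x effects matrix, zero columns for null
#'   effects), `latent` (nested list `latent[[facet]][[timepoint]]`).
#' @export
draw_subject_couplings <- function(cfg, effects, seed = cfg$seed) {
  n <- cfg$n_subjects
  .with_seed(seed, {
    deltas <- matrix(0, n, length(effects),
                     dimnames = list(NULL, vapply(effects, `[[`, "", "facet")))
    latent <- list()
    for (e in seq_along(effects)) {
      ef <- effects[[e]]
      delta <- rnorm(n, 0, cfg$coupling_sd)
      if (ef$effect != 0 || length(ef$target_networks) > 0L)
        deltas[, e] <- delta
      z <- as.numeric(scale(delta))
      latent[[ef$facet]] <- lapply(
        setNames(names(ef$multipliers), names(ef$multipliers)),
        function(tp) {
          eff <- ef$effect * ef$multipliers[[tp]]
          eff * z + sqrt(1 - eff^2) * rnorm(n)
        })
    }
    list(deltas = deltas, latent = latent)
  })
}

# subject-level parcel correlation matrix: block structure plus this
# subject's deviations on each effect's target networks
.subject_sigma <- function(cfg, parc, effects, delta_row) {
  P <- n_parcels(parc)
  labs <- parc$network_labels
  sigma <- matrix(cfg$b, P, P)
  for (nw in unique(labs)) {
    idx <- labs == nw
    dev <- 0
    for (e in seq_along(effects))
      if (nw %in% effects[[e]]$target_networks) dev <- dev + delta_row[e]
    win <- min(max(cfg$w + dev, cfg$b + 0.01), 0.95)
    sigma[idx, idx] <- win
  }
  diag(sigma) <- 1
  sigma
}

#' Simulate one subject's parcel timeseries
#'
#' Frames follow an AR(1)-filtered multivariate normal with the subject's
#' block correlation structure (stationary covariance equal to the block
#' matrix). The FD trace mixes a small baseline motion level with Bernoulli
#' spikes; spike frames receive additive signal artifacts so censoring has
#' something real to remove.
#'
#' @param cfg a `cohort_config`.
#' @param parc the cohort `parcellation`.
#' @param effects list of `effect_spec`s.
#' @param delta_row this subject's deviation per effect.
#' @param seed integer seed.
#' @return a `parcel_timeseries` (FD attached, all frames initially retained).
#' @export
simulate_timeseries <- function(cfg, parc, effects, delta_row, seed) {
  sigma <- .subject_sigma(cfg, parc, effects, delta_row)
  L <- tryCatch(chol(sigma),
                error = function(e) stop("block covariance not positive definite"))
  P <- ncol(sigma)
  n <- cfg$frames_per_run * cfg$runs
  .with_seed(seed, {
    eps <- matrix(rnorm(n * P), n, P) %*% L
    x <- eps
    phi <- cfg$ar1
    if (phi != 0) {
      scl <- sqrt(1 - phi^2)
      for (t in 2:n) x[t, ] <- phi * x[t - 1L, ] + scl * eps[t, ]
    }
    fd <- abs(rnorm(n, 0.12, 0.06))
    spikes <- runif(n) < cfg$fd_spike_rate
    fd[spikes] <- fd[spikes] + cfg$fd_spike_magnitude
    if (any(spikes))
      x[spikes, ] <- x[spikes, ] +
        matrix(rnorm(sum(spikes) * P, 0, 4), sum(spikes), P)
    colnames(x) <- parc$parcel_ids
    parcel_timeseries(x, tr = cfg$tr, fd = fd)
  })
}

#' Draw one subject's connectivity matrix directly (fast mode)
#'
#' Samples a Wishart-perturbed correlation matrix around the subject's block
#' structure with degrees of freedom matching the usable frame count, i.e.
#' the sampling noise a real correlation estimate from that much data would
#' carry, without simulating frames.
#'
#' @param cfg a `cohort_config`.
#' @param parc the cohort `parcellation`.
#' @param effects list of `effect_spec`s.
#' @param delta_row this subject's deviation per effect.
#' @param seed integer seed.
#' @return a `connectivity_matrix`.
#' @export
simulate_connectivity <- function(cfg, parc, effects, delta_row, seed) {
  sigma <- .subject_sigma(cfg, parc, effects, delta_row)
  dof <- max(n_parcels(parc) + 2L,
             round(cfg$frames_per_run * cfg$runs * (1 - cfg$fd_spike_rate)))
  s <- .with_seed(seed, stats::rWishart(1L, dof, sigma)[, , 1L] / dof)
  connectivity_matrix(stats::cov2cor(s), parc)
}

#' Generate an item table from latent facet scores
#'
#' Every item is `loading * latent + sqrt(1 - loading^2) * noise`, then
#' discretized into `levels` equal-probability response categories
#' (`base`, ..., `base + levels - 1`); `continuous = TRUE` skips
#' discretization.
#'
#' @param latent numeric latent score per subject.
#' @param item_names column names to emit.
#' @param loading latent-to-item loading in (0, 1].
#' @param levels response levels (>= 2).
#' @param seed integer seed.
#' @param base lowest response value (0 for composite items, 1 for the
#'   impulsivity scale).
#' @param continuous emit the continuous item values instead.
#' @return data frame with `subject` plus one column per item.
#' @export
items_from_latent <- function(latent, item_names, loading = 0.8, levels = 4L,
                              seed = 1L, base = 0L, continuous = FALSE) {
  if (loading <= 0 || loading > 1) stop("loading must be in (0, 1]")
  if (levels < 2L) stop("need at least 2 response levels")
  n <- length(latent)
  .with_seed(seed, {
    cuts <- qnorm(seq_len(levels - 1L) / levels)
    items <- lapply(item_names, function(nm) {
      z <- loading * latent + sqrt(1 - loading^2) * rnorm(n)
      if (continuous) z else base + findInterval(z, cuts)
    })
    names(items) <- item_names
    cbind(data.frame(subject = paste0("sub", seq_len(n))), items)
  })
}

#' Simulate a raw demographic table
#'
#' Sex, ethnicity, race selections (including rare multiracial, don't-know
#' and refused responses), household income (1-10) and parental education
#' (0-21), drawn independently of the brain signal.
#'
#' @param n subject count.
#' @param seed integer seed.
#' @return data frame in the layout [encode_demographics()] expects.
#' @export
simulate_demographics <- function(n, seed = 1L) {
  .with_seed(seed, {
    race <- character(n)
    u <- runif(n)
    single <- sample(.race_categories, n, replace = TRUE,
                     prob = c(0.002, 0.02, 0.16, 0.006, 0.004, 0.001, 0.002,
                              0.005, 0.001, 0.002, 0.006, 0.001, 0.002, 0.74,
                              0.003, 0.002, 0.033))
    race <- single
    multi <- u < 0.11
    race[multi] <- vapply(which(multi), function(i)
      paste(sample(.race_categories, 2L), collapse = ";"), character(1))
    race[u > 0.990] <- "dont_know"
    race[u > 0.995] <- "refused"
    data.frame(
      subject = paste0("sub", seq_len(n)),
      sex = sample(c("male", "female"), n, replace = TRUE),
      ethnicity = sample(c("hispanic", "not_hispanic"), n, replace = TRUE,
                         prob = c(0.2, 0.8)),
      race = race,
      household_income = sample(1:10, n, replace = TRUE,
                                prob = c(2, 3, 3, 5, 7, 9, 16, 15, 25, 15)),
      parental_education = pmin(21L, pmax(0L, round(rnorm(n, 17, 2.4)))))
  })
}

#' Demographically matched two-arm split
#'
#' Stratifies subjects on sex x ethnicity x household-income tercile and
#' alternates arm assignment within each shuffled stratum, always giving any
#' odd remainder to the currently smaller arm, so every stratum (and the
#' whole sample) is balanced to within one subject.
#'
#' @param demo raw demographic table (needs `subject`, `sex`, `ethnicity`,
#'   `household_income`).
#' @param seed integer seed.
#' @return named integer vector of arm labels (1 or 2) keyed by subject id.
#' @export
assign_matched_split <- function(demo, seed = 1L) {
  n <- nrow(demo)
  if (n < 2L) stop("need at least 2 subjects to split")
  terc <- cut(rank(demo$household_income, ties.method = "first"),
              breaks = 3L, labels = FALSE)
  strata <- paste(demo$sex, demo$ethnicity, terc, sep = "|")
  arms <- integer(n)
  .with_seed(seed, {
    tally <- c(0L, 0L)
    for (st in unique(strata)) {
      idx <- sample(which(strata == st))
      first <- if (tally[1L] <= tally[2L]) 1L else 2L
      lab <- rep(c(first, 3L - first), length.out = length(idx))
      arms[idx] <- lab
      tally <- tally + c(sum(lab == 1L), sum(lab == 2L))
    }
  })
  setNames(arms, demo$subject)
}

#' Generate a full synthetic cohort
#'
#' End-to-end generation with the ground truth retained: parcellation,
#' per-subject coupling deviations and latent facet scores, connectivity
#' matrices (fast Wishart mode) or parcel timeseries, two-timepoint item
#' tables whose names match the shipped composite spec, demographics and a
#' matched arm split. Fully reproducible from (config, seed).
#'
#' @param cfg a `cohort_config`.
#' @param effects list of `effect_spec`s, one per facet to generate.
#' @param mode `"connectivity"` (fast; default) or `"timeseries"`.
#' @param composite_spec a `composite_spec` supplying item names.
#' @return An object of class `synthetic_cohort`: `parcellation`, `subjects`,
#'   `conns` or `timeseries`, `items` (`$baseline`, `$year2`), `demographics`,
#'   `arms`, `ground_truth` (subject, facet, timepoint, latent, delta).
#' @export
generate_cohort <- function(cfg = cohort_config(), effects = list(),
                            mode = c("connectivity", "timeseries"),
                            composite_spec = load_composite_spec()) {
  mode <- match.arg(mode)
  parc <- make_parcellation(cfg$network_sizes)
  n <- cfg$n_subjects
  subjects <- paste0("sub", seq_len(n))
  truth <- draw_subject_couplings(cfg, effects, derive_seed(cfg$seed, "couplings"))

  brain <- lapply(seq_len(n), function(i) {
    sseed <- derive_seed(cfg$seed, paste0("brain:", subjects[i]))
    if (mode == "connectivity")
      simulate_connectivity(cfg, parc, effects, truth$deltas[i, ], sseed)
    else simulate_timeseries(cfg, parc, effects, truth$deltas[i, ], sseed)
  })
  names(brain) <- subjects

  items <- list(baseline = data.frame(subject = subjects),
                year2 = data.frame(subject = subjects))
  gt <- list()
  for (e in seq_along(effects)) {
    ef <- effects[[e]]
    for (tp in names(ef$multipliers)) {
      lat <- truth$latent[[ef$facet]][[tp]]
      item_names <- if (ef$facet == "upps") {
        sp <- composite_spec$upps_items
        sp
      } else facet_items(composite_spec, ef$facet, tp)
      base <- if (ef$facet == "upps") 1L else 0L
      tab <- items_from_latent(
        lat, item_names, loading = cfg$item_loading,
        levels = cfg$item_levels, base = base,
        seed = derive_seed(cfg$seed, paste0("items:", ef$facet, ":", tp)))
      items[[tp]] <- cbind(items[[tp]],
                           tab[, item_names[!item_names %in% names(items[[tp]])],
                               drop = FALSE])
      gt[[length(gt) + 1L]] <- data.frame(
        subject = subjects, facet = ef$facet, timepoint = tp, latent = lat,
        delta = truth$deltas[, e])
    }
  }

  demo <- simulate_demographics(n, derive_seed(cfg$seed, "demographics"))
  arms <- assign_matched_split(demo, derive_seed(cfg$seed, "split"))

  out <- list(parcellation = parc, subjects = subjects,
              demographics = demo, arms = arms,
              items = items, ground_truth = do.call(rbind, gt),
              effects = effects, config = cfg)
  if (mode == "connectivity") out$conns <- brain else out$timeseries <- brain
  structure(out, class = "synthetic_cohort")
}

#' Read a cohort from its plain-text files
#'
#' Counterpart of [write_cohort()]: loads the parcel lookup, per-subject
#' connectivity matrices, item tables, demographics and arm labels from a
#' directory.
#'
#' @param dir directory written by [write_cohort()] (or files in the same
#'   dialects).
#' @return a `synthetic_cohort`-shaped list usable by
#'   [prepare_cpm_cohort()].
#' @export
read_cohort <- function(dir) {
  parc <- read_parcellation(file.path(dir, "parcellation.tsv"))
  arms_tab <- read.csv(file.path(dir, "arms.csv"))
  arms <- setNames(as.integer(arms_tab$arm), arms_tab$subject)
  cdir <- file.path(dir, "connectivity")
  files <- list.files(cdir, pattern = "\\.tsv$", full.names = TRUE)
  conns <- lapply(files, read_connectivity, parcellation = parc)
  names(conns) <- sub("\\.tsv$", "", basename(files))
  conns <- conns[order(match(names(conns), arms_tab$subject))]
  items <- list(baseline = read.csv(file.path(dir, "items_baseline.csv")),
                year2 = read.csv(file.path(dir, "items_year2.csv")))
  gt_path <- file.path(dir, "ground_truth.csv")
  structure(list(parcellation = parc, subjects = names(conns),
                 conns = conns, items = items,
                 demographics = read.csv(file.path(dir, "demographics.csv")),
                 arms = arms,
                 ground_truth = if (file.exists(gt_path)) read.csv(gt_path)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects, %d parcels, arms %d/%d, facets: %s\n",
              length(x$subjects), n_parcels(x$parcellation),
              sum(x$arms == 1L), sum(x$arms == 2L),
              paste(vapply(x$effects, `[[`, "", "facet"), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits exactly the dialects the other modules read: per-subject square
#' connectivity matrices, the parcel lookup, item and demographic CSVs, arm
#' labels and the ground-truth table.
#'
#' @param cohort a `synthetic_cohort` (connectivity mode).
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_parcellation(cohort$parcellation, file.path(dir, "parcellation.tsv"))
  if (!is.null(cohort$conns)) {
    cdir <- file.path(dir, "connectivity")
    if (!dir.exists(cdir)) dir.create(cdir)
    for (s in names(cohort$conns))
      write_connectivity(cohort$conns[[s]], file.path(cdir, paste0(s, ".tsv")))
  }
  write.csv(cohort$items$baseline, file.path(dir, "items_baseline.csv"),
            row.names = FALSE)
  write.csv(cohort$items$year2, file.path(dir, "items_year2.csv"),
            row.names = FALSE)
  write.csv(cohort$demographics, file.path(dir, "demographics.csv"),
            row.names = FALSE)
  write.csv(data.frame(subject = names(cohort$arms), arm = cohort$arms),
            file.path(dir, "arms.csv"), row.names = FALSE)
  write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(dir)
}
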