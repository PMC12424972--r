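# The synthetic-cohort generator: distributions, planted effects, splits.

test_that("parcellation construction is deterministic with the stated sizes", {
  p <- make_parcellation(c(A = 3, B = 2))
  expect_equal(n_parcels(p), 5L)
  expect_equal(p$network_labels, c("A", "A", "A", "B", "B"))
  p1 <- make_parcellation(c(only = 4))
  expect_equal(unique(p1$network_labels), "only")
  pfull <- make_parcellation(c(ctx = 333, sub = 19), n_subcortical = 19)
  expect_equal(n_parcels(pfull), 352L)
  expect_error(make_parcellation(c(3, 2)), "named")
})

test_that("planted couplings give the stated population correlation", {
  cfg <- cohort_config(n_subjects = 2000, seed = 5)
  # effect 0: scores independent of the deviation
  d0 <- draw_subject_couplings(cfg, list(effect_spec("a", "DMN", 0)), 1)
  expect_lt(abs(cor(d0$deltas[, 1], d0$latent$a$baseline)), 0.1)
  # effect 0.5: sample correlation close to 0.5 at n = 2000
  d5 <- draw_subject_couplings(cfg, list(effect_spec("b", "DMN", 0.5)), 2)
  expect_lt(abs(cor(d5$deltas[, 1], d5$latent$b$baseline) - 0.5), 0.04)
  # effect 1 with zero noise reproduces the standardized deviation exactly
  cfg1 <- cohort_config(n_subjects = 100, seed = 5)
  d1 <- draw_subject_couplings(cfg1,
                               list(effect_spec("c", "DMN", 0.999999)), 3)
  expect_gt(cor(d1$deltas[, 1], d1$latent$c$baseline), 0.999)
  # timepoint multipliers scale the planted correlation
  dm <- draw_subject_couplings(
    cfg, list(effect_spec("d", "DMN", 0.1,
                          multipliers = c(baseline = 1, year2 = 5))), 4)
  expect_lt(abs(cor(dm$deltas[, 1], dm$latent$d$year2) - 0.5), 0.05)
  expect_lt(abs(cor(dm$deltas[, 1], dm$latent$d$baseline) - 0.1), 0.07)
})

test_that("simulated timeseries carry the planted block correlations", {
  cfg <- cohort_config(n_subjects = 1, frames_per_run = 500, runs = 4,
                       network_sizes = c(A = 10, B = 10), w = 0.6, b = 0,
                       fd_spike_rate = 0, ar1 = 0.3, seed = 1)
  parc <- make_parcellation(cfg$network_sizes)
  ts <- simulate_timeseries(cfg, parc, list(effect_spec("x", "A", 0)),
                            0, seed = 9)
  r <- cor(ts$data)
  within <- c(r[1:10, 1:10][upper.tri(diag(10))],
              r[11:20, 11:20][upper.tri(diag(10))])
  between <- r[1:10, 11:20]
  expect_lt(abs(mean(within) - 0.6), 0.05)
  expect_lt(abs(mean(between)), 0.05)
  # no spikes: FD stays below the censoring threshold
  expect_true(all(ts$fd < 0.8))
})

test_that("fast-mode connectivity matches the block structure with sampling noise", {
  cfg <- cohort_config(n_subjects = 1, network_sizes = c(A = 10, B = 10),
                       w = 0.6, b = 0.05, seed = 1)
  parc <- make_parcellation(cfg$network_sizes)
  conn <- simulate_connectivity(cfg, parc, list(effect_spec("x", "A", 0)),
                                0, seed = 3)
  expect_s3_class(conn, "connectivity_matrix")
  v <- conn$values
  expect_lt(abs(mean(v[1:10, 1:10][upper.tri(diag(10))]) - 0.6), 0.08)
  expect_lt(abs(mean(v[1:10, 11:20]) - 0.05), 0.08)
  # a positive deviation raises within-network correlation on the target
  connd <- simulate_connectivity(cfg, parc, list(effect_spec("x", "A", 0.5)),
                                 0.15, seed = 3)
  expect_gt(mean(connd$values[1:10, 1:10][upper.tri(diag(10))]),
            mean(v[1:10, 1:10][upper.tri(diag(10))]))
})

test_that("items couple to the latent score as the loading dictates", {
  set.seed(6)
  latent <- rnorm(1000)
  # loading 1, continuous: composite reproduces the latent up to affine map
  t1 <- items_from_latent(latent, paste0("i", 1:4), loading = 1,
                          continuous = TRUE, seed = 2)
  expect_equal(cor(rowMeans(t1[, -1]), latent), 1, tolerance = 1e-10)
  # loading 0.7, 8 discretized items: strong but attenuated correlation
  t2 <- items_from_latent(latent, paste0("i", 1:8), loading = 0.7,
                          levels = 4, seed = 3)
  expect_gt(cor(rowMeans(t2[, -1]), latent), 0.85)
  # binary items take exactly two values
  t3 <- items_from_latent(latent, paste0("i", 1:3), levels = 2, seed = 4)
  expect_setequal(sort(unique(unlist(t3[, -1]))), c(0, 1))
})

test_that("matched split balances strata and the whole sample", {
  demo <- simulate_demographics(101, seed = 11)
  arms <- assign_matched_split(demo, seed = 12)
  expect_equal(abs(sum(arms == 1L) - sum(arms == 2L)), 1L)  # odd n
  # every stratum balanced to within one subject
  terc <- cut(rank(demo$household_income, ties.method = "first"), 3,
              labels = FALSE)
  strata <- paste(demo$sex, demo$ethnicity, terc)
  for (st in unique(strata)) {
    a <- arms[strata == st]
    expect_lte(abs(sum(a == 1L) - sum(a == 2L)), 1L)
  }
  expect_identical(assign_matched_split(demo, seed = 12), arms)
  # even n splits exactly in half
  demo2 <- simulate_demographics(100, seed = 13)
  arms2 <- assign_matched_split(demo2, seed = 14)
  expect_equal(sum(arms2 == 1L), 50L)
})

test_that("cohort generation is reproducible and runs the full pipeline at toy scale", {
  cfg <- cohort_config(n_subjects = 24, network_sizes = c(A = 5, B = 5),
                       seed = 33)
  effs <- list(effect_spec("intent", "A", 0.4))
  coh1 <- generate_cohort(cfg, effs)
  coh2 <- generate_cohort(cfg, effs)
  expect_identical(coh1$items, coh2$items)
  expect_identical(coh1$demographics, coh2$demographics)
  expect_identical(coh1$conns[[5]]$values, coh2$conns[[5]]$values)
  expect_identical(coh1$arms, coh2$arms)
  # ground truth stored for every generated facet x timepoint
  expect_setequal(unique(coh1$ground_truth$timepoint), c("baseline", "year2"))

  # end-to-end smoke at toy scale
  cc <- prepare_cpm_cohort(coh1, embedding_config(
    dims = 4, walk_length = 12, walks_per_node = 4, window = 3, epochs = 2,
    seed = 1))
  sr <- suppressWarnings(run_specification(
    cc, "intent", "baseline", 2, "PLSR", k = 20,
    cv_cfg = cv_config(outer_k = 2, inner_k = 2, seed = 1)))
  expect_s3_class(sr$result, "prediction_result")
  expect_true(is.finite(sr$result$r))
})

test_that("positive-definiteness holds across admissible couplings", {
  cfg <- cohort_config(n_subjects = 1, network_sizes = c(A = 10, B = 10),
                       w = 0.5, b = 0.2, coupling_sd = 0.15, seed = 1)
  parc <- make_parcellation(cfg$network_sizes)
  for (delta in c(-0.45, -0.2, 0, 0.2, 0.44)) {
    sigma <- neurocpm:::.subject_sigma(cfg, parc,
                                       list(effect_spec("x", "A", 0.5)), delta)
    expect_true(all(eigen(sigma, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
})

test_that("cohort files round-trip through the plain-text dialects", {
  cfg <- cohort_config(n_subjects = 6, network_sizes = c(A = 4, B = 4),
                       seed = 8)
  coh <- generate_cohort(cfg, list(effect_spec("access", "B", 0.3)))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  parc <- read_parcellation(file.path(dir, "parcellation.tsv"))
  expect_equal(parc$network_labels, coh$parcellation$network_labels)
  conn <- read_connectivity(file.path(dir, "connectivity", "sub3.tsv"), parc)
  expect_equal(conn$values, coh$conns$sub3$values, tolerance = 1e-10,
               ignore_attr = TRUE)
  gt <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(gt), 12L)
})
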