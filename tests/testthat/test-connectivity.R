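# Censoring, denoising, filtering and Pearson connectivity.

test_that("censor mask retains exactly the frames at or below threshold", {
  expect_equal(censor_mask(c(0.1, 0.2, 0.1), 0.3), c(TRUE, TRUE, TRUE))
  expect_equal(censor_mask(c(0.1, 0.4, 0.2), 0.3), c(TRUE, FALSE, TRUE))
  expect_error(censor_mask(c(0.5, 0.5), 0.3), "no usable data")
  expect_error(censor_mask(c(-0.1, 0.2), 0.3), "non-negative")
})

test_that("detrending removes constants and exact lines, fit on retained frames only", {
  n <- 50L
  const_col <- rep(3.7, n)
  line_col <- 2 + 0.5 * seq_len(n)
  ts <- parcel_timeseries(cbind(a = const_col, b = line_col), tr = 0.8)
  out <- detrend_demean(ts)
  expect_lt(max(abs(out$data)), 1e-10)

  # censored-frame outliers must not perturb the fit: compare against a
  # least-squares line fit on the retained subset only
  set.seed(42)
  y <- 1.5 - 0.02 * seq_len(n) + rnorm(n, 0, 0.3)
  retained <- rep(TRUE, n); retained[c(10, 30)] <- FALSE
  y_spiked <- y; y_spiked[c(10, 30)] <- 500
  ts2 <- parcel_timeseries(cbind(y_spiked, y_spiked), tr = 0.8,
                           retained = retained)
  out2 <- detrend_demean(ts2)
  tcen <- seq_len(n) - (n + 1) / 2
  oracle_fit <- lm(y_spiked[retained] ~ tcen[retained])
  oracle_resid <- y_spiked - (coef(oracle_fit)[1] + coef(oracle_fit)[2] * tcen)
  expect_equal(out2$data[, 1], unname(oracle_resid), tolerance = 1e-10)
  expect_lt(abs(mean(out2$data[retained, 1])), 1e-10)
})

test_that("nuisance regression residualizes against confounds with minimum-norm handling", {
  set.seed(7)
  n <- 120L
  conf <- cbind(wm = rnorm(n), csf = rnorm(n))
  # a parcel equal to a confound vanishes; an orthogonal parcel is untouched
  ortho <- residuals(lm(rnorm(n) ~ conf))
  ts <- parcel_timeseries(cbind(a = conf[, 1], b = ortho), tr = 0.8)
  out <- nuisance_regress(ts, nuisance_set(conf))
  expect_lt(max(abs(out$data[, "a"])), 1e-10)
  expect_equal(out$data[, "b"], ts$data[, "b"] - mean(ts$data[, "b"]),
               tolerance = 1e-10)
  # residuals orthogonal to confounds over retained frames
  expect_lt(max(abs(crossprod(conf, out$data))), 1e-8)

  # duplicated confound column gives the same residual as without it
  y <- rnorm(n)
  ts1 <- parcel_timeseries(cbind(y, y), tr = 0.8)
  r1 <- nuisance_regress(ts1, nuisance_set(conf))
  r2 <- nuisance_regress(ts1, nuisance_set(cbind(conf, conf[, 1])))
  expect_equal(r1$data, r2$data, tolerance = 1e-8)
})

test_that("bandpass filter matches the Butterworth magnitude response", {
  tr <- 0.8; n <- 2000L
  t_sec <- (seq_len(n) - 1) * tr
  cfg <- preprocess_config()
  # analytic |H(f)|^2 of the digital second-order Butterworth bandpass,
  # applied twice (forward + backward)
  gain2 <- function(f) {
    bf <- signal::butter(2, c(0.008, 0.09) / (1 / (2 * tr)), type = "pass")
    z <- exp(-1i * 2 * pi * f * tr * (seq_along(bf$b) - 1))
    abs(sum(bf$b * z) / sum(bf$a * exp(-1i * 2 * pi * f * tr *
                                         (seq_along(bf$a) - 1))))^2
  }
  for (freq in c(0.05, 0.4)) {
    x <- sin(2 * pi * freq * t_sec)
    ts <- parcel_timeseries(cbind(x, x), tr = tr)
    out <- bandpass_filter(ts, cfg)
    mid <- 500:1500  # avoid edge transients
    amp <- max(abs(out$data[mid, 1]))
    if (freq == 0.05) {
      expect_gt(gain2(freq), 0.9)      # oracle: passband
      expect_gt(amp, 0.95); expect_lt(amp, 1.05)
    } else {
      expect_lt(gain2(freq), 0.01)     # oracle: stopband
      expect_lt(amp, 0.10)
    }
  }
  # DC offset is removed (edge transients allowed, interior strictly flat)
  ts_dc <- parcel_timeseries(matrix(5, n, 2), tr = tr)
  out_dc <- bandpass_filter(ts_dc, cfg)
  expect_lt(abs(mean(out_dc$data)), 0.05)
  expect_lt(max(abs(out_dc$data[800:1200, ])), 0.02)
  # band edges above Nyquist are rejected
  expect_error(bandpass_filter(parcel_timeseries(matrix(rnorm(40), 20), tr = 10),
                               cfg), "Nyquist")
})

test_that("censored-frame interpolation is linear with boundary extension", {
  ts <- parcel_timeseries(cbind(c(1, 99, 3), c(4, -50, 8)), tr = 0.8,
                          retained = c(TRUE, FALSE, TRUE))
  out <- interpolate_censored(ts)
  expect_equal(out$data[2, ], c(2, 6))
  expect_equal(out$retained, c(TRUE, FALSE, TRUE))  # mask preserved
  # leading censored frame takes the first retained value
  ts2 <- parcel_timeseries(cbind(c(99, 2, 3), c(0, 5, 6)), tr = 0.8,
                           retained = c(FALSE, TRUE, TRUE))
  expect_equal(interpolate_censored(ts2)$data[1, ], c(2, 5))
  # no censoring: identity
  ts3 <- toy_timeseries(50)
  expect_equal(interpolate_censored(ts3)$data, ts3$data)
})

test_that("connectivity is Pearson over retained frames only", {
  cfg0 <- preprocess_config(min_retained_minutes = 0)
  x <- c(1, 2, 3); y <- c(1, 3, 2)
  ts <- parcel_timeseries(cbind(x, y, x2 = x, negx = -x), tr = 1)
  conn <- compute_connectivity(ts, cfg0)
  expect_equal(conn$values[1, 2], 0.5)          # hand-computed Pearson
  expect_equal(conn$values[1, 3], 1)            # duplicated parcel
  expect_equal(conn$values[1, 4], -1)           # negated parcel
  expect_equal(conn$values, t(conn$values))
  expect_equal(unname(diag(conn$values)), rep(1, 4))

  # retained frames only: censored frames carry garbage and must not matter
  set.seed(1)
  a <- rnorm(40); b <- rnorm(40)
  retained <- rep(c(TRUE, TRUE, TRUE, FALSE), 10)
  a2 <- a; a2[!retained] <- 1e6
  ts_r <- parcel_timeseries(cbind(a2, b), tr = 1, retained = retained)
  conn_r <- compute_connectivity(ts_r, cfg0)
  expect_equal(conn_r$values[1, 2], cor(a[retained], b[retained]))

  # zero-variance parcel names the culprit; duration screen enforces minutes
  ts_z <- parcel_timeseries(cbind(ok = rnorm(20), flat = rep(1, 20)), tr = 1)
  expect_error(compute_connectivity(ts_z, cfg0), "flat")
  expect_error(compute_connectivity(toy_timeseries(100), preprocess_config()),
               "retained minutes")
})

test_that("edge vectorization is the row-major strict upper triangle and round-trips", {
  m <- matrix(c(1, .1, .2, .1, 1, .3, .2, .3, 1), 3)
  v <- vectorize_edges(m)
  expect_equal(as.numeric(v), c(.1, .2, .3))
  expect_equal(unname(attr(v, "index")), cbind(c(1, 1, 2), c(2, 3, 3)),
               ignore_attr = TRUE)
  expect_equal(length(vectorize_edges(diag(352))), 61776L)
  expect_true(all(vectorize_edges(diag(5)) == 0))
  expect_error(vectorize_edges(matrix(0, 2, 3)), "square")

  set.seed(3)
  conn <- block_connectivity(4, 5, noise_dof = 200)
  v2 <- vectorize_edges(conn)
  expect_equal(edges_to_matrix(as.numeric(v2), 20), unname(conn$values),
               tolerance = 1e-12)
})

test_that("connectivity of iid noise stays near zero across seeds", {
  worst <- vapply(1:20, function(s) {
    set.seed(s)
    ts <- parcel_timeseries(matrix(rnorm(5000 * 10), 5000, 10), tr = 0.1)
    conn <- compute_connectivity(ts, preprocess_config(min_retained_minutes = 0))
    max(abs(conn$values[upper.tri(conn$values)]))
  }, numeric(1))
  expect_true(all(worst < 0.1))
})

test_that("preprocessing chain is invariant to per-parcel affine rescaling", {
  set.seed(11)
  ts <- toy_timeseries(900, P = 5, tr = 0.8, seed = 11)
  ts$fd <- abs(rnorm(900, 0.15, 0.08))
  scales <- c(2, 0.5, 10, 1, 100)
  offsets <- c(-3, 7, 0, 100, -50)
  ts2 <- ts
  ts2$data <- sweep(sweep(ts$data, 2, scales, "*"), 2, offsets, "+")
  cfg <- preprocess_config(min_retained_minutes = 0)
  c1 <- preprocess_to_connectivity(ts, cfg = cfg)
  c2 <- preprocess_to_connectivity(ts2, cfg = cfg)
  expect_equal(c1$values, c2$values, tolerance = 1e-10)
})

test_that("a spike confined to censored frames barely moves connectivity", {
  set.seed(5)
  ts <- toy_timeseries(900, P = 5, tr = 0.8, seed = 5)
  ts$fd <- abs(rnorm(900, 0.12, 0.05))
  ts$fd[450] <- 1.5                       # censored frame
  cfg <- preprocess_config(min_retained_minutes = 0)
  base <- preprocess_to_connectivity(ts, cfg = cfg)

  # filter-leakage bound from a spike-free control perturbation
  ts_ctrl <- ts; ts_ctrl$data[450, ] <- ts_ctrl$data[450, ] + 0.01
  ctrl <- preprocess_to_connectivity(ts_ctrl, cfg = cfg)
  bound <- max(abs(ctrl$values - base$values)) * 1e4 + 1e-3

  ts_spike <- ts; ts_spike$data[450, ] <- ts_spike$data[450, ] + 1e4 * c(1, -1, 2, -2, 3)
  spiked <- preprocess_to_connectivity(ts_spike, cfg = cfg)
  expect_lt(max(abs(spiked$values - base$values)), bound)
})
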