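test_that("initial-volume discarding trims exactly and rejects empties", {
  set.seed(3)
  b <- bold_from_matrix(matrix(rnorm(10 * 4), 10, 4))
  expect_identical(discard_initial_volumes(b, 0), b)
  expect_equal(discard_initial_volumes(b, 5)$n_volumes, 5)
  expect_equal(discard_initial_volumes(b, 5)$data[, , , 1], b$data[, , , 6])
  expect_error(discard_initial_volumes(b, 10), "n_volumes")
})

test_that("CompCor recovers a planted tissue component", {
  set.seed(4)
  n_t <- 80
  sig <- sin(2 * pi * 0.04 * (1:n_t) * 2)
  # 30 tissue voxels = shared signal with random gains + tiny noise
  gains <- runif(30, 0.5, 2)
  mat <- outer(sig, gains) + matrix(rnorm(n_t * 30, sd = 0.01), n_t)
  b <- bold_from_matrix(mat)
  wm <- array(FALSE, c(30, 1, 1)); wm[1:15, 1, 1] <- TRUE
  csf <- array(FALSE, c(30, 1, 1)); csf[16:30, 1, 1] <- TRUE
  comp <- compcor_components(b, wm, csf, k = 1)
  expect_gt(abs(cor(comp[, 1], sig)), 0.99)
  expect_equal(sd(comp[, 1]), 1)
  # one-voxel mask with k = 1: component equals the standardized series up to sign
  one <- array(FALSE, c(30, 1, 1)); one[1, 1, 1] <- TRUE
  none <- array(FALSE, c(30, 1, 1))
  c1 <- compcor_components(b, one, none, k = 1)
  v <- resid(lm(mat[, 1] ~ seq_len(n_t)))
  expect_gt(abs(cor(c1[, 1], v)), 1 - 1e-10)
  # default k is 5; masks smaller than k are rejected
  expect_equal(ncol(compcor_components(b, wm, csf)), 5)
  expect_error(compcor_components(b, one, none, k = 5), "fewer than k")
})

test_that("motion expansion is the 6 parameters plus backward differences", {
  z <- matrix(0, 10, 6)
  expect_equal(motion_regressors(z), matrix(0, 10, 12), ignore_attr = TRUE)
  step <- z; step[5:10, 1] <- 1      # +1 mm step in x at volume 5
  r <- motion_regressors(step)
  expect_equal(r[, 7], c(rep(0, 4), 1, rep(0, 5)), ignore_attr = TRUE)
  const <- matrix(2, 10, 6)
  rc <- motion_regressors(const)
  expect_true(all(rc[, 1:6] == 2) && all(rc[, 7:12] == 0))
})

test_that("volume flagging follows the composite-motion and intensity rules", {
  set.seed(5)
  n_t <- 50
  quiet <- bold_from_matrix(matrix(1, n_t, 8))
  zero_mo <- matrix(0, n_t, 6)
  expect_length(flag_bad_volumes(quiet, zero_mo), 0)
  # one planted 2 mm translation jump between volumes 19 and 20:
  # composite displacement exceeds 0.9 mm exactly at the post-jump volume
  mo <- zero_mo; mo[20:n_t, 1] <- 2
  b <- bold_from_matrix(matrix(rnorm(n_t * 8), n_t, 8))
  expect_identical(flag_bad_volumes(b, mo), 20L)
  # rotations count through the 65 mm arc: 0.02 rad -> 1.3 mm
  mo2 <- zero_mo; mo2[31:n_t, 5] <- 0.02
  expect_identical(flag_bad_volumes(b, mo2), 31L)
  # global-intensity spike flags the spiked volume
  mat <- matrix(rnorm(n_t * 8, sd = 0.01), n_t, 8)
  mat[25, ] <- mat[25, ] + 50
  flags <- flag_bad_volumes(bold_from_matrix(mat), zero_mo)
  expect_true(25 %in% flags)
})

test_that("flagging covers the planted spikes of a simulated session", {
  cfg <- small_config(spike_rate = 0.08, spike_mm = 1.5, n_volumes = 80)
  s <- generate_session(cfg, rng_state = 31)
  flags <- flag_bad_volumes(s$bold, s$motion)
  expect_true(all(s$truth$spike_volumes %in% flags))
})

test_that("exclusion uses strict 30% / 3 mm boundaries", {
  mo <- matrix(0.2, 350, 6)
  ok <- qc_exclusion(integer(0), 350, mo)
  expect_false(ok$excluded)
  # 106/350 = 30.3% > 30% -> excluded; 105/350 = 30% exactly -> kept
  expect_true(qc_exclusion(seq_len(106), 350, mo)$excluded)
  expect_false(qc_exclusion(seq_len(105), 350, mo)$excluded)
  # 3 mm exactly -> kept; 3.1 mm -> excluded even with no bad volumes
  mo3 <- mo; mo3[7, 2] <- 3.0
  expect_false(qc_exclusion(integer(0), 350, mo3)$excluded)
  mo31 <- mo; mo31[7, 2] <- 3.1
  r <- qc_exclusion(integer(0), 350, mo31)
  expect_true(r$excluded)
  expect_match(r$reason, "3.10 mm")
})

test_that("cleaning orthogonalizes against every nuisance column", {
  set.seed(6)
  n_t <- 120
  mo <- matrix(cumsum(rnorm(n_t * 6, sd = 0.01)), n_t, 6)
  mat <- matrix(rnorm(n_t * 40), n_t, 40)
  b <- bold_from_matrix(mat)
  wm <- array(FALSE, c(40, 1, 1)); wm[31:35, 1, 1] <- TRUE
  csf <- array(FALSE, c(40, 1, 1)); csf[36:40, 1, 1] <- TRUE
  cc <- compcor_components(b, wm, csf, k = 5)
  nuis <- nuisance_matrix(cc, motion_regressors(mo))
  expect_equal(ncol(nuis), 19)
  bad <- c(10L, 55L)
  # residuals before filtering: regress manually and check orthogonality
  spikes <- matrix(0, n_t, 2); spikes[cbind(bad, 1:2)] <- 1
  res <- qr.resid(qr(cbind(nuis, spikes)), mat)
  dots <- abs(crossprod(nuis, res))
  norms <- outer(sqrt(colSums(nuis^2)), sqrt(colSums(res^2)))
  expect_lt(max(dots / norms), 1e-8)
})

test_that("scrubbed volumes have zero influence on the cleaned series", {
  set.seed(7)
  n_t <- 120
  mat <- matrix(rnorm(n_t * 10), n_t, 10)
  mo <- matrix(0, n_t, 6)
  nuis <- nuisance_matrix(matrix(rnorm(n_t * 2), n_t, 2),
                          motion_regressors(mo)[, , drop = FALSE])
  nuis <- nuis[, apply(nuis, 2, sd) > 0 | colnames(nuis) == "intercept"]
  bad <- c(30L, 31L, 90L)
  b1 <- bold_from_matrix(mat)
  mat2 <- mat
  mat2[bad, ] <- mat2[bad, ] + matrix(runif(length(bad) * 10, -50, 50),
                                      length(bad))
  b2 <- bold_from_matrix(mat2)
  c1 <- clean_timeseries(b1, nuis, bad)
  c2 <- clean_timeseries(b2, nuis, bad)
  expect_equal(c1$data, c2$data, tolerance = 1e-8)
})

test_that("band-pass response meets the stop/pass band specification", {
  tr <- 2
  n_t <- 350
  tt <- (0:(n_t - 1)) * tr
  filt <- butter_bandpass(0.01, 0.1, fs = 1 / tr, order = 2)
  gain_at <- function(f) {
    x <- sin(2 * pi * f * tt)
    y <- filtfilt_bandpass(x, filt)
    core <- 40:310  # avoid edge transients
    sd(y[core]) / sd(x[core])
  }
  expect_lt(20 * log10(gain_at(0.005)), -20)   # >= 20 dB attenuation
  expect_gt(20 * log10(gain_at(0.05)), -1)     # <= 1 dB attenuation
  # monotone attenuation away from the band on both sides
  lows <- sapply(c(0.002, 0.004, 0.006, 0.008), gain_at)
  expect_true(all(diff(lows) > 0))
  highs <- sapply(c(0.12, 0.15, 0.2, 0.24), gain_at)
  expect_true(all(diff(highs) < 0))
  # matches the analytic Butterworth magnitude (squared for filtfilt)
  analytic <- filter_response(filt, c(0.005, 0.05), 1 / tr)^2
  expect_equal(gain_at(0.005), analytic[1], tolerance = 0.05)
  expect_equal(gain_at(0.05), analytic[2], tolerance = 0.01)
})

test_that("smoothing: identity at fwhm 0, mean conservation, analytic kernel", {
  set.seed(8)
  a <- array(rnorm(12^3), c(12, 12, 12))
  expect_identical(smooth_map(a, 0, 3), a)
  const <- array(3.5, c(8, 8, 8))
  expect_equal(smooth_map(const, 8, 3), const, tolerance = 1e-12)
  # impulse response equals the normalized 3D Gaussian kernel
  n <- 17
  imp <- array(0, c(n, n, n)); imp[9, 9, 9] <- 1
  out <- smooth_map(imp, 8, 3)
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 3
  g <- seq_len(n) - 9
  k3 <- exp(-outer(outer(g^2, g^2, "+"), g^2, "+") / (2 * sigma^2))
  k3 <- array(k3, c(n, n, n)) / sum(k3)
  expect_lt(max(abs(out - k3)), 1e-6)
})

test_that("preprocessing is deterministic and excludes high-motion sessions", {
  cfg <- small_config(n_volumes = 60)
  s <- generate_session(cfg, rng_state = 41)
  m <- sim_masks(cfg)
  p1 <- preprocess_session(s$bold, s$motion, m)
  p2 <- preprocess_session(s$bold, s$motion, m)
  expect_identical(p1$cleaned$data, p2$cleaned$data)
  expect_equal(p1$n_retained, 55)
  # inject > 3 mm motion -> session excluded, no cleaned data
  mo <- s$motion; mo[40, 1] <- 4
  p3 <- preprocess_session(s$bold, mo, m)
  expect_true(p3$qc$excluded)
  expect_null(p3$cleaned)
})
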