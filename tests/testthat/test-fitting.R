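# peak detection and the three fitting models

test_that("peak detection finds a noiseless comb and nothing on a flat spectrum", {
  s <- preprocess(make_comb())
  pk <- detect_peaks(s)
  expect_equal(nrow(pk$peaks), 15)
  w <- seq(590, 650, by = 0.035)
  flat <- spectrum(w, rep(1, length(w)) + 1e-12 * seq_along(w))
  expect_equal(nrow(detect_peaks(flat, min_prominence = 0.5)$peaks), 0)
})

test_that("peak detection at SNR 10 recovers >= 13/15 peaks with no false positives", {
  hits <- integer(0); fps <- integer(0)
  centers <- seq(595, 645, length.out = 15)
  for (k in 1:100) {
    s <- preprocess(make_comb(noise_sd = 1 / 10, seed = k))
    pk <- detect_peaks(s)
    d <- vapply(pk$peaks$lambda_nm, function(x) min(abs(centers - x)),
                numeric(1))
    hits <- c(hits, sum(d < 0.3))
    fps <- c(fps, sum(d >= 0.3))
  }
  expect_gte(min(hits), 13)
  expect_equal(sum(fps), 0)
})

test_that("Lorentzian fit recovers an exact single line to sub-1e-4 nm", {
  s <- make_comb(centers = 620, gamma = 0.15)
  pk <- fit_lorentzian_superposition(s)
  expect_equal(nrow(pk$peaks), 1)
  expect_lt(abs(pk$peaks$lambda_nm - 620), 1e-4)
  expect_equal(pk$peaks$gamma_nm, 0.15, tolerance = 1e-3)
  expect_false(pk$unresolved)
})

test_that("Monte-Carlo scatter of fitted centers at SNR 40 is a few millinm", {
  errs <- c()
  centers <- seq(595, 645, length.out = 15)
  for (k in 1:30) {
    s <- make_comb(noise_sd = 1 / 40, seed = 200 + k)
    pk <- fit_lorentzian_superposition(s)
    for (cc in centers) {
      j <- which.min(abs(pk$peaks$lambda_nm - cc))
      if (abs(pk$peaks$lambda_nm[j] - cc) < 0.3)
        errs <- c(errs, pk$peaks$lambda_nm[j] - cc)
    }
  }
  # same order as the published ~0.005 nm at SNR 40 (order-level check)
  expect_gt(sd(errs), 0.005 / 5)
  expect_lt(sd(errs), 0.005 * 5)
  # unbiased: mean error well below the scatter
  expect_lt(abs(mean(errs)), sd(errs) / 3)
})

test_that("a blended pair half a linewidth apart raises the unresolved flag", {
  s <- make_comb(centers = c(620, 620.075), gamma = 0.15)
  pk <- fit_lorentzian_superposition(s)
  expect_true(pk$unresolved)
})

test_that("chirped sinusoid self-recovery is exact on noiseless data", {
  w <- seq(590, 650, by = 0.035)
  y <- 0.8 * sin(4.5 * (1 - 5e-7 * (w - 590)^2) * w + 1.0) + 1.2
  f <- fit_chirped_sinusoid(spectrum(w, y))
  expect_equal(f$model$A, 0.8, tolerance = 1e-6)
  expect_equal(f$model$k, 4.5, tolerance = 1e-6)
  expect_equal(f$model$B, 5e-7, tolerance = 1e-6 * 5e-7 + 1e-12)
  expect_equal(f$model$phi %% (2 * pi), 1.0, tolerance = 1e-5)
  expect_lt(f$rms, 1e-8)
})

test_that("fitted chirp constant is consistent with zero for unchirped data", {
  # B = 0 truth at SNR 10: |B| below 3 of its own standard errors
  nb <- 0
  for (k in 1:10) {
    w <- seq(590, 650, by = 0.035)
    set.seed(400 + k)
    y <- 0.8 * sin(4.5 * w + 1.0) + 1.2 + rnorm(length(w), sd = 0.08)
    f <- fit_chirped_sinusoid(spectrum(w, y))
    sB <- f$model$sigma[3]
    if (is.finite(sB) && abs(f$model$B) < 3 * sB) nb <- nb + 1
  }
  expect_gte(nb, 8)
})

test_that("inverse-wavelength sinusoid recovers its scale constant exactly", {
  w <- seq(590, 650, by = 0.035)
  kp <- 2 * pi * pi * 1.47 * 60000  # d = 60 um at n_eff = 1.47
  y <- 0.7 * sin(kp / w + 0.3) + 1
  f <- fit_inverse_wavelength_sinusoid(spectrum(w, y))
  expect_equal(f$model$kp, kp, tolerance = 1e-8)
  expect_equal(f$model$fsr_inv_nm, fsr_from_geometry(1.47, 60),
               tolerance = 1e-8)
  # implausible implied diameter is rejected
  y2 <- 0.7 * sin(kp / 30 / w + 0.3) + 1
  expect_error(fit_inverse_wavelength_sinusoid(spectrum(w, y2)), "rejected")
})

test_that("inverse-sinusoid initialization converges across noisy seeds at SNR >= 5", {
  ok <- 0
  kp <- 2 * pi * pi * 1.47 * 60000
  w <- seq(590, 650, by = 0.035)
  for (k in 1:50) {
    set.seed(500 + k)
    y <- 0.7 * sin(kp / w + 0.3) + 1 + rnorm(length(w), sd = 0.7 / 5)
    f <- tryCatch(fit_inverse_wavelength_sinusoid(spectrum(w, y)),
                  error = function(e) NULL)
    if (!is.null(f) && abs(f$model$kp - kp) / kp < 1e-3) ok <- ok + 1
  }
  expect_gte(ok, 48)
})

test_that("low-SNR sinusoid branch tracks true resonance positions to 0.03 nm", {
  sc <- synth_config(d0 = 60, snr = 10, seed = 3, polarizations = "TE")
  g <- generate_spectrum(sc)
  pk <- fit_spectrum(preprocess(g$spectrum))
  expect_true(pk$model_used %in% c("chirped-sinusoid", "inverse-sinusoid"))
  errs <- vapply(pk$peaks$lambda_nm, function(x)
    min(abs(g$truth$lines$lambda_nm - x)), numeric(1))
  expect_lt(median(errs), 0.03)
})

test_that("unchirped Eq-2 and Eq-3 models give coinciding peak grids", {
  # same inverse-wavelength comb fitted by both models: maxima must agree
  sc <- synth_config(d0 = 60, snr = 30, seed = 11, polarizations = "TE")
  s <- preprocess(generate_spectrum(sc)$spectrum)
  f2 <- fit_chirped_sinusoid(s)
  f3 <- fit_inverse_wavelength_sinusoid(s)
  m2 <- f2$peaks$peaks$lambda_nm
  m3 <- f3$peaks$peaks$lambda_nm
  common <- vapply(m3, function(x) min(abs(m2 - x)), numeric(1))
  expect_lt(median(common), 0.02)
})

test_that("model selection is deterministic in the estimated SNR", {
  s_hi <- preprocess(generate_spectrum(synth_config(snr = Inf))$spectrum)
  expect_equal(fit_spectrum(s_hi)$model_used, "lorentzian")
  s_lo <- preprocess(generate_spectrum(
    synth_config(snr = 8, seed = 1, polarizations = "TE"))$spectrum)
  expect_true(fit_spectrum(s_lo)$model_used %in%
                c("chirped-sinusoid", "inverse-sinusoid"))
  # threshold override forces the branch
  expect_equal(fit_spectrum(s_lo, snr_threshold = 1)$model_used, "lorentzian")
})

test_that("position-uncertainty surrogate scales as the Cramer-Rao form", {
  s1 <- peak_position_uncertainty(0.15, 40, 0.035)
  expect_equal(peak_position_uncertainty(0.15, 80, 0.035), s1 / 2)
  expect_lt(peak_position_uncertainty(0.15, 1e9, 0.035), 1e-9)
  # denser sampling reduces the uncertainty
  expect_lt(peak_position_uncertainty(0.15, 40, 0.0175), s1)
  # instrument regime: same order as the published ~0.005 nm (factor 3)
  expect_gt(s1, 0.005 / 3)
  expect_lt(s1, 0.005 * 3)
})
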