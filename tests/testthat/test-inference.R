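# diameter and refractive-index inference

test_that("FSR estimator is exact on exactly periodic-in-1/lambda peaks", {
  u <- 1 / 620 + (0:14) * fsr_from_geometry(1.47, 60)
  pk <- peak_set(data.frame(lambda_nm = sort(1 / u), gamma_nm = 0.15,
                            amplitude = 1, sigma_lambda_nm = 0.005))
  est <- diameter_from_fsr(pk, n_eff = 1.47)
  expect_equal(est$d_um, 60, tolerance = 1e-9)
  expect_equal(est$method, "fsr")
  # telescoped and mean-of-differences forms agree by construction; the
  # estimate is invariant under removing interior peaks
  pk2 <- peak_set(pk$peaks[-c(4, 9), ])
  expect_equal(diameter_from_fsr(pk2, 1.47)$d_um, 60, tolerance = 1e-9)
})

test_that("two peaks still give a valid estimate with a large uncertainty", {
  u <- 1 / 620 + (0:1) * fsr_from_geometry(1.47, 60)
  pk <- peak_set(data.frame(lambda_nm = sort(1 / u), gamma_nm = 0.15,
                            amplitude = 1, sigma_lambda_nm = 0.005))
  est <- diameter_from_fsr(pk, 1.47)
  expect_equal(est$d_um, 60, tolerance = 1e-6)
  u15 <- 1 / 620 + (0:14) * fsr_from_geometry(1.47, 60)
  pk15 <- peak_set(data.frame(lambda_nm = sort(1 / u15), gamma_nm = 0.15,
                              amplitude = 1, sigma_lambda_nm = 0.005))
  expect_gt(est$sigma_d_um, diameter_from_fsr(pk15, 1.47)$sigma_d_um)
})

test_that("FSR estimate from the asymptotic TE ladder quantifies the n_eff bias", {
  # the Airy dispersion term makes the ladder ~1% denser than the
  # geometric FSR at n_eff = n_LD: the recovered d is biased low by that much
  lad <- mode_ladder(60, optical_config(), polarizations = "TE")
  pk <- peak_set(data.frame(lambda_nm = lad$lambda_nm, gamma_nm = 0.15,
                            amplitude = 1, sigma_lambda_nm = 0.005))
  est <- diameter_from_fsr(pk, n_eff = 1.47)
  expect_equal(est$d_um, 59.35, tolerance = 1e-3)
  expect_lt(abs(est$d_um - 60) / 60, 0.015)
})

test_that("interleaved TE/TM ladders are split before the FSR estimate", {
  full <- mode_ladder(60, optical_config())
  pk <- peak_set(data.frame(lambda_nm = full$lambda_nm, gamma_nm = 0.15,
                            amplitude = 1, sigma_lambda_nm = 0.005))
  lads <- split_polarization_ladders(pk)
  expect_length(lads, 2)
  # each recovered ladder is a single polarization of the forward model
  for (lp in lads) {
    matched <- vapply(lp$peaks$lambda_nm, function(x) {
      i <- which.min(abs(full$lambda_nm - x))
      full$polarization[i]
    }, character(1))
    expect_length(unique(matched), 1)
  }
  est <- diameter_from_fsr(pk, n_eff = 1.47)
  expect_equal(est$d_um, 59.35, tolerance = 0.01)
})

test_that("mode-assignment fit recovers diameter and mode numbers from a noiseless comb", {
  sc <- synth_config(d0 = 60, n_cell = 1.36, snr = Inf)
  g <- generate_spectrum(sc)
  pk <- fit_lorentzian_superposition(g$spectrum)
  est <- diameter_from_mode_fit(pk, optical_config(n_cell = 1.36))
  expect_equal(est$d_um, 60, tolerance = 2e-5)  # sub-nm on a 60 um droplet
  expect_lt(est$sigma_d_um, diameter_from_fsr(pk, 1.47)$sigma_d_um * 10)
  asg <- attr(est, "assignment")
  truth <- g$truth$lines
  j <- vapply(asg$lambda_nm, function(x) which.min(abs(truth$lambda_nm - x)),
              integer(1))
  expect_equal(asg$l, truth$l[j])
  expect_equal(asg$polarization, truth$polarization[j])
})

test_that("mode fit stays within 3 sigma of truth across noisy seeds", {
  hits <- 0
  for (k in 1:20) {
    sc <- synth_config(d0 = 60, n_cell = 1.36, snr = 40, seed = 600 + k)
    pk <- fit_lorentzian_superposition(preprocess(generate_spectrum(sc)$spectrum))
    est <- tryCatch(diameter_from_mode_fit(pk, optical_config(n_cell = 1.36)),
                    error = function(e) NULL)
    if (is.null(est)) next
    # allow for the shared systematic bias of baseline-subtracted fits
    if (abs(est$d_um - 60) < 3 * est$sigma_d_um + 5e-3) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("single-polarization combs cannot identify n_cell", {
  sc <- synth_config(d0 = 60, snr = Inf, polarizations = "TE")
  pk <- fit_lorentzian_superposition(generate_spectrum(sc)$spectrum)
  expect_warning(
    est <- diameter_from_mode_fit(pk, optical_config(n_cell = 1.36),
                                  fit_ncell = TRUE),
    "not identifiable")
  expect_true(is.na(est$n_cell_fit))
})

test_that("shift tracking is exact under a global wavelength scaling", {
  lad <- mode_ladder(60, optical_config(), polarizations = "TE")
  mk <- function(lams) peak_set(data.frame(
    lambda_nm = lams, gamma_nm = 0.15, amplitude = 1, sigma_lambda_nm = 0.005))
  eps <- 1e-5
  d0 <- size_estimate(60, 1e-3, "fsr", n_eff_assumed = 1.47)
  tr <- track_diameter_change(list(mk(lad$lambda_nm),
                                   mk(lad$lambda_nm * (1 + eps))),
                              times_min = c(0, 30), d0 = d0)
  expect_equal(tr$dd_nm[2], 0.6, tolerance = 1e-6)  # eps * d0 = 1e-5 * 60 um
  # independent of how many peaks participate
  tr2 <- track_diameter_change(list(mk(lad$lambda_nm[1:5]),
                                    mk(lad$lambda_nm[1:5] * (1 + eps))),
                               times_min = c(0, 30), d0 = d0)
  expect_equal(tr2$dd_nm[2], 0.6, tolerance = 1e-6)
})

test_that("a 1 um/h lipolysis ramp is recovered within 5% at SNR 20", {
  traj <- data.frame(t_min = seq(0, 60, by = 12),
                     d_um = 60 - seq(0, 1, length.out = 6), n_cell = 1.36)
  sc <- synth_config(d0 = 60, snr = 20, seed = 42, scenario = "custom",
                     trajectory = traj)
  pks <- lapply(1:6, function(i)
    fit_spectrum(preprocess(generate_spectrum(sc, i)$spectrum)))
  tr <- track_diameter_change(pks, traj$t_min)
  rate <- mean(tr$rate_um_per_h[-1])
  expect_equal(rate, -1, tolerance = 0.05)
})

test_that("inferred and true diameter changes correlate with R2 >= 0.99 across cells", {
  res <- t(vapply(0:9, function(seed) {
    ft <- fit_trajectory(d0 = 40 + 4 * seed, dd_total = 0.5 + 0.5 * seed,
                         seed = seed)
    tr <- track_diameter_change(ft$peaks, ft$traj$t_min)
    c(true = -(0.5 + 0.5 * seed) * 1e3, est = tr$dd_nm[nrow(tr)])
  }, numeric(2)))
  r2 <- summary(stats::lm(est ~ true, as.data.frame(res)))$r.squared
  expect_gte(r2, 0.99)
})

test_that("confidence intervals for tracked changes cover the truth", {
  covered <- 0; total <- 0
  for (k in 1:25) {
    dd_true <- 0.3
    ft <- fit_trajectory(d0 = 60, dd_total = dd_true, n_steps = 4,
                         seed = 700 + k, t_end = 90)
    tr <- track_diameter_change(ft$peaks, ft$traj$t_min)
    n <- nrow(tr)
    total <- total + 1
    half <- 1.96 * tr$dd_sigma_nm[n]
    if (abs(tr$dd_nm[n] - (-dd_true * 1e3)) < half) covered <- covered + 1
  }
  expect_gte(covered / total, 0.9)
})

test_that("minimal resolvable change follows d*ws/lambda", {
  expect_equal(min_resolvable_change(60, 0.04, 620), 60e3 * 0.04 / 620)
  expect_equal(min_resolvable_change(60, 0.04, 620), 3.871, tolerance = 1e-3)
  expect_equal(min_resolvable_change(60, 0.08, 620),
               2 * min_resolvable_change(60, 0.04, 620))
  # across the 600-690 nm detection band the figure stays between 3.5 and 4 nm
  vals <- min_resolvable_change(60, 0.04, seq(600, 690, by = 5))
  expect_true(all(vals >= 3.4 & vals <= 4.0))
})

test_that("index steps are recovered from TE/TM splitting to 0.002", {
  run_pair <- function(n1, n2) {
    pks <- lapply(c(n1, n2), function(ncl) {
      sc <- synth_config(d0 = 60, n_cell = ncl, snr = Inf)
      fit_lorentzian_superposition(preprocess(generate_spectrum(sc)$spectrum))
    })
    ns <- ncell_series_from_splitting(pks, cfg = optical_config(n_cell = 1.36))
    -attr(ns, "dn_cell")
  }
  expect_equal(run_pair(1.367, 1.339), 0.028, tolerance = 0.002 / 0.028)
  expect_equal(run_pair(1.392, 1.360), 0.032, tolerance = 0.002 / 0.032)
})

test_that("a constant-index series shows no spurious index drift", {
  pks <- lapply(c(801, 802, 803), function(sd_) {
    sc <- synth_config(d0 = 60, n_cell = 1.367, snr = 40, seed = sd_)
    fit_lorentzian_superposition(preprocess(generate_spectrum(sc)$spectrum))
  })
  ns <- ncell_series_from_splitting(pks, cfg = optical_config(n_cell = 1.36))
  dn <- attr(ns, "dn_cell")
  expect_lt(abs(dn), 3 * sqrt(sum(ns$sigma_ncell[c(1, 3)]^2)) + 1e-3)
})
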