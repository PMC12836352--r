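# forward optical model: asymptotic and exact Mie resonance positions

test_that("resonance wavelength scales exactly linearly with diameter", {
  cfg <- optical_config()
  l1 <- asymptotic_mode_position(439, "TE", 60, cfg)
  l2 <- asymptotic_mode_position(439, "TE", 120, cfg)
  expect_equal(l2, 2 * l1, tolerance = 1e-14)
})

test_that("asymptotic positions agree with the exact Mie oracle in the instrument regime", {
  # d = 60 um, 1.47/1.36, mode near 614 nm (frozen oracle values computed
  # with the Riccati-Bessel root finder and cross-checked externally)
  cfg <- optical_config()
  expect_equal(asymptotic_mode_position(439, "TE", 60, cfg), 614.5029,
               tolerance = 1e-6)
  expect_equal(exact_mode_position(439, "TE", 60, cfg), 614.5725,
               tolerance = 1e-6)
  for (pol in c("TE", "TM")) {
    la <- asymptotic_mode_position(439, pol, 60, cfg)
    le <- exact_mode_position(439, pol, 60, cfg)
    expect_lt(abs(la - le), 0.1)
  }
})

test_that("oracle agreement improves with angular mode number", {
  cfg <- optical_config(n_ld = 1.08 * 1.36, n_cell = 1.36)
  err_at <- function(l) {
    f <- mean(vapply(c("TE", "TM"), function(pol) {
      # choose d so the resonance sits near 620 nm
      la <- asymptotic_mode_position(l, pol, 60, cfg)
      d <- 60 * 620 / la
      abs(asymptotic_mode_position(l, pol, d, cfg) -
            exact_mode_position(l, pol, d, cfg))
    }, numeric(1)))
    f
  }
  e300 <- err_at(300)
  e600 <- err_at(600)
  expect_lt(e600, e300)
})

test_that("TE is red-shifted relative to TM at equal mode number", {
  for (rho_ncell in list(c(1.47, 1.36), c(1.47, 1.40), c(1.6, 1.35))) {
    cfg <- optical_config(rho_ncell[1], rho_ncell[2])
    lte <- asymptotic_mode_position(400, "TE", 60, cfg)
    ltm <- asymptotic_mode_position(400, "TM", 60, cfg)
    expect_gt(lte, ltm)
    expect_gt(exact_mode_position(400, "TE", 60, cfg),
              exact_mode_position(400, "TM", 60, cfg))
  }
})

test_that("resonance ladder is strictly decreasing in mode number", {
  cfg <- optical_config()
  lam <- asymptotic_mode_position(400:460, "TE", 60, cfg)
  expect_true(all(diff(lam) < 0))
  lam_ex <- vapply(420:425, exact_mode_position, numeric(1),
                   polarization = "TM", d = 60, cfg = cfg)
  expect_true(all(diff(lam_ex) < 0))
})

test_that("exact solver still finds roots at high contrast and low mode number", {
  cfg <- optical_config(n_ld = 2.0 * 1.36, n_cell = 1.36)
  lam <- exact_mode_position(60, "TE", 9, cfg, bracket_nm = 20)
  expect_true(is.finite(lam) && lam > 0)
})

test_that("FSR arithmetic matches the closed form and the mode ladder", {
  expect_equal(fsr_from_geometry(1.47, 60), 3.608956e-6, tolerance = 1e-6)
  expect_equal(fsr_wavelength_spacing(1.47, 60, 620), 1.387283,
               tolerance = 1e-6)
  expect_equal(fsr_from_geometry(1.47, 120), fsr_from_geometry(1.47, 60) / 2)
  # mean spacing of the asymptotic TE ladder matches 1/(pi n_eff d) for an
  # effective index between n_cell and n_LD: the Airy dispersion term makes
  # the working index n_LD / 1.0106 ~ 1.455 at this size
  cfg <- optical_config()
  lad <- mode_ladder(60, cfg, polarizations = "TE")
  du <- abs(mean(diff(1 / lad$lambda_nm)))
  n_eff_implied <- 1 / (pi * du * 60e3)
  expect_equal(n_eff_implied, 1.47 / 1.0106, tolerance = 0.005)
  expect_gt(n_eff_implied, cfg$n_cell)
  expect_lt(n_eff_implied, cfg$n_ld)
  expect_error(fsr_from_geometry(0.9, 60))
})

test_that("splitting parameter matches closed form and inverts exactly", {
  expect_equal(splitting_parameter(1.47 / 1.367), 0.3677, tolerance = 1e-3)
  expect_equal(splitting_parameter(1.47 / 1.339), 0.4127, tolerance = 1e-3)
  expect_lt(splitting_parameter(1.0001), 0.02)
  # round trip to machine precision
  for (rho in c(1.02, 1.075, 1.2, 1.8)) {
    n_cell <- 1.47 / rho
    expect_equal(invert_ncell_from_splitting(splitting_parameter(rho), 1.47),
                 n_cell, tolerance = 1e-12)
  }
  expect_equal(invert_ncell_from_splitting(0, 1.47), 1.47)
  expect_equal(invert_ncell_from_splitting(0.3677, 1.47), 1.367,
               tolerance = 1e-3)
  expect_equal(invert_ncell_from_splitting(0.4127, 1.47), 1.339,
               tolerance = 1e-3)
  expect_error(invert_ncell_from_splitting(1.01, 1.47))
  expect_error(splitting_parameter(0.99))
})

test_that("splitting parameter is consistent with the asymptotic TE-TM gap", {
  # at expansion order 1 the polarization enters only through P/sqrt(rho^2-1),
  # so the TE-TM gap equals S exactly; the order-2 term shrinks it
  cfg <- optical_config(expansion_order = 1)
  lte <- asymptotic_mode_position(439, "TE", 60, cfg)
  ltm <- asymptotic_mode_position(439, "TM", 60, cfg)
  S_obs <- (1 / ltm - 1 / lte) * pi * cfg$n_ld * 60e3
  expect_equal(S_obs, splitting_parameter(cfg$rho), tolerance = 1e-3)
  cfg2 <- optical_config(expansion_order = 2)
  S_obs2 <- (1 / asymptotic_mode_position(439, "TM", 60, cfg2) -
               1 / asymptotic_mode_position(439, "TE", 60, cfg2)) *
    pi * cfg2$n_ld * 60e3
  expect_lt(S_obs2, S_obs)
})

test_that("apparent size shift from an index perturbation behaves physically", {
  cfg <- optical_config(n_cell = 1.37)
  expect_identical(apparent_size_shift_from_index(0, 60, 620, cfg, "TM"), 0)
  dd <- apparent_size_shift_from_index(0.001, 60, 620, cfg, "TM")
  # a red shift is read as growth, ~2 nm for a 60 um droplet
  expect_gt(dd, 0)
  expect_equal(dd, 2.2, tolerance = 0.25 * 2.2)
  expect_lt(apparent_size_shift_from_index(-0.001, 60, 620, cfg, "TM"), 0)
})

test_that("evanescent penetration depth matches the closed form", {
  d88 <- penetration_depth(620, 1.47, 1.36)
  expect_equal(d88, 88.43, tolerance = 1e-3)
  expect_lt(d88, 100)
  # linear in wavelength, vanishing at infinite contrast
  expect_equal(penetration_depth(1240, 1.47, 1.36), 2 * d88)
  expect_lt(penetration_depth(620, 10, 1.36), 5)
  expect_error(penetration_depth(620, 1.3, 1.36))
})

test_that("optical config validates its invariants", {
  expect_error(optical_config(n_ld = 1.3, n_cell = 1.36), "guided")
  expect_error(optical_config(q = 0))
  expect_error(optical_config(band = c(650, 590)))
  cfg <- optical_config()
  expect_equal(cfg$rho, 1.47 / 1.36)
  expect_equal(cfg$airy_zero, 2.338107, tolerance = 1e-6)
})

test_that("mode ladder covers the band for both polarizations", {
  lad <- mode_ladder(60, optical_config())
  expect_true(all(lad$lambda_nm >= 590 & lad$lambda_nm <= 650))
  expect_setequal(unique(lad$polarization), c("TE", "TM"))
  expect_false(is.unsorted(lad$lambda_nm))
  expect_error(mode_ladder(0.5, optical_config()), "too small")
})
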