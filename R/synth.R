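#' Configuration for the synthetic-spectrum generator
#'
#' Defines the instrument and scenario emulated by [generate_spectrum()] and
#' [generate_timeseries()]: droplet size trajectory, optical constants,
#' linewidth, dye-gain envelope, SNR, sampling, and scenario type.  Defaults
#' reproduce the study conditions: 0.07 nm instrument resolution sampled at
#' its Nyquist step 0.035 nm, linewidth 0.15 nm, dye band 590--650 nm, and
#' SNR selectable between the low (~10) and high (~40) regimes.
#'
#' @param d0 Initial droplet diameter in um (default 60).
#' @param n_ld Droplet refractive index (default 1.47).
#' @param n_cell Cytoplasm refractive index (default 1.36).
#' @param polarizations Subset of `c("TE", "TM")` to include.
#' @param gamma_nm Lorentzian linewidth (FWHM) in nm, default 0.15.
#' @param gain_center_nm,gain_fwhm_nm Gaussian dye-gain envelope (615 nm /
#'   30 nm FWHM surrogate for the dye emission profile).
#' @param snr Target signal-to-noise ratio (`Inf` disables noise).
#' @param sampling_nm Grid step in nm (default 0.035).
#' @param band Wavelength band in nm (default `c(590, 650)`).
#' @param seed Integer seed controlling every noise draw.
#' @param scenario `"control"`, `"lipolysis"`, `"rupture"`, or `"custom"`.
#' @param trajectory Optional data frame `t_min`, `d_um`, `n_cell` giving
#'   the droplet trajectory; built by scenario defaults when `NULL`.
#' @param forward_model `"asymptotic"` (default; same model family as the
#'   fitters, so recovery tests isolate inference error) or `"exact"`.
#' @return A `wgm_synth_config` list.
#' @export
synth_config <- function(d0 = 60, n_ld = 1.47, n_cell = 1.36,
                         polarizations = c("TE", "TM"), gamma_nm = 0.15,
                         gain_center_nm = 615, gain_fwhm_nm = 30,
                         snr = 40, sampling_nm = 0.035, band = c(590, 650),
                         seed = 0L, scenario = c("control", "lipolysis",
                                                 "rupture", "custom"),
                         trajectory = NULL, forward_model = c("asymptotic",
                                                              "exact")) {
  scenario <- match.arg(scenario)
  forward_model <- match.arg(forward_model)
  stopifnot(d0 > 0, snr > 0, band[1] < band[2], sampling_nm > 0)
  if (is.null(trajectory))
    trajectory <- default_trajectory(scenario, d0, n_cell)
  stopifnot(all(c("t_min", "d_um", "n_cell") %in% names(trajectory)),
            !is.unsorted(trajectory$t_min, strictly = TRUE))
  structure(list(
    d0 = d0, n_ld = n_ld, n_cell = n_cell, polarizations = polarizations,
    gamma_nm = gamma_nm, gain_center_nm = gain_center_nm,
    gain_fwhm_nm = gain_fwhm_nm, snr = snr, sampling_nm = sampling_nm,
    band = as.numeric(band), seed = as.integer(seed), scenario = scenario,
    trajectory = trajectory, forward_model = forward_model
  ), class = "wgm_synth_config")
}

# scenario trajectories: time in minutes
# control: constant diameter with ws-equivalent jitter added at generation;
# lipolysis: slow baseline shrinkage with a 30-min burst up to 1 um/h;
# rupture: constant size, cytoplasm index step (membrane rupture) at t=60
#          plus lasing-like linewidth narrowing and amplitude jump.
default_trajectory <- function(scenario, d0, n_cell) {
  switch(scenario,
    control = data.frame(t_min = seq(0, 180, by = 30),
                         d_um = d0, n_cell = n_cell),
    lipolysis = {
      t <- seq(0, 180, by = 15)
      # piecewise rate in um/h: 0.1 baseline, 1.0 burst in (60, 90], 0.3 after
      rate <- ifelse(t <= 60, 0.1, ifelse(t <= 90, 1.0, 0.3))
      dd <- cumsum(c(0, diff(t) / 60 * rate[-1]))
      data.frame(t_min = t, d_um = d0 - dd, n_cell = n_cell)
    },
    rupture = data.frame(t_min = seq(0, 120, by = 30),
                         d_um = d0,
                         n_cell = c(1.367, 1.367, 1.339, 1.339, 1.339)),
    custom = stop("scenario 'custom' requires an explicit trajectory"))
}

#' Generate one synthetic WGM spectrum with ground truth
#'
#' Renders the mode ladder of the chosen forward model as Lorentzian lines
#' of width `gamma_nm`, weights them by the Gaussian dye-gain envelope,
#' samples on the configured grid and adds homoscedastic Gaussian noise
#' scaled so that the mean line amplitude over the noise standard deviation
#' equals the target SNR.  Fully reproducible: the noise draw is controlled
#' by `cfg$seed` and `t_index`.
#'
#' @param cfg A [synth_config()].
#' @param t_index Row of the trajectory to render (1-based, default 1).
#' @param gamma_nm,amp_scale Optional overrides of linewidth and a global
#'   amplitude factor (used by the rupture scenario's lasing transition).
#' @return A list with `spectrum` (a `wgm_spectrum`) and `truth` (list with
#'   `d_um`, `n_cell`, `t_min`, and a data frame `lines` of exact mode
#'   positions and amplitudes).
#' @export
generate_spectrum <- function(cfg, t_index = 1L, gamma_nm = NULL,
                              amp_scale = 1) {
  stopifnot(inherits(cfg, "wgm_synth_config"))
  row <- cfg$trajectory[t_index, ]
  if (is.null(gamma_nm)) gamma_nm <- cfg$gamma_nm
  ocfg <- optical_config(cfg$n_ld, row$n_cell, band = cfg$band)
  ladder <- mode_ladder(row$d_um, ocfg, polarizations = cfg$polarizations,
                        model = cfg$forward_model)
  gain_sd <- cfg$gain_fwhm_nm / (2 * sqrt(2 * log(2)))
  amps <- amp_scale * exp(-(ladder$lambda_nm - cfg$gain_center_nm)^2 /
                            (2 * gain_sd^2))
  w <- seq(cfg$band[1], cfg$band[2], by = cfg$sampling_nm)
  y <- lorentz_comb(w, ladder$lambda_nm, amps, rep(gamma_nm, nrow(ladder)))
  if (is.finite(cfg$snr)) {
    noise_sd <- mean(amps) / cfg$snr
    # deterministic, decorrelated noise per (seed, t_index)
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed((cfg$seed * 1009L + as.integer(t_index)) %% .Machine$integer.max)
    y <- y + stats::rnorm(length(w), sd = noise_sd)
  }
  s <- spectrum(w, y, t_min = row$t_min, resolution_nm = 0.07)
  list(spectrum = s,
       truth = list(d_um = row$d_um, n_cell = row$n_cell, t_min = row$t_min,
                    gamma_nm = gamma_nm,
                    lines = cbind(ladder, amplitude = amps)))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic time series with ground truth
#'
#' Renders every trajectory row of a scenario.  The control scenario adds a
#' Gaussian diameter jitter equivalent to the observed peak-scatter floor
#' (`ws`, default 0.04 nm: jitter amplitude `d * ws / lambda`); the rupture
#' scenario narrows the linewidth to 0.05 nm and boosts amplitudes 5x after
#' the index step (subthreshold-to-lasing transition).  Optionally writes
#' the spectra, manifest and truth table in the formats [read_spectrum()]
#' and [read_manifest()] consume.
#'
#' @param cfg A [synth_config()].
#' @param dir Optional output directory; when given, spectra are written as
#'   CSV plus `manifest.csv` and `truth.csv`.
#' @param cell_id Cell identifier recorded in metadata.
#' @param ws_nm Peak-scatter floor emulated in the control scenario.
#' @return List with `spectra` (list of `wgm_spectrum`), `truth` (data
#'   frame `t_min`, `d_um`, `n_cell`, `gamma_nm`), and, if written, `dir`
#'   and `manifest`.
#' @export
generate_timeseries <- function(cfg, dir = NULL, cell_id = "cell1",
                                ws_nm = 0.04) {
  stopifnot(inherits(cfg, "wgm_synth_config"))
  traj <- cfg$trajectory
  n <- nrow(traj)
  lam_ref <- mean(cfg$band)
  if (cfg$scenario == "control") {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
    set.seed((cfg$seed * 2003L + 1L) %% .Machine$integer.max)
    jitter_um <- stats::rnorm(n, sd = traj$d_um * ws_nm / lam_ref)
    cfg$trajectory$d_um <- traj$d_um + jitter_um
    traj <- cfg$trajectory
  }
  rupture_step <- if (cfg$scenario == "rupture")
    which(diff(traj$n_cell) != 0)[1] + 1L else NA_integer_
  out <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    lasing <- !is.na(rupture_step) && i >= rupture_step
    g <- generate_spectrum(cfg, i,
                           gamma_nm = if (lasing) 0.05 else cfg$gamma_nm,
                           amp_scale = if (lasing) 5 else 1)
    g$spectrum$meta$cell_id <- cell_id
    out[[i]] <- g$spectrum
    truth[[i]] <- data.frame(t_min = g$truth$t_min, d_um = g$truth$d_um,
                             n_cell = g$truth$n_cell,
                             gamma_nm = g$truth$gamma_nm)
  }
  truth <- do.call(rbind, truth)
  res <- list(spectra = out, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, sprintf("%s_t%03d.csv", cell_id, seq_len(n)))
    for (i in seq_len(n)) write_spectrum(out[[i]], paths[i])
    manifest <- data.frame(cell_id = cell_id, t_min = truth$t_min,
                           path = paths)
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    res$dir <- dir
    res$manifest <- manifest
  }
  res
}
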