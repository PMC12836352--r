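# shared fixture builders (all synthetic, generated at test time)

# sparse equal-amplitude Lorentzian comb on a uniform grid
make_comb <- function(centers = seq(595, 645, length.out = 15), amp = 1,
                      gamma = 0.15, step = 0.035, band = c(590, 650),
                      noise_sd = 0, seed = NULL, baseline = 0) {
  w <- seq(band[1], band[2], by = step)
  y <- rep(0, length(w))
  for (cc in centers)
    y <- y + amp * (gamma / 2)^2 / ((w - cc)^2 + (gamma / 2)^2)
  if (length(baseline) == 1) baseline <- rep(baseline, length(w))
  y <- y + baseline
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(w), sd = noise_sd)
  }
  spectrum(w, y)
}

# a synthetic two-point lipolysis trajectory rendered with the package's
# generator, returning fitted peak sets
fit_trajectory <- function(d0, dd_total, n_steps = 6, snr = 20, seed = 0,
                           polarizations = c("TE", "TM"), t_end = 150) {
  traj <- data.frame(t_min = seq(0, t_end, length.out = n_steps),
                     d_um = seq(d0, d0 - dd_total, length.out = n_steps),
                     n_cell = 1.36)
  sc <- synth_config(d0 = d0, snr = snr, seed = seed, scenario = "custom",
                     trajectory = traj, polarizations = polarizations)
  pks <- lapply(seq_len(n_steps), function(i)
    fit_spectrum(preprocess(generate_spectrum(sc, i)$spectrum)))
  list(peaks = pks, traj = traj)
}
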