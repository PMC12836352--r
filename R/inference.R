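#' Size estimate container
#'
#' @param d_um Diameter in um.
#' @param sigma_d_um Uncertainty in um.
#' @param method `"fsr"`, `"mode-fit"`, or `"shift-track"`.
#' @param n_eff_assumed Effective index assumed (FSR method).
#' @param n_cell_fit Fitted cytoplasm index (mode fit), or `NA`.
#' @param sigma_ncell Uncertainty of the fitted index, or `NA`.
#' @return A `wgm_size_estimate` list.
#' @export
size_estimate <- function(d_um, sigma_d_um, method, n_eff_assumed = NA_real_,
                          n_cell_fit = NA_real_, sigma_ncell = NA_real_) {
  stopifnot(d_um > 0, sigma_d_um > 0)
  structure(list(d_um = d_um, sigma_d_um = sigma_d_um, method = method,
                 n_eff_assumed = n_eff_assumed, n_cell_fit = n_cell_fit,
                 sigma_ncell = sigma_ncell),
            class = "wgm_size_estimate")
}

#' @export
print.wgm_size_estimate <- function(x, ...) {
  cat(sprintf("LD diameter: %.4f +/- %.4f um (%s)%s\n", x$d_um, x$sigma_d_um,
              x$method,
              if (!is.na(x$n_cell_fit))
                sprintf(", n_cell = %.4f", x$n_cell_fit) else ""))
  invisible(x)
}

#' Split an interleaved TE/TM peak ladder into two single-polarization ladders
#'
#' A mixed TE+TM comb shows alternating short/long gaps in inverse
#' wavelength (the TE--TM splitting vs its complement to one FSR).  Gaps are
#' classified by a two-cluster 1-D split; when the alternation is clear the
#' peaks are divided into the two interleaved ladders.
#'
#' @param p A `wgm_peakset`.
#' @return A list of one (no interleaving detected) or two `wgm_peakset`
#'   objects.
#' @export
split_polarization_ladders <- function(p) {
  pk <- p$peaks
  if (nrow(pk) < 6) return(list(p))
  o <- order(pk$lambda_nm, decreasing = TRUE)  # ascending 1/lambda
  u <- 1 / pk$lambda_nm[o]
  gaps <- diff(u)
  m <- stats::median(gaps)
  lo <- gaps[gaps < m]; hi <- gaps[gaps >= m]
  if (length(lo) < 2 || length(hi) < 2) return(list(p))
  # robust cluster centers/spreads: a missed line makes a double-width gap
  # that must not mask the short/long alternation
  s_gap <- stats::median(lo); l_gap <- stats::median(hi)
  sep <- l_gap - s_gap
  spread <- max(stats::mad(lo), stats::mad(hi), 1e-12)
  if (sep < 4 * spread || sep < 0.2 * mean(gaps)) return(list(p))
  # walk the ladder: each gap is decomposed as a*short + b*long (missed
  # lines span several elementary gaps); odd a+b swaps the ladder, so a
  # missing line cannot flip the parity of everything after it
  lad <- integer(length(u)); lad[1] <- 1L
  cur <- 1L
  for (i in seq_along(gaps)) {
    best <- c(1L, 0L); bestres <- abs(gaps[i] - s_gap)
    for (a in 0:3) for (b in 0:3) {
      if (a + b == 0) next
      res <- abs(gaps[i] - (a * s_gap + b * l_gap))
      if (res < bestres) { bestres <- res; best <- c(a, b) }
    }
    if (sum(best) %% 2 == 1) cur <- 3L - cur
    lad[i + 1] <- cur
  }
  if (min(table(lad)) < 2) return(list(p))
  lapply(split(o, lad), function(i)
    peak_set(pk[i, , drop = FALSE], model_used = p$model_used, snr = p$snr,
             fit_residual = p$fit_residual))
}

#' Droplet diameter from the free spectral range
#'
#' Inverts the FSR relation: the mean spacing of consecutive resonances in
#' inverse wavelength equals `1 / (pi * n_eff * d)`, so
#' `d = 1 / (pi * n_eff * mean|delta(1/lambda)|)`.  The mean of consecutive
#' differences telescopes to `|1/lambda_last - 1/lambda_first| / (N-1)`;
#' both forms are computed and asserted equal.  The uncertainty propagates
#' the position uncertainties of the two end peaks.  If the ladder shows
#' the alternating-gap signature of interleaved TE/TM modes it is split
#' first and the per-ladder estimates combined.
#'
#' @param p A `wgm_peakset` with at least 3 peaks (2 accepted with inflated
#'   uncertainty).
#' @param n_eff Effective refractive index (default 1.47: the droplet index
#'   dominates, the evanescent cytoplasm contribution is percent-level).
#' @return A `wgm_size_estimate` with `method = "fsr"`.
#' @export
diameter_from_fsr <- function(p, n_eff = 1.47) {
  ladders <- split_polarization_ladders(p)
  ests <- lapply(ladders, function(lp) fsr_estimate_single(lp, n_eff))
  if (length(ests) == 1) return(ests[[1]])
  wts <- vapply(ests, function(e) 1 / e$sigma_d_um^2, numeric(1))
  d <- sum(vapply(ests, `[[`, numeric(1), "d_um") * wts) / sum(wts)
  size_estimate(d, sqrt(1 / sum(wts)), "fsr", n_eff_assumed = n_eff)
}

fsr_estimate_single <- function(p, n_eff) {
  pk <- p$peaks
  n <- nrow(pk)
  if (n < 2) stop("need at least 2 peaks for an FSR estimate")
  o <- order(pk$lambda_nm, decreasing = TRUE)  # ascending 1/lambda
  u <- 1 / pk$lambda_nm[o]
  gaps <- diff(u)
  mean_du <- mean(gaps)
  tele <- (u[n] - u[1]) / (n - 1)
  stopifnot(abs(mean_du - tele) < 1e-15 + 1e-9 * abs(tele))
  # detection can skip a weak line or admit a spurious one; count the
  # number of FSR intervals each gap spans (missed line -> 2, spurious
  # line -> 0 + 1) so the mean spacing stays per-mode
  n_int <- n - 1
  if (n >= 5) {
    m <- stats::median(gaps)
    k <- pmax(round(gaps / m), 0)
    if (sum(k) > 0) { mean_du <- (u[n] - u[1]) / sum(k); n_int <- sum(k) }
  }
  d_nm <- 1 / (pi * n_eff * mean_du)
  sig <- pk$sigma_lambda_nm[o]
  if (all(is.na(sig))) sig <- rep(0.01, n)
  sig_u <- sig / pk$lambda_nm[o]^2
  sigma_du <- sqrt(sig_u[1]^2 + sig_u[n]^2) / n_int
  sigma_d <- d_nm * sigma_du / mean_du
  size_estimate(d_nm / 1e3, max(sigma_d / 1e3, 1e-9), "fsr",
                n_eff_assumed = n_eff)
}

#' Droplet diameter (and optionally cytoplasm index) from mode assignment
#'
#' Assigns an angular mode number and polarization to every peak by matching
#' the observed ladder against the asymptotic first-order radial mode model,
#' then refines the diameter -- and, when both polarizations are present and
#' `fit_ncell = TRUE`, the cytoplasm index -- by least squares on the
#' wavelength residuals.  The search grid covers the FSR-based diameter
#' prior +/- 2%; integer mode-offset ambiguities appear as distinct minima
#' of the residual curve and raise an error when degenerate within twice
#' the best residual.
#'
#' @param p A `wgm_peakset` with >= 4 peaks.
#' @param cfg An [optical_config()]; `cfg$n_cell` is the assumed (or
#'   starting) cytoplasm index.
#' @param fit_ncell Also fit `n_cell` from the TE/TM splitting.
#' @param grid_halfwidth Relative half-width of the diameter search grid.
#' @return A `wgm_size_estimate` with `method = "mode-fit"`; the peak
#'   assignment is attached as attribute `"assignment"`.
#' @export
diameter_from_mode_fit <- function(p, cfg = optical_config(),
                                   fit_ncell = FALSE,
                                   grid_halfwidth = 0.02) {
  pk <- p$peaks
  if (nrow(pk) < 4) stop("mode fit needs at least 4 peaks")
  lam <- pk$lambda_nm
  band <- range(lam) + c(-1, 1)
  # diameter prior from the FSR of the (split) ladder, n_eff = n_ld
  d0 <- diameter_from_fsr(p, n_eff = cfg$n_ld)$d_um
  dgrid <- d0 * seq(1 - grid_halfwidth, 1 + grid_halfwidth,
                    length.out = 401)
  rms_for_d <- function(d) {
    lad <- mode_ladder(d, cfg, band = band)
    i <- vapply(lam, function(x) which.min(abs(lad$lambda_nm - x)),
                integer(1))
    sqrt(mean((lam - lad$lambda_nm[i])^2))
  }
  rms <- vapply(dgrid, rms_for_d, numeric(1))
  # candidate basins: distinct integer mode offsets are separated in d by
  # ~lambda/(pi*n_ld) (the rollover spacing); keep the best few basins and
  # decide between them after refinement, so that a poor starting n_cell
  # cannot fake a degeneracy
  basin_um <- mean(band) / (pi * cfg$n_ld) / 1e3
  o <- order(rms)
  cand <- dgrid[o[1]]
  for (i in o[-1]) {
    if (length(cand) >= 3) break
    if (all(abs(dgrid[i] - cand) > basin_um / 2)) cand <- c(cand, dgrid[i])
  }
  refined <- lapply(seq_along(cand), function(ci)
    refine_mode_fit(cand[ci], lam, cfg, fit_ncell, band, quiet = ci > 1))
  rr <- vapply(refined, `[[`, numeric(1), "rms")
  best <- which.min(rr)
  contender <- which(rr < 2 * rr[best] + 1e-12 & seq_along(rr) != best)
  if (length(contender) > 0)
    stop(sprintf(
      "ambiguous mode assignment: %d candidate diameters within 2x residual (e.g. %.3f vs %.3f um)",
      length(contender) + 1L, refined[[best]]$d,
      refined[[contender[1]]]$d))
  r <- refined[[best]]
  est <- size_estimate(r$d, r$sigma_d, "mode-fit",
                       n_eff_assumed = cfg$n_ld,
                       n_cell_fit = r$n_cell, sigma_ncell = r$sigma_n)
  attr(est, "assignment") <- r$assignment
  est
}

# iterative assignment + Levenberg-Marquardt refinement of (d [, n_cell])
# for one candidate basin
refine_mode_fit <- function(d_start, lam, cfg, fit_ncell, band,
                            quiet = FALSE) {
  d_best <- d_start
  warned <- quiet
  fit <- NULL
  for (iter in 1:3) {
    lad <- mode_ladder(d_best, cfg, band = band)
    i <- vapply(lam, function(x) which.min(abs(lad$lambda_nm - x)),
                integer(1))
    assign_l <- lad$l[i]
    assign_pol <- lad$polarization[i]
    if (fit_ncell && length(unique(assign_pol)) < 2) {
      if (!warned)
        warning("single-polarization ladder: n_cell not identifiable, fit_ncell disabled")
      warned <- TRUE
      fit_ncell <- FALSE
    }
    par0 <- if (fit_ncell) c(d_best, cfg$n_cell) else d_best
    fn <- function(pr) {
      ncl <- if (fit_ncell) pr[2] else cfg$n_cell
      ccfg <- optical_config(cfg$n_ld, ncl, cfg$q, cfg$band,
                             cfg$expansion_order)
      lam - asym_positions_vec(assign_l, assign_pol, pr[1], ccfg)
    }
    lower <- if (fit_ncell) c(d_best * 0.9, 1.30) else d_best * 0.9
    upper <- if (fit_ncell) c(d_best * 1.1, cfg$n_ld - 0.01) else d_best * 1.1
    fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                              fn = fn,
                              control = minpack.lm::nls.lm.control(maxiter = 100))
    d_new <- fit$par[1]
    if (fit_ncell) cfg <- optical_config(cfg$n_ld, fit$par[2], cfg$q,
                                         cfg$band, cfg$expansion_order)
    if (abs(d_new - d_best) < 1e-9) { d_best <- d_new; break }
    d_best <- d_new
  }
  cv <- tryCatch({
    dof <- max(length(lam) - length(fit$par), 1)
    s2 <- sum(fit$fvec^2) / dof
    s2 * chol2inv(chol(fit$hessian))
  }, error = function(e) NULL)
  sigma_d <- if (!is.null(cv)) sqrt(max(cv[1, 1], 0)) else NA_real_
  if (!is.finite(sigma_d) || sigma_d == 0) sigma_d <- 1e-6
  sigma_n <- if (fit_ncell && !is.null(cv)) sqrt(max(cv[2, 2], 0)) else NA_real_
  list(d = d_best, rms = sqrt(mean(fit$fvec^2)), sigma_d = sigma_d,
       n_cell = if (fit_ncell) cfg$n_cell else NA_real_, sigma_n = sigma_n,
       assignment = data.frame(lambda_nm = lam, l = assign_l,
                               polarization = assign_pol))
}

# vectorized asymptotic positions for mixed (l, polarization) vectors
asym_positions_vec <- function(l, pol, d, cfg) {
  out <- numeric(length(l))
  for (p in unique(pol)) {
    k <- pol == p
    out[k] <- asymptotic_mode_position(l[k], p, d, cfg)
  }
  out
}

#' Track nanometer-scale diameter changes across a time series
#'
#' Between consecutive time points, peaks are matched in inverse wavelength
#' (nearest neighbour after removing the shift expected from the FSR-based
#' diameter trend, which resolves rollovers where the true shift exceeds
#' half an FSR), and the diameter change is
#' `delta_d = d * mean(delta_lambda_i / lambda_i)` over matched peaks --
#' exact under a homothety of the spectrum.  The cumulative `delta_d(t)` is
#' referenced to the first time point.  Also reports the per-interval rate
#' in um/h, the observed peak-scatter `ws` (residual scatter of matched
#' peaks around the common shift, in nm), and the implied resolvable
#' change `(delta_d)_min = d * ws / lambda`.
#'
#' @param peaksets List of `wgm_peakset`, time-ordered.
#' @param times_min Numeric vector of acquisition times (minutes).
#' @param d0 A `wgm_size_estimate` for the first time point (computed from
#'   the first peak set if `NULL`).
#' @param cell_id Identifier carried into the output.
#' @param n_eff Effective index for the per-time FSR trend estimates.
#' @return A `wgm_size_track`: data frame (`cell_id`, `t_min`, `d_um`,
#'   `dd_nm`, `dd_sigma_nm`, `rate_um_per_h`, `n_matched`) with attributes
#'   `ws_nm`, `dd_min_nm`, `d0`.
#' @export
track_diameter_change <- function(peaksets, times_min, d0 = NULL,
                                  cell_id = NA_character_, n_eff = 1.47) {
  stopifnot(length(peaksets) == length(times_min), length(peaksets) >= 2,
            !is.unsorted(times_min, strictly = TRUE))
  lam_ref <- mean(peaksets[[1]]$peaks$lambda_nm)
  d_scale_corr <- 0
  if (is.null(d0)) {
    d0 <- diameter_from_fsr(peaksets[[1]], n_eff)
    # an internally derived FSR diameter is biased low by the Airy
    # dispersion of the mode ladder (~0.618*nu^(-2/3)); correct the scale
    # used to convert relative shifts into absolute nanometers
    nu0 <- pi * n_eff * d0$d_um * 1e3 / lam_ref
    d_scale_corr <- 0.6186 * nu0^(-2 / 3)
  }
  n_t <- length(peaksets)
  d_fsr <- vapply(peaksets, function(p)
    diameter_from_fsr(p, n_eff)$d_um, numeric(1))
  dd_step <- numeric(n_t - 1)
  sig_step <- numeric(n_t - 1)
  n_matched <- integer(n_t - 1)
  resid_scatter <- c()
  d_curr <- d0$d_um * (1 + d_scale_corr)
  d_series <- numeric(n_t); d_series[1] <- d_curr
  for (k in seq_len(n_t - 1)) {
    u1 <- 1 / peaksets[[k]]$peaks$lambda_nm
    u2 <- 1 / peaksets[[k + 1]]$peaks$lambda_nm
    fsr <- 1 / (pi * n_eff * d_curr * 1e3)
    # expected relative shift from the FSR-based diameter trend (resolves
    # rollover: |true shift| may exceed FSR/2), then refined by comb
    # alignment: the trend is only good to ~0.2 FSR, not enough to separate
    # same-polarization neighbours (1 FSR) from cross-polarization ones
    # (~0.4 FSR), so the shift that aligns the most peaks tightly wins,
    # with ties broken toward the trend
    shift_rel <- -(d_fsr[k + 1] - d_fsr[k]) / d_fsr[k]
    fsr_rel0 <- fsr / mean(u1)
    cand <- shift_rel + seq(-0.6, 0.6, by = 0.04) * fsr_rel0
    score <- vapply(cand, function(eps) {
      up <- u1 * (1 + eps)
      jj <- vapply(up, function(x) which.min(abs(u2 - x)), integer(1))
      sum(abs(u2[jj] - up) < 0.08 * fsr)
    }, numeric(1))
    top <- which(score >= max(score) - 1)
    best <- top[which.min(abs(cand[top] - shift_rel))]
    u1_pred <- u1 * (1 + cand[best])
    j <- vapply(u1_pred, function(x) which.min(abs(u2 - x)), integer(1))
    ok <- abs(u2[j] - u1_pred) < 0.2 * fsr
    if (sum(ok) < 2) {
      warning(sprintf("fewer than 2 matched peaks between t=%g and t=%g; gap flagged",
                      times_min[k], times_min[k + 1]))
      dd_step[k] <- NA_real_
      n_matched[k] <- sum(ok)
      d_series[k + 1] <- d_curr
      next
    }
    rel <- u1[ok] / u2[j][ok] - 1       # = delta_lambda / lambda
    # trim cross-polarization mismatches: in an interleaved comb the wrong
    # neighbour sits a large fraction of one FSR away, far outside the
    # tight cluster of true matches around the median shift
    if (length(rel) >= 4) {
      fsr_rel <- fsr / mean(u1[ok])     # one FSR in relative-shift units
      keep <- abs(rel - stats::median(rel)) < 0.15 * fsr_rel
      rel <- rel[keep]
      ok[ok] <- keep
    }
    dd_step[k] <- d_curr * mean(rel)    # um
    sig_step[k] <- d_curr * stats::sd(rel) / sqrt(length(rel))
    n_matched[k] <- sum(ok)
    lam_bar <- mean(1 / u1[ok])
    resid_scatter <- c(resid_scatter,
                       (rel - mean(rel)) * lam_bar)  # nm-scale residuals
    d_curr <- d_curr + dd_step[k]
    d_series[k + 1] <- d_curr
  }
  dd_cum <- cumsum(c(0, ifelse(is.na(dd_step), 0, dd_step)))
  rate <- dd_step / (diff(times_min) / 60)
  # observed peak scatter ws: within-step residual scatter of matched peaks
  # (incoherent fit noise) plus the temporal scatter of the track around a
  # linear trend (coherent wobble of a nominally stable droplet), in nm
  ws_resid <- if (length(resid_scatter) > 1) stats::sd(resid_scatter) else 0
  ws_temp <- 0
  if (n_t >= 4) {
    det <- stats::residuals(stats::lm(dd_cum ~ times_min))  # um
    ws_temp <- stats::sd(det) * lam_ref / d0$d_um
  }
  ws <- sqrt(ws_resid^2 + ws_temp^2)
  if (ws == 0) ws <- NA_real_
  # total uncertainty: accumulated matching noise plus the scale systematic
  # of the constant-n_eff assumption (the Airy dispersion term makes the
  # ladder spacing differ from the geometric FSR by ~0.618*nu^(-2/3), ~1%
  # here, which propagates multiplicatively into delta_d)
  nu_bar <- pi * n_eff * d0$d_um * 1e3 / lam_ref
  scale_sys <- 0.6186 * nu_bar^(-2 / 3)
  sig_cum <- sqrt(cumsum(c(0, ifelse(is.na(dd_step), 0, sig_step^2))) +
                    (scale_sys * dd_cum)^2)
  out <- data.frame(cell_id = cell_id, t_min = times_min,
                    d_um = d_series, dd_nm = dd_cum * 1e3,
                    dd_sigma_nm = sig_cum * 1e3,
                    rate_um_per_h = c(NA_real_, rate),
                    n_matched = c(NA_integer_, n_matched))
  structure(out, class = c("wgm_size_track", "data.frame"),
            ws_nm = ws,
            dd_min_nm = if (is.na(ws)) NA_real_ else
              min_resolvable_change(d0$d_um, ws, lam_ref),
            d0 = d0)
}

#' Minimal resolvable diameter change
#'
#' The peak-scatter floor `ws` (nm) observed on a stable droplet limits the
#' resolvable diameter change to `(delta_d)_min = d * ws / lambda`.
#'
#' @param d Diameter in um.
#' @param ws Peak-position scatter in nm.
#' @param lambda Wavelength in nm.
#' @return Resolvable change in nm.
#' @examples
#' min_resolvable_change(60, 0.04, 620)  # ~3.9 nm
#' @export
min_resolvable_change <- function(d, ws, lambda) {
  stopifnot(all(d > 0), all(ws >= 0), all(lambda > 0))
  (d * 1e3) * ws / lambda
}

#' Cytoplasm refractive-index time series from TE/TM splitting
#'
#' Per time point, runs the mode-assignment fit with `n_cell` free (the
#' droplet index held fixed), using the closed-form splitting inversion as
#' the initializer: the mean TE--TM pair separation gives
#' `S = delta_lambda * pi * n_LD * d / lambda^2` and
#' `n_cell = n_LD * sqrt(1 - S^2)`.  Reports the fitted index and its
#' uncertainty at every time point and the net change.
#'
#' @param peaksets List of `wgm_peakset`, time-ordered, each containing
#'   both polarizations.
#' @param d A `wgm_size_estimate` (used for the search prior).
#' @param cfg An [optical_config()]; `cfg$n_ld` is held fixed.
#' @param times_min Optional time stamps.
#' @return Data frame `t_min`, `n_cell`, `sigma_ncell`, with attribute
#'   `dn_cell` (last minus first fitted index).
#' @export
ncell_series_from_splitting <- function(peaksets, d = NULL,
                                        cfg = optical_config(),
                                        times_min = NULL) {
  if (is.null(times_min)) times_min <- seq_along(peaksets)
  res <- lapply(peaksets, function(p) {
    # initializer: the observed short-gap fraction of the interleaved
    # ladder is inverted through the full expansion (the leading-order
    # closed form n_cell = n_LD*sqrt(1-S^2) is biased at moderate nu
    # because the polarization-dependent nu^(-2/3) term shrinks the
    # apparent splitting); fall back to the caller's cfg on failure
    cfg_t <- tryCatch({
      S0 <- splitting_from_peakset(p)
      d0 <- diameter_from_fsr(p, n_eff = cfg$n_ld)$d_um
      nu_bar <- pi * cfg$n_ld * d0 * 1e3 / mean(p$peaks$lambda_nm)
      n0 <- invert_ncell_model(S0, nu_bar, cfg)
      optical_config(cfg$n_ld, n0, cfg$q, cfg$band, cfg$expansion_order)
    }, error = function(e) cfg)
    est <- tryCatch(diameter_from_mode_fit(p, cfg_t, fit_ncell = TRUE),
                    error = function(e) NULL)
    if (is.null(est))
      est <- diameter_from_mode_fit(p, cfg, fit_ncell = TRUE)
    if (is.na(est$n_cell_fit))
      stop("polarization unassigned: splitting-based index inversion not applicable")
    c(est$n_cell_fit, est$sigma_ncell)
  })
  m <- do.call(rbind, res)
  out <- data.frame(t_min = times_min, n_cell = m[, 1], sigma_ncell = m[, 2])
  structure(out, dn_cell = m[nrow(m), 1] - m[1, 1])
}

# invert the observed TE-TM short-gap fraction (of one FSR) to n_cell using
# the full asymptotic expansion at the working mode number nu_bar
invert_ncell_model <- function(s_obs, nu_bar, cfg) {
  frac_model <- function(rho) {
    fte0 <- mode_condition_rhs(nu_bar, rho, rho, cfg$airy_zero,
                               cfg$expansion_order)
    fte1 <- mode_condition_rhs(nu_bar + 1, rho, rho, cfg$airy_zero,
                               cfg$expansion_order)
    ftm0 <- mode_condition_rhs(nu_bar, 1 / rho, rho, cfg$airy_zero,
                               cfg$expansion_order)
    (ftm0 - fte0) / (fte1 - fte0)
  }
  r <- stats::uniroot(function(rho) frac_model(rho) - s_obs,
                      c(1.015, 1.35), tol = 1e-10)
  cfg$n_ld / r$root
}

# leading-order TE-TM splitting parameter from the alternating-gap pattern
# of an interleaved peak ladder: the short gap (TM -> TE of the same mode
# number, in inverse wavelength) as a fraction of one full FSR
splitting_from_peakset <- function(p) {
  pk <- p$peaks
  if (nrow(pk) < 6) stop("need >= 6 peaks to read the splitting")
  u <- sort(1 / pk$lambda_nm)
  gaps <- diff(u)
  odd <- mean(gaps[seq(1, length(gaps), by = 2)])
  even <- mean(gaps[seq(2, length(gaps), by = 2)])
  if (abs(odd - even) < 0.1 * (odd + even) / 2)
    stop("no alternating-gap signature: ladders not interleaved")
  min(odd, even) / (odd + even)
}
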