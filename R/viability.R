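#' Spectral transition score between two time points
#'
#' Composite dissimilarity of two spectra of the same cell, designed to
#' light up at a subthreshold-to-lasing transition.  Three components, each
#' in [0, 1] before weighting:
#' \itemize{
#'   \item decorrelation: `1 -` the maximum normalized cross-correlation of
#'     the mean-centered intensities over lags up to `max_lag_nm`;
#'   \item peakiness change: relative change of the crest factor
#'     (max / mean intensity), a scale-invariant proxy for the amplitude
#'     jump at lasing onset;
#'   \item linewidth change: relative change of the median fitted
#'     linewidth (lasing narrows the lines).
#' }
#' All components are invariant under a global intensity rescaling of
#' either spectrum.
#'
#' @param s_prev,s_curr Preprocessed `wgm_spectrum` objects on the same
#'   band.
#' @param weights Numeric length-3 weights (decorrelation, peakiness,
#'   linewidth); default `c(0.4, 0.3, 0.3)`.
#' @param max_lag_nm Maximum cross-correlation lag (default 2 nm, a few
#'   FSR-scale shifts).
#' @return Nonnegative transition score.
#' @export
spectral_transition_score <- function(s_prev, s_curr,
                                      weights = c(0.4, 0.3, 0.3),
                                      max_lag_nm = 2) {
  if (abs(min(s_prev$wavelength) - min(s_curr$wavelength)) > 1e-6 ||
      abs(max(s_prev$wavelength) - max(s_curr$wavelength)) > 1e-6)
    stop("band mismatch between spectra")
  y1 <- s_prev$intensity; y2 <- s_curr$intensity
  step <- stats::median(diff(s_prev$wavelength))
  max_lag <- max(1L, as.integer(round(max_lag_nm / step)))
  a <- y1 - mean(y1); b <- y2 - mean(y2)
  cc <- stats::ccf(a, b, lag.max = max_lag, plot = FALSE)$acf
  decorr <- max(0, min(1, 1 - max(cc)))
  # amplitude component: absolute peak height kept by preprocess() in the
  # metadata (invariant when both spectra are rescaled together); falls
  # back to the crest factor for spectra without it; relative change is
  # measured against the earlier spectrum and capped at 1
  a1 <- s_prev$meta$scale; a2 <- s_curr$meta$scale
  if (is.null(a1) || is.null(a2)) {
    crest <- function(y) max(y) / mean(y)
    a1 <- crest(y1); a2 <- crest(y2)
  }
  peaky <- min(abs(a2 - a1) / a1, 1)
  width_of <- function(s) {
    pk <- tryCatch(fit_lorentzian_superposition(s), error = function(e) NULL)
    if (is.null(pk) || nrow(pk$peaks) == 0) return(NA_real_)
    stats::median(pk$peaks$gamma_nm)
  }
  w1 <- width_of(s_prev); w2 <- width_of(s_curr)
  widthc <- if (is.na(w1) || is.na(w2)) 0 else min(abs(w2 - w1) / w1, 1)
  sum(weights * c(decorr, peaky, widthc))
}

#' Classify cell state from a size track, transition scores and index series
#'
#' Applies the diagnostic rules to one cell:
#' \itemize{
#'   \item `lasing_flag`: the spectral transition score between two
#'     consecutive time points crosses `lasing_threshold` (default 0.5);
#'   \item `rupture_flag`: the fitted cytoplasm index drops by at least
#'     `rupture_dn` (default 0.01) within two consecutive points (the
#'     observed membrane ruptures showed drops of 0.028 and 0.032);
#'   \item `static_flag`: the maximum |diameter change| over a trailing
#'     window of at least `static_window_h` hours stays below
#'     `3 * (delta_d)_min` while the population median change exceeds it
#'     (damaged cells lose LD dynamics).
#' }
#' All flags are monotone in their thresholds: raising a threshold never
#' creates a flag.
#'
#' @param track A `wgm_size_track` (>= 3 time points).
#' @param scores Transition scores between consecutive time points (length
#'   `nrow(track) - 1`), or `NULL` to skip lasing detection.
#' @param ncell_series Data frame from [ncell_series_from_splitting()], or
#'   `NULL` to skip rupture detection.
#' @param population_dd_nm Median |diameter change| of the surrounding cell
#'   population over the same window (nm); needed for `static_flag`.
#' @param lasing_threshold,rupture_dn,static_window_h Thresholds (defaults
#'   0.5, 0.01 refractive-index units, 3 h).
#' @param dd_min_nm Resolvable-change floor; taken from the track attribute
#'   when `NULL`.
#' @return Data frame of `wgm_viability_flags`: one row per time point with
#'   `t_min`, `transition_score`, `lasing_flag`, `rupture_flag`,
#'   `static_flag` and an `evidence` column (list of contributing values).
#' @export
classify_state <- function(track, scores = NULL, ncell_series = NULL,
                           population_dd_nm = NA_real_,
                           lasing_threshold = 0.5, rupture_dn = 0.01,
                           static_window_h = 3, dd_min_nm = NULL) {
  n <- nrow(track)
  if (n < 3) stop("need at least 3 time points")
  if (is.null(dd_min_nm)) dd_min_nm <- attr(track, "dd_min_nm")
  if (is.null(dd_min_nm) || is.na(dd_min_nm)) dd_min_nm <- 3.9
  lasing <- rep(FALSE, n); rupture <- rep(FALSE, n); static <- rep(FALSE, n)
  score_t <- rep(NA_real_, n)
  evidence <- vector("list", n)
  for (i in seq_len(n)) evidence[[i]] <- list()
  if (!is.null(scores)) {
    stopifnot(length(scores) == n - 1)
    score_t[-1] <- scores
    hit <- which(scores > lasing_threshold) + 1L
    lasing[hit] <- TRUE
    for (i in hit) evidence[[i]]$transition_score <- score_t[i]
  }
  if (!is.null(ncell_series)) {
    dn <- diff(ncell_series$n_cell)
    hit <- which(dn <= -rupture_dn) + 1L
    for (i in hit) {
      j <- which(track$t_min >= ncell_series$t_min[i])[1]
      if (is.na(j)) j <- n
      rupture[j] <- TRUE
      evidence[[j]]$dn_cell <- dn[i - 1L]
    }
  }
  if (!is.na(population_dd_nm)) {
    for (i in seq_len(n)) {
      in_win <- track$t_min >= track$t_min[i] - static_window_h * 60 &
        track$t_min <= track$t_min[i]
      if (diff(range(track$t_min[in_win])) < static_window_h * 60 - 1e-9) next
      own <- max(abs(track$dd_nm[in_win] - track$dd_nm[in_win][1]))
      if (own < 3 * dd_min_nm && population_dd_nm > 3 * dd_min_nm) {
        static[i] <- TRUE
        evidence[[i]]$max_abs_dd_nm <- own
        evidence[[i]]$population_dd_nm <- population_dd_nm
      }
    }
  }
  out <- data.frame(cell_id = track$cell_id, t_min = track$t_min,
                    transition_score = score_t, lasing_flag = lasing,
                    rupture_flag = rupture, static_flag = static)
  out$evidence <- evidence
  class(out) <- c("wgm_viability_flags", "data.frame")
  out
}
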