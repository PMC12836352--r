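#' Construct a spectrum object
#'
#' A spectrum is a two-column table of wavelength (nm) and intensity
#' (arbitrary units) plus acquisition metadata.  The wavelength grid is kept
#' strictly ascending; duplicate wavelengths are averaged.
#'
#' @param wavelength_nm Numeric vector, wavelength grid in nm.
#' @param intensity Numeric vector of the same length.
#' @param cell_id Optional cell identifier.
#' @param t_min Acquisition time in minutes.
#' @param excitation `"CW"` or `"pulsed"`.
#' @param exposure_s Exposure time in seconds.
#' @param resolution_nm Instrument resolution (FWHM) in nm, default 0.07.
#' @return A `wgm_spectrum` object (list with `wavelength`, `intensity`,
#'   `meta`).
#' @export
spectrum <- function(wavelength_nm, intensity, cell_id = NA_character_,
                     t_min = NA_real_, excitation = c("CW", "pulsed"),
                     exposure_s = NA_real_, resolution_nm = 0.07) {
  stopifnot(is.numeric(wavelength_nm), is.numeric(intensity),
            length(wavelength_nm) == length(intensity))
  if (length(wavelength_nm) < 16)
    stop("spectrum too short: need at least 16 samples")
  if (resolution_nm <= 0) stop("resolution must be positive")
  excitation <- match.arg(excitation)
  if (is.unsorted(wavelength_nm, strictly = FALSE)) {
    warning("wavelength grid not ascending; sorting")
    o <- order(wavelength_nm)
    wavelength_nm <- wavelength_nm[o]
    intensity <- intensity[o]
  }
  if (anyDuplicated(wavelength_nm)) {
    agg <- tapply(intensity, wavelength_nm, mean)
    wavelength_nm <- as.numeric(names(agg))
    intensity <- as.numeric(agg)
  }
  structure(list(
    wavelength = as.numeric(wavelength_nm),
    intensity = as.numeric(intensity),
    meta = list(cell_id = cell_id, t_min = t_min, excitation = excitation,
                exposure_s = exposure_s, resolution_nm = resolution_nm,
                preprocessed = FALSE, baseline_method = NA_character_)
  ), class = "wgm_spectrum")
}

#' @export
print.wgm_spectrum <- function(x, ...) {
  cat(sprintf("WGM spectrum: %d samples, %.2f-%.2f nm%s%s\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              if (!is.na(x$meta$cell_id)) paste0(", cell ", x$meta$cell_id) else "",
              if (!is.na(x$meta$t_min)) sprintf(", t = %g min", x$meta$t_min) else ""))
  invisible(x)
}

#' Read a spectrum from a text file
#'
#' Accepts two-column CSV or whitespace-delimited ASCII (optional header
#' line).  Non-monotone grids are sorted with a warning, duplicate
#' wavelengths averaged, unparseable rows reported by line number.
#'
#' @param path File path.
#' @param dialect `"csv"`, `"whitespace"`, or `"auto"` (default: by file
#'   extension).
#' @param ... Metadata fields passed to [spectrum()].
#' @return A `wgm_spectrum`.
#' @export
read_spectrum <- function(path, dialect = c("auto", "csv", "whitespace"), ...) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "whitespace"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  split_fun <- if (dialect == "csv") function(s) strsplit(s, ",")[[1]]
               else function(s) strsplit(trimws(s), "[[:space:]]+")[[1]]
  start <- 1L
  first <- suppressWarnings(as.numeric(split_fun(lines[1])))
  if (anyNA(first)) start <- 2L  # header line
  parsed <- lapply(lines[start:length(lines)], function(s)
    suppressWarnings(as.numeric(split_fun(s))))
  bad <- which(vapply(parsed, function(p) length(p) < 2 || anyNA(p[1:2]), logical(1)))
  if (length(bad))
    stop("unparseable rows at lines: ",
         paste(bad + start - 1L, collapse = ", "))
  w <- vapply(parsed, `[`, numeric(1), 1L)
  i <- vapply(parsed, `[`, numeric(1), 2L)
  if (length(w) < 16) stop("spectrum too short: need at least 16 samples")
  spectrum(w, i, ...)
}

#' Write a spectrum to a text file
#'
#' Two-column output, bit-exact round-trip at full double precision.
#'
#' @param s A `wgm_spectrum`.
#' @param path Output path.
#' @param dialect `"csv"` or `"whitespace"`.
#' @export
write_spectrum <- function(s, path, dialect = c("csv", "whitespace")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else " "
  header <- paste("wavelength_nm", "intensity", sep = sep)
  body <- paste(formatC(s$wavelength, format = "g", digits = 17),
                formatC(s$intensity, format = "g", digits = 17), sep = sep)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write a time-series manifest
#'
#' A manifest is a CSV with columns `cell_id`, `t_min`, `path` pointing at
#' one spectrum file per time point.
#'
#' @param path Manifest CSV path.
#' @return `read_manifest`: data frame with the three columns.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "t_min", "path")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  m[order(m$cell_id, m$t_min), need]
}

#' @rdname read_manifest
#' @param manifest Data frame with columns `cell_id`, `t_min`, `path`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[, c("cell_id", "t_min", "path")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Background-subtract and normalize a spectrum
#'
#' Subtracts a baseline (rolling median, default window 20x the instrument
#' resolution, or a polynomial of degree `k`), clips negatives to zero and
#' normalizes the maximum to 1.  Idempotent on already-flat baselines;
#' records the method in the metadata.
#'
#' @param s A `wgm_spectrum`.
#' @param baseline_method `"rolling-median"` or `"polynomial"`.
#' @param poly_degree Degree for the polynomial baseline (default 3).
#' @param window_nm Rolling-median window; default `20 * resolution`.
#' @return Preprocessed `wgm_spectrum` (max intensity 1).
#' @export
preprocess <- function(s, baseline_method = c("rolling-median", "polynomial"),
                       poly_degree = 3, window_nm = NULL) {
  baseline_method <- match.arg(baseline_method)
  y <- s$intensity
  w <- s$wavelength
  if (all(y == 0)) stop("all-zero spectrum")
  # idempotent: a spectrum that has already been background-subtracted and
  # normalized is returned unchanged
  if (isTRUE(s$meta$preprocessed)) return(s)
  if (baseline_method == "rolling-median") {
    if (is.null(window_nm)) window_nm <- 20 * s$meta$resolution_nm
    step <- stats::median(diff(w))
    k <- max(3L, as.integer(round(window_nm / step)))
    if (k %% 2 == 0) k <- k + 1L
    if (k >= length(y)) {
      baseline <- rep(stats::median(y), length(y))
    } else {
      baseline <- stats::runmed(y, k, endrule = "median")
    }
  } else {
    fit <- stats::lm(y ~ stats::poly(w, poly_degree))
    baseline <- stats::fitted(fit)
  }
  resid <- y - as.numeric(baseline)
  # noise scale measured before clipping (clipping halves the apparent
  # noise and would bias downstream detection thresholds)
  nsig <- stats::mad(diff(resid)) / sqrt(2)
  y2 <- as.numeric(pmax(resid, 0))
  if (max(y2) == 0) y2 <- pmax(y - min(y), 0)
  if (max(y2) == 0) stop("spectrum is constant: nothing above baseline")
  scale <- max(y2)
  y2 <- y2 / scale
  out <- s
  out$intensity <- y2
  out$meta$preprocessed <- TRUE
  out$meta$baseline_method <- baseline_method
  out$meta$noise_sigma <- nsig / scale
  out$meta$scale <- scale  # absolute peak height before normalization
  # unclipped residual kept for unbiased noise estimation downstream
  # (in-memory only; dropped by the text writers)
  out$meta$residual <- resid / scale
  out
}

#' Estimate the signal-to-noise ratio of a spectrum
#'
#' SNR is defined as the mean detected peak amplitude divided by the
#' standard deviation of the intensity in peak-free regions (the grid minus
#' +/- 3 widths around each detected peak).  Capped at 1e4; returns `NA`
#' when no peaks are detectable.
#'
#' @param s A preprocessed `wgm_spectrum`.
#' @param gamma_nm Assumed linewidth for the exclusion zones (default 0.15).
#' @param cap Upper cap (default 1e4).
#' @return SNR (dimensionless), or `NA_real_` if undefined.
#' @export
estimate_snr <- function(s, gamma_nm = 0.15, cap = 1e4) {
  pk <- detect_peaks(s)
  if (nrow(pk$peaks) < 3) return(NA_real_)  # no detectable comb
  w <- s$wavelength
  # exclusion half-width +/-3*Gamma, shrunk when the comb is so dense that
  # no peak-free region would remain
  free <- rep(TRUE, length(w))
  for (mult in c(3, 2, 1.5, 1)) {
    free <- rep(TRUE, length(w))
    for (lc in pk$peaks$lambda_nm)
      free[abs(w - lc) <= mult * gamma_nm] <- FALSE
    runs0 <- rle(free)
    if (sum(runs0$lengths[runs0$values] >= 8) >= 5) break
  }
  if (sum(free) < 10) return(NA_real_)
  # noise scale from 4th differences within contiguous peak-free segments:
  # the [1,-4,6,-4,1] filter (variance gain 70) annihilates the smooth
  # Lorentzian tails and gain envelope, leaving white noise
  # prefer the unclipped baseline residual kept by preprocess(); fall back
  # to the clipped intensities with a clipping-deflation correction
  src <- s$meta$residual
  clipped <- is.null(src)
  if (clipped) src <- s$intensity
  runs <- rle(free)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  d4 <- c()
  for (r in which(runs$values & runs$lengths >= 8)) {
    seg <- src[starts[r]:ends[r]]
    d4 <- c(d4, diff(seg, differences = 4))
  }
  if (length(d4) < 10) return(NA_real_)
  sigma <- stats::sd(d4) / sqrt(70)
  if (clipped) {
    # clipping correction: preprocessing clips negatives at 0 and the
    # rolling median centers valleys near zero, so a large fraction of the
    # noise samples in peak-free regions are clipped; the zero fraction
    # estimates the clipping point and the variance deflation of a
    # left-censored normal is undone
    vals <- s$intensity[free]
    p0 <- mean(vals == 0)
    if (p0 > 0.02) {
      p0 <- min(p0, 0.7)
      a <- -stats::qnorm(p0)
      ex <- a * stats::pnorm(a) + stats::dnorm(a)
      ex2 <- (a^2 + 1) * stats::pnorm(a) + a * stats::dnorm(a)
      deflation <- sqrt(ex2 - ex^2)  # sd of max(N(a,1),0)
      sigma <- sigma / deflation
    }
  }
  amp <- mean(pk$peaks$amplitude)
  if (sigma == 0) return(cap)
  min(amp / sigma, cap)
}
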