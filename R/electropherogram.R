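#' Electropherogram trace container
#'
#' A capillary-electrophoresis trace of a cDNA library: signal versus
#' fragment size (bp) or migration time (minutes).  Adapter-dimer
#' contamination shows up as a discrete peak below the library peak size
#' (around 88 bp on Ion Torrent chemistry, around 120 bp on Illumina
#' TruSeq small RNA libraries).
#'
#' @param x strictly increasing numeric positions (>= 16 points).
#' @param signal non-negative signal values, same length.
#' @param units `"bp"` or `"minutes"` (informational).
#' @return Object of class `epg_trace`.
#' @export
epg_trace <- function(x, signal, units = c("bp", "minutes")) {
  units <- match.arg(units)
  stopifnot(length(x) == length(signal), length(x) >= 16L,
            all(diff(x) > 0), all(signal >= 0))
  structure(list(x = as.numeric(x), signal = as.numeric(signal),
                 units = units), class = "epg_trace")
}

#' Read a trace from a 2-column CSV
#'
#' Columns x (size/time) and signal; a non-numeric first row is treated
#' as a header.
#'
#' @param path CSV path.
#' @param units see [epg_trace()].
#' @export
read_trace_csv <- function(path, units = "bp") {
  first <- read.table(path, sep = ",", nrows = 1L,
                      stringsAsFactors = FALSE)
  header <- is.na(suppressWarnings(as.numeric(first[[1]])))
  tab <- read.table(path, sep = ",", header = header,
                    stringsAsFactors = FALSE)
  epg_trace(tab[[1]], tab[[2]], units)
}

moving_average <- function(v, width = 5L) {
  if (length(v) < width) return(v)
  as.numeric(stats::filter(v, rep(1 / width, width), sides = 2L)) ->
    sm
  # edges: shrink the window instead of dropping points
  half <- width %/% 2L
  n <- length(v)
  for (i in seq_len(half)) {
    sm[i] <- mean(v[1:(i + half)])
    sm[n - i + 1L] <- mean(v[(n - i + 1L - half):n])
  }
  sm
}

call_peak_in_window <- function(x, sm, raw, lo, hi, baseline, thr,
                                floor_level) {
  idx <- which(x >= lo & x <= hi)
  if (length(idx) < 3L) return(NULL)
  inner <- idx[idx > 1L & idx < length(x)]
  is_max <- sm[inner] >= sm[inner - 1L] & sm[inner] >= sm[inner + 1L] &
    sm[inner] > thr
  cand <- inner[is_max]
  if (!length(cand)) return(NULL)
  peak <- cand[which.max(sm[cand])]
  # trapezoidal area over the window above the noise-floor level; not
  # rectified pointwise, so zero-mean residual noise cancels instead of
  # accumulating with window width
  y <- raw[idx] - floor_level
  area <- sum(diff(x[idx]) * (y[-1] + y[-length(y)]) / 2)
  list(center = x[peak], height = sm[peak] - baseline,
       area = max(area, 0), window = c(lo, hi))
}

#' Detect an adapter-dimer peak in a library electropherogram
#'
#' Smooths the signal (moving average, 5 points), estimates the baseline
#' as the 5th percentile of the smoothed signal, and calls a peak where a
#' local maximum exceeds `baseline + 3 * MAD` of the baseline-region
#' noise (estimated robustly from first differences, immune to
#' zero-clipped baselines).  Peak areas are trapezoidal integrals of the
#' raw signal above the quiet-region noise floor over each window.  The
#' tallest qualifying peak in the dimer and library windows is reported
#' together with the dimer-to-total area ratio
#' `dimer_area / (dimer_area + library_area)` (0 when no dimer peak is
#' called).
#'
#' @param trace an [epg_trace()].
#' @param dimer_window,library_window numeric `c(lo, hi)` windows in the
#'   trace's x units; must be disjoint and inside the x range.  Defaults
#'   match Ion Torrent sizing (dimers near 88 bp, libraries near 110 bp);
#'   use roughly 110-130 / 135-170 for Illumina TruSeq small RNA
#'   libraries.
#' @return List: `dimer` (peak call or `NULL`), `library` (peak call or
#'   `NULL`), `dimer_ratio`.
#' @export
detect_dimer_peak <- function(trace, dimer_window = c(80, 95),
                              library_window = c(100, 130)) {
  stopifnot(inherits(trace, "epg_trace"))
  lo <- min(trace$x); hi <- max(trace$x)
  win <- rbind(dimer_window, library_window)
  if (any(win[, 1] >= win[, 2]) || any(win < lo - 1e-9) ||
      any(win > hi + 1e-9))
    stop("peak windows must be ordered and inside the trace's x range")
  if (max(dimer_window) > min(library_window) &&
      max(library_window) > min(dimer_window) &&
      !(max(dimer_window) <= min(library_window) ||
        max(library_window) <= min(dimer_window)))
    stop("dimer and library windows must be disjoint")
  sm <- moving_average(trace$signal, 5L)
  baseline <- unname(quantile(sm, 0.05))
  # baseline-region noise, estimated robustly from first differences so
  # that zero-clipped baselines do not collapse the scale
  noise <- mad(diff(trace$signal)) / sqrt(2)
  thr <- baseline + 3 * noise
  if (max(sm) <= thr) {
    warning("flat or featureless trace; no peaks called")
    return(list(dimer = NULL, library = NULL, dimer_ratio = 0))
  }
  # noise-floor level for area subtraction: mean raw signal over the
  # quiet (non-peak) region
  quiet <- sm <= baseline + 2 * noise
  floor_level <- if (any(quiet)) mean(trace$signal[quiet]) else baseline
  dp <- call_peak_in_window(trace$x, sm, trace$signal, dimer_window[1],
                            dimer_window[2], baseline, thr, floor_level)
  lp <- call_peak_in_window(trace$x, sm, trace$signal, library_window[1],
                            library_window[2], baseline, thr, floor_level)
  ratio <- if (is.null(dp)) 0
           else if (is.null(lp)) 1
           else dp$area / (dp$area + lp$area)
  list(dimer = dp, library = lp, dimer_ratio = ratio)
}

#' Simulate an electropherogram trace
#'
#' Sum of Gaussian peaks (parameterised by center, standard deviation and
#' total area) plus seeded Gaussian noise, clipped at zero.
#'
#' @param peaks list of `c(center, sd, area)` triples (or a 3-column
#'   matrix).
#' @param noise_sd standard deviation of the additive noise.
#' @param x_grid positions at which to evaluate the trace.
#' @param seed RNG seed.
#' @param units see [epg_trace()].
#' @return An [epg_trace()].
#' @export
simulate_trace <- function(peaks, noise_sd = 0, x_grid = seq(40, 200, 0.5),
                           seed = 1L, units = "bp") {
  if (is.list(peaks)) peaks <- do.call(rbind, peaks)
  sig <- numeric(length(x_grid))
  if (!is.null(peaks) && length(peaks)) {
    peaks <- matrix(peaks, ncol = 3L)
    if (any(peaks[, 1] < min(x_grid) | peaks[, 1] > max(x_grid)))
      stop("peak centers must lie within the x grid")
    for (r in seq_len(nrow(peaks))) {
      ctr <- peaks[r, 1]; sd <- peaks[r, 2]; area <- peaks[r, 3]
      sig <- sig + area / (sd * sqrt(2 * pi)) *
        exp(-(x_grid - ctr)^2 / (2 * sd^2))
    }
  }
  if (noise_sd > 0)
    sig <- with_seed(seed, sig + rnorm(length(sig), 0, noise_sd))
  epg_trace(x_grid, pmax(sig, 0), units)
}
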