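# Empirical mode decomposition, analytic-signal phase extraction, and the
# session-level trimming rules that turn raw parcel signals into aligned
# instantaneous-phase matrices.

# Indices of strict local maxima and minima. Plateaus are collapsed by
# carrying the last nonzero slope sign forward, so a flat top counts once.
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(maxima = integer(), minima = integer()))
  d <- diff(x)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(list(maxima = integer(), minima = integer()))
  # carry last nonzero sign forward across zero-slope runs
  filled <- s
  last <- s[nz[1L]]
  for (i in seq_len(n - 1L)) {
    if (filled[i] == 0) filled[i] <- last else last <- filled[i]
  }
  turn <- which(diff(filled) != 0) + 1L
  maxima <- turn[filled[turn - 1L] > 0]
  minima <- turn[filled[turn - 1L] < 0]
  list(maxima = maxima, minima = minima)
}

# Cubic-spline envelope through extrema, with mirror extension of up to
# `n_mirror` extrema beyond each end to tame the boundary (end effect).
spline_envelope <- function(x, idx, n_mirror = 2L) {
  n <- length(x)
  k <- length(idx)
  m <- min(n_mirror, k)
  left_t <- 2 - rev(idx[seq_len(m)])          # reflect about t = 1
  left_v <- rev(x[idx[seq_len(m)]])
  right_t <- 2L * n - rev(rev(idx)[seq_len(m)])  # reflect about t = n
  right_v <- rev(rev(x[idx])[seq_len(m)])
  tt <- c(left_t, idx, right_t)
  vv <- c(left_v, x[idx], right_v)
  keep <- !duplicated(tt)
  f <- stats::splinefun(tt[keep], vv[keep], method = "fmm")
  f(seq_len(n))
}

sift_one_imf <- function(x, sd_threshold, max_sifts) {
  h <- x
  for (k in seq_len(max_sifts)) {
    ext <- local_extrema(h)
    if (length(ext$maxima) < 2L || length(ext$minima) < 2L) break
    upper <- spline_envelope(h, ext$maxima)
    lower <- spline_envelope(h, ext$minima)
    m <- (upper + lower) / 2
    h_new <- h - m
    denom <- sum(h^2)
    if (denom == 0) break
    sd_k <- sum((h - h_new)^2) / denom
    h <- h_new
    if (sd_k < sd_threshold) break
  }
  h
}

#' Empirical mode decomposition by envelope sifting
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) plus a slow
#' residual. Each sift finds local extrema, interpolates upper and lower
#' cubic-spline envelopes (with mirror extension of the outermost extrema to
#' mitigate the end effect), and subtracts the envelope mean; sifting stops
#' when the Cauchy-type criterion `sum((h_prev - h)^2) / sum(h_prev^2)`
#' falls below `sd_threshold` or after `max_sifts` passes. Extraction
#' recurses on the residual until `max_imfs` modes are found or the residual
#' has fewer than four extrema. Mode 1 of the returned set is the fastest
#' oscillation (mode index 0 in zero-based pipeline configs).
#'
#' The decomposition is complete by construction: the residual is defined as
#' the input minus the IMF sum, so `rowSums(cbind(imfs, residual))`
#' reproduces the input to machine precision.
#'
#' @param signal numeric vector, length >= 16, all finite.
#' @param max_imfs maximum number of modes to extract (default 4).
#' @param sd_threshold sifting stop threshold (default 0.2).
#' @param max_sifts cap on sifting passes per mode (default 100).
#'
#' @return an object of class `imf_set`: list with `imfs` (time x modes
#'   matrix, possibly 0 columns), `residual`, `n_imfs`, and `degenerate`
#'   (TRUE when the input had fewer than 4 extrema and was returned whole as
#'   the residual).
#' @export
sift_emd <- function(signal, max_imfs = 4L, sd_threshold = 0.2,
                     max_sifts = 100L) {
  signal <- as.numeric(signal)
  if (length(signal) < 16L) stop("signal too short for sifting (need >= 16 samples)")
  if (any(!is.finite(signal))) stop("non-finite values in signal")
  ext0 <- local_extrema(signal)
  if (length(ext0$maxima) + length(ext0$minima) < 4L) {
    return(structure(
      list(imfs = matrix(numeric(), length(signal), 0L), residual = signal,
           n_imfs = 0L, degenerate = TRUE),
      class = "imf_set"
    ))
  }
  imfs <- list()
  residual <- signal
  for (k in seq_len(max_imfs)) {
    ext <- local_extrema(residual)
    if (length(ext$maxima) + length(ext$minima) < 4L) break
    imf <- sift_one_imf(residual, sd_threshold, max_sifts)
    imfs[[k]] <- imf
    residual <- residual - imf
  }
  imfs <- if (length(imfs)) do.call(cbind, imfs) else
    matrix(numeric(), length(signal), 0L)
  colnames(imfs) <- if (ncol(imfs)) paste0("imf", seq_len(ncol(imfs)) - 1L)
  structure(
    list(imfs = imfs, residual = residual, n_imfs = ncol(imfs),
         degenerate = FALSE),
    class = "imf_set"
  )
}

#' @export
print.imf_set <- function(x, ...) {
  cat("imf_set: ", x$n_imfs, " IMF(s) + residual over ",
      length(x$residual), " samples",
      if (x$degenerate) " (degenerate: < 4 extrema)", "\n", sep = "")
  invisible(x)
}

# Phase unwrapping: remove 2*pi jumps from a wrapped phase sequence.
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1L], p[1L] + cumsum(d))
}

#' Instantaneous phase, amplitude and frequency via the analytic signal
#'
#' Builds the analytic signal in the frequency domain (double the
#' positive-frequency coefficients, zero the negative ones, leave DC and,
#' for even lengths, the Nyquist bin untouched) and returns its argument
#' (phase in (-pi, pi]), modulus (amplitude envelope) and the derivative of
#' the unwrapped phase as instantaneous frequency in Hz. Frequency uses
#' centered differences in the interior and one-sided differences at the
#' ends.
#'
#' @param imf numeric vector: a zero-mean narrowband component.
#' @param tr sampling interval in seconds.
#'
#' @return list with `phase`, `amplitude`, `frequency` (all same length as
#'   the input).
#' @export
analytic_phase <- function(imf, tr = 1) {
  imf <- as.numeric(imf)
  n <- length(imf)
  if (n < 4L) stop("input too short for the analytic signal")
  if (any(!is.finite(imf))) stop("non-finite values in input")
  if (all(imf == 0)) stop("all-zero input: phase undefined")
  X <- stats::fft(imf)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  phase <- Arg(z)
  amplitude <- Mod(z)
  up <- unwrap_phase(phase)
  freq <- numeric(n)
  freq[2:(n - 1L)] <- (up[3:n] - up[1:(n - 2L)]) / (2 * tr)
  freq[1L] <- (up[2L] - up[1L]) / tr
  freq[n] <- (up[n] - up[n - 1L]) / tr
  list(phase = phase, amplitude = amplitude, frequency = freq / (2 * pi))
}

#' Per-session instantaneous phase matrix
#'
#' Runs the full phase-extraction chain for every parcel of a session:
#' discard the first `discard_initial` seconds of raw signal (scan-onset
#' transients), sift with [sift_emd()], select the configured mode
#' (`mode_index` 0 = fastest), extract phase with [analytic_phase()], then
#' trim `edge_trim` samples from each end of the phase series (decomposition
#' edge artifacts). All parcels share one retained time grid.
#'
#' @param session a [session_series()].
#' @param config a [run_config()].
#' @param max_imfs forwarded to [sift_emd()].
#'
#' @return object of class `phase_series`: list with `phases` (time x
#'   parcels matrix in (-pi, pi]), `tr`, `parcel_ids`, `session_id`,
#'   `mode_index`, and `trimmed` (samples removed: `initial`, `edge`).
#' @export
session_phases <- function(session, config = run_config(), max_imfs = 4L) {
  stopifnot(inherits(session, "session_series"))
  tr <- session$tr
  n_raw <- nrow(session$data)
  n_discard <- floor(config$discard_initial / tr)
  n_keep <- n_raw - n_discard - 2L * config$edge_trim
  min_needed <- n_discard + 2L * config$edge_trim + 16L
  if (n_raw < min_needed) {
    stop("session '", session$session_id, "' too short: ", n_raw,
         " samples; need at least ", min_needed, " (", n_discard,
         " initial discard + 2 x ", config$edge_trim,
         " edge trim + 16 for sifting)")
  }
  keep_idx <- (n_discard + config$edge_trim + 1L):(n_raw - config$edge_trim)
  mode_col <- config$mode_index + 1L
  phases <- matrix(NA_real_, n_keep, ncol(session$data),
                   dimnames = list(NULL, session$parcel_ids))
  for (j in seq_len(ncol(session$data))) {
    x <- session$data[(n_discard + 1L):n_raw, j]
    dec <- sift_emd(x, max_imfs = max_imfs)
    if (dec$n_imfs < mode_col) {
      stop("parcel '", session$parcel_ids[j], "' in session '",
           session$session_id, "' yielded only ", dec$n_imfs,
           " mode(s); mode_index ", config$mode_index, " unavailable")
    }
    ph <- analytic_phase(dec$imfs[, mode_col], tr = tr)$phase
    phases[, j] <- ph[(config$edge_trim + 1L):(length(ph) - config$edge_trim)]
  }
  structure(
    list(phases = phases, tr = tr, parcel_ids = session$parcel_ids,
         session_id = session$session_id, mode_index = config$mode_index,
         trimmed = list(initial = n_discard, edge = config$edge_trim),
         raw_keep_idx = keep_idx),
    class = "phase_series"
  )
}

#' @export
print.phase_series <- function(x, ...) {
  cat("phase_series '", x$session_id, "' (mode ", x$mode_index, "): ",
      nrow(x$phases), " samples x ", ncol(x$phases), " parcels (",
      round(nrow(x$phases) * x$tr / 60, 2), " min retained; discarded ",
      x$trimmed$initial, " initial + 2 x ", x$trimmed$edge,
      " edge samples)\n", sep = "")
  invisible(x)
}

#' Retained minutes per session after trimming
#'
#' Arithmetic helper: retained samples = raw samples - floor(discard/tr)
#' - 2 * edge_trim, converted to minutes.
#'
#' @param n_samples raw samples per session.
#' @param tr sampling interval in seconds.
#' @param config a [run_config()].
#' @return minutes of retained data.
#' @export
retained_minutes <- function(n_samples, tr, config = run_config()) {
  n_keep <- n_samples - floor(config$discard_initial / tr) -
    2L * config$edge_trim
  if (n_keep <= 0) stop("trimming removes the whole session")
  n_keep * tr / 60
}
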