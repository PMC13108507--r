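# Phase-randomized surrogates preserving per-parcel amplitude spectra, and
# empirical-vs-null comparison statistics.

# Phase-randomize one real series: randomize positive-frequency phases,
# mirror to negative frequencies (Hermitian symmetry), leave DC and the
# Nyquist bin (even lengths) untouched so the inverse transform stays real.
phase_randomize_one <- function(x, seed) {
  n <- length(x)
  X <- stats::fft(x)
  # positive-frequency bins excluding DC; for even n, bin n/2+1 is Nyquist
  pos <- if (n %% 2L == 0L) seq(2L, n / 2L) else seq(2L, (n + 1L) / 2L)
  if (length(pos) == 0L) return(x)
  set.seed(seed)
  ang <- stats::runif(length(pos), 0, 2 * pi)
  X[pos] <- X[pos] * exp(1i * ang)
  X[n + 2L - pos] <- Conj(X[pos])
  Re(stats::fft(X, inverse = TRUE) / n)
}

#' Phase-randomized surrogate of a session
#'
#' For each parcel independently: Fourier transform, multiply every
#' positive-frequency coefficient by a random unit phasor, mirror the
#' conjugates onto the negative frequencies, keep DC and (for even lengths)
#' the Nyquist coefficient unchanged, and invert. The surrogate has exactly
#' the original per-parcel amplitude spectrum (hence autocorrelation, by
#' Wiener-Khinchin) but coordinated phase relationships between parcels are
#' destroyed. Each parcel uses a distinct sub-seed, so randomizations are
#' independent and the result is a pure function of `(session, seed)`.
#'
#' @param session a [session_series()] with >= 4 time points.
#' @param seed integer seed.
#' @return a [session_series()] of the same shape, session id suffixed
#'   `.surr`.
#' @export
phase_randomize <- function(session, seed = 1L) {
  stopifnot(inherits(session, "session_series"))
  if (nrow(session$data) < 4L) stop("need at least 4 time points")
  sur <- vapply(seq_len(ncol(session$data)), function(j) {
    phase_randomize_one(session$data[, j], seed = mix_seed(seed, j))
  }, numeric(nrow(session$data)))
  session_series(sur, tr = session$tr,
                 session_id = paste0(session$session_id, ".surr"),
                 parcel_ids = session$parcel_ids)
}

#' Null sync/metastability distribution from surrogate sessions
#'
#' For every session of the cohort, conceptually generates
#' `n_surrogates_per_session` phase-randomized surrogates and picks
#' `pick_per_session` of them at random; each picked surrogate is pushed
#' through the full phase-extraction and network-metrics pipeline. Because
#' every surrogate is a pure function of its per-(session, index) sub-seed,
#' only the picked surrogates are actually materialized; the result is
#' bit-identical to generating all of them first. The null sample size is
#' `n_sessions * pick_per_session` per network (84 sessions with pick 1
#' give 84 null samples matched to the 84 empirical sessions).
#'
#' @param cohort a [validate_cohort()] result.
#' @param n_surrogates_per_session surrogates per session (>= 1).
#' @param pick_per_session how many to evaluate per session (default 1).
#' @param config a [run_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return data frame with columns `session_id`, `surrogate_index`,
#'   `network`, `sync`, `metastability`.
#' @export
surrogate_null_metrics <- function(cohort, n_surrogates_per_session = 100L,
                                   pick_per_session = 1L,
                                   config = run_config(),
                                   seed = config$seed) {
  stopifnot(inherits(cohort, "cohort"))
  n_surrogates_per_session <- as.integer(n_surrogates_per_session)
  pick_per_session <- as.integer(pick_per_session)
  if (n_surrogates_per_session < 1L) stop("need n_surrogates_per_session >= 1")
  if (pick_per_session < 1L || pick_per_session > n_surrogates_per_session) {
    stop("pick_per_session must be in 1..n_surrogates_per_session")
  }
  rows <- list()
  for (i in seq_along(cohort$sessions)) {
    ses <- cohort$sessions[[i]]
    set.seed(mix_seed(seed, i))
    picked <- sort(sample.int(n_surrogates_per_session, pick_per_session))
    for (idx in picked) {
      sur <- phase_randomize(ses, seed = mix_seed(seed, i, idx))
      ph <- session_phases(sur, config)
      met <- network_metrics(ph, cohort$assignment)
      rows[[length(rows) + 1L]] <-
        data.frame(session_id = ses$session_id, surrogate_index = idx,
                   network = met$network, sync = met$sync,
                   metastability = met$metastability,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Empirical per-session sync/metastability (matched to the null)
#'
#' Convenience wrapper running [session_phases()] + [network_metrics()] on
#' every session of a cohort, returning the tidy table the surrogate
#' comparison consumes.
#'
#' @param cohort a [validate_cohort()] result.
#' @param config a [run_config()].
#' @return data frame with columns `session_id`, `network`, `sync`,
#'   `metastability`.
#' @export
empirical_metrics <- function(cohort, config = run_config()) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(cohort$sessions, function(ses) {
    met <- network_metrics(session_phases(ses, config), cohort$assignment)
    data.frame(session_id = ses$session_id, network = met$network,
               sync = met$sync, metastability = met$metastability,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Compare empirical and null metric distributions
#'
#' Two-sample comparison of empirical versus surrogate-null values:
#' pooled-variance Student t test (df = n1 + n2 - 2; Welch available via
#' `var_equal = FALSE`), Mann-Whitney U, and Cohen's d with the pooled
#' sample SD. d carries the sign of (mean empirical - mean null).
#'
#' @param empirical numeric vector of empirical metric values (>= 2).
#' @param null numeric vector of null metric values (>= 2).
#' @param var_equal use the pooled-variance t test (default TRUE).
#' @return object of class `surrogate_comparison`: list with `t`, `df`,
#'   `p_t`, `U`, `p_u`, `cohens_d`, group means/SDs and sizes.
#' @export
compare_empirical_null <- function(empirical, null, var_equal = TRUE) {
  empirical <- as.numeric(empirical)
  null <- as.numeric(null)
  n1 <- length(empirical)
  n2 <- length(null)
  if (n1 < 2L || n2 < 2L) stop("both groups need at least 2 values")
  v1 <- stats::var(empirical)
  v2 <- stats::var(null)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled variance: groups are constant")
  tt <- stats::t.test(empirical, null, var.equal = var_equal)
  ut <- suppressWarnings(stats::wilcox.test(empirical, null))
  structure(
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p_t = tt$p.value, U = unname(ut$statistic), p_u = ut$p.value,
         cohens_d = (mean(empirical) - mean(null)) / sp,
         mean_empirical = mean(empirical), sd_empirical = stats::sd(empirical),
         mean_null = mean(null), sd_null = stats::sd(null),
         n_empirical = n1, n_null = n2),
    class = "surrogate_comparison"
  )
}

#' @export
print.surrogate_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("surrogate_comparison: empirical %.3f +/- %.3f (n=%d) vs ",
           "null %.3f +/- %.3f (n=%d)\n  t(%g) = %.2f, p = %.3g; U = %g, ",
           "p = %.3g; Cohen's d = %.2f\n"),
    x$mean_empirical, x$sd_empirical, x$n_empirical,
    x$mean_null, x$sd_null, x$n_null,
    x$df, x$t, x$p_t, x$U, x$p_u, x$cohens_d))
  invisible(x)
}
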