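# Synthetic multi-session cohorts: coupled phase oscillators with community
# structure (the positive control) and band-limited linear noise with no
# cross-parcel dependence (the negative control).

#' Simulation configuration for synthetic cohorts
#'
#' The defaults emulate a highly sampled single-subject resting-state
#' acquisition: 84 sessions of ~10 min at TR 1.16 s (517 samples = 599.72 s,
#' so each session is a whole number of samples), 333 parcels in 13 labeled
#' networks, slow intrinsic oscillations drawn from 0.01-0.07 Hz, moderate
#' within-network coupling, and additive Gaussian observation noise.
#'
#' @param n_parcels number of parcels.
#' @param network_sizes integer partition of `n_parcels` into contiguous
#'   networks.
#' @param network_labels labels for the networks (no `"Global"`; it is added
#'   automatically by [make_network_assignment()]).
#' @param n_sessions number of sessions to generate.
#' @param session_duration seconds per session; must be a whole number of
#'   samples at `tr`.
#' @param tr sampling interval in seconds.
#' @param intrinsic_freq_range two-element Hz range for the oscillators'
#'   natural frequencies; must lie strictly inside (0, Nyquist).
#' @param coupling_per_network dimensionless Kuramoto coupling `K_n >= 0`,
#'   one per network.
#' @param noise_sd additive observation noise SD (signal amplitude is 1).
#' @param phase_noise_sd intensity of stochastic phase forcing in
#'   rad/sqrt(s) (Euler-Maruyama diffusion term).
#' @param seed integer master seed; identical configs are bit-reproducible.
#'
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_parcels = 333L,
                              network_sizes = c(24L, 40L, 5L, 41L, 32L, 24L,
                                                8L, 4L, 38L, 8L, 23L, 39L,
                                                47L),
                              network_labels = c("Aud", "CiO", "CiP", "Def",
                                                 "DoA", "FrP", "ReT", "Sal",
                                                 "SMl", "SMm", "VeA", "Vis",
                                                 "non"),
                              n_sessions = 84L,
                              session_duration = 599.72,
                              tr = 1.16,
                              intrinsic_freq_range = c(0.01, 0.07),
                              coupling_per_network = rep(0.15,
                                                         length(network_sizes)),
                              noise_sd = 0.3,
                              phase_noise_sd = 0.1,
                              seed = 1L) {
  n_parcels <- as.integer(n_parcels)
  network_sizes <- as.integer(network_sizes)
  if (sum(network_sizes) != n_parcels) {
    stop("network_sizes must partition n_parcels: sum is ",
         sum(network_sizes), ", n_parcels is ", n_parcels)
  }
  if (any(network_sizes < 1L)) stop("network sizes must be >= 1")
  if (length(network_labels) != length(network_sizes)) {
    stop("need one label per network")
  }
  if (anyDuplicated(network_labels)) stop("duplicate network labels")
  n_samples <- session_duration / tr
  if (abs(n_samples - round(n_samples)) > 1e-8) {
    stop("session_duration/tr = ", n_samples,
         " is not a whole number of samples")
  }
  if (length(intrinsic_freq_range) != 2L ||
      intrinsic_freq_range[1L] <= 0 ||
      intrinsic_freq_range[1L] > intrinsic_freq_range[2L]) {
    stop("intrinsic_freq_range must be a non-decreasing positive Hz pair")
  }
  if (intrinsic_freq_range[2L] >= 1 / (2 * tr)) {
    stop("upper intrinsic frequency ", intrinsic_freq_range[2L],
         " Hz is at or above Nyquist (", 1 / (2 * tr), " Hz)")
  }
  if (length(coupling_per_network) != length(network_sizes)) {
    stop("need one coupling value per network")
  }
  if (any(coupling_per_network < 0)) stop("coupling must be >= 0")
  if (noise_sd < 0 || phase_noise_sd < 0) stop("noise SDs must be >= 0")
  structure(
    list(n_parcels = n_parcels, network_sizes = network_sizes,
         network_labels = as.character(network_labels),
         n_sessions = as.integer(n_sessions),
         session_duration = session_duration, tr = tr,
         intrinsic_freq_range = intrinsic_freq_range,
         coupling_per_network = as.numeric(coupling_per_network),
         noise_sd = noise_sd, phase_noise_sd = phase_noise_sd,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Deterministic sub-seed derivation: exact integer arithmetic in doubles
# (all operands < 2^53), reduced mod 2^31 - 1.
mix_seed <- function(seed, a, b = 0L) {
  as.integer((abs(seed) + 1000003 * (a + 1) + 7919 * (b + 1)) %% 2147483647)
}

#' Build a network assignment from block sizes
#'
#' Parcels are named `P001, P002, ...` and assigned to contiguous blocks per
#' label; the all-parcels "Global" network is always appended, so 13 labeled
#' networks give 14 networks in total (15 when a subcortical block is
#' included as a 14th label).
#'
#' @param network_sizes integer block sizes.
#' @param labels one label per block.
#' @return a [network_assignment()].
#' @export
make_network_assignment <- function(network_sizes, labels) {
  network_sizes <- as.integer(network_sizes)
  if (length(labels) != length(network_sizes)) {
    stop("need one label per network size")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate network labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  n <- sum(network_sizes)
  parcel_ids <- sprintf("P%03d", seq_len(n))
  network_assignment(parcel_ids, rep(as.character(labels), network_sizes))
}

#' Simulate sessions of community-coupled Kuramoto oscillators
#'
#' Each parcel is a phase oscillator with natural frequency drawn once per
#' subject (uniform over `2*pi*intrinsic_freq_range`) that is coupled, with
#' network-specific strength `K_n`, to the mean field of its own network
#' only: `dtheta_p = omega_p dt + (K_n/|n|) sum_{q in n} sin(theta_q -
#' theta_p) dt + phase_noise_sd dW`. Integration is Euler-Maruyama at an
#' internal step of `tr/10` (slow <= 0.07 Hz dynamics make this stable),
#' subsampled to TR. The observed signal is `cos(theta_p(t))` plus Gaussian
#' noise. Each session restarts from fresh uniform random phases (sessions
#' are independent runs); natural frequencies are shared across sessions
#' (one subject, one intrinsic dynamic).
#'
#' The latent phase matrix of each session is attached as attribute
#' `latent_phases` for validation against the ground truth.
#'
#' @param config a [simulation_config()].
#' @param substeps internal integration steps per TR; the default `tr/10` is
#'   raised automatically when strong coupling demands a finer step (the
#'   Euler scheme needs `K * dt` well below 1).
#' @return list of `n_sessions` [session_series()] objects.
#' @export
simulate_kuramoto_sessions <- function(config, substeps = 10L) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_parcels
  n_samples <- as.integer(round(config$session_duration / config$tr))
  k_max <- max(config$coupling_per_network)
  substeps <- max(as.integer(substeps), ceiling(4 * k_max * config$tr))
  dt <- config$tr / substeps
  group <- rep(seq_along(config$network_sizes), config$network_sizes)
  sizes <- config$network_sizes[group]     # |n| per parcel
  K <- config$coupling_per_network[group]  # K_n per parcel
  parcel_ids <- sprintf("P%03d", seq_len(n))

  set.seed(config$seed)
  omega <- stats::runif(n, 2 * pi * config$intrinsic_freq_range[1L],
                        2 * pi * config$intrinsic_freq_range[2L])
  pn <- config$phase_noise_sd * sqrt(dt)

  sessions <- vector("list", config$n_sessions)
  for (s in seq_len(config$n_sessions)) {
    set.seed(mix_seed(config$seed, s))
    theta <- stats::runif(n, -pi, pi)
    rec <- matrix(NA_real_, n_samples, n)
    rec[1L, ] <- theta
    for (k in seq_len(n_samples - 1L)) {
      for (sub in seq_len(substeps)) {
        # mean field per network: sum_q sin(theta_q - theta_p)
        #   = |n| * R_n * sin(psi_n - theta_p)
        gs <- rowsum(cbind(cos(theta), sin(theta)), group)
        Rn <- sqrt(gs[, 1L]^2 + gs[, 2L]^2) / config$network_sizes
        psi <- atan2(gs[, 2L], gs[, 1L])
        drift <- omega + K * Rn[group] * sin(psi[group] - theta)
        theta <- theta + drift * dt
        if (pn > 0) theta <- theta + pn * stats::rnorm(n)
      }
      rec[k + 1L, ] <- theta
    }
    rec <- (rec + pi) %% (2 * pi) - pi
    obs <- cos(rec)
    if (config$noise_sd > 0) {
      obs <- obs + config$noise_sd * stats::rnorm(length(obs))
    }
    ses <- session_series(obs, tr = config$tr,
                          session_id = sprintf("sess-%03d", s),
                          parcel_ids = parcel_ids)
    attr(ses, "latent_phases") <- rec
    sessions[[s]] <- ses
  }
  sessions
}

# One band-limited Gaussian parcel signal: white noise filtered in the
# frequency domain to the configured band, standardized to unit SD.
band_limited_noise <- function(n_samples, tr, band, seed) {
  set.seed(seed)
  w <- stats::rnorm(n_samples)
  W <- stats::fft(w)
  freqs <- (seq_len(n_samples) - 1L) / (n_samples * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)  # two-sided -> absolute frequency
  keep <- freqs >= band[1L] & freqs <= band[2L]
  W[!keep] <- 0
  x <- Re(stats::fft(W, inverse = TRUE) / n_samples)
  x / stats::sd(x)
}

#' Simulate sessions of independent band-limited noise (linear null)
#'
#' Every parcel is an independent Gaussian process spectrally restricted to
#' `intrinsic_freq_range`; there is no cross-parcel dependence by
#' construction, making this the negative control for every coupling-
#' sensitive statistic. Each parcel's draw depends only on (seed, session,
#' parcel index), so parcels are exchangeable: the same parcel index yields
#' the same series regardless of how many other parcels are generated.
#'
#' @param config a [simulation_config()] (coupling and noise fields are
#'   ignored).
#' @return list of `n_sessions` [session_series()] objects.
#' @export
simulate_linear_null <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_parcels
  n_samples <- as.integer(round(config$session_duration / config$tr))
  parcel_ids <- sprintf("P%03d", seq_len(n))
  lapply(seq_len(config$n_sessions), function(s) {
    mat <- vapply(seq_len(n), function(j) {
      band_limited_noise(n_samples, config$tr, config$intrinsic_freq_range,
                         seed = mix_seed(config$seed, s, j))
    }, numeric(n_samples))
    session_series(mat, tr = config$tr,
                   session_id = sprintf("sess-%03d", s),
                   parcel_ids = parcel_ids)
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes one TSV per session, the assignment table, and a YAML manifest
#' recording the full simulation configuration for provenance.
#'
#' @param sessions list of [session_series()].
#' @param assignment a [network_assignment()].
#' @param config the [simulation_config()] that generated the cohort.
#' @param out_dir output directory (created if needed).
#' @return path of the manifest file, invisibly.
#' @export
write_cohort <- function(sessions, assignment, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(sessions))
  for (i in seq_along(sessions)) {
    paths[i] <- file.path(out_dir, paste0(sessions[[i]]$session_id, ".tsv"))
    write_session(sessions[[i]], paths[i])
  }
  ass_path <- file.path(out_dir, "assignment.tsv")
  write_network_assignment(assignment, ass_path)
  manifest <- list(
    subject_id = "synthetic",
    tr = sessions[[1L]]$tr,
    assignment = basename(ass_path),
    sessions = basename(paths),
    simulation_config = unclass(config)
  )
  man_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, man_path)
  invisible(man_path)
}
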