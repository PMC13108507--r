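# Shared fixture builders. Everything is generated in code; a small cache
# avoids re-simulating the same cohort across test files in one run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Two-network, 20-parcel, 24-session stationary cohort in the weak partial
# synchrony regime (the reliability test bed).
two_network_config <- function(n_sessions = 24L, seed = 11L) {
  simulation_config(
    n_parcels = 20L, network_sizes = c(10L, 10L),
    network_labels = c("A", "B"), n_sessions = n_sessions,
    session_duration = 300, tr = 2,
    coupling_per_network = c(0.1, 0.2),
    noise_sd = 0.3, phase_noise_sd = 0.1, seed = seed
  )
}

two_network_cohort <- function() {
  cached("two_network_cohort", {
    cfg <- two_network_config()
    validate_cohort(
      simulate_kuramoto_sessions(cfg),
      make_network_assignment(cfg$network_sizes, cfg$network_labels)
    )
  })
}

# Strongly coupled single-network cohort (surrogate positive control).
coupled_cohort <- function() {
  cached("coupled_cohort", {
    cfg <- simulation_config(
      n_parcels = 12L, network_sizes = 12L, network_labels = "A",
      n_sessions = 20L, session_duration = 300, tr = 2,
      coupling_per_network = 10, noise_sd = 0.1, phase_noise_sd = 0.1,
      seed = 21L
    )
    validate_cohort(simulate_kuramoto_sessions(cfg),
                    make_network_assignment(12L, "A"))
  })
}

# Run config used throughout the synthetic tests: 30 s onset discard keeps
# the 5-min sessions long enough while exercising both trimming rules.
test_run_config <- function(...) {
  args <- utils::modifyList(
    list(discard_initial = 30, edge_trim = 5L, n_iterations = 100L,
         seed = 42L),
    list(...))
  do.call(run_config, args)
}

# Cohort of n identical copies of one deterministic session.
copies_cohort <- function(n = 6L) {
  cached(paste0("copies_cohort_", n), {
    cfg <- simulation_config(
      n_parcels = 6L, network_sizes = c(3L, 3L),
      network_labels = c("A", "B"), n_sessions = 1L,
      session_duration = 300, tr = 2, coupling_per_network = c(0.5, 0.5),
      noise_sd = 0, phase_noise_sd = 0, seed = 7L
    )
    base <- simulate_kuramoto_sessions(cfg)[[1L]]
    sessions <- lapply(seq_len(n), function(i) {
      session_series(base$data, tr = base$tr,
                     session_id = sprintf("copy-%02d", i),
                     parcel_ids = base$parcel_ids)
    })
    validate_cohort(sessions,
                    make_network_assignment(c(3L, 3L), c("A", "B")))
  })
}

# Random phase matrix in (-pi, pi] with parcel-id column names.
random_phase_matrix <- function(n_time, n_parcels) {
  matrix(stats::runif(n_time * n_parcels, -pi, pi), n_time, n_parcels,
         dimnames = list(NULL, sprintf("P%03d", seq_len(n_parcels))))
}
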