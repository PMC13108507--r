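test_that("configuration invariants are enforced", {
  expect_error(
    simulation_config(n_parcels = 10L, network_sizes = c(4L, 4L),
                      network_labels = c("A", "B")),
    "partition")
  expect_error(
    simulation_config(n_parcels = 4L, network_sizes = 4L,
                      network_labels = "A", tr = 2,
                      session_duration = 100,
                      intrinsic_freq_range = c(0.01, 0.3)),
    "Nyquist")
  expect_error(
    simulation_config(n_parcels = 4L, network_sizes = 4L,
                      network_labels = "A", session_duration = 101,
                      tr = 2),
    "whole number")
  expect_error(
    simulation_config(n_parcels = 4L, network_sizes = 4L,
                      network_labels = "A", session_duration = 100, tr = 2,
                      coupling_per_network = -1),
    ">= 0")
})

test_that("same config and seed give bit-identical sessions", {
  cfg <- simulation_config(n_parcels = 6L, network_sizes = c(3L, 3L),
                           network_labels = c("A", "B"), n_sessions = 2L,
                           session_duration = 100, tr = 2, seed = 5L)
  a <- simulate_kuramoto_sessions(cfg)
  b <- simulate_kuramoto_sessions(cfg)
  expect_identical(lapply(a, `[[`, "data"), lapply(b, `[[`, "data"))
  ln1 <- simulate_linear_null(cfg)
  ln2 <- simulate_linear_null(cfg)
  expect_identical(lapply(ln1, `[[`, "data"), lapply(ln2, `[[`, "data"))
})

test_that("uncoupled noiseless oscillators have E[R^2] = 1/N", {
  cfg <- simulation_config(n_parcels = 10L, network_sizes = 10L,
                           network_labels = "A", n_sessions = 30L,
                           session_duration = 480, tr = 2,
                           coupling_per_network = 0, noise_sd = 0,
                           phase_noise_sd = 0.1, seed = 7L)
  sessions <- simulate_kuramoto_sessions(cfg)
  r2 <- vapply(sessions, function(s) {
    theta <- attr(s, "latent_phases")
    mean(Mod(rowMeans(exp(1i * theta)))^2)
  }, numeric(1))
  mc_se <- stats::sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - 1 / 10), 3 * mc_se)
})

test_that("large identical-frequency coupling phase-locks the network", {
  cfg <- simulation_config(n_parcels = 8L, network_sizes = 8L,
                           network_labels = "A", n_sessions = 1L,
                           session_duration = 480, tr = 2,
                           intrinsic_freq_range = c(0.05, 0.05),
                           coupling_per_network = 50, noise_sd = 0,
                           phase_noise_sd = 0, seed = 3L)
  theta <- attr(simulate_kuramoto_sessions(cfg)[[1L]], "latent_phases")
  phi <- Mod(rowMeans(exp(1i * theta)))
  post <- phi[-(1:30)]  # after the locking transient
  expect_lt(abs(mean(post) - 1), 0.01)
  expect_lt(stats::sd(post), 0.01)
})

test_that("within-network synchrony is non-decreasing in coupling strength", {
  sync_at <- function(K) {
    mean(vapply(1:20, function(rep) {
      cfg <- simulation_config(n_parcels = 8L, network_sizes = 8L,
                               network_labels = "A", n_sessions = 1L,
                               session_duration = 300, tr = 2,
                               coupling_per_network = K, noise_sd = 0,
                               phase_noise_sd = 0.1, seed = 300L + rep)
      theta <- attr(simulate_kuramoto_sessions(cfg)[[1L]], "latent_phases")
      mean(Mod(rowMeans(exp(1i * theta))))
    }, numeric(1)))
  }
  s <- c(sync_at(0), sync_at(0.15), sync_at(50))
  expect_true(all(diff(s) > 0))
})

test_that("linear null has no cross-parcel correlation and stays in band", {
  cfg <- simulation_config(n_parcels = 12L, network_sizes = 12L,
                           network_labels = "A", n_sessions = 1L,
                           session_duration = 600, tr = 2, seed = 5L)
  x <- simulate_linear_null(cfg)[[1L]]$data
  C <- stats::cor(x)
  expect_lt(mean(abs(C[upper.tri(C)])), 3 / sqrt(nrow(x)))
  pow <- Mod(stats::fft(x[, 1L]))^2
  k <- seq_len(nrow(x)) - 1L
  fr <- pmin(k, nrow(x) - k) / (nrow(x) * 2)  # fold to absolute frequency
  out_band <- sum(pow[fr < 0.01 | fr > 0.07]) / sum(pow)
  expect_lt(out_band, 0.01)
})

test_that("linear null parcels are exchangeable (per-parcel seed streams)", {
  base <- simulation_config(n_parcels = 6L, network_sizes = 6L,
                            network_labels = "A", n_sessions = 1L,
                            session_duration = 300, tr = 2, seed = 9L)
  wide <- simulate_linear_null(base)[[1L]]$data
  narrow_cfg <- simulation_config(n_parcels = 3L, network_sizes = 3L,
                                  network_labels = "A", n_sessions = 1L,
                                  session_duration = 300, tr = 2, seed = 9L)
  narrow <- simulate_linear_null(narrow_cfg)[[1L]]$data
  # parcel j depends only on (seed, session, j), not on the other parcels
  expect_identical(unname(wide[, 1:3]), unname(narrow))
})

test_that("network assignments append Global and preserve counts", {
  a <- make_network_assignment(c(3L, 2L), c("A", "B"))
  expect_identical(a$networks, c("A", "B", "Global"))
  expect_identical(a$members$A, c("P001", "P002", "P003"))
  expect_identical(a$members$B, c("P004", "P005"))
  expect_identical(a$members$Global, sprintf("P%03d", 1:5))
  # 13 labeled networks -> 14 including Global; 14 -> 15
  a13 <- make_network_assignment(rep(2L, 13), paste0("N", 1:13))
  expect_length(a13$networks, 14L)
  a14 <- make_network_assignment(rep(2L, 14), paste0("N", 1:14))
  expect_length(a14$networks, 15L)
  expect_error(make_network_assignment(c(2L, 2L), c("A", "A")), "duplicate")
})

test_that("metastability peaks at intermediate coupling", {
  meta_at <- function(K) {
    mean(vapply(1:20, function(rep) {
      cfg <- simulation_config(n_parcels = 10L, network_sizes = 10L,
                               network_labels = "A", n_sessions = 1L,
                               session_duration = 480, tr = 2,
                               coupling_per_network = K, noise_sd = 0,
                               phase_noise_sd = 0.1, seed = 400L + rep)
      theta <- attr(simulate_kuramoto_sessions(cfg)[[1L]], "latent_phases")
      phi <- Mod(rowMeans(exp(1i * theta)))
      sqrt(mean((phi - mean(phi))^2))
    }, numeric(1)))
  }
  m0 <- meta_at(0)
  m_mid <- meta_at(0.15)
  m_hi <- meta_at(50)
  expect_gt(m_mid, m0)
  expect_gt(m_mid, m_hi)
})
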