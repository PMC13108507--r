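test_that("split plans are unique, disjoint and seed-deterministic", {
  ids <- sprintf("s%02d", 1:8)
  plan <- build_split_plan(ids, 20L, seed = 3L)
  expect_length(plan$iterations, 20L)
  keys <- vapply(plan$iterations, function(it) {
    expect_length(intersect(it$A, it$B), 0L)
    expect_setequal(c(it$A, it$B), ids)
    a <- if ("s01" %in% it$A) it$A else it$B
    paste(sort(a), collapse = ",")
  }, character(1))
  expect_false(anyDuplicated(keys) > 0)
  # per-duration draws come from B, without replacement, sized k
  for (it in plan$iterations) {
    for (k in seq_along(it$draws)) {
      expect_length(it$draws[[k]], k)
      expect_true(all(it$draws[[k]] %in% it$B))
      expect_false(anyDuplicated(it$draws[[k]]) > 0)
    }
  }
  expect_identical(build_split_plan(ids, 20L, seed = 3L), plan)
})

test_that("the combinatorial bound on unique partitions is enforced", {
  ids <- c("a", "b", "c", "d")
  plan <- build_split_plan(ids, 3L, seed = 1L)  # all C(4,2)/2 = 3 partitions
  keys <- vapply(plan$iterations, function(it) {
    a <- if ("a" %in% it$A) it$A else it$B
    paste(sort(a), collapse = ",")
  }, character(1))
  expect_setequal(keys, c("a,b", "a,c", "a,d"))
  expect_error(build_split_plan(ids, 4L, seed = 1L), "3 distinct")
  expect_error(build_split_plan(c("a", "b", "c"), 1L), "even")
})

test_that("scalar similarity follows the normalized absolute-error formula", {
  expect_equal(scalar_similarity(0.2, 0.2), 1)
  expect_equal(scalar_similarity(0.25, 0.2), 0.75)
  expect_equal(scalar_similarity(0.3, 0.1), -1)  # negative allowed
  expect_equal(scalar_similarity(0.3, 0.1, form = "absolute"), 0.8)
  expect_error(scalar_similarity(0.3, 0), "baseline is 0")
})

test_that("departure from baseline maps correlation to 1 - r", {
  set.seed(31)
  ref <- rnorm(20)
  orth <- unname(stats::residuals(stats::lm(rnorm(20) ~ ref)))  # cor = 0
  vecs <- list(ref, ref + 0, -ref, orth)
  d <- departure_from_baseline(vecs, reference_index = 1L)
  expect_equal(d[1], 0)
  expect_equal(d[2], 0, tolerance = 1e-12)
  expect_equal(d[3], 2)
  expect_equal(d[4], 1, tolerance = 1e-12)
  expect_error(departure_from_baseline(list(1:3, 1:4)), "length")
  expect_error(departure_from_baseline(list(1:3)), "2 sessions")
})

test_that("profile summaries match hand-computed mean, SD and CI", {
  prof <- summarize_profile(matrix(c(0.8, 0.9), 2, 1), durations = 10)
  expect_equal(prof$mean, 0.85)
  expect_equal(prof$sd, 0.05)  # population SD of {0.8, 0.9}
  expect_equal(prof$ci_hi - prof$mean, 1.96 * 0.05 / sqrt(2))
  const <- summarize_profile(matrix(0.7, 50, 3))
  expect_equal(const$mean, rep(0.7, 3))
  expect_equal(const$sd, rep(0, 3))
  expect_equal(const$ci_lo, const$ci_hi)
  expect_warning(summarize_profile(matrix(1, 1, 2)), "single iteration")
})

test_that("CI half-width shrinks as 1/sqrt(n iterations)", {
  set.seed(37)
  sims <- rnorm(400, 0.9, 0.02)
  p100 <- summarize_profile(matrix(sims[1:100], 100, 1))
  p400 <- summarize_profile(matrix(sims, 400, 1))
  ratio <- (p100$ci_hi - p100$ci_lo) / (p400$ci_hi - p400$ci_lo)
  expect_equal(ratio, 2, tolerance = 0.2)
})

test_that("identical sessions give similarity exactly 1 with zero spread", {
  cohort <- copies_cohort(6L)
  rc <- test_run_config(n_iterations = 5L)
  plan <- build_split_plan(cohort$session_ids, 5L, seed = 2L)
  for (kind in c("combined", "fc", "sync", "metastability")) {
    prof <- convergence_profile(cohort, plan, kind, rc)
    expect_equal(prof$mean, rep(1, nrow(prof)), tolerance = 1e-9)
    expect_equal(prof$sd, rep(0, nrow(prof)), tolerance = 1e-9)
  }
  sp <- scalar_convergence_profile(cohort, plan, "Global", "sync", rc)
  expect_equal(sp$mean, rep(1, nrow(sp)), tolerance = 1e-9)
})

test_that("baseline metrics equal metrics of the concatenated phase series", {
  cohort <- two_network_cohort()
  rc <- test_run_config()
  ids <- cohort$session_ids[1:3]
  base <- baseline_metrics(cohort, ids, "combined", rc)
  ph <- lapply(cohort$sessions[1:3], session_phases, config = rc)
  conc <- do.call(rbind, lapply(ph, `[[`, "phases"))
  direct <- feature_vector(network_metrics(conc, cohort$assignment),
                           "combined")
  expect_equal(base, direct, tolerance = 1e-12)
  expect_error(baseline_metrics(cohort, character(0)), "empty")
  expect_error(baseline_metrics(cohort, "nope", config = rc), "unknown")
})

test_that("concatenation order of sampled sessions does not change metrics", {
  cohort <- two_network_cohort()
  rc <- test_run_config()
  stats <- cohort_feature_stats(cohort, rc)
  ids <- cohort$session_ids[c(2, 5, 9)]
  expect_equal(baseline_metrics(stats, ids, "combined"),
               baseline_metrics(stats, rev(ids), "combined"))
  expect_equal(baseline_metrics(stats, ids, "fc"),
               baseline_metrics(stats, rev(ids), "fc"))
})

test_that("profiles are bit-reproducible under the master seed", {
  cohort <- copies_cohort(4L)
  rc <- test_run_config(n_iterations = 3L)
  p1 <- cmd_reliability(cohort, rc, "combined")
  p2 <- cmd_reliability(cohort, rc, "combined")
  expect_identical(as.data.frame(p1), as.data.frame(p2))
})

test_that("sessions split into equal contiguous relabeled parts", {
  m <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("P", 1:4)))
  ses <- session_series(m, tr = 2, session_id = "s1",
                        parcel_ids = paste0("P", 1:4))
  parts <- msc_session_split(list(ses), 3L)
  expect_length(parts, 3L)
  expect_identical(parts[[1L]]$data, m[1:10, ])
  expect_identical(parts[[3L]]$data, m[21:30, ])
  expect_identical(parts[[2L]]$session_id, "s1.2")
  # 10 sessions x 3 parts -> 30 sessions
  many <- msc_session_split(rep(list(ses), 10L), 3L)
  expect_length(many, 30L)
  expect_identical(msc_session_split(list(ses), 1L), list(ses))
  odd <- session_series(m[1:29, ], tr = 2, session_id = "s2",
                        parcel_ids = paste0("P", 1:4))
  expect_error(msc_session_split(list(odd), 3L), "remainder 2")
})

test_that("scalar profiles reject unknown networks", {
  cohort <- copies_cohort(4L)
  rc <- test_run_config(n_iterations = 3L)
  plan <- build_split_plan(cohort$session_ids, 3L, seed = 1L)
  expect_error(scalar_convergence_profile(cohort, plan, "Zebra", "sync", rc),
               "unknown network")
})
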