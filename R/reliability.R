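# Split-half resampling engine: baseline-vs-sample similarity as a function
# of total acquisition duration, scalar similarity, departure from baseline,
# and profile summaries.

#' Precompute per-session sufficient statistics for pooled metrics
#'
#' Computing sync/metastability on phase series concatenated across sessions
#' only requires, per session and network, the count, sum and sum of squares
#' of the order-parameter time course (phi is instantaneous, so pooling time
#' points is exact). Likewise, Pearson correlations over concatenated raw
#' series are exact functions of per-session counts, column sums and
#' cross-products. This step runs the expensive phase extraction once per
#' session; every split/duration combination downstream is then O(1) in the
#' session length.
#'
#' The raw series entering the FC comparator get the identical trimming
#' window as the phase series (initial discard plus edge trim), keeping the
#' two metric families comparable.
#'
#' @param cohort a [validate_cohort()] result.
#' @param config a [run_config()].
#' @return object of class `cohort_stats`, keyed by session id.
#' @export
cohort_feature_stats <- function(cohort, config = run_config()) {
  stopifnot(inherits(cohort, "cohort"))
  assignment <- cohort$assignment
  nets <- assignment$networks
  per_session <- lapply(cohort$sessions, function(ses) {
    ph <- session_phases(ses, config)
    phi <- vapply(nets, function(nw) {
      order_parameter(ph, assignment$members[[nw]])
    }, numeric(nrow(ph$phases)))
    raw <- ses$data[ph$raw_keep_idx, , drop = FALSE]
    list(
      n = nrow(phi),
      phi_sum = colSums(phi),
      phi_sumsq = colSums(phi^2),
      fc_n = nrow(raw),
      fc_sum = colSums(raw),
      fc_cross = crossprod(raw)
    )
  })
  names(per_session) <- cohort$session_ids
  structure(
    list(per_session = per_session, networks = nets,
         assignment = assignment, tr = cohort$tr,
         minutes_per_session = vapply(per_session, function(s)
           s$n * cohort$tr / 60, numeric(1))),
    class = "cohort_stats"
  )
}

# Pooled per-network sync/metastability over a set of sessions (exactly the
# metrics of the concatenated phase series).
pooled_network_metrics <- function(stats, session_ids) {
  ss <- stats$per_session[session_ids]
  n <- sum(vapply(ss, `[[`, numeric(1), "n"))
  s1 <- Reduce(`+`, lapply(ss, `[[`, "phi_sum"))
  s2 <- Reduce(`+`, lapply(ss, `[[`, "phi_sumsq"))
  sync <- s1 / n
  meta <- sqrt(pmax(0, s2 / n - sync^2))
  res <- data.frame(network = stats$networks, sync = unname(sync),
                    metastability = unname(meta), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(res) <- c("network_metrics", "data.frame")
  res
}

# Pooled Fisher-z FC over a set of sessions (exactly the FC of the
# concatenated trimmed raw series).
pooled_fc <- function(stats, session_ids) {
  ss <- stats$per_session[session_ids]
  n <- sum(vapply(ss, `[[`, numeric(1), "fc_n"))
  cs <- Reduce(`+`, lapply(ss, `[[`, "fc_sum"))
  cp <- Reduce(`+`, lapply(ss, `[[`, "fc_cross"))
  mu <- cs / n
  cov <- (cp - n * tcrossprod(mu)) / n
  d <- sqrt(diag(cov))
  if (any(d == 0)) {
    stop("zero-variance parcel(s) in pooled FC: ",
         paste(names(d)[d == 0], collapse = ", "))
  }
  r <- cov / tcrossprod(d)
  z <- fisher_z(r)
  diag(z) <- 0
  class(z) <- c("fc_matrix", class(z))
  z
}

# One feature vector of the requested kind from pooled session statistics.
pooled_feature <- function(stats, session_ids, metric_kind,
                           network = "Global") {
  switch(metric_kind,
    fc = fc_vector(pooled_fc(stats, session_ids),
                   stats$assignment$members[[network]]),
    sync = ,
    metastability = ,
    combined = feature_vector(pooled_network_metrics(stats, session_ids),
                              kind = metric_kind),
    stop("unknown metric kind: ", metric_kind)
  )
}

#' Build a split-half resampling plan
#'
#' Repeatedly splits the session ids into two disjoint halves A (baseline)
#' and B (test pool); partitions are unique across iterations (rejection of
#' duplicates). Within each iteration, the k-session sample for duration
#' step k is a fresh draw without replacement from B, independently at each
#' duration. The whole plan is a deterministic function of the seed.
#'
#' @param session_ids character vector, even length >= 4.
#' @param n_iterations number of unique half-splits; must not exceed
#'   `choose(n, n/2) / 2`, the number of distinct unordered partitions.
#' @param seed integer seed.
#' @return object of class `split_plan`: list of iterations, each with `A`,
#'   `B`, and `draws` (list: duration step k -> k sampled ids from B).
#' @export
build_split_plan <- function(session_ids, n_iterations, seed = 1L) {
  session_ids <- as.character(session_ids)
  n <- length(session_ids)
  if (n < 4L || n %% 2L != 0L) {
    stop("need an even number of sessions >= 4 to half-split (got ", n, ")")
  }
  half <- n %/% 2L
  n_partitions <- choose(n, half) / 2
  if (n_iterations > n_partitions) {
    stop("requested ", n_iterations, " unique splits but only ",
         format(n_partitions, big.mark = ","), " distinct ", half, "|",
         half, " partitions of ", n, " sessions exist")
  }
  set.seed(seed)
  seen <- new.env(hash = TRUE)
  iterations <- vector("list", n_iterations)
  i <- 0L
  while (i < n_iterations) {
    a_idx <- sort(sample.int(n, half))
    # canonical partition key: orient so session 1 is in A
    key_idx <- if (1L %in% a_idx) a_idx else sort(setdiff(seq_len(n), a_idx))
    key <- paste(key_idx, collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    i <- i + 1L
    A <- session_ids[a_idx]
    B <- session_ids[-a_idx]
    draws <- lapply(seq_len(half), function(k) sample(B, k))
    iterations[[i]] <- list(A = A, B = B, draws = draws)
  }
  structure(list(iterations = iterations, session_ids = session_ids,
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Baseline feature vector from one subset of sessions
#'
#' Computes the metric of the requested kind on the concatenation of the
#' subset's sessions: phase series are concatenated along time before the
#' order-parameter statistics (instantaneous, so no cross-session phase
#' continuity is needed); for `metric_kind = "fc"` the trimmed raw series
#' are concatenated before the correlation matrix.
#'
#' @param cohort a [validate_cohort()] result or a precomputed
#'   [cohort_feature_stats()] object.
#' @param subset_ids session ids forming the baseline subset.
#' @param metric_kind `"fc"`, `"sync"`, `"metastability"`, or `"combined"`.
#' @param config a [run_config()] (ignored when `cohort` is already a
#'   `cohort_stats`).
#' @param network parcel subset for `"fc"` (default `"Global"`).
#' @return numeric feature vector.
#' @export
baseline_metrics <- function(cohort, subset_ids, metric_kind = "combined",
                             config = run_config(), network = "Global") {
  stats <- if (inherits(cohort, "cohort_stats")) cohort else
    cohort_feature_stats(cohort, config)
  subset_ids <- as.character(subset_ids)
  if (length(subset_ids) == 0L) stop("baseline subset is empty")
  missing <- setdiff(subset_ids, names(stats$per_session))
  if (length(missing) > 0L) {
    stop("unknown session id(s): ", paste(missing, collapse = ", "))
  }
  pooled_feature(stats, subset_ids, metric_kind, network)
}

#' Similarity profile of a feature vector versus acquisition duration
#'
#' For every iteration of the plan: the baseline vector is computed from all
#' sessions of subset A (~half the cohort); for every duration step k the
#' test vector is computed from the iteration's k sampled sessions of subset
#' B and compared with the baseline by Pearson correlation. Mean, SD and 95%
#' CI of the similarity across iterations are reported per duration.
#'
#' @param cohort a [validate_cohort()] result or [cohort_feature_stats()].
#' @param plan a [build_split_plan()].
#' @param metric_kind `"fc"`, `"sync"`, `"metastability"`, or `"combined"`.
#' @param config a [run_config()].
#' @param network parcel subset for `"fc"` (default `"Global"`).
#' @return a `reliability_profile` (see [summarize_profile()]); the raw
#'   iterations x durations similarity matrix is attached as attribute
#'   `raw`.
#' @export
convergence_profile <- function(cohort, plan, metric_kind = "combined",
                                config = run_config(), network = "Global") {
  stopifnot(inherits(plan, "split_plan"))
  stats <- if (inherits(cohort, "cohort_stats")) cohort else
    cohort_feature_stats(cohort, config)
  n_iter <- length(plan$iterations)
  n_dur <- length(plan$iterations[[1L]]$draws)
  sims <- matrix(NA_real_, n_iter, n_dur)
  for (i in seq_len(n_iter)) {
    it <- plan$iterations[[i]]
    base <- pooled_feature(stats, it$A, metric_kind, network)
    for (k in seq_len(n_dur)) {
      test <- pooled_feature(stats, it$draws[[k]], metric_kind, network)
      sims[i, k] <- stats::cor(test, base)
    }
  }
  durations <- seq_len(n_dur) * mean(stats$minutes_per_session)
  prof <- summarize_profile(sims, durations = durations,
                            metric = paste0(metric_kind,
                                            if (metric_kind == "fc")
                                              paste0(".", network)))
  attr(prof, "raw") <- sims
  prof
}

#' Normalized scalar similarity to baseline
#'
#' `1 - |test - baseline| / |baseline|`: the similarity scale used when the
#' compared quantity is a single network's scalar (correlation is undefined
#' for scalars). Values may be negative when the error exceeds the baseline
#' magnitude; they are deliberately not clipped. With
#' `form = "absolute"`, returns `1 - |test - baseline|` instead.
#'
#' @param test scalar test value.
#' @param baseline scalar baseline value (nonzero for the normalized form).
#' @param form `"normalized"` (default) or `"absolute"`.
#' @return scalar similarity, 1 = perfect agreement.
#' @export
scalar_similarity <- function(test, baseline,
                              form = c("normalized", "absolute")) {
  form <- match.arg(form)
  if (form == "normalized" && baseline == 0) {
    stop("baseline is 0: normalized similarity undefined")
  }
  err <- abs(test - baseline)
  if (form == "normalized") 1 - err / abs(baseline) else 1 - err
}

#' Reliability profile of one network's scalar metric
#'
#' Same split-half engine as [convergence_profile()] but the compared
#' quantity is one network's scalar sync or metastability, and similarity is
#' [scalar_similarity()] instead of correlation.
#'
#' @param cohort a [validate_cohort()] result or [cohort_feature_stats()].
#' @param plan a [build_split_plan()].
#' @param network network label (must exist in the assignment).
#' @param metric `"sync"` or `"metastability"`.
#' @param config a [run_config()]; `scalar_similarity_form` selects the
#'   similarity variant.
#' @return a `reliability_profile` with attribute `raw`.
#' @export
scalar_convergence_profile <- function(cohort, plan, network,
                                       metric = c("sync", "metastability"),
                                       config = run_config()) {
  metric <- match.arg(metric)
  stopifnot(inherits(plan, "split_plan"))
  stats <- if (inherits(cohort, "cohort_stats")) cohort else
    cohort_feature_stats(cohort, config)
  if (!network %in% stats$networks) {
    stop("unknown network '", network, "'; available: ",
         paste(stats$networks, collapse = ", "))
  }
  scalar_of <- function(ids) {
    m <- pooled_network_metrics(stats, ids)
    m[[metric]][m$network == network]
  }
  n_iter <- length(plan$iterations)
  n_dur <- length(plan$iterations[[1L]]$draws)
  sims <- matrix(NA_real_, n_iter, n_dur)
  for (i in seq_len(n_iter)) {
    it <- plan$iterations[[i]]
    base <- scalar_of(it$A)
    for (k in seq_len(n_dur)) {
      sims[i, k] <- scalar_similarity(scalar_of(it$draws[[k]]), base,
                                      form = config$scalar_similarity_form)
    }
  }
  durations <- seq_len(n_dur) * mean(stats$minutes_per_session)
  prof <- summarize_profile(sims, durations = durations,
                            metric = paste0(metric, ".", network))
  attr(prof, "raw") <- sims
  prof
}

#' Departure from a reference session
#'
#' `1 - Pearson r` between each session's feature vector and the reference
#' session's vector: 0 for the reference itself, 1 for an uncorrelated
#' vector, 2 for a perfectly anti-correlated one. Used to quantify
#' state changes (e.g. pharmacological sessions) against a first baseline
#' session.
#'
#' @param session_vectors list of equal-length feature vectors, one per
#'   session (named or not).
#' @param reference_index index of the reference session (default 1).
#' @return numeric vector of departures, one per session.
#' @export
departure_from_baseline <- function(session_vectors, reference_index = 1L) {
  if (length(session_vectors) < 2L) stop("need at least 2 sessions")
  lens <- vapply(session_vectors, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("feature vectors differ in length: ",
         paste(unique(lens), collapse = " vs "))
  }
  ref <- session_vectors[[reference_index]]
  out <- vapply(session_vectors, function(v) 1 - stats::cor(v, ref),
                numeric(1))
  out[reference_index] <- 0
  out
}

#' Summarize raw similarities into a reliability profile
#'
#' Per duration: mean, population SD, and normal-approximation 95% CI of the
#' mean (`mean +/- 1.96 * SD / sqrt(n_iterations)`). A single iteration
#' yields SD 0 and a degenerate CI, flagged with a warning.
#'
#' @param similarities iterations x durations numeric matrix.
#' @param durations duration grid (minutes), one per column.
#' @param metric metric name carried into the output.
#' @return object of class `reliability_profile`: data frame with columns
#'   `metric`, `duration_min`, `mean`, `sd`, `ci_lo`, `ci_hi`, plus
#'   attribute `n_iterations`.
#' @export
summarize_profile <- function(similarities, durations = NULL,
                              metric = "metric") {
  sims <- as.matrix(similarities)
  n_iter <- nrow(sims)
  if (n_iter < 1L) stop("need at least one iteration")
  if (n_iter == 1L) {
    warning("single iteration: SD reported as 0 and CI degenerate")
  }
  if (is.null(durations)) durations <- seq_len(ncol(sims))
  if (length(durations) != ncol(sims)) {
    stop("durations length must match the number of columns")
  }
  mu <- colMeans(sims)
  sdv <- sqrt(colMeans(sims^2) - mu^2)
  sdv[sdv < 0] <- 0
  hw <- 1.96 * sdv / sqrt(n_iter)
  prof <- data.frame(metric = metric, duration_min = durations, mean = mu,
                     sd = sdv, ci_lo = mu - hw, ci_hi = mu + hw,
                     row.names = NULL, stringsAsFactors = FALSE)
  attr(prof, "n_iterations") <- n_iter
  class(prof) <- c("reliability_profile", "data.frame")
  prof
}

#' @export
print.reliability_profile <- function(x, ...) {
  cat("reliability_profile '", x$metric[1L], "': ",
      attr(x, "n_iterations"), " iterations, durations ",
      round(min(x$duration_min), 2), "-", round(max(x$duration_min), 2),
      " min\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Split sessions into equal contiguous parts
#'
#' Divides each session into `parts` contiguous, non-overlapping blocks of
#' equal length, relabeled `<id>.1, <id>.2, ...` (e.g. ten 30-min sessions
#' into thirty 10-min sessions). The session length must be exactly
#' divisible by `parts`.
#'
#' @param sessions list of [session_series()].
#' @param parts number of blocks per session.
#' @return flat list of `length(sessions) * parts` sessions.
#' @export
msc_session_split <- function(sessions, parts) {
  parts <- as.integer(parts)
  if (parts < 1L) stop("parts must be >= 1")
  if (parts == 1L) return(sessions)
  out <- list()
  for (ses in sessions) {
    n <- nrow(ses$data)
    if (n %% parts != 0L) {
      stop("session '", ses$session_id, "' has ", n,
           " samples, not divisible by ", parts, " (remainder ",
           n %% parts, ")")
    }
    block <- n %/% parts
    for (p in seq_len(parts)) {
      rows <- ((p - 1L) * block + 1L):(p * block)
      out[[length(out) + 1L]] <-
        session_series(ses$data[rows, , drop = FALSE], tr = ses$tr,
                       session_id = paste0(ses$session_id, ".", p),
                       parcel_ids = ses$parcel_ids)
    }
  }
  out
}

#' Write a reliability profile as TSV
#'
#' @param profile a `reliability_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
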