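# Kuramoto order parameter, per-network sync/metastability scalars, the
# combined feature vector, and the static functional-connectivity comparator.

#' Kuramoto order parameter time course
#'
#' The instantaneous phase synchrony of a set of parcels is the modulus of
#' the complex mean of their unit phasors: `phi(t) = |mean(exp(1i *
#' theta_p(t)))|` over the parcels in the subset. `phi = 1` means full phase
#' alignment; for uniformly dispersed phases it approaches `1/sqrt(N)` in
#' expectation of `phi` squared `= 1/N`.
#'
#' @param phases a `phase_series` (from [session_phases()]) or a time x
#'   parcels numeric matrix of phases in radians.
#' @param parcel_subset parcel ids (or column indices) to include; default
#'   all.
#'
#' @return numeric vector `phi(t)` in `[0, 1]`, one value per time point.
#' @export
order_parameter <- function(phases, parcel_subset = NULL) {
  theta <- if (inherits(phases, "phase_series")) phases$phases else
    as.matrix(phases)
  if (!is.null(parcel_subset)) {
    theta <- theta[, parcel_subset, drop = FALSE]
  }
  if (ncol(theta) == 0L) stop("empty parcel subset")
  z <- exp(1i * theta)
  Mod(rowMeans(z))
}

#' Sync and metastability of a synchrony time course
#'
#' Sync is the time average of the instantaneous synchrony `phi(t)`;
#' metastability is its standard deviation over time (population
#' normalization, divisor `n`), following the Kuramoto-literature definition
#' of metastability as the variance of the order parameter. Since `phi` is
#' bounded in `[0, 1]`, metastability is bounded by 0.5.
#'
#' @param phi numeric vector: an order-parameter time course.
#' @return named numeric vector `c(sync = ..., metastability = ...)`.
#' @export
sync_and_metastability <- function(phi) {
  phi <- as.numeric(phi)
  if (length(phi) < 2L) stop("need at least 2 time points")
  if (any(!is.finite(phi))) stop("non-finite synchrony values")
  m <- mean(phi)
  v <- mean((phi - m)^2)
  c(sync = m, metastability = sqrt(v))
}

#' Per-network sync and metastability
#'
#' Applies [order_parameter()] and [sync_and_metastability()] to every
#' network of the assignment, including the all-parcels "Global" network.
#' A single-parcel network necessarily has `phi(t) = 1` (one unit phasor),
#' hence sync 1 and metastability 0; this degenerate case is flagged with a
#' warning.
#'
#' @param phases a `phase_series` or time x parcels phase matrix with parcel
#'   ids as column names.
#' @param assignment a [network_assignment()].
#'
#' @return object of class `network_metrics`: data frame with columns
#'   `network`, `sync`, `metastability`, rows in the assignment's fixed
#'   network order.
#' @export
network_metrics <- function(phases, assignment) {
  stopifnot(inherits(assignment, "network_assignment"))
  theta <- if (inherits(phases, "phase_series")) phases$phases else
    as.matrix(phases)
  if (!all(assignment$parcel_ids %in% colnames(theta))) {
    stop("phase matrix is missing parcels named in the assignment")
  }
  singletons <- names(assignment$members)[
    vapply(assignment$members, length, integer(1)) == 1L]
  if (length(singletons) > 0L) {
    warning("single-parcel network(s) ", paste(singletons, collapse = ", "),
            ": sync = 1 and metastability = 0 by definition")
  }
  out <- t(vapply(assignment$networks, function(nw) {
    sync_and_metastability(order_parameter(theta, assignment$members[[nw]]))
  }, numeric(2)))
  res <- data.frame(network = assignment$networks,
                    sync = out[, "sync"],
                    metastability = out[, "metastability"],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("network_metrics", "data.frame")
  res
}

#' Assemble an ordered feature vector from network metrics
#'
#' The combined sync-metastability feature vector concatenates all networks'
#' sync values followed by all networks' metastability values, in the fixed
#' network order of the assignment (for 14 networks this is the
#' 28-dimensional vector). `kind = "sync"` or `"metastability"` returns the
#' corresponding single block.
#'
#' @param metrics a [network_metrics()] result.
#' @param kind `"sync"`, `"metastability"`, or `"combined"`.
#' @return named numeric vector of class `feature_vector`.
#' @export
feature_vector <- function(metrics, kind = c("combined", "sync",
                                             "metastability")) {
  kind <- match.arg(kind)
  stopifnot(inherits(metrics, "network_metrics"))
  s <- stats::setNames(metrics$sync, paste0("sync.", metrics$network))
  m <- stats::setNames(metrics$metastability,
                       paste0("meta.", metrics$network))
  v <- switch(kind, sync = s, metastability = m, combined = c(s, m))
  structure(v, kind = kind, class = c("feature_vector", "numeric"))
}

#' Static functional connectivity matrix
#'
#' Pearson correlation between every pair of parcel time series, Fisher
#' z-transformed (`atanh`). Correlations are clipped to `+/-(1 - 1e-15)`
#' before the transform so that numerically perfect correlations stay
#' finite; the clip is inert for real data. The diagonal is set to 0 and is
#' excluded from all downstream vectorizations.
#'
#' @param x time x parcels numeric matrix (or a [session_series()]).
#' @return object of class `fc_matrix`: symmetric parcels x parcels matrix
#'   of Fisher z values.
#' @export
static_fc <- function(x) {
  if (inherits(x, "session_series")) x <- x$data
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 time points for FC")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    ids <- colnames(x)
    if (is.null(ids)) ids <- as.character(seq_len(ncol(x)))
    stop("zero-variance parcel(s): ", paste(ids[sds == 0], collapse = ", "))
  }
  r <- stats::cor(x)
  r <- fisher_z(r)
  diag(r) <- 0
  class(r) <- c("fc_matrix", class(r))
  r
}

#' Fisher z transform with clipping
#'
#' `atanh(r)` after clipping `r` to `+/-(1 - 1e-15)` so `|r| = 1` maps to a
#' finite value.
#'
#' @param r correlation value(s).
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  lim <- 1 - 1e-15
  atanh(pmin(pmax(r, -lim), lim))
}

#' Vectorize a functional-connectivity submatrix
#'
#' Extracts the upper triangle (diagonal excluded) of the FC submatrix
#' restricted to a parcel subset, row-major, as a feature vector. For the
#' per-network FC comparator the subset is the network's own parcels; the
#' Global network uses all parcels (`333` parcels give `333*332/2 = 55278`
#' edges).
#'
#' @param fc an [static_fc()] matrix.
#' @param parcel_subset parcel ids or indices, length >= 2; default all.
#' @return numeric vector of the subset's unique off-diagonal edges.
#' @export
fc_vector <- function(fc, parcel_subset = NULL) {
  m <- unclass(fc)
  if (!is.null(parcel_subset)) {
    m <- m[parcel_subset, parcel_subset, drop = FALSE]
  }
  if (ncol(m) < 2L) stop("parcel subset must contain at least 2 parcels")
  # row-major upper triangle: transpose before masking (R fills by column)
  tm <- t(m)
  tm[lower.tri(tm)]
}

#' Redundancy of network metrics across replications
#'
#' Pearson correlation between every pair of metric columns across rows
#' (sessions or iterations -- the unit of replication is whatever the rows
#' are). Reports the mean absolute off-diagonal correlation, the full
#' correlation matrix, and the mean absolute correlation of pairs involving
#' the Global metric when a column named like `"Global"` is present.
#' Constant columns carry no correlation information and are excluded with a
#' warning.
#'
#' @param metric_values replications x metrics numeric matrix with column
#'   names.
#' @return list with `mean_abs_r`, `cor_matrix`, `global_mean_abs_r` (NA if
#'   no Global column), `excluded` (names of dropped constant columns).
#' @export
metric_redundancy <- function(metric_values) {
  m <- as.matrix(metric_values)
  if (nrow(m) < 3L) stop("need at least 3 replications (rows)")
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  sds <- apply(m, 2L, stats::sd)
  excluded <- colnames(m)[sds == 0]
  if (length(excluded) > 0L) {
    warning("excluding constant column(s): ", paste(excluded, collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  if (ncol(m) < 2L) stop("fewer than 2 non-constant metric columns")
  C <- stats::cor(m)
  off <- abs(C[upper.tri(C)])
  is_global <- grepl("Global", colnames(m))
  global_mean <- if (any(is_global)) {
    rows <- abs(C[is_global, !is_global, drop = FALSE])
    mean(rows)
  } else NA_real_
  list(mean_abs_r = mean(off), cor_matrix = C,
       global_mean_abs_r = global_mean, excluded = excluded)
}

#' Write per-session network metrics as tidy TSV
#'
#' @param metrics_table data frame with columns `session_id`, `network`,
#'   `sync`, `metastability`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics_table, path) {
  utils::write.table(metrics_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
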