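#' Construct a session time-series object
#'
#' A `session_series` holds one scan session's parcellated BOLD data as a
#' time x parcels matrix together with the repetition time (TR) and stable
#' parcel identifiers. All downstream computations (phase extraction,
#' synchrony, functional connectivity) consume this container.
#'
#' @param data numeric matrix, rows = time points (one per TR), columns =
#'   parcels.
#' @param tr repetition time in seconds (sampling interval).
#' @param session_id character scalar naming the session.
#' @param parcel_ids character vector of unique parcel names, one per column.
#'   Defaults to the column names of `data`.
#'
#' @return an object of class `session_series`.
#' @export
session_series <- function(data, tr, session_id = "session",
                           parcel_ids = colnames(data)) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(parcel_ids)) {
    parcel_ids <- sprintf("P%03d", seq_len(ncol(data)))
  }
  parcel_ids <- as.character(parcel_ids)
  if (length(parcel_ids) != ncol(data)) {
    stop("parcel_ids length (", length(parcel_ids),
         ") does not match number of columns (", ncol(data), ")")
  }
  if (anyDuplicated(parcel_ids)) {
    stop("duplicate parcel ids: ",
         paste(unique(parcel_ids[duplicated(parcel_ids)]), collapse = ", "))
  }
  if (nrow(data) < 2L) stop("a session needs at least 2 time points")
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0) {
    stop("tr must be a positive number (seconds)")
  }
  bad <- which(!is.finite(data), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-finite values in session '", session_id, "', e.g. parcel '",
         parcel_ids[bad[1L, 2L]], "' at time point ", bad[1L, 1L])
  }
  colnames(data) <- parcel_ids
  structure(
    list(data = data, tr = tr, session_id = as.character(session_id),
         parcel_ids = parcel_ids),
    class = "session_series"
  )
}

#' @export
print.session_series <- function(x, ...) {
  cat("session_series '", x$session_id, "': ", nrow(x$data), " time points x ",
      ncol(x$data), " parcels, TR = ", x$tr, " s (",
      round(nrow(x$data) * x$tr / 60, 2), " min)\n", sep = "")
  invisible(x)
}

#' Read a parcellated session from delimited text
#'
#' The on-disk format is tab-separated text: a header row of parcel ids
#' followed by one row per time point. Parse errors are reported with the
#' offending row and column so malformed upstream exports can be located.
#' Missing values are rejected rather than imputed: frame censoring and
#' interpolation are preprocessing concerns, not part of this pipeline.
#'
#' @param path path to a TSV file.
#' @param tr repetition time in seconds.
#' @param session_id session name; defaults to the file name without
#'   extension.
#' @param sep field separator (default tab).
#'
#' @return a [session_series()].
#' @export
read_session <- function(path, tr, session_id = NULL, sep = "\t") {
  if (!file.exists(path)) stop("session file not found: ", path)
  if (is.null(session_id)) {
    session_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("session file '", path, "' has no data rows")
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1L]]
  p <- length(header)
  if (anyDuplicated(header)) {
    stop("duplicate parcel ids in header of '", path, "'")
  }
  n <- length(fields) - 1L
  mat <- matrix(NA_real_, n, p)
  for (i in seq_len(n)) {
    row <- fields[[i + 1L]]
    if (length(row) != p) {
      stop("ragged row in '", path, "': data row ", i, " has ", length(row),
           " fields, header has ", p)
    }
    vals <- suppressWarnings(as.numeric(row))
    bad <- which(is.na(vals) & !(toupper(row) %in% c("NA", "NAN")))
    if (length(bad) > 0L) {
      stop("non-numeric value '", row[bad[1L]], "' in '", path,
           "' at data row ", i, ", column ", bad[1L],
           " (parcel '", header[bad[1L]], "')")
    }
    nav <- which(!is.finite(vals))
    if (length(nav) > 0L) {
      stop("missing/non-finite value in '", path, "' at data row ", i,
           " for parcel '", header[nav[1L]], "'")
    }
    mat[i, ] <- vals
  }
  session_series(mat, tr = tr, session_id = session_id, parcel_ids = header)
}

#' Write a session to delimited text
#'
#' Values are written with 17 significant digits so that a write/read round
#' trip reproduces the matrix exactly.
#'
#' @param session a [session_series()].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, sep = "\t") {
  stopifnot(inherits(session, "session_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(session$parcel_ids, collapse = sep), con)
  body <- apply(session$data, 1L, function(r) {
    paste(sprintf("%.17g", r), collapse = sep)
  })
  writeLines(body, con)
  invisible(path)
}

#' Construct a parcel-to-network assignment
#'
#' Every parcel is assigned to exactly one labeled functional network (hard
#' assignment). A "Global" network containing every parcel is always
#' appended, so an assignment with 13 labeled networks exposes 14 networks
#' in total. Network order is fixed (label order of first appearance, Global
#' last) and is used for all feature vectors, so baseline and test vectors
#' are always aligned.
#'
#' @param parcel_ids character vector of parcel names.
#' @param network_labels character vector, same length, giving each parcel's
#'   network label.
#'
#' @return an object of class `network_assignment` with elements
#'   `parcel_ids`, `network_of` (named character), `networks` (ordered
#'   labels including `"Global"`), and `members` (list of parcel-id vectors
#'   per network).
#' @export
network_assignment <- function(parcel_ids, network_labels) {
  parcel_ids <- as.character(parcel_ids)
  network_labels <- as.character(network_labels)
  if (length(parcel_ids) != length(network_labels)) {
    stop("parcel_ids and network_labels must have the same length")
  }
  if (anyDuplicated(parcel_ids)) {
    stop("parcel listed twice in assignment: ",
         paste(unique(parcel_ids[duplicated(parcel_ids)]), collapse = ", "))
  }
  if (any(!nzchar(network_labels)) || anyNA(network_labels)) {
    stop("empty network label for parcel(s): ",
         paste(parcel_ids[!nzchar(network_labels) | is.na(network_labels)],
               collapse = ", "))
  }
  if ("Global" %in% network_labels) {
    stop("'Global' is reserved for the all-parcels network")
  }
  labels <- unique(network_labels)  # first-appearance order
  members <- lapply(labels, function(l) parcel_ids[network_labels == l])
  names(members) <- labels
  members$Global <- parcel_ids
  network_of <- stats::setNames(network_labels, parcel_ids)
  structure(
    list(parcel_ids = parcel_ids, network_of = network_of,
         networks = c(labels, "Global"), members = members),
    class = "network_assignment"
  )
}

#' @export
print.network_assignment <- function(x, ...) {
  cat("network_assignment: ", length(x$parcel_ids), " parcels, ",
      length(x$networks), " networks (incl. Global)\n", sep = "")
  sizes <- vapply(x$members, length, integer(1))
  cat(paste0("  ", names(sizes), ": ", sizes, collapse = "\n"), "\n")
  invisible(x)
}

#' Read a parcel-to-network assignment table
#'
#' Two-column tab-separated text with header `parcel_id`, `network`.
#' Networks are ordered by first appearance in the file; "Global" is
#' appended automatically.
#'
#' @param path path to the TSV file.
#' @return a [network_assignment()].
#' @export
read_network_assignment <- function(path) {
  if (!file.exists(path)) stop("assignment file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2L) stop("assignment file needs columns parcel_id, network")
  network_assignment(tab[[1L]], tab[[2L]])
}

#' Write a network assignment table
#'
#' @param assignment a [network_assignment()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_network_assignment <- function(assignment, path) {
  stopifnot(inherits(assignment, "network_assignment"))
  tab <- data.frame(parcel_id = assignment$parcel_ids,
                    network = unname(assignment$network_of),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Analysis run configuration
#'
#' Bundles the tunable parameters of the phase/metrics/reliability pipeline.
#'
#' @param mode_index which intrinsic mode carries the phase: 0 (fastest,
#'   canonical 0.04-0.07 Hz BOLD band) or 1 (slower, 0.01-0.04 Hz).
#' @param discard_initial seconds discarded from the start of every session
#'   before phase extraction, to drop scan-onset transients (default 60).
#' @param edge_trim samples trimmed from each end of every phase series to
#'   suppress decomposition edge artifacts (default 5).
#' @param n_iterations number of random split-half iterations for the
#'   reliability engine (default 1000).
#' @param duration_increment optional duration grid step in minutes; by
#'   default the grid is one retained session per step.
#' @param seed master seed for all randomized stages.
#' @param similarity_kind `"vector-correlation"` (Pearson correlation of
#'   feature vectors) or `"scalar-similarity"` (normalized absolute error,
#'   for single-network scalars).
#' @param scalar_similarity_form `"normalized"` for 1 - |err|/|baseline| or
#'   `"absolute"` for 1 - |err|.
#'
#' @return an object of class `run_config`.
#' @export
run_config <- function(mode_index = 0L,
                       discard_initial = 60,
                       edge_trim = 5L,
                       n_iterations = 1000L,
                       duration_increment = NULL,
                       seed = 1L,
                       similarity_kind = c("vector-correlation",
                                           "scalar-similarity"),
                       scalar_similarity_form = c("normalized", "absolute")) {
  similarity_kind <- match.arg(similarity_kind)
  scalar_similarity_form <- match.arg(scalar_similarity_form)
  mode_index <- as.integer(mode_index)
  if (!mode_index %in% c(0L, 1L)) stop("mode_index must be 0 or 1")
  if (discard_initial < 0) stop("discard_initial must be >= 0 seconds")
  edge_trim <- as.integer(edge_trim)
  if (edge_trim < 0L) stop("edge_trim must be >= 0 samples")
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  structure(
    list(mode_index = mode_index, discard_initial = discard_initial,
         edge_trim = edge_trim, n_iterations = n_iterations,
         duration_increment = duration_increment, seed = as.integer(seed),
         similarity_kind = similarity_kind,
         scalar_similarity_form = scalar_similarity_form),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("run config not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown run config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' Validate a multi-session cohort against a network assignment
#'
#' Checks that all sessions share one TR and one parcel set in one order,
#' and that the order matches the assignment. Returns the cohort handle the
#' reliability and surrogate engines consume.
#'
#' @param sessions list of [session_series()] objects.
#' @param assignment a [network_assignment()].
#'
#' @return an object of class `cohort`: list with `sessions`, `assignment`,
#'   `tr`, `session_ids`.
#' @export
validate_cohort <- function(sessions, assignment) {
  stopifnot(inherits(assignment, "network_assignment"))
  if (length(sessions) < 1L) stop("cohort needs at least one session")
  ok <- vapply(sessions, inherits, logical(1), what = "session_series")
  if (!all(ok)) stop("all cohort elements must be session_series objects")
  ids <- vapply(sessions, `[[`, character(1), "session_id")
  if (anyDuplicated(ids)) {
    stop("duplicate session ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  }
  trs <- vapply(sessions, `[[`, numeric(1), "tr")
  if (length(unique(trs)) != 1L) {
    stop("sessions disagree on TR: ",
         paste(ids[trs != trs[1L]], collapse = ", "),
         " differ from '", ids[1L], "'")
  }
  ref <- sessions[[1L]]$parcel_ids
  for (s in sessions) {
    if (!identical(s$parcel_ids, ref)) {
      missing <- setdiff(ref, s$parcel_ids)
      extra <- setdiff(s$parcel_ids, ref)
      stop("session '", s$session_id, "' parcel set/order mismatch",
           if (length(missing)) paste0("; missing: ",
                                       paste(missing, collapse = ", ")),
           if (length(extra)) paste0("; extra: ",
                                     paste(extra, collapse = ", ")))
    }
  }
  if (!identical(ref, assignment$parcel_ids)) {
    stop("cohort parcel ids/order do not match the network assignment")
  }
  structure(
    list(sessions = sessions, assignment = assignment, tr = trs[1L],
         session_ids = ids),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  n <- vapply(x$sessions, function(s) nrow(s$data), integer(1))
  cat("cohort: ", length(x$sessions), " sessions, ",
      length(x$assignment$parcel_ids), " parcels, TR = ", x$tr, " s, ",
      round(sum(n) * x$tr / 60, 1), " min total\n", sep = "")
  invisible(x)
}
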