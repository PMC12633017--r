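#' Fluorescence trace container
#'
#' A `trace_set` holds a neurons-by-time matrix of normalized fluorescence
#' (dF/F), the bin width in seconds, and an optional partition of the time
#' axis into trials. All model-fitting functions in the package accept either
#' a `trace_set` or a plain numeric matrix (one row per neuron).
#'
#' @param values Numeric matrix, neurons x time, finite entries.
#' @param dt Bin width in seconds (positive scalar).
#' @param trial_ids Optional integer vector of length `ncol(values)` assigning
#'   each bin to a trial; bins of a trial must be contiguous. `NULL` means a
#'   single continuous recording.
#' @return An object of class `trace_set`.
#' @examples
#' y <- trace_set(matrix(rnorm(20), 2, 10), dt = 0.1)
#' dim(y)
#' @export
trace_set <- function(values, dt = 1, trial_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("trace values must be finite; found NA/NaN/Inf at entry ",
         which(!is.finite(values))[1L])
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a positive scalar (seconds)")
  if (!is.null(trial_ids)) {
    trial_ids <- as.integer(trial_ids)
    if (length(trial_ids) != ncol(values))
      stop("trial_ids must have one entry per time bin")
    if (any(trial_ids != cummax(trial_ids)) || any(diff(unique(trial_ids)) <= 0))
      stop("trial bins must be contiguous and trial ids nondecreasing")
  }
  structure(list(values = values, dt = dt, trial_ids = trial_ids),
            class = "trace_set")
}

#' @export
as.matrix.trace_set <- function(x, ...) x$values

#' Coerce to a trace_set
#' @param x A `trace_set` or a neurons-by-time numeric matrix.
#' @param dt Bin width used when `x` is a bare matrix.
#' @return A `trace_set`.
#' @export
as_trace_set <- function(x, dt = 1) {
  if (inherits(x, "trace_set")) x else trace_set(x, dt = dt)
}

#' @export
dim.trace_set <- function(x) dim(x$values)

#' @export
print.trace_set <- function(x, ...) {
  nt <- if (is.null(x$trial_ids)) 1L else length(unique(x$trial_ids))
  cat(sprintf("<trace_set> %d neurons x %d bins (dt = %g s, %d trial%s)\n",
              nrow(x$values), ncol(x$values), x$dt, nt, if (nt > 1) "s" else ""))
  invisible(x)
}

#' Split a trace_set into per-trial matrices
#'
#' @param y A `trace_set`.
#' @return A list of neurons-by-time matrices, one per trial (a single-element
#'   list when the recording is continuous).
#' @export
trial_split <- function(y) {
  y <- as_trace_set(y)
  if (is.null(y$trial_ids)) return(list(y$values))
  lapply(split(seq_len(ncol(y$values)), y$trial_ids),
         function(ix) y$values[, ix, drop = FALSE])
}

#' Read fluorescence traces from CSV
#'
#' The CSV layout is one row per neuron with a header row of bin times in
#' seconds (so `dt` is recovered from the header spacing). An optional JSON
#' sidecar `<path>.meta.json` may carry `dt` and `trial_ids`, which override
#' the header-derived values.
#'
#' @param path CSV file path.
#' @param dt Bin width override; `NULL` derives it from the header.
#' @return A `trace_set`.
#' @export
read_traces <- function(path, dt = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  vals <- as.matrix(tab)
  if (!is.numeric(vals)) {
    bad <- which(!vapply(tab, is.numeric, logical(1)))[1L]
    stop("non-numeric trace column ", bad, " in ", path)
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at neuron %d, bin %d in %s",
                 bad[1L], bad[2L], path))
  }
  times <- suppressWarnings(as.numeric(colnames(tab)))
  if (is.null(dt))
    dt <- if (length(times) > 1L && !anyNA(times)) stats::median(diff(times)) else 1
  trial_ids <- NULL
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$dt)) dt <- meta$dt
    if (!is.null(meta$trial_ids)) trial_ids <- as.integer(meta$trial_ids)
  }
  dimnames(vals) <- NULL
  trace_set(vals, dt = dt, trial_ids = trial_ids)
}

#' Write fluorescence traces to CSV
#'
#' Inverse of [read_traces()]: one row per neuron, header of bin times; trial
#' structure (when present) goes to a JSON sidecar `<path>.meta.json`.
#'
#' @param y A `trace_set` (or matrix).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(y, path) {
  y <- as_trace_set(y)
  tab <- as.data.frame(y$values)
  names(tab) <- formatC((seq_len(ncol(y$values)) - 1L) * y$dt,
                        format = "g", digits = 10)
  utils::write.csv(tab, path, row.names = FALSE)
  if (!is.null(y$trial_ids) || y$dt != 1) {
    jsonlite::write_json(list(dt = y$dt, trial_ids = y$trial_ids),
                         paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}
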