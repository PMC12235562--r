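#' Construct an epoched EEG container
#'
#' An `epochset` bundles a cue-locked trial tensor with its per-trial
#' metadata. Voltages are in microvolts; `times` gives the latency of each
#' sample in ms with cue onset at 0 (the canonical epoch spans -500..1498 ms
#' sampled at 500 Hz, i.e. 1000 samples on a 2-ms grid).
#'
#' @param data numeric array, trials x channels x samples (uV).
#' @param times numeric vector of per-sample latencies (ms).
#' @param srate sampling rate in Hz.
#' @param channels character vector of unique channel labels (10-20 names).
#' @param trials data.frame of per-trial metadata, one row per trial
#'   (see [trial_table()] for the expected columns).
#' @return an object of class `epochset`.
#' @export
epochset <- function(data, times, srate, channels, trials) {
  es <- structure(
    list(data = data, times = as.numeric(times), srate = as.numeric(srate),
         channels = as.character(channels), trials = trials),
    class = "epochset")
  validate_epochset(es)
}

#' Validate an epochset against its invariants
#'
#' Checks dimensional consistency between the tensor, the time axis, the
#' channel labels and the trial table, plus positivity of the sampling rate
#' and uniqueness of channel labels. Zero-trial sets are valid.
#'
#' @param es an `epochset`.
#' @return `es`, invisibly usable, after passing all checks.
#' @export
validate_epochset <- function(es) {
  d <- es$data
  if (!is.array(d) || length(dim(d)) != 3)
    stop("data must be a 3-d array (trials x channels x samples)", call. = FALSE)
  if (!is.numeric(es$srate) || length(es$srate) != 1 || es$srate <= 0)
    stop("srate must be a single positive number", call. = FALSE)
  if (anyDuplicated(es$channels))
    stop("channel labels must be unique", call. = FALSE)
  if (dim(d)[2] != length(es$channels))
    stop(sprintf("dimension error: tensor has %d channels but %d channel labels",
                 dim(d)[2], length(es$channels)), call. = FALSE)
  if (dim(d)[3] != length(es$times))
    stop(sprintf("dimension error: tensor has %d samples but %d time points",
                 dim(d)[3], length(es$times)), call. = FALSE)
  if (!is.data.frame(es$trials))
    stop("trials must be a data.frame", call. = FALSE)
  if (dim(d)[1] != nrow(es$trials))
    stop(sprintf("dimension error: tensor has %d trials but trial table has %d rows",
                 dim(d)[1], nrow(es$trials)), call. = FALSE)
  if (length(es$times) > 1) {
    step <- diff(es$times)
    if (any(abs(step - 1000 / es$srate) > 1e-6))
      stop("times must advance in 1000/srate ms steps", call. = FALSE)
  }
  if (any(es$trials$rt < 0, na.rm = TRUE))
    stop("rt must be >= 0 when present", call. = FALSE)
  es
}

#' @export
print.epochset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epochset> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$srate))
  if (length(x$times))
    cat(sprintf("  times %g..%g ms; channels: %s%s\n",
                min(x$times), max(x$times),
                paste(utils::head(x$channels, 6), collapse = ", "),
                if (length(x$channels) > 6) ", ..." else ""))
  invisible(x)
}

#' @export
dim.epochset <- function(x) dim(x$data)

#' Subset an epochset by trial
#'
#' @param es an `epochset`.
#' @param i trial indices (integer or logical) to keep.
#' @return an `epochset` restricted to the selected trials.
#' @export
subset_trials <- function(es, i) {
  es$data <- es$data[i, , , drop = FALSE]
  es$trials <- es$trials[i, , drop = FALSE]
  rownames(es$trials) <- NULL
  validate_epochset(es)
}

## Canonical trial-table columns and their types. rt is NA for omissions.
trial_table_cols <- c("subject", "age_group", "age", "context", "block",
                      "cue_type", "congruency", "rt", "accuracy", "prev_rt")

#' Assemble a per-trial metadata table
#'
#' Column semantics: `context` is the task context (`strategic` or
#' `affective`); `cue_type` is one of predict_congruent / no_prediction /
#' predict_incongruent (strategic) or positive / neutral / negative
#' (affective); `congruency` refers to the flanker array; `accuracy` is
#' `correct`, `incorrect` or `timeout`; `rt` and `prev_rt` are in ms and
#' may be `NA` for omissions (`prev_rt` is `NA` for the first trial of a
#' block's sequence).
#'
#' @param ... vectors for the columns named in the details, recycled to a
#'   common length.
#' @return a `data.frame` with the canonical column order.
#' @export
trial_table <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_table_cols, names(df))
  for (m in missing_cols) df[[m]] <- NA
  df <- df[trial_table_cols]
  validate_trial_table(df)
}

strategic_cues <- c("predict_congruent", "no_prediction", "predict_incongruent")
affective_cues <- c("positive", "neutral", "negative")

validate_trial_table <- function(df) {
  bad <- (df$context == "strategic" & !df$cue_type %in% strategic_cues) |
         (df$context == "affective" & !df$cue_type %in% affective_cues)
  if (any(bad, na.rm = TRUE))
    stop("cue_type inconsistent with task context in ",
         sum(bad, na.rm = TRUE), " trial(s)", call. = FALSE)
  if (any(df$rt < 0, na.rm = TRUE))
    stop("rt must be >= 0 when present", call. = FALSE)
  df
}

#' Write an epochset to an HDF5 container
#'
#' Layout: `/data` (float32, trials x channels x samples), `/times`
#' (float64, ms), `/trials` (compound table), plus root attributes
#' `srate` and `channel_names`. Missing `rt`/`prev_rt` values are stored
#' as NaN and restored to `NA` on read.
#'
#' @param es a valid `epochset`.
#' @param path output file path (`.h5`).
#' @param overwrite overwrite an existing file? Defaults to `FALSE`, in
#'   which case an existing file is an error.
#' @return `path`, invisibly.
#' @export
write_epochset <- function(es, path, overwrite = FALSE) {
  validate_epochset(es)
  if (file.exists(path)) {
    if (!overwrite)
      stop("file exists (pass overwrite = TRUE to replace): ", path,
           call. = FALSE)
    unlink(path)
  }
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (!isTRUE(ok))
    stop("cannot create HDF5 file at: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  ## rhdf5 cannot write 0-row compound tables; degenerate sets get an
  ## empty-marker attribute instead.
  chunk <- if (all(dim(es$data) > 0)) pmin(dim(es$data), c(64, 16, 1024))
  rhdf5::h5createDataset(path, "data", dims = dim(es$data),
                         H5type = "H5T_IEEE_F32LE", level = 0,
                         chunk = chunk)
  rhdf5::h5write(es$data, path, "data")
  rhdf5::h5write(es$times, path, "times")
  tr <- es$trials
  num_cols <- c("rt", "prev_rt", "age", "block")
  for (k in num_cols)
    tr[[k]] <- as.numeric(tr[[k]])
  for (k in setdiff(names(tr), num_cols))
    tr[[k]] <- as.character(tr[[k]])
  if (nrow(tr) > 0) {
    rhdf5::h5write(tr, path, "trials", DataFrameAsCompound = TRUE)
  } else {
    rhdf5::h5write(names(tr), path, "trials_schema_only")
  }
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(es$srate, fid, "srate")
  rhdf5::h5writeAttribute(es$channels, fid, "channel_names")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read an epochset from an HDF5 container
#'
#' Inverse of [write_epochset()]; validates the layout and the resulting
#' object, raising a format error naming any missing member.
#'
#' @param path path to an HDF5 file written by [write_epochset()].
#' @return an `epochset`.
#' @export
read_epochset <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  members <- rhdf5::h5ls(path)$name
  for (need in c("data", "times"))
    if (!need %in% members)
      stop("format error: missing dataset '/", need, "' in ", path,
           call. = FALSE)
  if (!any(c("trials", "trials_schema_only") %in% members))
    stop("format error: missing dataset '/trials' in ", path, call. = FALSE)
  fid <- rhdf5::H5Fopen(path)
  attrs <- rhdf5::h5readAttributes(fid, "/")
  rhdf5::H5Fclose(fid)
  for (need in c("srate", "channel_names"))
    if (is.null(attrs[[need]]))
      stop("format error: missing root attribute '", need, "' in ", path,
           call. = FALSE)
  data <- rhdf5::h5read(path, "data")
  times <- as.numeric(rhdf5::h5read(path, "times"))
  if ("trials" %in% members) {
    tr <- rhdf5::h5read(path, "trials")
    num_cols <- c("rt", "prev_rt", "age", "block")
    for (k in names(tr)) {
      tr[[k]] <- if (k %in% num_cols) as.numeric(tr[[k]])
                 else as.character(as.vector(tr[[k]]))
      if (k %in% num_cols) tr[[k]][is.nan(tr[[k]])] <- NA_real_
    }
    tr <- tr[trial_table_cols]
  } else {
    cols <- rhdf5::h5read(path, "trials_schema_only")
    tr <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    for (k in c("rt", "prev_rt", "age", "block")) tr[[k]] <- numeric(0)
    tr <- tr[trial_table_cols]
  }
  epochset(data = data, times = times, srate = as.numeric(attrs$srate),
           channels = as.character(attrs$channel_names), trials = tr)
}
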