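#' Labeled multichannel trial container
#'
#' Bundles epoched EEG trials with their class labels, sampling rate and
#' channel names. Trials are stored as a 3-D numeric array
#' (trial x channel x sample, microvolts). Labels are the binary motor-imagery
#' classes `"L"` (left hand) and `"R"` (right hand).
#'
#' @param data 3-D numeric array, trial x channel x sample.
#' @param labels character or factor of per-trial labels in `{"L","R"}`;
#'   may be `NULL` for unlabeled (prediction-only) sets.
#' @param fs sampling rate in Hz.
#' @param channels ordered channel names; defaults to `c("C3","Cz","C4")`.
#' @return An object of class `trial_set`.
#' @examples
#' x <- array(rnorm(2 * 3 * 64), c(2, 3, 64))
#' ts <- trial_set(x, c("L", "R"), fs = 128)
#' ts
#' @export
trial_set <- function(data, labels = NULL, fs,
                      channels = c("C3", "Cz", "C4")) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (trial x channel x sample)")
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data)))
    stop("trial data must be finite numeric")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (dim(data)[2] != length(channels))
    stop("channel dimension (", dim(data)[2], ") does not match `channels` (",
         length(channels), ")")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != dim(data)[1])
      stop("`labels` length must equal the number of trials")
    if (!all(labels %in% c("L", "R")))
      stop("labels must be \"L\" or \"R\"")
    labels <- factor(labels, levels = c("L", "R"))
  }
  structure(list(data = data, labels = labels, fs = fs, channels = channels),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<trial_set> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples @ ", x$fs, " Hz\n", sep = "")
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("  labels:  ", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  } else cat("  labels:   none\n")
  invisible(x)
}

#' @export
`[.trial_set` <- function(x, i, ...) {
  trial_set(x$data[i, , , drop = FALSE],
            if (!is.null(x$labels)) as.character(x$labels[i]) else NULL,
            x$fs, x$channels)
}

n_trials <- function(x) dim(x$data)[1]

#' Write / read a trial set as a plain-text container
#'
#' The on-disk format is a flat whitespace-separated sample table (one row per
#' trial x channel, samples in columns) plus a JSON sidecar holding the array
#' shape, sampling rate, channel names and labels. Both files are plain text
#' so the container is portable and diffable.
#'
#' @param x a [trial_set()].
#' @param path base path; `<path>.dat` and `<path>.json` are written.
#' @return `write_trialset` returns `path` invisibly; `read_trialset` returns
#'   a [trial_set()].
#' @export
write_trialset <- function(x, path) {
  stopifnot(inherits(x, "trial_set"))
  d <- dim(x$data)
  m <- aperm(x$data, c(2, 1, 3))          # rows: channel within trial
  dim(m) <- c(d[2] * d[1], d[3])
  utils::write.table(format(m, digits = 10, trim = TRUE),
                     paste0(path, ".dat"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- list(n_trials = d[1], n_channels = d[2], n_samples = d[3],
               fs = x$fs, channels = x$channels,
               labels = if (is.null(x$labels)) NULL else as.character(x$labels))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trialset
#' @export
read_trialset <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(paste0(path, ".dat")))
  arr <- aperm(array(m, c(meta$n_channels, meta$n_trials, meta$n_samples)),
               c(2, 1, 3))
  trial_set(arr, meta$labels, as.numeric(meta$fs), meta$channels)
}
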