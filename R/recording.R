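#' Segmented recordings
#'
#' A segmented recording holds `n + 1` ordered segments of a uniformly
#' sampled single-channel signal sharing one sampling rate `fs`. Each
#' segment `i` is sampled at its own local times `j / fs`,
#' `j = 0, ..., N_i - 1`; the unknown gap between consecutive segments is
#' never stored — it is absorbed by the per-segment phase shift of the
#' artifact model. The object is a tibble with integer columns
#' `segment_id` (contiguous from 0) and `sample_index` (restarting at 0 in
#' each segment) and a numeric `value` column, with the sampling rate kept
#' in the `fs` attribute, so the usual dplyr verbs apply.
#'
#' @param values a numeric vector (one segment) or a list of numeric
#'   vectors (one per segment, in order).
#' @param fs sampling rate in Hz; must be a single positive number.
#' @return a `segmented_recording` tibble.
#' @examples
#' rec <- segmented_recording(list(sin(1:100 / 5), cos(1:80 / 5)), fs = 250)
#' n_segments(rec)
#' segment_lengths(rec)
#' @export
segmented_recording <- function(values, fs) {
  if (is.numeric(values)) values <- list(values)
  if (!is.list(values) || length(values) == 0L) {
    stop("`values` must be a non-empty numeric vector or list of numeric vectors",
         call. = FALSE)
  }
  df <- tibble::tibble(
    segment_id   = rep(seq_along(values) - 1L, lengths(values)),
    sample_index = unlist(lapply(lengths(values), function(n) seq_len(n) - 1L),
                          use.names = FALSE),
    value        = as.double(unlist(values, use.names = FALSE))
  )
  as_recording(df, fs)
}

#' Coerce a data frame to a segmented recording
#'
#' @param x a data frame with columns `segment_id`, `sample_index`, `value`.
#' @param fs sampling rate in Hz.
#' @return a validated `segmented_recording` tibble.
#' @export
as_recording <- function(x, fs) {
  if (!is.data.frame(x)) stop("`x` must be a data frame", call. = FALSE)
  needed <- c("segment_id", "sample_index", "value")
  if (!all(needed %in% names(x))) {
    stop("recording needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(x[needed])
  out$segment_id <- as.integer(out$segment_id)
  out$sample_index <- as.integer(out$sample_index)
  out$value <- as.double(out$value)
  out <- out[order(out$segment_id, out$sample_index), , drop = FALSE]
  attr(out, "fs") <- as.double(fs)
  class(out) <- c("segmented_recording", class(tibble::tibble()))
  validate_recording(out)
}

validate_recording <- function(rec) {
  fs <- attr(rec, "fs")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive finite number (Hz)", call. = FALSE)
  }
  if (nrow(rec) == 0L) stop("recording has no samples", call. = FALSE)
  if (anyNA(rec$value) || any(!is.finite(rec$value))) {
    stop("recording values must be finite", call. = FALSE)
  }
  ids <- unique(rec$segment_id)
  if (!identical(ids, seq_along(ids) - 1L)) {
    stop("segment ids must be contiguous integers starting at 0", call. = FALSE)
  }
  idx <- split(rec$sample_index, rec$segment_id)
  ok <- vapply(idx, function(v) identical(as.integer(v), seq_along(v) - 1L),
               logical(1))
  if (!all(ok)) {
    bad <- ids[!ok]
    stop("segment(s) ", paste(bad, collapse = ", "),
         ": sample_index must run 0..N_i-1 without gaps or duplicates",
         call. = FALSE)
  }
  rec
}

#' @export
print.segmented_recording <- function(x, ...) {
  cat(sprintf("<segmented_recording: %d segment(s), %d samples, fs = %g Hz>\n",
              n_segments(x), nrow(x), recording_fs(x)))
  NextMethod()
}

#' Recording accessors
#'
#' @param rec a `segmented_recording`.
#' @return `recording_fs()` the sampling rate in Hz; `n_segments()` the
#'   number of segments (`n + 1`); `n_gaps()` the number of unknown gaps
#'   `n`; `segment_lengths()` an integer vector of per-segment sample
#'   counts; `segment_values()` a list of per-segment value vectors.
#' @name recording-accessors
NULL

#' @rdname recording-accessors
#' @export
recording_fs <- function(rec) attr(rec, "fs")

#' @rdname recording-accessors
#' @export
n_segments <- function(rec) length(unique(rec$segment_id))

#' @rdname recording-accessors
#' @export
n_gaps <- function(rec) n_segments(rec) - 1L

#' @rdname recording-accessors
#' @export
segment_lengths <- function(rec) {
  as.integer(unname(table(rec$segment_id)))
}

#' @rdname recording-accessors
#' @export
segment_values <- function(rec) {
  unname(split(rec$value, rec$segment_id))
}

# Flat numeric view used by all numeric kernels: 1-based segment index,
# within-segment sample index j, values y.
rec_flat <- function(rec) {
  list(
    seg = rec$segment_id + 1L,
    j   = as.double(rec$sample_index),
    y   = rec$value,
    fs  = recording_fs(rec),
    n_seg = n_segments(rec),
    lengths = segment_lengths(rec)
  )
}

# Replace the values of a recording, keeping its index structure.
rec_replace_values <- function(rec, values) {
  stopifnot(length(values) == nrow(rec))
  rec$value <- as.double(values)
  rec
}

#' Read a segmented recording from a delimited text file
#'
#' The on-disk format is CSV with a header row and columns
#' `segment_id,sample_index,value`; lines starting with `#` are ignored.
#' `sample_index` must restart at 0 in every segment and be gap-free.
#'
#' @param path path to a CSV file.
#' @param fs sampling rate in Hz (not stored in the CSV).
#' @return a `segmented_recording`.
#' @seealso [write_segments()]
#' @export
read_segments <- function(path, fs) {
  raw <- readr::read_csv(path, comment = "#", col_types = readr::cols(
    segment_id = readr::col_integer(),
    sample_index = readr::col_integer(),
    value = readr::col_double()
  ), progress = FALSE)
  if (nrow(raw) == 0L) stop("empty segment file: ", path, call. = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0L) {
    stop("parse error in ", path, ": row ", probs$row[1], ", ",
         probs$expected[1], " but got '", probs$actual[1], "'", call. = FALSE)
  }
  if (anyNA(raw$value) || anyNA(raw$segment_id) || anyNA(raw$sample_index)) {
    stop("parse error in ", path, ": non-numeric or missing fields",
         call. = FALSE)
  }
  as_recording(raw, fs)
}

#' Write a segmented recording to a delimited text file
#'
#' Emits the same CSV dialect read by [read_segments()], at full double
#' precision (shortest round-trippable decimal representation).
#'
#' @param rec a `segmented_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(rec, path) {
  if (!inherits(rec, "segmented_recording")) rec <- validate_recording(rec)
  if (nrow(rec) == 0L) stop("refusing to write an empty recording", call. = FALSE)
  readr::write_csv(tibble::as_tibble(rec[c("segment_id", "sample_index", "value")]),
                   path, progress = FALSE)
  invisible(path)
}

#' Plot a segmented recording
#'
#' One panel per segment, value against local time `j / fs`.
#'
#' @param object a `segmented_recording`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.segmented_recording <- function(object, ...) {
  fs <- recording_fs(object)
  df <- dplyr::mutate(tibble::as_tibble(object),
                      time_s = .data$sample_index / fs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$segment_id), scales = "free_x") +
    ggplot2::labs(x = "time within segment (s)", y = "value (a.u.)")
}
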