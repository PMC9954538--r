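#' Construct a labeled set of EEG epochs
#'
#' @param data numeric array, trials x channels x timepoints (consistent
#'   units across trials, typically microvolts).
#' @param labels per-trial class labels (factor, character or integer),
#'   length = number of trials; may be `NULL` for unlabeled epochs.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_names ordered channel identifiers matching the channel axis.
#' @param metadata optional named list carried along (provenance, configs).
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels = NULL, sampling_rate,
                      channel_names = NULL, metadata = list()) {
  d <- dim(data)
  if (length(d) != 3L)
    stop_eegtrm("data must be trials x channels x timepoints",
                class = "eegtrm_dimension_error")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(d[2L]))
  if (length(channel_names) != d[2L])
    stop_eegtrm("%d channel names for %d channels",
                length(channel_names), d[2L],
                class = "eegtrm_dimension_error")
  if (!is.null(labels) && length(labels) != d[1L])
    stop_eegtrm("%d labels for %d trials", length(labels), d[1L],
                class = "eegtrm_dimension_error")
  structure(list(data = data, labels = labels,
                 sampling_rate = as.numeric(sampling_rate),
                 channel_names = as.character(channel_names),
                 metadata = metadata),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d time points @ %g Hz\n",
              d[1L], d[2L], d[3L], x$sampling_rate))
  if (!is.null(x$labels))
    print(table(labels = x$labels))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Subset trials of an epoch set
#' @param x an [epoch_set]; @param i trial indices; @param ... unused.
#' @export
`[.epoch_set` <- function(x, i, ...) {
  epoch_set(x$data[i, , , drop = FALSE],
            if (is.null(x$labels)) NULL else x$labels[i],
            x$sampling_rate, x$channel_names, x$metadata)
}

#' Write / read epochs in the package's plain-text array container
#'
#' The container is a pair of files sharing a stem: `<stem>.json` (metadata:
#' dimensions, channel names, labels, sampling rate, free-form metadata) and
#' `<stem>.csv` (payload: one row per trial x channel, trial-major, one column
#' per time point). Both are plain text and diff-friendly.
#'
#' @param x an [epoch_set].
#' @param stem path stem without extension.
#' @return `write_epochs` returns `stem` invisibly; `read_epochs` an
#'   [epoch_set].
#' @export
write_epochs <- function(x, stem) {
  d <- dim(x$data)
  meta <- list(container = "eegtrm-epochs-v1",
               trials = d[1L], channels = d[2L], timepoints = d[3L],
               sampling_rate = x$sampling_rate,
               channel_names = x$channel_names,
               labels = x$labels, metadata = x$metadata)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  flat <- matrix(aperm(x$data, c(3L, 2L, 1L)), d[3L], d[1L] * d[2L])
  utils::write.table(t(flat), paste0(stem, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(stem)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (!identical(meta$container, "eegtrm-epochs-v1"))
    stop_eegtrm("not an eegtrm epochs container: %s", stem,
                class = "eegtrm_config_error")
  flat <- as.matrix(utils::read.table(paste0(stem, ".csv"), sep = ","))
  data <- aperm(array(t(flat), c(meta$timepoints, meta$channels, meta$trials)),
                c(3L, 2L, 1L))
  epoch_set(data, meta$labels, meta$sampling_rate, meta$channel_names,
            as.list(meta$metadata))
}

#' Write / read a continuous record in the plain-text container
#'
#' Same container family as [write_epochs()]: `<stem>.json` holds sampling
#' rate, channel names, markers and metadata; `<stem>.csv` holds the
#' channels x samples payload (one row per channel).
#'
#' @param x an [eeg_record].
#' @param stem path stem without extension.
#' @return `write_record` returns `stem` invisibly; `read_record` an
#'   [eeg_record].
#' @export
write_record <- function(x, stem) {
  meta <- list(container = "eegtrm-record-v1",
               channels = nrow(x$data), samples = ncol(x$data),
               sampling_rate = x$sampling_rate,
               channel_names = x$channel_names,
               markers = x$markers, metadata = x$metadata)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "columns")
  utils::write.table(x$data, paste0(stem, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(stem)
}

#' @rdname write_record
#' @export
read_record <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (!identical(meta$container, "eegtrm-record-v1"))
    stop_eegtrm("not an eegtrm record container: %s", stem,
                class = "eegtrm_config_error")
  data <- as.matrix(utils::read.table(paste0(stem, ".csv"), sep = ","))
  dimnames(data) <- NULL
  markers <- if (length(meta$markers)) as.data.frame(meta$markers) else NULL
  eeg_record(data, meta$sampling_rate, meta$channel_names, markers,
             as.list(meta$metadata))
}
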