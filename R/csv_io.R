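#' Export an event matrix to CSV
#'
#' One row per event, a header row of channel names, comma separation,
#' '.' decimal, UTF-8, full precision (values survive a round trip through
#' [import_csv()] exactly). Channel names containing commas or quotes are
#' quoted per CSV convention. Optional sidecar columns carry the batch id and
#' truth labels when present.
#'
#' @param events an [event_matrix()].
#' @param path output file path.
#' @param include_labels if `TRUE` (default) append `batch_id` /
#'   `truth_label` columns when the matrix carries them.
#' @return `path`, invisibly.
#' @export
export_csv <- function(events, path, include_labels = TRUE) {
  df <- as.data.frame(events$values)
  names(df) <- events$channel_names
  if (include_labels) {
    if (!is.null(events$batch_id)) df[["batch_id"]] <- events$batch_id
    if (!is.null(events$truth_labels)) df[["truth_label"]] <- events$truth_labels
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Import an event matrix from CSV
#'
#' Inverse of [export_csv()]. Columns named `batch_id` / `truth_label` are
#' recognized as metadata; all other columns become channels.
#'
#' @param path CSV file with a header row of channel names.
#' @param channel_kinds per-channel kinds (default: inferred, FSC/SSC ->
#'   scatter, otherwise marker).
#' @param sample_id sample identifier for the returned matrix.
#' @return an [event_matrix()].
#' @export
import_csv <- function(path, channel_kinds = NULL, sample_id = basename(path)) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  batch <- if ("batch_id" %in% names(df)) as.character(df[["batch_id"]][1]) else NULL
  truth <- if ("truth_label" %in% names(df)) as.character(df[["truth_label"]]) else NULL
  df <- df[, setdiff(names(df), c("batch_id", "truth_label")), drop = FALSE]
  if (is.null(channel_kinds)) {
    channel_kinds <- ifelse(grepl("^(FSC|SSC)", names(df)), "scatter", "marker")
  }
  event_matrix(as.matrix(df), names(df), channel_kinds,
               sample_id = sample_id, batch_id = batch, truth_labels = truth)
}
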