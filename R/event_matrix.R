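#' Event matrix: per-cell measurements with channel metadata
#'
#' The central container of the package. Holds an events x channels matrix of
#' fluorescence (or scatter) values together with ordered channel names, a
#' per-channel kind tag, sample/batch identifiers, and optional ground-truth
#' population labels (used by the simulator and the recovery tests).
#'
#' Channel kinds distinguish the spaces a matrix can live in:
#' \describe{
#'   \item{detector}{raw instrument detectors (pre-unmixing)}
#'   \item{marker}{unmixed per-fluorophore abundances, named by marker}
#'   \item{scatter}{forward/side scatter (FSC-A, FSC-H, SSC-A)}
#'   \item{viability}{the viability dye channel}
#'   \item{derived}{appended parameters such as UMAP coordinates}
#' }
#'
#' @param values numeric matrix, events in rows, channels in columns.
#' @param channel_names character vector, one unique name per column.
#' @param channel_kinds character vector of per-channel kinds (recycled if
#'   length 1); each must be one of the kinds listed above.
#' @param sample_id single character sample identifier.
#' @param batch_id optional single character batch identifier.
#' @param truth_labels optional character/factor vector with one population
#'   label per event.
#' @return an object of class `event_matrix`.
#' @examples
#' m <- event_matrix(matrix(rnorm(20), 10, 2), c("CD3", "CD19"), "marker")
#' dim(m)
#' @export
event_matrix <- function(values, channel_names = colnames(values),
                         channel_kinds = "detector",
                         sample_id = "sample", batch_id = NULL,
                         truth_labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) sf_stop("'values' must be numeric", "sf_bad_input")
  if (is.null(channel_names)) {
    sf_stop("channel names are required", "sf_bad_input")
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != ncol(values)) {
    sf_stop("length(channel_names) must equal ncol(values)", "sf_bad_input")
  }
  if (anyDuplicated(channel_names)) {
    sf_stop(sprintf("duplicate channel names: %s",
                    paste(unique(channel_names[duplicated(channel_names)]),
                          collapse = ", ")),
            "sf_duplicate_channel")
  }
  kinds <- c("detector", "marker", "scatter", "viability", "derived")
  channel_kinds <- as.character(channel_kinds)
  if (length(channel_kinds) == 1L) {
    channel_kinds <- rep(channel_kinds, ncol(values))
  }
  if (length(channel_kinds) != ncol(values)) {
    sf_stop("length(channel_kinds) must equal ncol(values)", "sf_bad_input")
  }
  if (!all(channel_kinds %in% kinds)) {
    sf_stop(sprintf("unknown channel kind(s): %s",
                    paste(setdiff(channel_kinds, kinds), collapse = ", ")),
            "sf_bad_input")
  }
  if (!is.null(truth_labels)) {
    truth_labels <- as.character(truth_labels)
    if (length(truth_labels) != nrow(values)) {
      sf_stop("truth_labels must have one entry per event", "sf_bad_input")
    }
  }
  dimnames(values) <- list(NULL, channel_names)
  structure(
    list(values = values,
         channel_names = channel_names,
         channel_kinds = channel_kinds,
         sample_id = as.character(sample_id),
         batch_id = if (is.null(batch_id)) NULL else as.character(batch_id),
         truth_labels = truth_labels),
    class = "event_matrix"
  )
}

#' @export
dim.event_matrix <- function(x) dim(x$values)

#' Number of events in an event matrix
#' @param x an `event_matrix`.
#' @return integer event count.
#' @export
n_events <- function(x) nrow(x$values)

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("<event_matrix> %d events x %d channels (sample '%s'%s)\n",
              nrow(x$values), ncol(x$values), x$sample_id,
              if (is.null(x$batch_id)) "" else paste0(", batch '", x$batch_id, "'")))
  tab <- table(factor(x$channel_kinds,
                      c("detector", "marker", "scatter", "viability", "derived")))
  tab <- tab[tab > 0]
  cat("  channels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$truth_labels)) {
    cat("  truth labels:", length(unique(x$truth_labels)), "populations\n")
  }
  invisible(x)
}

#' @export
as.data.frame.event_matrix <- function(x, ...) {
  as.data.frame(x$values, ...)
}

#' Subset events of an event matrix
#'
#' Row-subsets the values and truth labels, keeping channel metadata intact.
#'
#' @param x an `event_matrix`.
#' @param i logical or integer event index.
#' @return an `event_matrix` with the selected events.
#' @export
subset_events <- function(x, i) {
  event_matrix(x$values[i, , drop = FALSE], x$channel_names, x$channel_kinds,
               x$sample_id, x$batch_id,
               if (is.null(x$truth_labels)) NULL else x$truth_labels[i])
}

#' Extract one channel as a numeric vector
#' @param x an `event_matrix`.
#' @param channel channel name.
#' @return numeric vector of per-event values.
#' @export
channel_values <- function(x, channel) {
  j <- match(channel, x$channel_names)
  if (is.na(j)) {
    sf_stop(sprintf("channel '%s' not present", channel), "sf_missing_channel")
  }
  x$values[, j]
}

#' Append derived parameters to an event matrix
#'
#' Widens the matrix with new columns (for example UMAP coordinates so that
#' embeddings travel with the events when written back to FCS). New channels
#' are tagged `derived`.
#'
#' @param events an `event_matrix`.
#' @param new_channels numeric matrix (or vector) with one row per event.
#' @param names channel names for the new columns; defaults to the column
#'   names of `new_channels`.
#' @return a widened `event_matrix`.
#' @examples
#' m <- event_matrix(matrix(0, 5, 1), "CD3", "marker")
#' m2 <- append_parameters(m, cbind(UMAP_1 = rnorm(5), UMAP_2 = rnorm(5)))
#' m2$channel_kinds
#' @export
append_parameters <- function(events, new_channels, names = colnames(new_channels)) {
  if (is.vector(new_channels)) new_channels <- matrix(new_channels, ncol = 1)
  new_channels <- as.matrix(new_channels)
  if (is.null(names)) sf_stop("new channel names are required", "sf_bad_input")
  if (nrow(new_channels) != nrow(events$values)) {
    sf_stop(sprintf("new channels have %d rows but the matrix has %d events",
                    nrow(new_channels), nrow(events$values)),
            "sf_row_mismatch")
  }
  clash <- intersect(names, events$channel_names)
  if (length(clash)) {
    sf_stop(sprintf("channel name(s) already present: %s",
                    paste(clash, collapse = ", ")),
            "sf_duplicate_channel")
  }
  event_matrix(cbind(events$values, new_channels),
               c(events$channel_names, names),
               c(events$channel_kinds, rep("derived", ncol(new_channels))),
               events$sample_id, events$batch_id, events$truth_labels)
}
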