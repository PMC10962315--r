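#' Post-unmixing compensation matrix
#'
#' Residual cross-channel spillover left after spectral unmixing can be
#' corrected with a small percent-coefficient matrix, the convention used by
#' acquisition software compensation tools (e.g. a -2.79 percent correction
#' from one channel into another). The matrix is square over the unmixed
#' channels with a diagonal of 100; entry `[i, j]` is the percent of channel
#' i's true signal observed in channel j.
#'
#' @param coefficients square numeric matrix in percent units with
#'   dimnames naming the channels; diagonal must be 100.
#' @return an object of class `compensation_matrix`.
#' @export
compensation_matrix <- function(coefficients) {
  coefficients <- as.matrix(coefficients)
  if (nrow(coefficients) != ncol(coefficients)) {
    sf_stop("compensation matrix must be square", "sf_bad_input")
  }
  if (is.null(rownames(coefficients))) {
    sf_stop("compensation matrix needs channel dimnames", "sf_bad_input")
  }
  if (!all(is.finite(coefficients))) {
    sf_stop("compensation coefficients must be finite", "sf_bad_input")
  }
  if (any(abs(diag(coefficients) - 100) > 1e-9)) {
    sf_stop("compensation matrix diagonal must be 100 (percent units)",
            "sf_bad_input")
  }
  colnames(coefficients) <- rownames(coefficients)
  structure(list(coefficients = coefficients), class = "compensation_matrix")
}

#' Identity compensation over a channel set
#' @param channels character vector of channel names.
#' @return a [compensation_matrix()] that leaves data unchanged.
#' @export
identity_compensation <- function(channels) {
  m <- diag(100, length(channels))
  dimnames(m) <- list(channels, channels)
  compensation_matrix(m)
}

#' Single-coefficient spillover correction
#'
#' Convenience constructor for the common case of correcting one residual
#' interaction, e.g. `spillover_correction(chs, "BYG575", "BYG710", -2.79)`.
#'
#' @param channels all unmixed channel names.
#' @param from,to source and destination channels of the spillover.
#' @param percent spillover coefficient in percent of the source channel.
#' @return a [compensation_matrix()].
#' @export
spillover_correction <- function(channels, from, to, percent) {
  comp <- identity_compensation(channels)
  if (!all(c(from, to) %in% channels)) {
    sf_stop("'from'/'to' must name unmixed channels", "sf_missing_channel")
  }
  comp$coefficients[from, to] <- percent
  comp
}

#' Apply post-unmixing compensation
#'
#' Inverts the percent spillover model: with S = coefficients/100 (so
#' `observed = true %*% S`), the compensated values are
#' `observed %*% solve(S)`. An identity matrix leaves the data unchanged.
#'
#' @param unmixed an [event_matrix()] in marker space.
#' @param comp a [compensation_matrix()] whose channels all exist in
#'   `unmixed` (channels outside the compensation matrix pass through).
#' @return a compensated [event_matrix()].
#' @export
apply_compensation <- function(unmixed, comp) {
  stopifnot(inherits(comp, "compensation_matrix"))
  chs <- rownames(comp$coefficients)
  missing <- setdiff(chs, unmixed$channel_names)
  if (length(missing)) {
    sf_stop(sprintf("compensation channels absent from data: %s",
                    paste(missing, collapse = ", ")),
            "sf_missing_channel")
  }
  S <- comp$coefficients / 100
  inv <- tryCatch(solve(S), error = function(e) {
    sf_stop("compensation matrix is singular", "sf_singular_matrix")
  })
  out <- unmixed
  j <- match(chs, unmixed$channel_names)
  out$values[, j] <- unmixed$values[, j, drop = FALSE] %*% inv
  out
}
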