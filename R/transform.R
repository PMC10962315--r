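#' Arcsinh display/gating transform
#'
#' Standard cytometry transform: `asinh(x / cofactor)`. Near zero it is linear
#' (so negatives and unstained events stay resolvable), at high intensity it is
#' logarithmic. All gating cutoffs in this package are expressed in these
#' transformed units.
#'
#' @param x numeric vector or matrix of raw intensities.
#' @param cofactor positive scale divisor; default 6000, appropriate for the
#'   raw-intensity scale of the built-in simulator and typical spectral data.
#' @return transformed values, same shape as `x`.
#' @export
flow_asinh <- function(x, cofactor = 6000) {
  if (cofactor <= 0) sf_stop("cofactor must be positive", "sf_bad_input")
  asinh(x / cofactor)
}

#' Inverse of [flow_asinh()]
#' @param y transformed values.
#' @param cofactor the cofactor used in the forward transform.
#' @return raw-scale values.
#' @export
flow_sinh <- function(y, cofactor = 6000) sinh(y) * cofactor

#' Default raw-scale intensity levels for marker expression classes
#'
#' Log-normal location/scale (on the raw intensity scale) for the four
#' expression classes used by gates and the simulator. The geometric means
#' (50 / 800 / 5000 / 20000) give stain indices around 10 at the default
#' noise model, typical of a well-titrated panel.
#'
#' @return a list with `meanlog` and `sdlog` numeric vectors named
#'   `neg`, `int`, `pos`, `hi`.
#' @export
default_levels <- function() {
  list(
    meanlog = c(neg = log(50), int = log(800), pos = log(5000), hi = log(20000)),
    sdlog   = c(neg = 0.5,     int = 0.5,      pos = 0.4,       hi = 0.4)
  )
}

#' Default gating cutoffs in transformed units
#'
#' One-dimensional cutoffs separating the expression classes, placed at the
#' geometric midpoints between adjacent class means and then transformed:
#' \itemize{
#'   \item `pos`: negative/positive boundary, geometric mean of the neg and
#'     pos class centers;
#'   \item `hi`: positive/high boundary;
#'   \item `int`: the intermediate band (between the neg/int and int/pos
#'     geometric midpoints), used for e.g. CD45-intermediate basophils.
#' }
#'
#' @param cofactor arcsinh cofactor (must match the transform applied to the
#'   events being gated).
#' @param levels level definitions as from [default_levels()].
#' @return list with numeric scalars `pos`, `hi` and length-2 vector `int`.
#' @export
default_cutoffs <- function(cofactor = 6000, levels = default_levels()) {
  gm <- function(a, b) sqrt(exp(levels$meanlog[[a]]) * exp(levels$meanlog[[b]]))
  list(
    pos = flow_asinh(gm("neg", "pos"), cofactor),
    hi  = flow_asinh(gm("pos", "hi"), cofactor),
    int = c(flow_asinh(gm("neg", "int"), cofactor),
            flow_asinh(gm("int", "pos"), cofactor))
  )
}

#' Transform the fluorescence channels of an event matrix
#'
#' Applies [flow_asinh()] to marker, detector and viability channels; scatter
#' and derived channels are left on their native scale.
#'
#' @param events an `event_matrix`.
#' @param cofactor arcsinh cofactor.
#' @return an `event_matrix` in transformed units.
#' @export
transform_events <- function(events, cofactor = 6000) {
  out <- events
  j <- events$channel_kinds %in% c("marker", "detector", "viability")
  out$values[, j] <- flow_asinh(events$values[, j, drop = FALSE], cofactor)
  out
}
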