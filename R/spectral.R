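#' Spectral signature of a fluorophore
#'
#' A fluorophore's relative emission profile across the instrument's detector
#' channels (48 on a four-laser full-spectrum cytometer). Profiles are
#' non-negative and stored normalized to unit Euclidean norm, so the
#' similarity index and the unmixing model see only spectral shape, not
#' brightness.
#'
#' @param fluorophore fluorophore (or marker) name.
#' @param profile numeric vector of non-negative relative intensities, one per
#'   detector.
#' @return an object of class `spectral_signature`.
#' @examples
#' s <- spectral_signature("FITC", dnorm(1:48, mean = 15, sd = 3))
#' sum(s$profile^2)  # 1
#' @export
spectral_signature <- function(fluorophore, profile) {
  profile <- as.numeric(profile)
  if (any(!is.finite(profile)) || any(profile < 0)) {
    sf_stop("signature profile must be finite and non-negative", "sf_bad_signature")
  }
  nrm <- sqrt(sum(profile^2))
  if (nrm == 0) sf_stop("signature profile is all zero", "sf_bad_signature")
  structure(list(fluorophore = as.character(fluorophore),
                 profile = profile / nrm),
            class = "spectral_signature")
}

#' @export
print.spectral_signature <- function(x, ...) {
  cat(sprintf("<spectral_signature> %s over %d detectors (peak at detector %d)\n",
              x$fluorophore, length(x$profile), which.max(x$profile)))
  invisible(x)
}

#' Ordered collection of spectral signatures
#'
#' Houses the mixing matrix M of the linear model `y = M a`: one unit-norm
#' column per fluorophore, optionally plus a cellular autofluorescence
#' endmember that lets the unmixer absorb intrinsic cell fluorescence.
#'
#' @param signatures list of [spectral_signature()] objects (or a numeric
#'   matrix with fluorophores in rows and detectors in columns).
#' @param autofluorescence optional [spectral_signature()] for cellular
#'   autofluorescence.
#' @return an object of class `signature_matrix`.
#' @export
signature_matrix <- function(signatures, autofluorescence = NULL) {
  if (is.matrix(signatures)) {
    nm <- rownames(signatures) %||% paste0("F", seq_len(nrow(signatures)))
    signatures <- lapply(seq_len(nrow(signatures)), function(i) {
      spectral_signature(nm[i], signatures[i, ])
    })
  }
  if (!length(signatures)) sf_stop("at least one signature required", "sf_bad_input")
  lens <- vapply(signatures, function(s) length(s$profile), integer(1))
  if (length(unique(lens)) != 1) {
    sf_stop("all signatures must share one detector count", "sf_length_mismatch")
  }
  nms <- vapply(signatures, function(s) s$fluorophore, character(1))
  if (anyDuplicated(nms)) {
    sf_stop(sprintf("duplicate fluorophore names: %s",
                    paste(unique(nms[duplicated(nms)]), collapse = ", ")),
            "sf_duplicate_channel")
  }
  if (!is.null(autofluorescence)) {
    stopifnot(inherits(autofluorescence, "spectral_signature"))
    if (length(autofluorescence$profile) != lens[1]) {
      sf_stop("autofluorescence detector count differs from signatures",
              "sf_length_mismatch")
    }
  }
  structure(list(signatures = signatures, autofluorescence = autofluorescence),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d fluorophores x %d detectors%s\n",
              length(x$signatures), length(x$signatures[[1]]$profile),
              if (is.null(x$autofluorescence)) "" else " (+ autofluorescence)"))
  invisible(x)
}

#' Fluorophore names of a signature matrix
#' @param sigs a `signature_matrix`.
#' @param af include the autofluorescence endmember name ("AF") if present.
#' @return character vector.
#' @export
fluorophore_names <- function(sigs, af = FALSE) {
  nms <- vapply(sigs$signatures, function(s) s$fluorophore, character(1))
  if (af && !is.null(sigs$autofluorescence)) nms <- c(nms, "AF")
  nms
}

# detectors x endmembers mixing matrix (unit-norm columns)
mixing_matrix <- function(sigs, include_af = TRUE) {
  cols <- lapply(sigs$signatures, function(s) s$profile)
  nms <- fluorophore_names(sigs)
  if (include_af && !is.null(sigs$autofluorescence)) {
    cols <- c(cols, list(sigs$autofluorescence$profile))
    nms <- c(nms, "AF")
  }
  M <- do.call(cbind, cols)
  colnames(M) <- nms
  M
}

#' Similarity index between two spectral signatures
#'
#' Cosine similarity of the two unit-norm profiles: 0 means the fluorophores
#' share no spectral characteristics (disjoint detector support), 1 means
#' identical spectra. Panel design screens pairwise similarity against a
#' compatibility ceiling (0.98 by convention; see [validate_panel()]).
#'
#' @param a,b [spectral_signature()] objects with equal detector counts.
#' @return similarity score in \[0, 1\].
#' @examples
#' s1 <- spectral_signature("A", c(1, 0, 1))
#' s2 <- spectral_signature("B", c(0, 1, 1))
#' similarity_index(s1, s2)  # 0.5
#' @export
similarity_index <- function(a, b) {
  stopifnot(inherits(a, "spectral_signature"), inherits(b, "spectral_signature"))
  if (length(a$profile) != length(b$profile)) {
    sf_stop("signatures have different detector counts", "sf_length_mismatch")
  }
  # profiles are unit-norm by construction
  min(1, max(0, sum(a$profile * b$profile)))
}

#' Pairwise similarity matrix of a signature set
#'
#' @param sigs a [signature_matrix()] with at least two signatures.
#' @return symmetric numeric matrix in \[0, 1\] with unit diagonal, fluorophore
#'   names on both dimensions.
#' @export
similarity_matrix <- function(sigs) {
  if (length(sigs$signatures) < 2) {
    sf_stop("need at least two signatures", "sf_bad_input")
  }
  M <- mixing_matrix(sigs, include_af = FALSE)
  S <- crossprod(M)
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  S
}

#' Extract a cellular autofluorescence signature from an unlabeled control
#'
#' The per-detector median of unlabeled (unstained) events, normalized to a
#' unit-norm signature. Used as an extra endmember in the unmixing model so
#' that intrinsic baseline cell fluorescence is removed from marker
#' abundances. Medians rather than means are used for outlier robustness.
#'
#' @param unlabeled an [event_matrix()] of detector-space events from an
#'   unstained control; fewer than 50 events triggers a warning, zero events
#'   an error.
#' @return a [spectral_signature()] named "AF".
#' @export
extract_autofluorescence <- function(unlabeled) {
  j <- unlabeled$channel_kinds == "detector"
  if (!any(j)) sf_stop("no detector channels in control", "sf_missing_channel")
  v <- unlabeled$values[, j, drop = FALSE]
  if (nrow(v) == 0) sf_stop("empty unlabeled control", "sf_empty_input")
  if (nrow(v) < 50) {
    sf_warn(sprintf("only %d unlabeled events; autofluorescence estimate may be unstable",
                    nrow(v)))
  }
  med <- matrixStats::colMedians(v)
  med <- pmax(med, 0)
  if (sum(med) == 0) sf_stop("median autofluorescence profile is all zero",
                             "sf_bad_signature")
  spectral_signature("AF", med)
}

#' Ordinary-least-squares spectral unmixing
#'
#' Solves, for every event with detector readout `y`, the linear model
#' `y = M a + e` for the fluorophore abundance vector `a` minimizing
#' `||M a - y||^2` (unconstrained OLS via QR; negative abundances are
#' retained, not clipped). Columns of `M` are the unit-norm reference
#' signatures, plus the autofluorescence endmember when the signature set
#' carries one. Scatter channels pass through untouched; the viability
#' fluorophore (channel named in `viability`) is tagged accordingly.
#'
#' @param raw an [event_matrix()] whose detector channels match the signature
#'   detector count.
#' @param sigs a [signature_matrix()] of full column rank (two effectively
#'   identical signatures make the problem singular and raise an error naming
#'   the colliding pair).
#' @param keep_af keep the autofluorescence abundance as its own column
#'   (default `TRUE`; it can be dropped afterwards with [drop_af()]).
#' @param viability name of the viability fluorophore, if any, used to tag
#'   the unmixed channel kind.
#' @return an [event_matrix()] in marker space.
#' @export
unmix <- function(raw, sigs, keep_af = TRUE, viability = NULL) {
  det <- raw$channel_kinds == "detector"
  Y <- raw$values[, det, drop = FALSE]
  M <- mixing_matrix(sigs, include_af = TRUE)
  if (ncol(Y) != nrow(M)) {
    sf_stop(sprintf("raw data has %d detector channels but signatures have %d detectors",
                    ncol(Y), nrow(M)),
            "sf_length_mismatch")
  }
  qr_M <- qr(M)
  if (qr_M$rank < ncol(M)) {
    S <- crossprod(M)
    diag(S) <- 0
    idx <- which(S == max(S), arr.ind = TRUE)[1, ]
    sf_stop(sprintf(
      "signature matrix is rank deficient; most similar pair: %s / %s (similarity %.4f)",
      colnames(M)[idx[1]], colnames(M)[idx[2]], max(S)),
      "sf_rank_deficient")
  }
  A <- t(qr.coef(qr_M, t(Y)))  # events x endmembers
  colnames(A) <- colnames(M)

  kinds <- rep("marker", ncol(A))
  if (!is.null(sigs$autofluorescence)) kinds[colnames(A) == "AF"] <- "derived"
  if (!is.null(viability)) kinds[colnames(A) == viability] <- "viability"

  pass <- which(!det)
  out_vals <- cbind(A, raw$values[, pass, drop = FALSE])
  out <- event_matrix(out_vals,
                      c(colnames(A), raw$channel_names[pass]),
                      c(kinds, raw$channel_kinds[pass]),
                      raw$sample_id, raw$batch_id, raw$truth_labels)
  out
}

#' Drop the autofluorescence abundance channel
#' @param events an unmixed [event_matrix()].
#' @return the matrix without the "AF" column (unchanged if absent).
#' @export
drop_af <- function(events) {
  j <- events$channel_names != "AF"
  if (all(j)) return(events)
  event_matrix(events$values[, j, drop = FALSE], events$channel_names[j],
               events$channel_kinds[j], events$sample_id, events$batch_id,
               events$truth_labels)
}

#' Descriptive spectral-interference proxy for a panel
#'
#' The condition number of the mixing matrix (ratio of extreme singular
#' values). Larger values mean the signature set is closer to collinear, so
#' unmixing spreads noise more. This is a descriptive diagnostic of this
#' package only; it is not comparable to any vendor panel-complexity metric.
#'
#' @param sigs a [signature_matrix()].
#' @return positive scalar condition number.
#' @export
panel_condition_number <- function(sigs) {
  M <- mixing_matrix(sigs, include_af = TRUE)
  d <- svd(M, nu = 0, nv = 0)$d
  d[1] / d[length(d)]
}

#' Read a signature library from CSV
#'
#' Expected layout: first column fluorophore names, remaining columns the
#' per-detector relative intensities. A row named "AF" (case-insensitive) is
#' treated as the autofluorescence endmember.
#'
#' @param path CSV file.
#' @return a [signature_matrix()].
#' @export
read_signatures_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  nms <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  af_row <- which(toupper(nms) == "AF")
  af <- if (length(af_row)) spectral_signature("AF", vals[af_row[1], ]) else NULL
  keep <- setdiff(seq_along(nms), af_row)
  sig_list <- lapply(keep, function(i) spectral_signature(nms[i], vals[i, ]))
  signature_matrix(sig_list, autofluorescence = af)
}

#' Write a signature library to CSV
#' @param sigs a [signature_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signatures_csv <- function(sigs, path) {
  M <- signif(t(mixing_matrix(sigs, include_af = TRUE)), 6)
  df <- data.frame(fluorophore = rownames(M), M, check.names = FALSE,
                   row.names = NULL)
  names(df)[-1] <- sprintf("det%02d", seq_len(ncol(M)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
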