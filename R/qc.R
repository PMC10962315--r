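#' Stain index of a positive/negative peak pair
#'
#' Separation-quality metric of a stained versus unstained population:
#' `(median(positive) - median(negative)) / (2 * sd(negative))`. The plain
#' standard deviation is used here, as the metric is conventionally printed;
#' the rest of the QC module uses the robust SD.
#'
#' @param positive_values fluorescence intensities of the positive peak.
#' @param negative_values intensities of the negative peak (at least 2
#'   values, so the SD is defined).
#' @return the stain index (a unitless scalar).
#' @examples
#' stain_index(c(990, 1000, 1010), c(55, 100, 145))  # 10
#' @export
stain_index <- function(positive_values, negative_values) {
  if (length(negative_values) < 2) {
    sf_stop("need at least 2 negative values to define an SD", "sf_bad_input")
  }
  if (!all(is.finite(positive_values)) || !all(is.finite(negative_values))) {
    sf_stop("stain index inputs must be finite", "sf_bad_input")
  }
  s <- stats::sd(negative_values)
  if (s == 0) sf_stop("negative peak has zero SD", "sf_zero_sd")
  (stats::median(positive_values) - stats::median(negative_values)) / (2 * s)
}

#' Split a 1-D intensity vector into negative/positive peaks
#'
#' Places a data-driven threshold at the deepest kernel-density valley between
#' the two largest modes. Falls back to the midpoint between the two k-means
#' centers when the density estimate is unimodal.
#'
#' @param x numeric vector of (transformed) intensities.
#' @return the threshold value; events `>= threshold` count as positive
#'   (half-open convention used throughout the package).
#' @export
split_threshold <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4 || stats::sd(x) == 0) {
    sf_stop("cannot split a (near-)constant vector", "sf_bad_input")
  }
  d <- stats::density(x, n = 512)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1
  if (length(is_max) >= 2) {
    # two largest modes, deepest valley between them
    ord <- is_max[order(y[is_max], decreasing = TRUE)[1:2]]
    lo <- min(ord); hi <- max(ord)
    valley <- lo + which.min(y[lo:hi]) - 1
    return(d$x[valley])
  }
  km <- stats::kmeans(x, centers = range(x), iter.max = 25)
  mean(km$centers)
}

#' Screen a signature set against a pairwise similarity ceiling
#'
#' Fluorophore pairs whose spectral similarity exceeds the compatibility
#' threshold (0.98 by default: more similar pairs cannot be reliably unmixed
#' together) are reported as violations. An empty report means the panel
#' passes.
#'
#' @param sigs a [signature_matrix()] with at least 2 signatures.
#' @param max_pairwise_similarity threshold in \[0, 1\], default 0.98.
#' @return a data.frame with columns `fluor_a`, `fluor_b`, `similarity`
#'   (zero rows if the panel passes), with the threshold attached as the
#'   `threshold` attribute.
#' @export
validate_panel <- function(sigs, max_pairwise_similarity = 0.98) {
  if (max_pairwise_similarity < 0 || max_pairwise_similarity > 1) {
    sf_stop("similarity threshold must lie in [0, 1]", "sf_bad_input")
  }
  S <- similarity_matrix(sigs)
  idx <- which(upper.tri(S) & S > max_pairwise_similarity, arr.ind = TRUE)
  report <- data.frame(
    fluor_a = rownames(S)[idx[, 1]],
    fluor_b = colnames(S)[idx[, 2]],
    similarity = S[idx],
    stringsAsFactors = FALSE
  )
  report <- report[order(-report$similarity), , drop = FALSE]
  rownames(report) <- NULL
  attr(report, "threshold") <- max_pairwise_similarity
  report
}

#' Single-color versus multicolor concordance statistics
#'
#' Compares a marker's staining in a single-color control against the full
#' multicolor cocktail, mirroring histogram-overlay review: `shift` is the
#' difference of positive-peak medians (multicolor minus single color) and
#' `spread_ratio` the ratio of robust SDs of the positive peaks. Values near
#' (0, 1) indicate concordant resolution.
#'
#' @param single_color,multicolor [event_matrix()] objects containing
#'   `marker`.
#' @param marker channel to compare.
#' @param threshold optional positive/negative split; defaults to a
#'   data-driven [split_threshold()] on the pooled values.
#' @return list with `shift`, `spread_ratio` and the `threshold` used.
#' @export
concordance_stat <- function(single_color, multicolor, marker, threshold = NULL) {
  xs <- channel_values(single_color, marker)
  xm <- channel_values(multicolor, marker)
  thr <- threshold %||% split_threshold(c(xs, xm))
  pos_s <- xs[xs >= thr]
  pos_m <- xm[xm >= thr]
  if (!length(pos_s) || !length(pos_m)) {
    sf_stop("no positive events on one side of the comparison", "sf_empty_input")
  }
  list(shift = stats::median(pos_m) - stats::median(pos_s),
       spread_ratio = robust_sd(pos_m) / robust_sd(pos_s),
       threshold = thr)
}

#' NxN spillover screen over unmixed markers
#'
#' Numeric surrogate for visual NxN plot review. Residual spillover from
#' marker i into marker j displaces j's negative cluster upward among
#' i-positive events — the population misalignment a reviewer spots in the
#' density plot. For each ordered pair (i, j), events are split at
#' data-driven thresholds on both markers and the score is the shift of j's
#' negative cluster between the i-positive and i-negative groups, in
#' robust-SD units:
#' `(median(j | i+, j-) - median(j | i-, j-)) / robust_sd(j | i-, j-)`.
#' Conditioning on j's negative side keeps the statistic stable when j is
#' strongly bimodal (the overall median of a balanced mixture is not).
#' Independent, well-unmixed channels score near 0; spillover inflates
#' (i, j) but not (j, i). Pairs with |score| above `flag_threshold` are
#' flagged for compensation review.
#'
#' @param unmixed an [event_matrix()] of (transformed) unmixed intensities.
#' @param markers channels to screen (at least 2).
#' @param flag_threshold flag cutoff in robust-SD units (default 1.0).
#' @return list with matrices `score`, `flag` and `evaluable` (pairs lacking
#'   positive or negative events on the conditioning marker are marked not
#'   evaluable and get an NA score).
#' @export
nxn_screen <- function(unmixed, markers, flag_threshold = 1.0) {
  if (length(markers) < 2) sf_stop("need at least two markers", "sf_bad_input")
  vals <- sapply(markers, function(m) channel_values(unmixed, m))
  p <- length(markers)
  score <- matrix(NA_real_, p, p, dimnames = list(markers, markers))
  evaluable <- matrix(TRUE, p, p, dimnames = list(markers, markers))
  diag(evaluable) <- FALSE
  thr <- vapply(seq_len(p), function(i) {
    tryCatch(split_threshold(vals[, i]), error = function(e) NA_real_)
  }, numeric(1))
  for (i in seq_len(p)) {
    pos <- if (is.na(thr[i])) rep(FALSE, nrow(vals)) else vals[, i] >= thr[i]
    if (!any(pos) || all(pos) || is.na(thr[i])) {
      evaluable[i, ] <- FALSE
      next
    }
    for (j in seq_len(p)[-i]) {
      if (is.na(thr[j])) {
        evaluable[i, j] <- FALSE
        next
      }
      jneg <- vals[, j] < thr[j]
      ref <- vals[!pos & jneg, j]
      shifted <- vals[pos & jneg, j]
      s <- robust_sd(ref)
      if (length(ref) < 5 || length(shifted) < 5 || s == 0) {
        evaluable[i, j] <- FALSE
        next
      }
      score[i, j] <- (stats::median(shifted) - stats::median(ref)) / s
    }
  }
  flag <- !is.na(score) & abs(score) > flag_threshold
  list(score = score, flag = flag, evaluable = evaluable,
       flag_threshold = flag_threshold)
}

#' Write a QC report to JSON (+ per-pair CSV)
#'
#' @param screen result of [nxn_screen()].
#' @param panel_report result of [validate_panel()] (optional).
#' @param json_path output JSON path.
#' @param csv_path optional per-pair CSV of NxN scores.
#' @return `json_path`, invisibly.
#' @export
write_qc_report <- function(screen, panel_report = NULL, json_path,
                            csv_path = NULL) {
  flagged <- which(screen$flag, arr.ind = TRUE)
  report <- list(
    flag_threshold = screen$flag_threshold,
    n_flagged = nrow(flagged),
    flagged_pairs = if (nrow(flagged)) data.frame(
      from = rownames(screen$score)[flagged[, 1]],
      into = colnames(screen$score)[flagged[, 2]],
      score = screen$score[flagged]
    ) else list(),
    similarity_violations = if (!is.null(panel_report)) panel_report else list()
  )
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(csv_path)) {
    long <- expand.grid(from = rownames(screen$score),
                        into = colnames(screen$score),
                        stringsAsFactors = FALSE)
    long$score <- as.vector(screen$score)
    long$flag <- as.vector(screen$flag)
    long$evaluable <- as.vector(screen$evaluable)
    utils::write.csv(long[long$from != long$into, ], csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
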