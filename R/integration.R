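#' Integration configuration
#'
#' Parameters for the batch-effect assessment/correction stage.
#'
#' @param n_components number of principal components (default 20).
#' @param perplexity perplexity of the LISI kernel (default 30).
#' @param k neighborhood size for LISI (default `3 * perplexity`).
#' @param high_lisi_threshold explicit high-LISI cutoff; by default the
#'   shipped map is used (1.667 for two batches, 2 for three) and any other
#'   batch count requires an explicit value.
#' @param recommend_below_fraction correction is recommended when the
#'   fraction of high-LISI cells falls below this proportion (default 0.20).
#' @param backend `"reference"` (built-in soft-k-means corrector) or
#'   `"external"` (a registered external integrator; errors if none is
#'   registered).
#' @param n_clusters soft clusters of the reference corrector (default 20).
#' @param max_iter,tol reference-corrector iteration cap (10) and mean-LISI
#'   convergence gain (0.01).
#' @param umap_neighbors,umap_min_dist UMAP backend parameters.
#' @param seed integer seed used for PCA tie-breaking-free stages (k-means
#'   initialization, UMAP).
#' @return an object of class `integration_config`.
#' @export
integration_config <- function(n_components = 20, perplexity = 30,
                               k = 3 * perplexity,
                               high_lisi_threshold = NULL,
                               recommend_below_fraction = 0.20,
                               backend = c("reference", "external"),
                               n_clusters = 20, max_iter = 10, tol = 0.01,
                               umap_neighbors = 15, umap_min_dist = 0.1,
                               seed = 1) {
  if (n_components < 2) sf_stop("n_components must be >= 2", "sf_bad_input")
  if (recommend_below_fraction <= 0 || recommend_below_fraction >= 1) {
    sf_stop("recommend_below_fraction must lie in (0, 1)", "sf_bad_input")
  }
  structure(list(n_components = n_components, perplexity = perplexity, k = k,
                 high_lisi_threshold = high_lisi_threshold,
                 recommend_below_fraction = recommend_below_fraction,
                 backend = match.arg(backend), n_clusters = n_clusters,
                 max_iter = max_iter, tol = tol,
                 umap_neighbors = umap_neighbors, umap_min_dist = umap_min_dist,
                 seed = seed),
            class = "integration_config")
}

new_embedding <- function(coordinates, space) {
  structure(list(coordinates = coordinates, space = space),
            class = "sf_embedding")
}

#' @export
print.sf_embedding <- function(x, ...) {
  cat(sprintf("<embedding> %d events x %d dims (%s space)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$space))
  invisible(x)
}

#' Scale channels to a [-1, 1] range centered on 0
#'
#' Affine min-max map per channel so the extremes sit at -1 and +1 (the
#' scaling applied before PCA, countering the large numeric disparities
#' between fluorescence channels). Constant channels are mapped to all-zero
#' with a warning.
#'
#' @param events an [event_matrix()] (>= 2 events).
#' @return an [event_matrix()] with every channel in \[-1, 1\].
#' @export
scale_channels <- function(events) {
  v <- events$values
  if (nrow(v) < 2) sf_stop("need at least two events to scale", "sf_bad_input")
  rng <- matrixStats::colRanges(v)
  span <- rng[, 2] - rng[, 1]
  const <- span == 0
  if (any(const)) {
    sf_warn(sprintf("constant channel(s) mapped to zero: %s",
                    paste(events$channel_names[const], collapse = ", ")))
    span[const] <- 1
  }
  out <- events
  out$values <- sweep(sweep(v, 2, rng[, 1], `-`), 2, span, `/`) * 2 - 1
  out$values[, const] <- 0
  out
}

#' Keep only the channels of given kinds
#' @param events an [event_matrix()].
#' @param kinds channel kinds to keep (default: marker channels, i.e. the
#'   integration features — viability, autofluorescence and scatter are
#'   excluded).
#' @return an [event_matrix()] restricted to those channels.
#' @export
select_channels <- function(events, kinds = "marker") {
  j <- events$channel_kinds %in% kinds
  if (!any(j)) sf_stop("no channels of the requested kind(s)", "sf_missing_channel")
  event_matrix(events$values[, j, drop = FALSE], events$channel_names[j],
               events$channel_kinds[j], events$sample_id, events$batch_id,
               events$truth_labels)
}

#' Principal-component embedding
#'
#' Centered, unscaled PCA of the scaled channel matrix; the top
#' `n_components` scores. Deterministic sign convention: each component is
#' flipped so that its largest-magnitude loading is positive.
#'
#' @param scaled an [event_matrix()] (typically from [scale_channels()]).
#' @param cfg an [integration_config()].
#' @return an embedding (`space = "pca"`) with `sdev` and `rotation`
#'   attached.
#' @export
pca_embed <- function(scaled, cfg = integration_config()) {
  v <- scaled$values
  if (cfg$n_components > ncol(v)) {
    sf_stop(sprintf("n_components (%d) exceeds channel count (%d)",
                    cfg$n_components, ncol(v)), "sf_bad_input")
  }
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE, rank. = cfg$n_components)
  flip <- apply(pc$rotation, 2, function(r) sign(r[which.max(abs(r))]))
  flip[flip == 0] <- 1
  emb <- new_embedding(sweep(pc$x, 2, flip, `*`), "pca")
  emb$sdev <- pc$sdev
  emb$rotation <- sweep(pc$rotation, 2, flip, `*`)
  emb
}

# ---- LISI -------------------------------------------------------------------

# perplexity-calibrated Gaussian kernel weights over one cell's kNN distances
tuned_kernel <- function(d2, perplexity, iters = 50, tol = 1e-5) {
  target <- log(perplexity)
  d2 <- d2 - min(d2)
  beta <- 1
  lo <- -Inf; hi <- Inf
  for (i in seq_len(iters)) {
    w <- exp(-beta * d2)
    sw <- sum(w)
    h <- log(sw) + beta * sum(d2 * w) / sw
    diff <- h - target
    if (abs(diff) < tol) break
    if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
    else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
  }
  w / sum(w)
}

#' Local inverse Simpson index of batch mixing
#'
#' For every cell, a Gaussian kernel over its neighborhood (the cell itself
#' plus its k nearest neighbors) is tuned so the kernel entropy matches
#' `log(perplexity)`; kernel mass is summed per
#' batch into probabilities p_b and the cell's score is the inverse Simpson
#' index `1 / sum(p_b^2)` — the effective number of batches in its
#' neighborhood, ranging from 1 (only its own batch nearby, no mixing) to B
#' (all batches equally represented).
#'
#' @param embedding an embedding (2-D UMAP by convention; PC space works
#'   too) or a bare coordinate matrix.
#' @param batches per-cell batch labels.
#' @param cfg an [integration_config()] (perplexity, k).
#' @return list with per-cell `lisi`, the label vector and `n_batches`.
#' @export
compute_lisi <- function(embedding, batches, cfg = integration_config()) {
  coords <- if (inherits(embedding, "sf_embedding")) embedding$coordinates
            else as.matrix(embedding)
  batches <- as.character(batches)
  n <- nrow(coords)
  if (length(batches) != n) sf_stop("one batch label per cell required", "sf_bad_input")
  if (n < 2) sf_stop("need at least two cells", "sf_bad_input")
  k <- cfg$k
  if (k >= n) {
    sf_warn(sprintf("k reduced from %d to %d (too few cells)", k, n - 1))
    k <- n - 1
  }
  ub <- sort(unique(batches))
  B <- length(ub)
  bid <- match(batches, ub)
  if (B == 1) {
    return(list(lisi = rep(1, n), batches = batches, n_batches = 1L))
  }
  # k + 1 neighbors including the cell itself (a cell belongs to its own
  # neighborhood); nn2 handles exact-duplicate coordinates correctly
  nn <- RANN::nn2(coords, k = k + 1)
  lisi <- vapply(seq_len(n), function(i) {
    w <- tuned_kernel(nn$nn.dists[i, ]^2, cfg$perplexity)
    nb <- bid[nn$nn.idx[i, ]]
    p <- vapply(seq_len(B), function(b) sum(w[nb == b]), numeric(1))
    1 / sum(p^2)
  }, numeric(1))
  list(lisi = pmin(pmax(lisi, 1), B), batches = batches, n_batches = B)
}

#' High-LISI fraction and batch-correction recommendation
#'
#' A cell is "high-LISI" (well integrated) when its score exceeds the
#' batch-count-specific threshold: 2 for three batches, 1.667 for two;
#' other batch counts require an explicit threshold in the config. If the
#' proportion of high-LISI cells on the pre-correction embedding is small
#' (below `recommend_below_fraction`, default 20 percent), the data cluster
#' by batch and correction is recommended.
#'
#' @param lisi_result result of [compute_lisi()] on a pre-correction
#'   embedding.
#' @param cfg an [integration_config()].
#' @return list with `threshold`, overall `high_fraction`, `per_batch`
#'   high fractions, and `recommendation` (`"correct"` /
#'   `"no-correction"`).
#' @export
recommend_correction <- function(lisi_result, cfg = integration_config()) {
  B <- lisi_result$n_batches
  thr <- cfg$high_lisi_threshold %||%
    switch(as.character(B), "2" = 1.667, "3" = 2,
           sf_stop(sprintf(
             "no default high-LISI threshold for %d batches; set high_lisi_threshold",
             B), "sf_missing_threshold"))
  high <- lisi_result$lisi > thr
  per_batch <- tapply(high, lisi_result$batches, mean)
  high_fraction <- mean(high)
  list(threshold = thr,
       high_fraction = high_fraction,
       per_batch = per_batch,
       recommendation = if (high_fraction < cfg$recommend_below_fraction)
         "correct" else "no-correction")
}

# ---- batch correction -------------------------------------------------------

external_integrators <- new.env(parent = emptyenv())

#' Register an external batch-correction backend
#'
#' The external backend contract: a function `(coordinates, batches, cfg)`
#' returning a corrected coordinate matrix of identical shape. Registering
#' one makes `backend = "external"` available in [batch_correct()].
#'
#' @param fun the integrator function, or `NULL` to unregister.
#' @return invisibly, the previous registration.
#' @export
register_integrator <- function(fun) {
  old <- external_integrators$fun
  external_integrators$fun <- fun
  invisible(old)
}

#' Batch correction in PC space
#'
#' Removes batch-specific displacement of the embedding while preserving the
#' population structure. The built-in reference corrector iterates soft
#' k-means: cells get soft cluster assignments, each cluster's per-batch
#' centroid offset from the cluster centroid is computed, and every cell is
#' moved by its assignment-weighted batch offsets. The first pass is the
#' k = 1 special case (global per-batch centering), which removes a constant
#' batch displacement even when batches are completely separated; later
#' passes refine locally with k soft clusters. Iteration stops when the
#' mean LISI (computed in the corrected PC space) gains less than `tol` or
#' after `max_iter` rounds; a round that would lower mean LISI is rolled
#' back, so the corrected embedding never mixes worse than the input. A
#' single batch is returned unchanged.
#'
#' @param pcs PC-space embedding from [pca_embed()].
#' @param batches per-cell batch labels.
#' @param cfg an [integration_config()]; `backend = "external"` delegates to
#'   the registered integrator (see [register_integrator()]).
#' @return corrected embedding (`space = "pca_corrected"`).
#' @export
batch_correct <- function(pcs, batches, cfg = integration_config()) {
  coords <- pcs$coordinates
  batches <- as.character(batches)
  if (length(batches) != nrow(coords)) {
    sf_stop("one batch label per cell required", "sf_bad_input")
  }
  ub <- unique(batches)
  if (length(ub) == 1) return(new_embedding(coords, "pca_corrected"))
  counts <- table(batches)
  if (any(counts < ncol(coords))) {
    sf_stop(sprintf("batch '%s' has fewer events than embedding dimensions",
                    names(counts)[which.min(counts)]), "sf_batch_too_small")
  }
  if (cfg$backend == "external") {
    fun <- external_integrators$fun
    if (is.null(fun)) {
      sf_stop("no external integrator registered; use register_integrator() or backend='reference'",
              "sf_backend_unavailable")
    }
    return(new_embedding(fun(coords, batches, cfg), "pca_corrected"))
  }

  k <- min(cfg$n_clusters, nrow(coords) - 1)
  x <- coords
  mean_lisi <- function(m) {
    # deterministic subsample for speed on large inputs
    idx <- if (nrow(m) > 5000) round(seq(1, nrow(m), length.out = 5000))
           else seq_len(nrow(m))
    mean(compute_lisi(m[idx, , drop = FALSE], batches[idx], cfg)$lisi)
  }
  correct_step <- function(x, R) {
    cluster_centroid <- crossprod(R, x) / pmax(colSums(R), 1e-12)
    for (b in ub) {
      i <- batches == b
      Rb <- R[i, , drop = FALSE]
      batch_centroid <- crossprod(Rb, x[i, , drop = FALSE]) /
        pmax(colSums(Rb), 1e-12)
      x[i, ] <- x[i, , drop = FALSE] - Rb %*% (batch_centroid - cluster_centroid)
    }
    x
  }
  best <- mean_lisi(x)
  centers <- NULL
  for (iter in seq_len(cfg$max_iter)) {
    if (iter == 1) {
      # k = 1 pass: global per-batch centering; exactly removes a constant
      # batch displacement even when batches are fully separated
      R <- matrix(1, nrow(x), 1)
    } else {
      if (is.null(centers)) {
        with_seed(cfg$seed, {
          centers <- stats::kmeans(x, centers = k, iter.max = 50)$centers
        })
      }
      d2 <- outer(rowSums(x^2), rowSums(centers^2), `+`) - 2 * x %*% t(centers)
      # soft assignments: bandwidth at the scale of the typical
      # point-to-center distance, so offsets are shared across batches
      sigma2 <- max(mean(d2), 1e-12)
      R <- exp(-(d2 - matrixStats::rowMins(d2)) / (2 * sigma2))
      R <- R / rowSums(R)
    }
    x_new <- correct_step(x, R)
    new_score <- mean_lisi(x_new)
    if (new_score < best) {           # roll back: never mix worse
      if (iter == 1) next else break
    }
    improved <- new_score - best
    x <- x_new
    best <- new_score
    if (!is.null(centers)) {
      centers <- crossprod(R, x) / pmax(colSums(R), 1e-12)
    }
    if (iter > 1 && improved < cfg$tol) break
  }
  new_embedding(x, "pca_corrected")
}

#' UMAP embedding of a PC-space matrix
#'
#' Two-dimensional UMAP via the uwot backend, run single-threaded with a
#' fixed seed so coordinates are reproducible.
#'
#' @param pcs embedding (or matrix) to project.
#' @param cfg an [integration_config()] (`umap_neighbors`, `umap_min_dist`,
#'   `seed`).
#' @return 2-D embedding (`space = "umap"`) with columns UMAP_1 / UMAP_2.
#' @export
embed_umap <- function(pcs, cfg = integration_config()) {
  coords <- if (inherits(pcs, "sf_embedding")) pcs$coordinates else as.matrix(pcs)
  if (nrow(coords) < 10) sf_stop("need at least 10 events for UMAP", "sf_bad_input")
  with_seed(cfg$seed, {
    um <- uwot::umap(coords, n_neighbors = min(cfg$umap_neighbors, nrow(coords) - 1),
                     min_dist = cfg$umap_min_dist, n_threads = 1,
                     n_sgd_threads = 0)
  })
  colnames(um) <- c("UMAP_1", "UMAP_2")
  new_embedding(um, "umap")
}

# ---- pipeline ---------------------------------------------------------------

#' Batch-effect assessment and correction pipeline
#'
#' Runs the full integration stage on a list of single-batch event matrices:
#' merge, select marker channels, arcsinh-transform, scale each channel to
#' \[-1, 1\], PCA, UMAP of the uncorrected PCs, LISI on that UMAP and the
#' correction recommendation; then (by default only when recommended)
#' batch-correct the PCs and re-embed. UMAP coordinates can be written back
#' onto the merged events via [append_parameters()].
#'
#' @param samples list of [event_matrix()] objects with distinct batch ids.
#' @param cfg an [integration_config()].
#' @param cofactor arcsinh cofactor applied before scaling.
#' @param correct `"auto"` (follow the recommendation), `TRUE` or `FALSE`.
#' @return list of class `integration_result`: `events` (merged, with UMAP
#'   parameters appended), `pca`, `umap_pre`, `lisi_pre`, `assessment`,
#'   `corrected`, `umap_post`, `lisi_post`, `batches`.
#' @export
integrate_batches <- function(samples, cfg = integration_config(),
                              cofactor = 6000, correct = "auto") {
  stopifnot(length(samples) >= 1)
  batches <- unlist(lapply(samples, function(s) {
    rep(s$batch_id %||% s$sample_id, n_events(s))
  }))
  merged_vals <- do.call(rbind, lapply(samples, function(s) s$values))
  proto <- samples[[1]]
  merged <- event_matrix(merged_vals, proto$channel_names, proto$channel_kinds,
                         sample_id = "merged",
                         truth_labels = if (all(!vapply(samples, function(s)
                           is.null(s$truth_labels), logical(1))))
                           unlist(lapply(samples, `[[`, "truth_labels")) else NULL)

  feats <- select_channels(merged, "marker")
  feats <- transform_events(feats, cofactor)
  scaled <- scale_channels(feats)
  cfg$n_components <- min(cfg$n_components, ncol(scaled$values))
  pcs <- pca_embed(scaled, cfg)
  umap_pre <- embed_umap(pcs, cfg)
  lisi_pre <- compute_lisi(umap_pre, batches, cfg)
  assessment <- recommend_correction(lisi_pre, cfg)

  do_correct <- if (identical(correct, "auto"))
    assessment$recommendation == "correct" else isTRUE(correct)
  corrected <- umap_post <- lisi_post <- NULL
  final_umap <- umap_pre
  if (do_correct) {
    corrected <- batch_correct(pcs, batches, cfg)
    umap_post <- embed_umap(corrected, cfg)
    lisi_post <- compute_lisi(umap_post, batches, cfg)
    final_umap <- umap_post
  }
  events <- append_parameters(merged, final_umap$coordinates)
  structure(list(events = events, pca = pcs, umap_pre = umap_pre,
                 lisi_pre = lisi_pre, assessment = assessment,
                 corrected = corrected, umap_post = umap_post,
                 lisi_post = lisi_post, batches = batches),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("<integration_result> %d cells, %d batches\n",
              length(x$batches), x$lisi_pre$n_batches))
  cat(sprintf("  pre-correction high-LISI fraction: %.3f (threshold %.3f) -> %s\n",
              x$assessment$high_fraction, x$assessment$threshold,
              x$assessment$recommendation))
  if (!is.null(x$lisi_post)) {
    cat(sprintf("  mean LISI %.3f -> %.3f after correction\n",
                mean(x$lisi_pre$lisi), mean(x$lisi_post$lisi)))
  }
  invisible(x)
}

#' Write an integration report to JSON
#' @param result an `integration_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_integration_report <- function(result, path) {
  rep <- list(
    n_cells = length(result$batches),
    n_batches = result$lisi_pre$n_batches,
    threshold = result$assessment$threshold,
    high_fraction = result$assessment$high_fraction,
    per_batch_high_fraction = as.list(result$assessment$per_batch),
    recommendation = result$assessment$recommendation,
    mean_lisi_pre = mean(result$lisi_pre$lisi),
    mean_lisi_post = if (!is.null(result$lisi_post)) mean(result$lisi_post$lisi)
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
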