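#' Cross-panel consistency ratios
#'
#' The two PBMC panels share the pan-leukocyte and lymphocyte structure, so
#' gating the same sample with both should give matching lymphocyte:CD45 and
#' NK:CD45 ratios — an internal control of panel agreement. Ratios are
#' fractions of the root (CD45+) event count.
#'
#' @param tb,mnd population tables from [run_gating_tree()] of the two
#'   panels on the same sample.
#' @param lymph_population,nk_population node names carrying the lymphocyte
#'   and NK counts.
#' @param tolerance maximum absolute ratio difference for the concordance
#'   flag (default 0.02).
#' @return list with per-panel `ratios` (data.frame), `differences` and
#'   `concordant`.
#' @export
cross_panel_ratios <- function(tb, mnd,
                               lymph_population = "Lymphocytes",
                               nk_population = "NK cells",
                               tolerance = 0.02) {
  one <- function(tab, panel) {
    n_root <- attr(tab, "n_root")
    if (is.null(n_root) || n_root == 0) {
      sf_stop("population table has no CD45+ (root) events", "sf_empty_input")
    }
    cnt <- function(p) {
      i <- match(p, tab$population)
      if (is.na(i)) sf_stop(sprintf("population '%s' absent from %s table", p, panel),
                            "sf_missing_channel")
      tab$count[i]
    }
    data.frame(panel = panel,
               lymph_cd45 = cnt(lymph_population) / n_root,
               nk_cd45 = cnt(nk_population) / n_root)
  }
  ratios <- rbind(one(tb, "tb"), one(mnd, "mnd"))
  differences <- c(lymph_cd45 = abs(diff(ratios$lymph_cd45)),
                   nk_cd45 = abs(diff(ratios$nk_cd45)))
  list(ratios = ratios, differences = differences,
       concordant = all(differences <= tolerance), tolerance = tolerance)
}

#' Population-by-marker expression matrix with clustering
#'
#' Mean (transformed) fluorescence intensity of every canonical population
#' over every marker — the numeric backbone of the clustered expression
#' heatmap. Each marker column is min-max scaled to \[0, 1\] (a degenerate
#' constant column scales to 1), and rows and columns are ordered by
#' average-linkage hierarchical clustering on Euclidean distances; ties are
#' broken by lexicographic name so the ordering is deterministic.
#'
#' @param events transformed marker-space [event_matrix()].
#' @param membership events x populations logical matrix from
#'   [run_gating_tree()] (or any per-event membership matrix).
#' @param populations populations (columns of `membership`) to include;
#'   populations with zero events are dropped with a message.
#' @param markers markers to include (default: all marker-kind channels).
#' @return list of class `population_marker_matrix`: `mfi`, `scaled`,
#'   `row_order`, `col_order`.
#' @export
population_marker_matrix <- function(events, membership,
                                     populations = colnames(membership),
                                     markers = NULL) {
  if (is.null(markers)) {
    markers <- events$channel_names[events$channel_kinds == "marker"]
  }
  populations <- sort(populations)
  markers <- sort(markers)
  counts <- colSums(membership[, populations, drop = FALSE])
  empty <- counts == 0
  if (any(empty)) {
    message("excluding population(s) with 0 events: ",
            paste(populations[empty], collapse = ", "))
    populations <- populations[!empty]
  }
  if (!length(populations)) sf_stop("no non-empty populations", "sf_empty_input")
  vals <- events$values[, markers, drop = FALSE]
  mfi <- t(vapply(populations, function(p) {
    colMeans(vals[membership[, p], , drop = FALSE])
  }, numeric(length(markers))))
  dimnames(mfi) <- list(populations, markers)

  rng <- apply(mfi, 2, range)
  span <- rng[2, ] - rng[1, ]
  scaled <- sweep(mfi, 2, rng[1, ], `-`)
  scaled <- sweep(scaled, 2, ifelse(span == 0, 1, span), `/`)
  scaled[, span == 0] <- 1  # degenerate column: defined as 1

  order_of <- function(m) {
    if (nrow(m) < 3) return(rownames(m))
    hc <- stats::hclust(stats::dist(m), method = "average")
    rownames(m)[hc$order]
  }
  structure(list(mfi = mfi, scaled = scaled,
                 row_order = order_of(scaled),
                 col_order = order_of(t(scaled))),
            class = "population_marker_matrix")
}

#' @export
print.population_marker_matrix <- function(x, ...) {
  cat(sprintf("<population_marker_matrix> %d populations x %d markers\n",
              nrow(x$mfi), ncol(x$mfi)))
  invisible(x)
}

#' Write a population-marker matrix to CSV (+ dendrogram-order JSON)
#' @param pmm a [population_marker_matrix()].
#' @param csv_path output CSV (scaled matrix in clustered order).
#' @param json_path optional sidecar with row/column orders.
#' @return `csv_path`, invisibly.
#' @export
write_marker_matrix <- function(pmm, csv_path, json_path = NULL) {
  m <- pmm$scaled[pmm$row_order, pmm$col_order, drop = FALSE]
  utils::write.csv(data.frame(population = rownames(m), m, check.names = FALSE),
                   csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(row_order = pmm$row_order,
                              col_order = pmm$col_order),
                         json_path, auto_unbox = FALSE)
  }
  invisible(csv_path)
}

#' Overlay-gate frequencies on a canonical population
#'
#' Activation/checkpoint/functional markers (e.g. PD-1, TIM-3 on T cells,
#' NKp30 on NK subsets) are expressed as overlay gates attachable to any
#' population rather than tree nodes. Reports the fraction of the target
#' population passing each overlay expression.
#'
#' @param events transformed marker-space [event_matrix()].
#' @param membership membership matrix from [run_gating_tree()].
#' @param population target population name.
#' @param overlays named character vector of gate expressions
#'   (e.g. `c("PD-1" = "CD279+")`).
#' @param cutoffs a [gating_cutoffs()].
#' @return data.frame with `overlay`, `population`, `count`,
#'   `pct_of_population`.
#' @export
overlay_frequencies <- function(events, membership, population, overlays,
                                cutoffs = gating_cutoffs()) {
  if (!population %in% colnames(membership)) {
    sf_stop(sprintf("population '%s' not in membership matrix", population),
            "sf_missing_channel")
  }
  base <- membership[, population]
  n_base <- sum(base)
  res <- lapply(names(overlays), function(nm) {
    sel <- base & eval_gate_expression(parse_gate_expr(overlays[[nm]]),
                                       events$values, cutoffs)
    data.frame(overlay = nm, population = population, count = sum(sel),
               pct_of_population = if (n_base > 0) 100 * sum(sel) / n_base else 0)
  })
  do.call(rbind, res)
}
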