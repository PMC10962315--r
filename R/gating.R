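#' @name gating
#' @title Declarative hierarchical gating
#'
#' @description
#' Gates are declared as a tree of named nodes, each with a parent, an
#' expression, and a flag distinguishing canonical populations from
#' intermediate steps. Expressions come in two forms:
#'
#' \itemize{
#'   \item threshold expressions, written in the compact field notation
#'     `"CD25+/CD127-"`: terms separated by `/` are ANDed; each term is a
#'     marker followed by a relation suffix `+`, `-`, `hi`, `lo` or `int`;
#'     a leading `!` negates a term (the NOT-gate used to exclude aggregate
#'     artifacts);
#'   \item rectangle gates over two channels (typically FSC-A/SSC-A scatter),
#'     given as `rect: {x, y, xmin, xmax, ymin, ymax}`.
#' }
#'
#' Relations are evaluated against per-marker cutoffs in arcsinh-transformed
#' units with half-open intervals (an event exactly on a cutoff is positive):
#' `+` is `v >= pos`; `-` is `v < pos`; `hi` is `v >= hi`; `lo` is
#' `pos <= v < hi`; `int` is the intermediate band.
NULL

# ---- expression parsing -----------------------------------------------------

parse_gate_term <- function(term) {
  negate <- startsWith(term, "!")
  if (negate) term <- substring(term, 2)
  rels <- c("int", "hi", "lo", "+", "-")
  for (r in rels) {
    if (endsWith(term, r)) {
      marker <- substr(term, 1, nchar(term) - nchar(r))
      if (nchar(marker) == 0) break
      return(list(marker = marker, rel = r, negate = negate))
    }
  }
  sf_stop(sprintf("cannot parse gate term '%s'", term), "sf_parse_error")
}

#' Parse a threshold gate expression
#' @param text expression such as `"CD25+/CD127-"`.
#' @return a gate expression object (list of AND-ed terms).
#' @export
parse_gate_expr <- function(text) {
  parts <- strsplit(trimws(text), "/", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (!length(parts)) sf_stop("empty gate expression", "sf_parse_error")
  structure(list(type = "terms", terms = lapply(parts, parse_gate_term)),
            class = "gate_expression")
}

rect_expr <- function(x, y, xmin, xmax, ymin, ymax) {
  if (!is.finite(xmin) || !is.finite(xmax) || xmin >= xmax ||
      !is.finite(ymin) || !is.finite(ymax) || ymin >= ymax) {
    sf_stop("rectangle gate needs finite min < max bounds", "sf_parse_error")
  }
  structure(list(type = "rect", x = x, y = y,
                 xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
            class = "gate_expression")
}

expr_markers <- function(expr) {
  if (expr$type == "rect") c(expr$x, expr$y)
  else vapply(expr$terms, `[[`, character(1), "marker")
}

# ---- cutoffs ----------------------------------------------------------------

#' Per-marker gating cutoffs
#'
#' Bundles the global default cutoffs with optional per-marker overrides.
#'
#' @param default list with `pos`, `hi` and length-2 `int`, as from
#'   [default_cutoffs()].
#' @param overrides named list of per-marker lists with any of the same
#'   fields.
#' @return an object of class `gating_cutoffs`.
#' @export
gating_cutoffs <- function(default = default_cutoffs(), overrides = list()) {
  structure(list(default = default, overrides = overrides),
            class = "gating_cutoffs")
}

marker_cutoffs <- function(cutoffs, marker) {
  ov <- cutoffs$overrides[[marker]]
  if (is.null(ov)) return(cutoffs$default)
  utils::modifyList(cutoffs$default, ov)
}

eval_term <- function(term, values, cutoffs) {
  j <- match(term$marker, colnames(values))
  if (is.na(j)) {
    sf_stop(sprintf("marker '%s' not present in events", term$marker),
            "sf_missing_channel")
  }
  v <- values[, j]
  cc <- marker_cutoffs(cutoffs, term$marker)
  res <- switch(term$rel,
    "+"  = v >= cc$pos,
    "-"  = v < cc$pos,
    "hi" = v >= cc$hi,
    "lo" = v >= cc$pos & v < cc$hi,
    "int" = v >= cc$int[1] & v < cc$int[2]
  )
  if (term$negate) !res else res
}

eval_gate_expression <- function(expr, values, cutoffs) {
  if (expr$type == "rect") {
    jx <- match(expr$x, colnames(values))
    jy <- match(expr$y, colnames(values))
    if (is.na(jx) || is.na(jy)) {
      sf_stop(sprintf("rectangle gate channel(s) missing: %s",
                      paste(c(expr$x, expr$y)[is.na(c(jx, jy))], collapse = ", ")),
              "sf_missing_channel")
    }
    return(values[, jx] >= expr$xmin & values[, jx] <= expr$xmax &
             values[, jy] >= expr$ymin & values[, jy] <= expr$ymax)
  }
  out <- rep(TRUE, nrow(values))
  for (term in expr$terms) out <- out & eval_term(term, values, cutoffs)
  out
}

# ---- tree -------------------------------------------------------------------

#' Construct a gating tree
#'
#' @param nodes list of node lists, each with `name`, `parent` (`"root"` for
#'   top-level gates), `expr` (a `gate_expression`), `canonical` flag, and
#'   optional `profile` (scatter class hint used by the simulator).
#' @param markers marker channels available in the panel (threshold terms may
#'   only reference these).
#' @param scatter_channels channels rectangle gates may reference.
#' @return an object of class `gating_tree`.
#' @export
gating_tree <- function(nodes, markers,
                        scatter_channels = c("FSC-A", "FSC-H", "SSC-A")) {
  nms <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    sf_stop(sprintf("duplicate gate name(s): %s",
                    paste(unique(nms[duplicated(nms)]), collapse = ", ")),
            "sf_duplicate_name")
  }
  if ("root" %in% nms) sf_stop("'root' is a reserved node name", "sf_duplicate_name")
  parents <- vapply(nodes, `[[`, character(1), "parent")
  unknown_parent <- setdiff(parents, c("root", nms))
  if (length(unknown_parent)) {
    sf_stop(sprintf("unknown parent(s): %s", paste(unknown_parent, collapse = ", ")),
            "sf_unknown_parent")
  }
  # cycle check: every node must reach root
  for (i in seq_along(nodes)) {
    seen <- character(0)
    p <- parents[i]
    while (p != "root") {
      if (p %in% seen) {
        sf_stop(sprintf("gating graph has a cycle through '%s'", p), "sf_cycle")
      }
      seen <- c(seen, p)
      p <- parents[match(p, nms)]
    }
  }
  allowed <- c(markers, scatter_channels)
  for (nd in nodes) {
    bad <- setdiff(expr_markers(nd$expr), allowed)
    if (length(bad)) {
      sf_stop(sprintf("gate '%s' references unknown marker(s): %s",
                      nd$name, paste(bad, collapse = ", ")),
              "sf_unknown_marker")
    }
  }
  # order nodes parents-first
  order <- character(0)
  remaining <- nms
  while (length(remaining)) {
    ready <- remaining[parents[match(remaining, nms)] %in% c("root", order)]
    if (!length(ready)) sf_stop("gating graph is not a tree", "sf_cycle")
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  nodes <- nodes[match(order, nms)]
  names(nodes) <- order
  structure(list(nodes = nodes, markers = markers,
                 scatter_channels = scatter_channels),
            class = "gating_tree")
}

#' @export
print.gating_tree <- function(x, ...) {
  canon <- sum(vapply(x$nodes, function(n) isTRUE(n$canonical), logical(1)))
  cat(sprintf("<gating_tree> %d gates (%d canonical populations), %d markers\n",
              length(x$nodes), canon, length(x$markers)))
  invisible(x)
}

#' Canonical population names of a gating tree
#' @param tree a [gating_tree()].
#' @return character vector.
#' @export
canonical_populations <- function(tree) {
  names(tree$nodes)[vapply(tree$nodes, function(n) isTRUE(n$canonical), logical(1))]
}

#' Parse a gating configuration file
#'
#' Reads a YAML (or JSON) gating configuration into a [gating_tree()].
#' Schema: top-level `markers` (list) and `gates` (list of mappings with
#' `name`, `parent`, `canonical`, and either `expr` (threshold notation) or
#' `rect`; rectangle gates may carry a `profile` hint). Unknown markers,
#' cyclic parents and duplicate names are rejected with located schema
#' errors.
#'
#' @param path configuration file path.
#' @return a [gating_tree()].
#' @export
parse_gating_config <- function(path) {
  if (!file.exists(path)) sf_stop(sprintf("no such config: %s", path), "sf_missing_file")
  cfg <- yaml::read_yaml(path)
  build_tree_from_config(cfg, where = path)
}

build_tree_from_config <- function(cfg, where = "config") {
  if (is.null(cfg$markers) || is.null(cfg$gates)) {
    sf_stop(sprintf("%s: 'markers' and 'gates' are required", where), "sf_parse_error")
  }
  nodes <- lapply(cfg$gates, function(g) {
    if (is.null(g$name)) sf_stop(sprintf("%s: gate without a name", where),
                                 "sf_parse_error")
    expr <- if (!is.null(g$rect)) {
      do.call(rect_expr, g$rect[c("x", "y", "xmin", "xmax", "ymin", "ymax")])
    } else if (!is.null(g$expr)) {
      parse_gate_expr(g$expr)
    } else {
      sf_stop(sprintf("%s: gate '%s' needs 'expr' or 'rect'", where, g$name),
              "sf_parse_error")
    }
    list(name = g$name, parent = g$parent %||% "root", expr = expr,
         canonical = isTRUE(g$canonical), profile = g$profile %||% NULL)
  })
  gating_tree(nodes, markers = unlist(cfg$markers))
}

# ---- evaluation -------------------------------------------------------------

#' Evaluate a gating tree on marker-space events
#'
#' Each node's membership is the intersection of its expression with its
#' parent's membership (root = all events). Counts, percent-of-parent and
#' percent-of-root are tabulated for every node; the table flags canonical
#' populations. Events are expected in transformed units (see
#' [transform_events()]); percentages of an empty parent are defined as 0.
#'
#' @param tree a [gating_tree()].
#' @param events an [event_matrix()] containing every referenced channel.
#' @param cutoffs a [gating_cutoffs()] object.
#' @return list with `membership` (events x nodes logical matrix) and
#'   `table` (a population table data.frame; the root event count is attached
#'   as attribute `n_root`).
#' @export
run_gating_tree <- function(tree, events, cutoffs = gating_cutoffs()) {
  vals <- events$values
  n <- nrow(vals)
  node_names <- names(tree$nodes)
  membership <- matrix(FALSE, n, length(node_names),
                       dimnames = list(NULL, node_names))
  parent_of <- vapply(tree$nodes, `[[`, character(1), "parent")
  for (nm in node_names) {
    own <- eval_gate_expression(tree$nodes[[nm]]$expr, vals, cutoffs)
    p <- parent_of[[nm]]
    membership[, nm] <- if (p == "root") own else own & membership[, p]
  }
  counts <- colSums(membership)
  parent_counts <- ifelse(parent_of == "root", n, counts[parent_of])
  tab <- data.frame(
    population = node_names,
    parent = unname(parent_of),
    canonical = vapply(tree$nodes, function(x) isTRUE(x$canonical), logical(1)),
    count = as.integer(counts),
    pct_of_parent = ifelse(parent_counts > 0, 100 * counts / parent_counts, 0),
    pct_of_root = if (n > 0) 100 * counts / n else 0,
    sample_id = events$sample_id,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(tab, "n_root") <- n
  list(membership = membership, table = tab)
}

# ---- pregates ---------------------------------------------------------------

#' Apply the standard acquisition pregates
#'
#' Sequentially keeps: singlets (FSC-A/FSC-H ratio within a band around the
#' modal ratio), non-RBC/non-debris events (scatter floor exclusion — the
#' panels carry no erythrocyte marker, so red cells and debris are excluded
#' on low scatter), viable events (viability dye negative), and CD45-positive
#' cells. Expects transformed fluorescence values and raw scatter.
#'
#' @param events an [event_matrix()] with scatter and viability channels.
#' @param viability name of the viability channel.
#' @param cd45 name of the pan-leukocyte channel (default "CD45").
#' @param cutoffs a [gating_cutoffs()].
#' @param singlet_band half-width of the singlet ratio band, as a fraction of
#'   the modal FSC-A/FSC-H ratio (default 0.15).
#' @param scatter_floor minimum FSC-A for non-RBC/debris events.
#' @return the surviving events, with a `pregate_counts` attribute recording
#'   events remaining after each step.
#' @export
apply_pregates <- function(events, viability = "ViaDye", cd45 = "CD45",
                           cutoffs = gating_cutoffs(),
                           singlet_band = 0.15, scatter_floor = 28000) {
  need <- c("FSC-A", "FSC-H", "SSC-A", viability, cd45)
  missing <- setdiff(need, events$channel_names)
  if (length(missing)) {
    sf_stop(sprintf("pregates require channel(s): %s", paste(missing, collapse = ", ")),
            "sf_missing_channel")
  }
  counts <- c(input = n_events(events))

  ratio <- channel_values(events, "FSC-A") / pmax(channel_values(events, "FSC-H"), 1)
  d <- stats::density(ratio, n = 512)
  modal <- d$x[which.max(d$y)]
  keep <- ratio >= modal * (1 - singlet_band) & ratio <= modal * (1 + singlet_band)
  events <- subset_events(events, keep)
  counts["singlets"] <- n_events(events)

  keep <- channel_values(events, "FSC-A") >= scatter_floor
  events <- subset_events(events, keep)
  counts["non_rbc"] <- n_events(events)

  cc <- marker_cutoffs(cutoffs, viability)
  keep <- channel_values(events, viability) < cc$pos
  events <- subset_events(events, keep)
  counts["viable"] <- n_events(events)

  cc <- marker_cutoffs(cutoffs, cd45)
  keep <- channel_values(events, cd45) >= cc$pos
  events <- subset_events(events, keep)
  counts["cd45_pos"] <- n_events(events)

  attr(events, "pregate_counts") <- counts
  events
}

# ---- rare populations -------------------------------------------------------

#' Detect rare populations outside the main hierarchies
#'
#' Reports, when the panel carries the required markers:
#' \itemize{
#'   \item CD4/CD8 double-positive T cells (CD3+, split as CD4hi/CD8lo and
#'     CD4lo/CD8hi);
#'   \item basophils: CD45-intermediate / CD123-high / HLA-DR-negative, where
#'     the CD45-intermediate band runs from the CD45 negative/positive cutoff
#'     up to the 10th percentile of CD45 among CD45+ events;
#'   \item innate lymphoid cells:
#'     CD45+/CD3-/CD8-/CD4-/TCRgd-/CD19-/CD20-/HLA-DR-/CD127+.
#' }
#' Frequencies are percentages of the input events (typically the pregated
#' live singlets).
#'
#' @param events transformed marker-space [event_matrix()], after pregates
#'   except that CD45-intermediate events must still be present (the default
#'   CD45+ pregate retains them).
#' @param cutoffs a [gating_cutoffs()].
#' @return data.frame with `population`, `count`, `pct_of_input` for every
#'   evaluable rare population; errors if none is evaluable.
#' @export
detect_rare_populations <- function(events, cutoffs = gating_cutoffs()) {
  vals <- events$values
  have <- function(...) all(c(...) %in% colnames(vals))
  rows <- list()
  n <- nrow(vals)

  if (have("CD3", "CD4", "CD8")) {
    t_cells <- eval_gate_expression(parse_gate_expr("CD3+"), vals, cutoffs)
    dp1 <- t_cells & eval_gate_expression(parse_gate_expr("CD4hi/CD8lo"), vals, cutoffs)
    dp2 <- t_cells & eval_gate_expression(parse_gate_expr("CD4lo/CD8hi"), vals, cutoffs)
    rows$dp1 <- data.frame(population = "DP T cells CD4hi/CD8lo", count = sum(dp1))
    rows$dp2 <- data.frame(population = "DP T cells CD4lo/CD8hi", count = sum(dp2))
  }
  if (have("CD45", "CD123", "HLA-DR")) {
    cc <- marker_cutoffs(cutoffs, "CD45")
    cd45 <- vals[, "CD45"]
    pos45 <- cd45[cd45 >= cc$pos]
    upper <- if (length(pos45)) stats::quantile(pos45, 0.10, names = FALSE) else cc$pos
    int45 <- cd45 >= cc$pos & cd45 < upper
    baso <- int45 &
      eval_gate_expression(parse_gate_expr("CD123hi/HLA-DR-"), vals, cutoffs)
    rows$baso <- data.frame(population = "Basophils", count = sum(baso))
  }
  if (have("CD45", "CD3", "CD8", "CD4", "TCRgd", "CD19", "CD20", "HLA-DR", "CD127")) {
    ilc <- eval_gate_expression(
      parse_gate_expr("CD45+/CD3-/CD8-/CD4-/TCRgd-/CD19-/CD20-/HLA-DR-/CD127+"),
      vals, cutoffs)
    rows$ilc <- data.frame(population = "ILCs", count = sum(ilc))
  }
  if (!length(rows)) {
    sf_stop("no rare population is evaluable with the available markers",
            "sf_missing_channel")
  }
  out <- do.call(rbind, unname(rows))
  out$pct_of_input <- if (n > 0) 100 * out$count / n else 0
  out$sample_id <- events$sample_id
  out
}
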