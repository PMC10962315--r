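#' @name panels
#' @title Shipped immunoprofiling panels
#'
#' @description
#' Three panels ship with the package as data files under
#' `inst/extdata/panels`: the PBMC T/B panel (27 fluorophores), the PBMC
#' M/N/D panel (25) and the bone-marrow panel (32), each bundling the marker
#' list, the full gating hierarchy, overlay gates and a synthetic
#' 48-detector signature library. Signature CSVs are synthetic stand-ins
#' generated by [make_signature_set()] with a fixed seed (real vendor
#' reference spectra are proprietary); their filenames carry the
#' `_synthetic` tag.
NULL

#' List the shipped panel identifiers
#' @return character vector of panel ids.
#' @export
list_panels <- function() c("tb", "mnd", "bmc")

#' Load a shipped (or custom) panel configuration
#'
#' @param panel one of `"tb"`, `"mnd"`, `"bmc"`, or a path to a panel YAML
#'   following the same schema.
#' @return an object of class `panel_config`: fields `panel`, `name`,
#'   `markers`, `viability`, `cofactor`, `tree` (a [gating_tree()]),
#'   `overlays`, `signatures` (a [signature_matrix()]), `cutoffs`.
#' @export
load_panel <- function(panel) {
  path <- if (file.exists(panel)) panel else
    system.file("extdata", "panels", paste0(panel, ".yaml"), package = "specflow")
  if (!nzchar(path) || !file.exists(path)) {
    sf_stop(sprintf("unknown panel '%s' (shipped: %s)", panel,
                    paste(list_panels(), collapse = ", ")),
            "sf_missing_file")
  }
  cfg <- yaml::read_yaml(path)
  tree <- build_tree_from_config(cfg, where = path)
  sigs <- NULL
  if (!is.null(cfg$signatures)) {
    sig_path <- file.path(dirname(path), cfg$signatures)
    if (file.exists(sig_path)) sigs <- read_signatures_csv(normalizePath(sig_path))
  }
  cutoffs <- gating_cutoffs(default_cutoffs(cfg$cofactor %||% 6000),
                            overrides = cfg$cutoffs %||% list())
  structure(list(panel = cfg$panel, name = cfg$name,
                 markers = unlist(cfg$markers),
                 viability = cfg$viability %||% "ViaDye",
                 cofactor = cfg$cofactor %||% 6000,
                 tree = tree,
                 overlays = unlist(cfg$overlays) %||% character(0),
                 signatures = sigs,
                 cutoffs = cutoffs),
            class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat(sprintf("<panel_config> %s: %d markers (%d fluorophores incl. viability), %d gates\n",
              x$name, length(x$markers), length(x$markers),
              length(x$tree$nodes)))
  invisible(x)
}

# Biological expression overrides for markers the gating paths leave
# unconstrained: without them negatively-defined gates (e.g. the T/B NK gate,
# HLA-DR-) would swallow populations that are in reality positive for the
# marker. Levels here only fill in path-unconstrained markers.
panel_template_overrides <- function(panel) {
  switch(panel,
    tb = {
      b_hla <- c("HLA-DR" = "pos")
      list(`Total B cells` = b_hla, `Plasmablasts` = b_hla,
           `CD20+ B cells` = b_hla, `Naive B` = b_hla,
           `Switched memory B` = b_hla, `Unswitched memory B` = b_hla,
           `DN memory B` = b_hla,
           `NKT-like cells` = c(TCRab = "pos"))
    },
    mnd = {
      mono <- c("HLA-DR" = "pos", CD11b = "pos", CD33 = "pos")
      list(`Classical monocytes` = mono, `Intermediate monocytes` = mono,
           `Nonclassical monocytes` = mono,
           `Classical monocytes-Normal` = mono[-1],
           `Intermediate monocytes-Normal` = mono[-1],
           `Nonclassical monocytes-Normal` = mono[-1],
           `NKT cells` = c(CD7 = "pos"))
    },
    bmc = {
      mono <- c(CD11b = "pos", CD33 = "pos")
      list(`Classical monocytes` = c("HLA-DR" = "pos", mono),
           `Nonclassical monocytes` = mono,
           `B cells` = c("HLA-DR" = "pos"),
           `Plasmablasts` = c("HLA-DR" = "pos"))
    },
    list()
  )
}

# Default generation shares per canonical population (broad physiological
# ranges, not any specific donor); "generic" parent templates carry the
# events that belong to a canonical parent but none of its canonical
# children. Normalized at simulation time.
panel_default_frequencies <- function(panel, tree) {
  pops <- canonical_populations(tree)
  x <- stats::setNames(rep(0.004, length(pops)), pops)
  ov <- switch(panel,
    tb = c("Total T cells" = 0.02, "CD8 T cells" = 0.01,
           "Naive CD8" = 0.05, "TEMRA CD8" = 0.015,
           "Central memory CD8" = 0.04, "Effector CD8" = 0.01,
           "Early effector CD8" = 0.02, "Terminal effector CD8" = 0.015,
           "CD4 T cells" = 0.02, "Naive CD4" = 0.10, "TEMRA CD4" = 0.01,
           "Central memory CD4" = 0.08, "Effector CD4" = 0.01,
           "Early effector CD4" = 0.02, "Regulatory T cells" = 0.02,
           "Th1" = 0.02, "Th2" = 0.02, "Th17" = 0.01,
           "Gamma delta T cells" = 0.006, "Activated T cells" = 0.01,
           "NKT-like cells" = 0.015, "NK cells" = 0.10,
           "Total B cells" = 0.01, "Plasmablasts" = 0.005,
           "CD20+ B cells" = 0.005, "Naive B" = 0.03,
           "Switched memory B" = 0.015, "Unswitched memory B" = 0.01),
    mnd = c("NKT cells" = 0.02, "NK cells" = 0.03,
            "Early NK cells" = 0.015, "Mature NK cells" = 0.06,
            "Terminal NK cells" = 0.01,
            "Classical monocytes" = 0.02, "Classical monocytes-Normal" = 0.10,
            "Classical monocytes-Immunosuppressed" = 0.01,
            "Intermediate monocytes" = 0.01, "Intermediate monocytes-Normal" = 0.02,
            "Nonclassical monocytes" = 0.01, "Nonclassical monocytes-Normal" = 0.03,
            "MDSC-like cells" = 0.008, "Monocytic MDSC-like cells" = 0.008,
            "Dendritic cells" = 0.005, "pDC" = 0.006, "cDC2" = 0.008),
    bmc = c("Total T cells" = 0.02, "CD8 T cells" = 0.01,
            "Effector CD8" = 0.02, "Central memory CD8" = 0.02,
            "Naive CD8" = 0.03, "TEMRA CD8" = 0.01,
            "CD4 T cells" = 0.01, "Effector CD4" = 0.02,
            "Central memory CD4" = 0.03, "Naive CD4" = 0.04,
            "TEMRA CD4" = 0.008, "Regulatory T cells" = 0.01,
            "NKT cells" = 0.006, "NKT CD8+" = 0.005, "NKT CD8-" = 0.005,
            "Gamma delta T cells" = 0.01,
            "HSC" = 0.003, "MPP" = 0.004, "MLP" = 0.002,
            "MLP I" = 0.003, "MLP II" = 0.003,
            "CMP" = 0.01, "GMP" = 0.012, "MEP" = 0.01,
            "CD10+ progenitors" = 0.015,
            "B cells" = 0.06, "Plasmablasts" = 0.006,
            "NK cells" = 0.01, "Early NK" = 0.01, "Mature NK" = 0.03,
            "Terminal NK" = 0.008,
            "Classical monocytes" = 0.08, "Nonclassical monocytes" = 0.02,
            "Dendritic cells" = 0.008, "pDC" = 0.006,
            "CD16+ cDC" = 0.005, "CD16- cDC" = 0.008,
            "ILCs" = 0.004, "MDSC-like" = 0.008),
    NULL
  )
  if (!is.null(ov)) x[names(ov)] <- ov
  x / sum(x)
}

# Extra generative populations outside the gating hierarchies (scatter-gated
# out or rare populations detected by dedicated gates).
panel_extra_templates <- function(panel, markers) {
  all_bg <- function(overrides, scatter, name, freq) {
    lv <- stats::setNames(rep("bg", length(markers)), markers)
    lv[names(overrides)] <- overrides
    if ("ViaDye" %in% markers) lv["ViaDye"] <- "neg"
    population_template(name, lv, freq, scatter)
  }
  switch(panel,
    tb = list(
      all_bg(c(CD45 = "pos", "HLA-DR" = "pos", CD4 = "int"), "monocyte",
             "Monocytes (unresolved)", 0.22),
      all_bg(c(CD45 = "pos", CD3 = "pos", TCRab = "pos", CD4 = "hi", CD8 = "pos",
               CD45RA = "pos", CD197 = "pos"), "lymphocyte",
             "DP T cells CD4hi/CD8lo", 0.002),
      all_bg(c(CD45 = "pos", CD3 = "pos", TCRab = "pos", CD4 = "pos", CD8 = "hi",
               CD45RA = "pos", CD197 = "pos"), "lymphocyte",
             "DP T cells CD4lo/CD8hi", 0.002),
      all_bg(c(CD45 = "pos", CD127 = "pos",
               CD3 = "neg", CD4 = "neg", CD8 = "neg", TCRgd = "neg",
               TCRab = "neg", CD19 = "neg", CD20 = "neg", "HLA-DR" = "neg"),
             "lymphocyte", "ILCs", 0.002)
    ),
    mnd = list(
      all_bg(c(CD45 = "pos", CD3 = "pos", CD5 = "pos"), "lymphocyte",
             "T cells (unresolved)", 0.40),
      all_bg(c(CD45 = "pos", CD19 = "pos", CD20 = "pos", "HLA-DR" = "pos"),
             "lymphocyte", "B cells (unresolved)", 0.06),
      all_bg(c(CD45 = "int", CD123 = "hi", "HLA-DR" = "neg",
               CD3 = "neg", CD14 = "neg", CD16 = "neg", CD19 = "neg"),
             "lymphocyte", "Basophils", 0.003)
    ),
    bmc = list(),
    list()
  )
}

#' Default ground-truth simulation mix for a shipped panel
#'
#' Combines [templates_from_gating()] on the panel's hierarchy (with the
#' panel's biological overrides and default physiological generation shares)
#' with the extra out-of-hierarchy populations (monocytes in the T/B sample,
#' basophils in M/N/D, ...). Frequencies are normalized to sum to 1.
#'
#' @param panel a `panel_config` from [load_panel()], or a panel id.
#' @return list of [population_template()] objects.
#' @export
panel_templates <- function(panel) {
  if (is.character(panel)) panel <- load_panel(panel)
  freqs <- panel_default_frequencies(panel$panel, panel$tree)
  tpl <- templates_from_gating(panel$tree, frequencies = freqs,
                               overrides = panel_template_overrides(panel$panel),
                               viability = panel$viability)
  extra <- panel_extra_templates(panel$panel, panel$markers)
  # extras keep their nominal shares (e.g. basophils at exactly 0.3%);
  # hierarchy-derived templates fill the remainder
  extra_tot <- sum(vapply(extra, `[[`, numeric(1), "frequency"))
  tree_tot <- sum(vapply(tpl, `[[`, numeric(1), "frequency"))
  tpl <- lapply(tpl, function(t) {
    t$frequency <- t$frequency / tree_tot * (1 - extra_tot); t
  })
  c(tpl, extra)
}

#' Simulate a complete sample for a shipped panel
#'
#' Convenience wrapper: default templates, panel signatures, standard
#' artifact rates.
#'
#' @param panel panel id or `panel_config`.
#' @param n_events number of events.
#' @param seed integer seed.
#' @param space `"detector"` or `"marker"`.
#' @param ... passed to [simulate_sample()].
#' @return an [event_matrix()] with truth labels.
#' @export
simulate_panel_sample <- function(panel, n_events, seed = 1,
                                  space = "detector", ...) {
  if (is.character(panel)) panel <- load_panel(panel)
  simulate_sample(panel_templates(panel), n_events, sigs = panel$signatures,
                  space = space, viability = panel$viability, seed = seed, ...)
}
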