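test_that("gate expression notation parses relations, bands and NOT terms", {
  e <- parse_gate_expr("CD25+/CD127-/HLA-DR-/CD45RAhi/CD4int/!CD19+")
  rels <- vapply(e$terms, `[[`, character(1), "rel")
  mks <- vapply(e$terms, `[[`, character(1), "marker")
  expect_equal(mks, c("CD25", "CD127", "HLA-DR", "CD45RA", "CD4", "CD19"))
  expect_equal(rels, c("+", "-", "-", "hi", "int", "+"))
  expect_true(e$terms[[6]]$negate)
  expect_error(parse_gate_expr("CD3"), class = "sf_parse_error")
})

test_that("tree construction rejects schema violations with located errors", {
  mk <- c("CD3", "CD4")
  node <- function(name, parent, expr) {
    list(name = name, parent = parent, expr = parse_gate_expr(expr),
         canonical = TRUE)
  }
  expect_error(gating_tree(list(node("a", "root", "CD99+")), mk),
               class = "sf_unknown_marker", regexp = "CD99")
  expect_error(gating_tree(list(node("a", "root", "CD3+"),
                                node("a", "root", "CD4+")), mk),
               class = "sf_duplicate_name")
  expect_error(gating_tree(list(node("a", "b", "CD3+"),
                                node("b", "a", "CD4+")), mk),
               class = "sf_cycle")
  expect_error(gating_tree(list(node("a", "ghost", "CD3+")), mk),
               class = "sf_unknown_parent")

  minimal <- gating_tree(list(node("T cells", "root", "CD3+")), mk)
  expect_length(minimal$nodes, 1L)  # plus the implicit root
})

test_that("the shipped configs parse and encode the published definitions", {
  tb <- load_panel("tb")
  treg <- tb$tree$nodes[["Regulatory T cells"]]
  expect_false(is.null(treg))
  rels <- vapply(treg$expr$terms, function(t) paste0(t$marker, t$rel), "")
  expect_setequal(rels, c("CD25+", "CD127-"))

  bmc <- load_panel("bmc")
  hsc <- bmc$tree$nodes[["HSC"]]
  # full path: CD34+ CD3- CD38- CD45RA- CD90+
  path <- character(0)
  node <- "HSC"
  while (node != "root") {
    nd <- bmc$tree$nodes[[node]]
    if (nd$expr$type == "terms") {
      path <- c(path, vapply(nd$expr$terms,
                             function(t) paste0(t$marker, t$rel), ""))
    }
    node <- nd$parent
  }
  expect_true(all(c("CD34+", "CD3-", "CD38-", "CD45RA-", "CD90+") %in% path))
})

test_that("memberships are nested, order-invariant, and quadrants partition", {
  pan <- load_panel("tb")
  m <- simulate_panel_sample(pan, 4000, seed = 31, space = "marker")
  tr <- transform_events(m, pan$cofactor)
  pg <- apply_pregates(tr, viability = pan$viability, cutoffs = pan$cutoffs)
  g <- run_gating_tree(pan$tree, pg, pan$cutoffs)

  # containment: every node within its parent
  for (nm in names(pan$tree$nodes)) {
    p <- pan$tree$nodes[[nm]]$parent
    if (p != "root") {
      expect_true(all(g$membership[g$membership[, nm], p]), label = nm)
    }
  }

  # CD45RA x CD197 quadrants partition the CD8 T-cell parent exactly
  quads <- c("Naive CD8", "TEMRA CD8", "Central memory CD8", "Effector CD8")
  expect_equal(rowSums(g$membership[, quads, drop = FALSE]),
               as.numeric(g$membership[, "CD8 T cells"]))

  # permutation invariance of the population table
  perm <- sample(n_events(pg))
  g2 <- run_gating_tree(pan$tree, subset_events(pg, perm), pan$cutoffs)
  expect_equal(g2$table$count, g$table$count)

  # zero-event parent: all descendants zero, percentages defined as 0
  none <- subset_events(pg, pg$values[, "CD3"] > 1e9)
  g0 <- run_gating_tree(pan$tree, none, pan$cutoffs)
  expect_true(all(g0$table$count == 0))
  expect_true(all(g0$table$pct_of_parent == 0))
})

test_that("pregates remove the artifact classes the generator labels", {
  pan <- load_panel("tb")
  art <- list(doublet = 0.05, dead = 0.03, rbc = 0.04, debris = 0.02)
  m <- simulate_panel_sample(pan, 20000, seed = 17, space = "marker",
                             artifacts = art)
  tr <- transform_events(m, pan$cofactor)
  pg <- apply_pregates(tr, viability = pan$viability, cutoffs = pan$cutoffs)
  expect_false(any(pg$truth_labels %in% c("doublet", "dead", "rbc", "debris")))

  counts <- attr(pg, "pregate_counts")
  truth_n <- table(factor(m$truth_labels,
                          c("doublet", "dead", "rbc", "debris")))
  # each pregate removes about the injected artifact fraction (3 binomial SDs)
  drop_singlet <- counts["input"] - counts["singlets"]
  tol <- 3 * sqrt(20000 * 0.05)
  expect_lt(abs(drop_singlet - truth_n[["doublet"]]), tol + 50)
  # survivors are about the non-artifact fraction
  expect_gt(counts[["cd45_pos"]], 20000 * (1 - sum(unlist(art))) * 0.95)

  no_via <- select_channels(tr, c("marker", "scatter"))
  expect_error(apply_pregates(no_via, viability = "ViaDye"),
               class = "sf_missing_channel")
})

test_that("gating recovers ground-truth populations on simulator defaults", {
  pan <- load_panel("mnd")
  raw <- simulate_panel_sample(pan, 30000, seed = 23)
  um <- unmix(raw, pan$signatures, viability = pan$viability)
  tr <- transform_events(drop_af(um), pan$cofactor)
  pg <- apply_pregates(tr, viability = pan$viability, cutoffs = pan$cutoffs)
  g <- run_gating_tree(pan$tree, pg, pan$cutoffs)
  canon <- canonical_populations(pan$tree)
  in_canon <- pg$truth_labels %in% canon
  idx <- cbind(which(in_canon),
               match(pg$truth_labels[in_canon], colnames(g$membership)))
  expect_gt(mean(g$membership[idx]), 0.99)
})

test_that("recovered population frequencies track generation shares", {
  pan <- load_panel("tb")
  m <- simulate_panel_sample(pan, 100000, seed = 41, space = "marker",
                             artifacts = list())
  tr <- transform_events(m, pan$cofactor)
  pg <- apply_pregates(tr, viability = pan$viability, cutoffs = pan$cutoffs)
  g <- run_gating_tree(pan$tree, pg, pan$cutoffs)
  truth_tab <- table(pg$truth_labels)
  n <- n_events(pg)
  # for leaf canonical populations membership ~ truth share
  leaves <- c("Naive CD8", "Central memory CD8", "Regulatory T cells",
              "Naive B", "Switched memory B", "NK cells")
  for (pop in leaves) {
    p_hat <- g$table$count[g$table$population == pop] / n
    p_true <- truth_tab[[pop]] / n
    expect_lt(abs(p_hat - p_true),
              max(0.005, 3 * sqrt(p_true * (1 - p_true) / n) + 0.002),
              label = pop)
  }
})

test_that("rare populations are detected at their injected rates", {
  pan <- load_panel("tb")
  m <- simulate_panel_sample(pan, 60000, seed = 29, space = "marker")
  tr <- transform_events(m, pan$cofactor)
  pg <- apply_pregates(tr, viability = pan$viability, cutoffs = pan$cutoffs)
  rp <- detect_rare_populations(pg, pan$cutoffs)
  truth <- table(pg$truth_labels)
  n <- n_events(pg)

  for (pop in c("DP T cells CD4hi/CD8lo", "DP T cells CD4lo/CD8hi", "ILCs")) {
    got <- rp$count[rp$population == pop]
    want <- truth[[pop]]
    expect_lt(abs(got - want), 3 * sqrt(want) + 0.35 * want, label = pop)
  }

  # no DP generated -> zero DP reported
  keep <- !grepl("^DP T cells", pg$truth_labels)
  rp0 <- detect_rare_populations(subset_events(pg, keep), pan$cutoffs)
  expect_lte(sum(rp0$count[grepl("^DP", rp0$population)]), 2)

  no_mk <- select_channels(pg, "scatter")
  expect_error(detect_rare_populations(no_mk), class = "sf_missing_channel")
})

test_that("templates invert gate definitions and flag contradictions", {
  pan <- load_panel("tb")
  tpl <- templates_from_gating(pan$tree, viability = pan$viability)
  names(tpl) <- vapply(tpl, `[[`, character(1), "name")
  treg <- tpl[["Regulatory T cells"]]
  expect_equal(unname(treg$levels["CD25"]), "pos")
  expect_equal(unname(treg$levels["CD127"]), "neg")
  expect_equal(unname(treg$levels["CD3"]), "pos")   # inherited from the path
  expect_equal(unname(treg$levels["ViaDye"]), "neg")

  bmc <- load_panel("bmc")
  btpl <- templates_from_gating(bmc$tree, viability = "ViaDye")
  names(btpl) <- vapply(btpl, `[[`, character(1), "name")
  hsc <- btpl[["HSC"]]
  expect_equal(unname(hsc$levels[c("CD34", "CD38", "CD45RA", "CD90")]),
               c("pos", "neg", "neg", "pos"))

  # contradictory path: marker required + and -
  mk <- c("CD3", "CD4")
  nodes <- list(
    list(name = "a", parent = "root", expr = parse_gate_expr("CD3+"),
         canonical = FALSE),
    list(name = "b", parent = "a", expr = parse_gate_expr("CD3-"),
         canonical = TRUE)
  )
  bad <- gating_tree(nodes, mk)
  expect_error(templates_from_gating(bad), class = "sf_contradictory_path",
               regexp = "CD3")

  single <- gating_tree(list(list(name = "only", parent = "root",
                                  expr = parse_gate_expr("CD3+"),
                                  canonical = TRUE)), mk)
  expect_length(templates_from_gating(single), 1L)
})

test_that("HSC gate admits only events generated as CD34+CD38-CD45RA-CD90+", {
  pan <- load_panel("bmc")
  m <- simulate_panel_sample(pan, 30000, seed = 37, space = "marker")
  tr <- transform_events(m, pan$cofactor)
  pg <- apply_pregates(tr, viability = pan$viability, cutoffs = pan$cutoffs)
  g <- run_gating_tree(pan$tree, pg, pan$cutoffs)
  in_gate <- pg$truth_labels[g$membership[, "HSC"]]
  expect_true(all(in_gate == "HSC"))
  expect_gt(sum(in_gate == "HSC"), 10)
})

test_that("overlay gates report checkpoint frequencies on a population", {
  pan <- load_panel("tb")
  m <- simulate_panel_sample(pan, 5000, seed = 43, space = "marker")
  tr <- transform_events(m, pan$cofactor)
  pg <- apply_pregates(tr, viability = pan$viability, cutoffs = pan$cutoffs)
  g <- run_gating_tree(pan$tree, pg, pan$cutoffs)
  ov <- overlay_frequencies(pg, g$membership, "Total T cells", pan$overlays,
                            pan$cutoffs)
  expect_setequal(ov$overlay, names(pan$overlays))
  expect_true(all(ov$pct_of_population >= 0 & ov$pct_of_population <= 100))
})
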