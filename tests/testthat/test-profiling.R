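gate_panel <- function(pan, m) {
  tr <- transform_events(m, pan$cofactor)
  pg <- apply_pregates(tr, viability = pan$viability, cutoffs = pan$cutoffs)
  list(events = pg, gated = run_gating_tree(pan$tree, pg, pan$cutoffs))
}

test_that("cross-panel ratios agree when both panels gate the same truth", {
  tb <- load_panel("tb")
  mnd <- load_panel("mnd")
  # one sample carrying the union of both marker sets
  mk <- union(tb$markers, mnd$markers)
  lv <- function(...) {
    x <- stats::setNames(rep("neg", length(mk)), mk)
    ov <- c(...)
    x[names(ov)] <- ov
    x
  }
  tpl <- list(
    population_template("T cells", lv(CD45 = "pos", CD3 = "pos", TCRab = "pos",
                                      CD5 = "pos", CD4 = "pos"), 0.45),
    population_template("B cells", lv(CD45 = "pos", CD19 = "pos", CD20 = "pos",
                                      "HLA-DR" = "pos", IgD = "pos"), 0.15),
    population_template("NK cells", lv(CD45 = "pos", CD7 = "pos", CD56 = "pos",
                                       CD16 = "pos"), 0.10),
    population_template("Monocytes", lv(CD45 = "pos", CD14 = "pos",
                                        "HLA-DR" = "pos", CD11b = "pos",
                                        CD33 = "pos"), 0.30,
                        scatter = "monocyte")
  )
  m <- simulate_sample(tpl, 40000, space = "marker", seed = 51,
                       artifacts = list())
  g_tb <- gate_panel(tb, m)
  g_mnd <- gate_panel(mnd, m)
  cpr <- cross_panel_ratios(g_tb$gated$table, g_mnd$gated$table)

  expect_true(all(cpr$ratios$lymph_cd45 >= 0 & cpr$ratios$lymph_cd45 <= 1))
  expect_true(all(cpr$ratios$nk_cd45 <= cpr$ratios$lymph_cd45))
  expect_lt(cpr$differences[["nk_cd45"]], 0.02)
  expect_lt(cpr$differences[["lymph_cd45"]], 0.02)
  expect_true(cpr$concordant)
  # NK fraction close to the generation share 0.10
  expect_lt(max(abs(cpr$ratios$nk_cd45 - 0.10)), 3 * sqrt(0.1 * 0.9 / 40000) + 0.01)

  # empty NK population: ratio 0 in both panels
  m0 <- simulate_sample(tpl[-3], 5000, space = "marker", seed = 52,
                        artifacts = list())
  cpr0 <- cross_panel_ratios(gate_panel(tb, m0)$gated$table,
                             gate_panel(mnd, m0)$gated$table)
  expect_lt(max(cpr0$ratios$nk_cd45), 0.01)
})

test_that("population-marker matrix reflects the generating templates", {
  pan <- load_panel("tb")
  m <- simulate_panel_sample(pan, 20000, seed = 53, space = "marker")
  g <- gate_panel(pan, m)
  pmm <- suppressMessages(population_marker_matrix(
    g$events, g$gated$membership,
    populations = canonical_populations(pan$tree)))

  expect_true(all(pmm$scaled >= 0 & pmm$scaled <= 1))
  # T cells high CD3, B cells low CD3; only B lineage high CD19
  expect_gt(pmm$scaled["Total T cells", "CD3"], 0.8)
  expect_lt(pmm$scaled["Total B cells", "CD3"], 0.2)
  expect_gt(pmm$scaled["Total B cells", "CD19"], 0.8)
  expect_lt(pmm$scaled["Total T cells", "CD19"], 0.2)

  # binarized template recovery for well-separated populations
  tpl <- templates_from_gating(pan$tree,
                               overrides = specflow:::panel_template_overrides("tb"),
                               viability = pan$viability)
  names(tpl) <- vapply(tpl, `[[`, character(1), "name")
  # only markers that discriminate between populations: a marker positive in
  # every template (e.g. CD45) min-max scales to noise
  lv_mat <- do.call(rbind, lapply(tpl, `[[`, "levels"))
  discriminative <- colnames(lv_mat)[apply(lv_mat, 2, function(z)
    any(z %in% c("pos", "hi")) && any(z %in% c("neg", "bg")))]
  for (pop in c("Total T cells", "Total B cells", "NK cells")) {
    lev <- tpl[[pop]]$levels
    hard <- intersect(names(lev)[lev %in% c("pos", "hi")],
                      intersect(discriminative, colnames(pmm$scaled)))
    expect_true(all(pmm$scaled[pop, hard] > 0.5), label = pop)
  }

  # event order invariance
  perm <- sample(n_events(g$events))
  g2 <- run_gating_tree(pan$tree, subset_events(g$events, perm), pan$cutoffs)
  pmm2 <- suppressMessages(population_marker_matrix(
    subset_events(g$events, perm), g2$membership,
    populations = canonical_populations(pan$tree)))
  expect_equal(pmm2$mfi, pmm$mfi, tolerance = 1e-12)
  expect_identical(pmm2$row_order, pmm$row_order)
})

test_that("degenerate marker-matrix cases are well defined", {
  ev <- event_matrix(cbind(A = c(1, 2, 3, 4), B = rep(2, 4)),
                     c("A", "B"), "marker")
  mem <- cbind(only = c(TRUE, TRUE, FALSE, FALSE),
               empty = rep(FALSE, 4))
  expect_message(pmm <- population_marker_matrix(ev, mem), regexp = "empty")
  expect_equal(nrow(pmm$mfi), 1L)
  expect_true(all(pmm$scaled == 1))  # single row: min-max guard yields 1
  expect_error(population_marker_matrix(ev, cbind(none = rep(FALSE, 4))),
               class = "sf_empty_input")
})

test_that("marker matrix writes CSV plus sidecar order JSON", {
  ev <- rand_events(30, 4, seed = 54)
  mem <- cbind(p1 = rep(c(TRUE, FALSE), 15), p2 = rep(c(FALSE, TRUE), 15),
               p3 = rep(TRUE, 30))
  pmm <- population_marker_matrix(ev, mem)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_marker_matrix(pmm, csv, js)
  back <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(back$population, pmm$row_order)
  expect_equal(unlist(jsonlite::read_json(js)$col_order), pmm$col_order)
})
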