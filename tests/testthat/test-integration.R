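test_that("channel scaling maps extremes to [-1, 1]", {
  ev <- event_matrix(cbind(a = c(0, 10, 5), b = c(-2, 2, 0)),
                     c("a", "b"), "marker")
  sc <- scale_channels(ev)
  expect_equal(sc$values[, "a"], c(-1, 1, 0))
  expect_equal(sc$values[, "b"], c(-1, 1, 0))

  set.seed(14)
  r <- event_matrix(matrix(rnorm(300), 100, 3), paste0("c", 1:3), "marker")
  rs <- scale_channels(r)
  expect_equal(unname(apply(rs$values, 2, max)), rep(1, 3))
  expect_equal(unname(apply(rs$values, 2, min)), rep(-1, 3))
  # idempotent on already-scaled data
  expect_equal(scale_channels(rs)$values, rs$values)

  const <- event_matrix(cbind(k = rep(4, 5), x = 1:5), c("k", "x"), "marker")
  expect_warning(sc2 <- scale_channels(const), regexp = "constant")
  expect_true(all(sc2$values[, "k"] == 0))
})

test_that("PCA embedding is exact on planar data and deterministic", {
  set.seed(15)
  basis <- qr.Q(qr(matrix(rnorm(25), 5, 5)))[, 1:2]
  scores <- matrix(rnorm(200), 100, 2) %*% t(basis)  # exactly rank 2
  ev <- event_matrix(scores, paste0("c", 1:5), "marker")
  cfg <- integration_config(n_components = 2)
  emb <- pca_embed(ev, cfg)
  recon <- emb$coordinates %*% t(emb$rotation)
  expect_equal(sweep(recon, 2, colMeans(scores), `+`), scores,
               ignore_attr = TRUE, tolerance = 1e-10)

  # duplicated events embed identically
  dup <- event_matrix(scores[c(1, 1, 2:100), ], paste0("c", 1:5), "marker")
  e2 <- pca_embed(dup, cfg)
  expect_equal(e2$coordinates[1, ], e2$coordinates[2, ])

  expect_error(pca_embed(ev, integration_config(n_components = 10)),
               class = "sf_bad_input")
})

test_that("LISI equals closed forms on hand-built neighborhoods", {
  cfg <- integration_config()
  set.seed(16)
  locs <- matrix(rnorm(400, sd = 50), 200, 2)

  # single batch: exactly 1 everywhere
  one <- compute_lisi(locs, rep("b", 200), cfg)
  expect_true(all(one$lisi == 1))

  # co-located interleaved triplets: kernel mass uniform over 3 batches
  tri <- compute_lisi(locs[rep(1:200, each = 3), ],
                      rep(c("A", "B", "C"), 200), cfg)
  expect_lt(max(abs(tri$lisi - 3)), 1e-3)

  # (0.5, 0.5) two-batch neighborhoods: inverse Simpson = 1/(0.25+0.25) = 2
  pair <- compute_lisi(locs[rep(1:200, each = 2), ],
                       rep(c("A", "B"), 200), cfg)
  expect_lt(max(abs(pair$lisi - 2)), 1e-3)

  # range and permutation invariance on arbitrary data
  b <- sample(c("x", "y", "z"), 200, replace = TRUE)
  l <- compute_lisi(locs, b, cfg)
  expect_true(all(l$lisi >= 1 & l$lisi <= 3))
  perm <- sample(200)
  lp <- compute_lisi(locs[perm, ], b[perm], cfg)
  expect_equal(lp$lisi, l$lisi[perm], tolerance = 1e-9)

  expect_warning(compute_lisi(locs[1:20, ], b[1:20], cfg), regexp = "k reduced")
})

test_that("recommendation thresholds follow the batch-count map", {
  fake <- function(lisi, batches) list(lisi = lisi, batches = batches,
                                       n_batches = length(unique(batches)))
  cfg <- integration_config()
  seg <- fake(rep(1.01, 300), rep(c("a", "b", "c"), 100))
  r <- recommend_correction(seg, cfg)
  expect_equal(r$threshold, 2)
  expect_equal(r$high_fraction, 0)
  expect_equal(r$recommendation, "correct")

  mixed <- fake(rep(2.9, 300), rep(c("a", "b", "c"), 100))
  r2 <- recommend_correction(mixed, cfg)
  expect_equal(r2$high_fraction, 1)
  expect_equal(r2$recommendation, "no-correction")

  two <- fake(rep(1.7, 100), rep(c("a", "b"), 50))
  expect_equal(recommend_correction(two, cfg)$threshold, 1.667)

  four <- fake(rep(1.5, 80), rep(c("a", "b", "c", "d"), 20))
  expect_error(recommend_correction(four, cfg), class = "sf_missing_threshold")
  expect_equal(recommend_correction(
    four, integration_config(high_lisi_threshold = 3))$threshold, 3)

  # recommendation flips exactly at the 20% boundary
  flip <- function(frac) {
    lisi <- c(rep(2.5, round(300 * frac)), rep(1.0, 300 - round(300 * frac)))
    recommend_correction(fake(lisi, rep(c("a", "b", "c"), 100)), cfg)$recommendation
  }
  expect_equal(flip(0.19), "correct")
  expect_equal(flip(0.21), "no-correction")
})

test_that("batch correction removes a constant offset between batches", {
  set.seed(18)
  base <- matrix(rnorm(600 * 5), 600, 5)
  shift <- c(6, -4, 2, 0, 3)
  coords <- rbind(base[1:300, ], sweep(base[301:600, ], 2, shift, `+`))
  batches <- rep(c("b1", "b2"), each = 300)
  pcs <- specflow:::new_embedding(coords, "pca")
  cfg <- integration_config(n_components = 5, seed = 2)
  corr <- batch_correct(pcs, batches, cfg)

  cent <- function(m) {
    cs <- rowsum(m, batches) / as.vector(table(batches))
    sqrt(sum((cs[1, ] - cs[2, ])^2))
  }
  expect_lt(cent(corr$coordinates), 0.1 * cent(coords))
  expect_equal(nrow(corr$coordinates), 600L)

  # mean LISI does not decrease
  pre <- mean(compute_lisi(coords, batches, cfg)$lisi)
  post <- mean(compute_lisi(corr$coordinates, batches, cfg)$lisi)
  expect_gte(post, pre)

  # single batch: identity
  same <- batch_correct(pcs, rep("only", 600), cfg)
  expect_equal(same$coordinates, coords)

  expect_error(batch_correct(pcs, rep(c("a", "b"), c(597, 3)), cfg),
               class = "sf_batch_too_small")
})

test_that("external backend delegates to the registered integrator", {
  pcs <- specflow:::new_embedding(matrix(rnorm(100), 50, 2), "pca")
  b <- rep(c("a", "b"), 25)
  cfg <- integration_config(n_components = 2, backend = "external")
  old <- register_integrator(NULL)
  expect_error(batch_correct(pcs, b, cfg), class = "sf_backend_unavailable")
  register_integrator(function(coords, batches, cfg) coords * 0)
  out <- batch_correct(pcs, b, cfg)
  expect_true(all(out$coordinates == 0))
  register_integrator(old)
})

test_that("UMAP embedding is reproducible per seed and preserves structure", {
  set.seed(19)
  x <- rbind(matrix(rnorm(400, 0), 200, 2), matrix(rnorm(400, 8), 200, 2))
  cfg <- integration_config(seed = 6)
  u1 <- embed_umap(x, cfg)
  u2 <- embed_umap(x, cfg)
  expect_identical(u1$coordinates, u2$coordinates)
  expect_equal(nrow(u1$coordinates), 400L)

  # two well-separated populations keep silhouette > 0.5 in 2-D
  lab <- rep(1:2, each = 200)
  cents <- rowsum(u1$coordinates, lab) / 200
  d_own <- sqrt(rowSums((u1$coordinates - cents[lab, ])^2))
  d_oth <- sqrt(rowSums((u1$coordinates - cents[3 - lab, ])^2))
  sil <- mean((d_oth - d_own) / pmax(d_oth, d_own))
  expect_gt(sil, 0.5)

  expect_error(embed_umap(x[1:5, ], cfg), class = "sf_bad_input")
})

test_that("full integration run appends UMAP parameters and reports", {
  tpl <- toy_templates()
  batches <- simulate_batches(tpl, 300, 2, batch_effect_spec(0.6, 200),
                              space = "marker", seed = 11, artifacts = list())
  res <- integrate_batches(batches, integration_config(seed = 11,
                                                       n_components = 2),
                           correct = TRUE)
  expect_s3_class(res, "integration_result")
  expect_true(all(c("UMAP_1", "UMAP_2") %in% res$events$channel_names))
  expect_equal(n_events(res$events), 600L)
  expect_gte(mean(res$lisi_post$lisi), mean(res$lisi_pre$lisi))

  path <- withr::local_tempfile(fileext = ".json")
  write_integration_report(res, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$n_batches, 2L)
  expect_true(rep$recommendation %in% c("correct", "no-correction"))
})
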