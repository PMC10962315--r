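test_that("similarity index hits its endpoints and the dot-product oracle", {
  a <- spectral_signature("a", c(1, 0, 1))
  b <- spectral_signature("b", c(0, 1, 1))
  expect_equal(similarity_index(a, a), 1)
  expect_equal(similarity_index(spectral_signature("x", c(1, 1, 0, 0)),
                                spectral_signature("y", c(0, 0, 1, 1))), 0)
  expect_equal(similarity_index(a, b), 0.5)
  expect_equal(similarity_index(a, b), similarity_index(b, a))
  expect_error(similarity_index(a, spectral_signature("z", c(1, 1))),
               class = "sf_length_mismatch")
})

test_that("similarity matrix equals the element-wise oracle on random sets", {
  sigs <- make_signature_set(5, 16, 0.95, seed = 7)
  S <- similarity_matrix(sigs)
  # brute-force pairwise loop
  for (i in 1:5) for (j in 1:5) {
    expect_equal(S[i, j],
                 similarity_index(sigs$signatures[[i]], sigs$signatures[[j]]),
                 tolerance = 1e-12)
  }
  expect_equal(diag(S), rep(1, 5), ignore_attr = TRUE)
  expect_true(all(S >= 0 & S <= 1))
  expect_equal(S, t(S))
})

test_that("autofluorescence extraction is the normalized per-detector median", {
  v <- c(2, 5, 1, 0)
  m <- event_matrix(matrix(rep(v, each = 100), 100, 4), paste0("d", 1:4),
                    "detector")
  af <- extract_autofluorescence(m)
  expect_equal(af$profile, v / sqrt(sum(v^2)))

  # symmetric noise leaves the median profile intact
  set.seed(9)
  noisy <- m
  noisy$values <- noisy$values + matrix(rnorm(400, 0, 0.05), 100, 4)
  af2 <- suppressWarnings(extract_autofluorescence(noisy))
  med <- unname(apply(noisy$values, 2, median))
  expect_equal(af2$profile, pmax(med, 0) / sqrt(sum(pmax(med, 0)^2)))

  empty <- event_matrix(matrix(numeric(0), 0, 4), paste0("d", 1:4), "detector")
  expect_error(extract_autofluorescence(empty), class = "sf_empty_input")
  expect_warning(extract_autofluorescence(subset_events(m, 1:10)),
                 regexp = "unstable")
})

test_that("unmixing inverts noise-free mixtures exactly (property over random sets)", {
  for (seed in 1:10) {
    set.seed(seed)
    nf <- sample(3:10, 1)
    nd <- nf + sample(2:8, 1)
    sigs <- make_signature_set(nf, nd, 0.95, seed = seed)
    M <- t(vapply(sigs$signatures, `[[`, numeric(nd), "profile"))
    A <- matrix(rexp(20 * nf, 1 / 500), 20, nf)
    af_int <- rexp(20, 1 / 100)
    Y <- A %*% M + outer(af_int, sigs$autofluorescence$profile)
    raw <- event_matrix(Y, sprintf("d%02d", 1:nd), "detector")
    um <- unmix(raw, sigs)
    expect_equal(unname(um$values[, seq_len(nf)]), A, tolerance = 1e-9)
    expect_equal(unname(um$values[, "AF"]), af_int, tolerance = 1e-9)
  }
})

test_that("unmixing matches the normal-equations oracle on noisy data", {
  sigs <- tiny_sigs(5, 20, seed = 3)
  M <- specflow:::mixing_matrix(sigs)
  set.seed(4)
  A <- matrix(rexp(50 * 5, 1 / 1000), 50, 5)
  Y <- A %*% t(M[, 1:5]) + matrix(rnorm(50 * 20, 0, 20), 50, 20)
  raw <- event_matrix(Y, sprintf("d%02d", 1:20), "detector")
  um <- unmix(raw, sigs)
  oracle <- Y %*% M %*% solve(crossprod(M))  # pseudoinverse solution
  expect_equal(unname(um$values), unname(oracle), tolerance = 1e-8)
})

test_that("pure single-fluorophore events load only their own channel", {
  sigs <- make_signature_set(4, 24, 0.5, seed = 11)
  M <- specflow:::mixing_matrix(sigs, include_af = FALSE)
  Y <- matrix(0, 4, 24)
  for (i in 1:4) Y[i, ] <- 5000 * M[, i]
  um <- unmix(event_matrix(Y, sprintf("d%02d", 1:24), "detector"), sigs)
  for (i in 1:4) {
    expect_equal(unname(um$values[i, i]), 5000, tolerance = 1e-6)
    expect_lt(max(abs(um$values[i, -i])), 1e-6)
  }
})

test_that("rank-deficient signature sets are rejected naming the colliding pair", {
  s1 <- spectral_signature("FITC", c(1, 2, 1, 0))
  s2 <- spectral_signature("GFP", c(1, 2, 1, 0))
  s3 <- spectral_signature("PE", c(0, 0, 1, 2))
  sigs <- signature_matrix(list(s1, s2, s3))
  raw <- event_matrix(matrix(1, 2, 4), paste0("d", 1:4), "detector")
  expect_error(unmix(raw, sigs), class = "sf_rank_deficient",
               regexp = "FITC / GFP|GFP / FITC")
})

test_that("adding the true autofluorescence endmember never increases residuals", {
  set.seed(21)
  sigs <- make_signature_set(6, 24, 0.9, seed = 21)
  M <- specflow:::mixing_matrix(sigs, include_af = FALSE)
  A <- matrix(rexp(100 * 6, 1 / 800), 100, 6)
  Y <- A %*% t(M) + outer(rexp(100, 1 / 200), sigs$autofluorescence$profile) +
    matrix(rnorm(2400, 0, 10), 100, 24)
  resid_norm <- function(s) {
    Mm <- specflow:::mixing_matrix(s)
    fit <- Y %*% Mm %*% solve(crossprod(Mm)) %*% t(Mm)
    sum((Y - fit)^2)
  }
  no_af <- signature_matrix(sigs$signatures)
  expect_lte(resid_norm(sigs), resid_norm(no_af))
})

test_that("compensation inverts percent spillover (closed-form 2x2 oracle)", {
  two <- function(c12) {
    m <- matrix(c(100, c12, 0, 100), 2, 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("A", "B")))
    compensation_matrix(m)
  }
  ev <- event_matrix(matrix(c(100, 10), 1, 2), c("A", "B"), "marker")

  # identity leaves data untouched
  ident <- identity_compensation(c("A", "B"))
  expect_equal(apply_compensation(ev, ident)$values, ev$values)

  # hand inversion: observed = true %*% S, S = [[1, c], [0, 1]]
  for (c12 in c(5, -2.79)) {
    comp <- apply_compensation(ev, two(c12))
    S <- matrix(c(1, c12 / 100, 0, 1), 2, 2, byrow = TRUE)
    expect_equal(unname(comp$values), unname(ev$values %*% solve(S)),
                 tolerance = 1e-12)
    # and explicitly: true B = observed B - c * true A
    expect_equal(unname(comp$values[1, 2]), 10 - (c12 / 100) * 100,
                 tolerance = 1e-12)
  }

  sing <- matrix(c(100, 100, 100, 100), 2, 2,
                 dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(apply_compensation(ev, compensation_matrix(sing)),
               class = "sf_singular_matrix")
})
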