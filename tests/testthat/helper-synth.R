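# Shared fixtures, built in code at test time.

# small well-separated signature set
tiny_sigs <- function(n = 4, nd = 12, seed = 42) {
  make_signature_set(n, nd, target_max_similarity = 0.9, seed = seed)
}

# minimal two-population marker-space templates over a toy 3-marker panel
toy_templates <- function() {
  mk <- c("CD45", "CDX", "ViaDye")
  list(
    population_template("X pos",
                        c(CD45 = "pos", CDX = "pos", ViaDye = "neg"), 0.4),
    population_template("X neg",
                        c(CD45 = "pos", CDX = "neg", ViaDye = "neg"), 0.6)
  )
}

# random event matrix
rand_events <- function(n = 50, p = 3, seed = 1, kind = "marker") {
  set.seed(seed)
  event_matrix(matrix(rexp(n * p, 1 / 100), n, p),
               paste0("M", seq_len(p)), kind)
}

expect_sf_error <- function(expr, class) {
  expect_error(expr, class = class)
}
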