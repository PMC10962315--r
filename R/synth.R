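#' @name synth
#' @title Synthetic spectral-flow simulator
#'
#' @description
#' Generates ground-truth-labelled synthetic cytometry data so every stage of
#' the pipeline — unmixing, QC, gating, profiling, integration — is testable
#' without instrument data. Populations are defined by templates mapping each
#' marker to an expression class (`neg`/`int`/`pos`/`hi`, log-normal on the
#' raw intensity scale, or `bg` for an unconstrained marker drawn positive at
#' a small background rate); events are mixed into detector space through a
#' signature matrix with a cellular autofluorescence term and heteroscedastic
#' Gaussian noise (SD `a + b * signal`). Acquisition artifacts (doublets,
#' dead cells, red-cell-like and debris events) mirror the populations the
#' standard pregates remove. All randomness flows from one seed.
NULL

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.null(seed) && exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# ---- signature sets ---------------------------------------------------------

#' Generate a synthetic spectral signature set
#'
#' Builds `n_fluors` smooth emission profiles over `n_detectors` detectors
#' (Gaussian main peak plus a small red-shifted shoulder, mimicking real dye
#' spectra) whose pairwise similarity indices all stay at or below
#' `target_max_similarity`, plus a broad autofluorescence endmember. A target
#' of 0 yields disjoint-support (orthonormal) signatures — one detector per
#' fluorophore. Construction is by iterative repair: offending pairs are
#' re-drawn with peaks pushed apart until the ceiling holds, or an
#' infeasibility error is raised.
#'
#' @param n_fluors number of fluorophores (at most `n_detectors`).
#' @param n_detectors instrument detector count (default 48, a four-laser
#'   full-spectrum configuration).
#' @param target_max_similarity pairwise similarity ceiling in \[0, 1\]
#'   (default 0.98, the panel-compatibility rule).
#' @param seed integer seed; the global RNG state is restored afterwards.
#' @param names optional fluorophore names (default F1..Fn).
#' @return a [signature_matrix()] with an autofluorescence endmember.
#' @export
make_signature_set <- function(n_fluors, n_detectors = 48,
                               target_max_similarity = 0.98, seed = NULL,
                               names = NULL) {
  if (n_fluors > n_detectors) {
    sf_stop("cannot fit more fluorophores than detectors", "sf_infeasible")
  }
  nms <- names %||% paste0("F", seq_len(n_fluors))
  if (length(nms) != n_fluors) sf_stop("wrong number of names", "sf_bad_input")
  with_seed(seed, {
    af <- spectral_signature("AF", exp(-((seq_len(n_detectors) - n_detectors / 3)^2) /
                                         (2 * (n_detectors / 2.5)^2)))
    if (target_max_similarity == 0) {
      sig_list <- lapply(seq_len(n_fluors), function(i) {
        p <- numeric(n_detectors); p[i] <- 1
        spectral_signature(nms[i], p)
      })
      return(signature_matrix(sig_list, autofluorescence = af))
    }
    det <- seq_len(n_detectors)
    peaks <- seq(1, n_detectors, length.out = n_fluors) +
      stats::runif(n_fluors, -0.3, 0.3)
    # narrow main peaks keep the mixing matrix well conditioned, so unmixing
    # does not amplify detector noise beyond the expression-class separation
    widths <- stats::runif(n_fluors, 0.5, 0.8)
    build <- function(i) {
      main <- stats::dnorm(det, peaks[i], widths[i])
      shoulder <- 0.04 * stats::dnorm(det, peaks[i] + 5, 3 * widths[i])
      spectral_signature(nms[i], main + shoulder)
    }
    sig_list <- lapply(seq_len(n_fluors), build)
    for (iter in seq_len(300)) {
      S <- similarity_matrix(signature_matrix(sig_list))
      diag(S) <- 0
      worst <- max(S)
      if (worst <= target_max_similarity) break
      idx <- which(S == worst, arr.ind = TRUE)[1, ]
      i <- idx[2]
      # push the second member of the worst pair away and narrow it
      peaks[i] <- peaks[i] + stats::runif(1, 0.5, 1.5) *
        sign(peaks[i] - peaks[idx[1]] + stats::runif(1, -0.1, 0.1))
      peaks[i] <- min(max(peaks[i], 1), n_detectors)
      widths[i] <- max(widths[i] * 0.9, 0.6)
      sig_list[[i]] <- build(i)
      if (iter == 300) {
        sf_stop(sprintf(
          "cannot reach pairwise similarity <= %.3f with %d fluorophores over %d detectors",
          target_max_similarity, n_fluors, n_detectors), "sf_infeasible")
      }
    }
    signature_matrix(sig_list, autofluorescence = af)
  })
}

# ---- templates --------------------------------------------------------------

#' Population template
#'
#' Generative description of one cell population: an expression class per
#' marker, a frequency, and a scatter profile.
#'
#' @param name population name (becomes the truth label).
#' @param levels named character vector mapping every marker to one of
#'   `"neg"`, `"int"`, `"pos"`, `"hi"`, `"bg"`.
#' @param frequency generation share (normalized across templates at
#'   simulation time).
#' @param scatter one of `"lymphocyte"`, `"monocyte"`, `"debris"`,
#'   `"rbc"`.
#' @return an object of class `population_template`.
#' @export
population_template <- function(name, levels, frequency = 1,
                                scatter = "lymphocyte") {
  ok <- c("neg", "int", "pos", "hi", "bg")
  if (!all(levels %in% ok)) {
    sf_stop(sprintf("unknown level(s): %s",
                    paste(setdiff(levels, ok), collapse = ", ")), "sf_bad_input")
  }
  scatter <- match.arg(scatter, c("lymphocyte", "monocyte", "debris", "rbc"))
  if (!is.finite(frequency) || frequency < 0) {
    sf_stop("frequency must be non-negative", "sf_bad_input")
  }
  structure(list(name = name, levels = levels, frequency = frequency,
                 scatter = scatter),
            class = "population_template")
}

merge_level <- function(current, rel, node, marker) {
  new <- switch(rel, "+" = "pos", "-" = "neg", "hi" = "hi", "lo" = "pos",
                "int" = "int")
  if (is.null(current)) return(new)
  if (current == new) return(current)
  compatible <- list(pos = c("hi", "int", "pos"), hi = "pos", int = "pos")
  if (new %in% (compatible[[current]] %||% character(0))) {
    # keep the more specific of the two
    return(if (current == "pos") new else current)
  }
  sf_stop(sprintf("gate '%s': contradictory requirements for marker '%s' (%s vs %s)",
                  node, marker, current, new),
          "sf_contradictory_path")
}

#' Derive generative templates from a gating tree
#'
#' Inverts gate definitions: for every canonical population, the threshold
#' terms along its root path become expression-class requirements
#' (`+` -> pos, `-` -> neg, `hi` -> hi, `int` -> int). Rectangle (scatter)
#' gates set the scatter profile via their `profile` hint. Markers left
#' unconstrained by the path default to the background class `"bg"`, unless
#' a biological override is supplied (e.g. B cells are HLA-DR positive even
#' though no B-cell gate uses HLA-DR — negatively-defined gates elsewhere in
#' the tree depend on it).
#'
#' @param tree a [gating_tree()].
#' @param frequencies named numeric generation shares per canonical
#'   population (default: equal shares).
#' @param overrides named list (per population) of named level vectors
#'   overriding the `"bg"` default for path-unconstrained markers.
#' @param baseline named level vector applied to every template's
#'   path-unconstrained markers before per-population overrides (e.g.
#'   `c(CD45 = "pos")`: the hierarchy starts below the CD45+ pregate, so no
#'   gate constrains CD45, yet every leukocyte expresses it).
#' @param viability name of the viability channel, forced to `"neg"`
#'   (live) in every template when present among the markers.
#' @return list of [population_template()] objects.
#' @export
templates_from_gating <- function(tree, frequencies = NULL, overrides = list(),
                                  baseline = c(CD45 = "pos"),
                                  viability = "ViaDye") {
  pops <- canonical_populations(tree)
  if (!length(pops)) sf_stop("tree has no canonical populations", "sf_bad_input")
  if (is.null(frequencies)) {
    frequencies <- stats::setNames(rep(1 / length(pops), length(pops)), pops)
  }
  parent_of <- vapply(tree$nodes, `[[`, character(1), "parent")
  lapply(pops, function(pop) {
    levels <- stats::setNames(rep("bg", length(tree$markers)), tree$markers)
    assigned <- list()
    scatter <- "lymphocyte"
    node <- pop
    chain <- character(0)
    while (node != "root") {
      chain <- c(node, chain)
      node <- parent_of[[node]]
    }
    for (nm in chain) {
      ex <- tree$nodes[[nm]]$expr
      if (ex$type == "rect") {
        scatter <- tree$nodes[[nm]]$profile %||% "lymphocyte"
      } else {
        for (term in ex$terms) {
          rel <- term$rel
          if (term$negate) {
            if (!rel %in% c("+", "-")) next  # negated band: leave unconstrained
            rel <- if (rel == "+") "-" else "+"
          }
          assigned[[term$marker]] <- merge_level(assigned[[term$marker]], rel,
                                                 nm, term$marker)
        }
      }
    }
    for (m in names(assigned)) levels[m] <- assigned[[m]]
    base_free <- intersect(setdiff(names(baseline), names(assigned)),
                           names(levels))
    levels[base_free] <- baseline[base_free]
    ov <- overrides[[pop]]
    if (!is.null(ov)) {
      free <- intersect(setdiff(names(ov), names(assigned)), names(levels))
      levels[free] <- ov[free]
    }
    if (viability %in% names(levels)) levels[viability] <- "neg"
    population_template(pop, levels, frequencies[[pop]] %||% 0, scatter)
  })
}

# ---- event synthesis --------------------------------------------------------

scatter_params <- list(
  lymphocyte = list(fsc = c(50000, 5000), ssc = c(20000, 3000)),
  monocyte   = list(fsc = c(90000, 7000), ssc = c(60000, 7000)),
  debris     = list(fsc = c(8000, 2500),  ssc = c(5000, 2000)),
  rbc        = list(fsc = c(15000, 3000), ssc = c(8000, 2500))
)

# raw marker abundances + scatter + truth for n events of given templates
draw_events <- function(templates, n, bg_rate, levels_def) {
  freqs <- vapply(templates, `[[`, numeric(1), "frequency")
  if (abs(sum(freqs) - 1) > 1e-9) freqs <- freqs / sum(freqs)
  nm <- vapply(templates, `[[`, character(1), "name")
  markers <- names(templates[[1]]$levels)
  pick <- sample.int(length(templates), n, replace = TRUE, prob = freqs)
  lv <- do.call(rbind, lapply(templates, function(t) t$levels))[pick, , drop = FALSE]
  is_bg <- lv == "bg"
  if (any(is_bg)) {
    lv[is_bg] <- ifelse(stats::runif(sum(is_bg)) < bg_rate, "pos", "neg")
  }
  A <- matrix(stats::rlnorm(length(lv), levels_def$meanlog[lv], levels_def$sdlog[lv]),
              nrow = n, dimnames = list(NULL, markers))
  prof <- vapply(templates, `[[`, character(1), "scatter")[pick]
  fsc <- ssc <- numeric(n)
  for (p in unique(prof)) {
    i <- prof == p
    sp <- scatter_params[[p]]
    fsc[i] <- stats::rnorm(sum(i), sp$fsc[1], sp$fsc[2])
    ssc[i] <- stats::rnorm(sum(i), sp$ssc[1], sp$ssc[2])
  }
  fsc <- pmax(fsc, 100); ssc <- pmax(ssc, 100)
  fsch <- fsc / stats::rnorm(n, 1, 0.03)
  list(A = A, fsc = fsc, ssc = ssc, fsch = fsch, truth = nm[pick])
}

#' Simulate one stained sample
#'
#' Draws per-event marker abundances from the population templates, adds
#' acquisition artifacts, and (in detector space) mixes abundances through
#' the signature matrix with a per-cell autofluorescence term and
#' heteroscedastic Gaussian noise of SD `a + b * signal`. Artifacts:
#' doublets are sums of two random singlets (FSC-H takes the larger of the
#' pair, so the FSC-A/FSC-H ratio doubles), dead cells carry a high
#' viability-dye signal, red-cell-like and debris events are unstained with
#' low scatter. Truth labels name the generating template or artifact class.
#' Deterministic per seed.
#'
#' @param templates list of [population_template()] over one marker set.
#' @param n_events total number of events (> 0).
#' @param sigs a [signature_matrix()] whose fluorophore names cover the
#'   template markers; required for `space = "detector"`.
#' @param space `"detector"` (mixed through the spectra) or `"marker"`
#'   (abundances directly, for pipeline stages downstream of unmixing).
#' @param artifacts list of artifact fractions `doublet`, `dead`, `rbc`,
#'   `debris` of `n_events`.
#' @param noise list with intercept `a` and slope `b` of the noise SD.
#' @param bg_rate probability that a background (`"bg"`) marker is positive.
#' @param af_meanlog,af_sdlog log-normal parameters of the per-cell
#'   autofluorescence intensity (detector space only).
#' @param viability viability channel name.
#' @param seed integer seed.
#' @param sample_id,batch_id identifiers for the returned matrix.
#' @param levels_def expression-class definitions ([default_levels()]).
#' @return an [event_matrix()] with truth labels (artifact classes
#'   `"doublet"`, `"dead"`, `"rbc"`, `"debris"`).
#' @export
simulate_sample <- function(templates, n_events, sigs = NULL,
                            space = c("detector", "marker"),
                            artifacts = list(doublet = 0.02, dead = 0.03,
                                             rbc = 0.03, debris = 0.02),
                            noise = list(a = 5, b = 0.02),
                            bg_rate = 0.002,
                            af_meanlog = log(300), af_sdlog = 0.3,
                            viability = "ViaDye",
                            seed = NULL, sample_id = "synthetic",
                            batch_id = NULL, levels_def = default_levels()) {
  space <- match.arg(space)
  if (n_events <= 0) sf_stop("n_events must be positive", "sf_bad_input")
  markers <- names(templates[[1]]$levels)
  with_seed(seed, {
    n_dbl <- round(n_events * (artifacts$doublet %||% 0))
    n_dead <- round(n_events * (artifacts$dead %||% 0))
    n_rbc <- round(n_events * (artifacts$rbc %||% 0))
    n_debris <- round(n_events * (artifacts$debris %||% 0))
    n_real <- n_events - n_dbl - n_dead - n_rbc - n_debris
    if (n_real <= 0) sf_stop("artifact fractions exhaust the sample", "sf_bad_input")

    main <- draw_events(templates, n_real, bg_rate, levels_def)
    parts <- list(main)

    if (n_dead > 0) {
      d <- draw_events(templates, n_dead, bg_rate, levels_def)
      if (viability %in% markers) {
        d$A[, viability] <- stats::rlnorm(n_dead, levels_def$meanlog[["hi"]],
                                          levels_def$sdlog[["hi"]])
      }
      d$truth <- rep("dead", n_dead)
      parts <- c(parts, list(d))
    }
    if (n_dbl > 0) {
      a <- draw_events(templates, n_dbl, bg_rate, levels_def)
      b <- draw_events(templates, n_dbl, bg_rate, levels_def)
      dbl <- list(A = a$A + b$A, fsc = a$fsc + b$fsc, ssc = a$ssc + b$ssc,
                  fsch = pmax(a$fsch, b$fsch), truth = rep("doublet", n_dbl))
      parts <- c(parts, list(dbl))
    }
    unstained <- function(n, profile, label) {
      lv <- matrix("neg", n, length(markers), dimnames = list(NULL, markers))
      A <- matrix(stats::rlnorm(length(lv), levels_def$meanlog[lv],
                                levels_def$sdlog[lv]),
                  nrow = n, dimnames = list(NULL, markers))
      sp <- scatter_params[[profile]]
      fsc <- pmax(stats::rnorm(n, sp$fsc[1], sp$fsc[2]), 100)
      list(A = A, fsc = fsc,
           ssc = pmax(stats::rnorm(n, sp$ssc[1], sp$ssc[2]), 100),
           fsch = fsc / stats::rnorm(n, 1, 0.03), truth = rep(label, n))
    }
    if (n_rbc > 0) parts <- c(parts, list(unstained(n_rbc, "rbc", "rbc")))
    if (n_debris > 0) parts <- c(parts, list(unstained(n_debris, "debris", "debris")))

    A <- do.call(rbind, lapply(parts, `[[`, "A"))
    scatter <- cbind(`FSC-A` = unlist(lapply(parts, `[[`, "fsc")),
                     `FSC-H` = unlist(lapply(parts, `[[`, "fsch")),
                     `SSC-A` = unlist(lapply(parts, `[[`, "ssc")))
    truth <- unlist(lapply(parts, `[[`, "truth"))
    perm <- sample.int(nrow(A))
    A <- A[perm, , drop = FALSE]
    scatter <- scatter[perm, , drop = FALSE]
    truth <- truth[perm]

    if (space == "detector") {
      if (is.null(sigs)) sf_stop("detector-space simulation needs signatures",
                                 "sf_bad_input")
      M <- mixing_matrix(sigs, include_af = FALSE)
      miss <- setdiff(markers, colnames(M))
      if (length(miss)) {
        sf_stop(sprintf("signatures missing for marker(s): %s",
                        paste(miss, collapse = ", ")), "sf_missing_channel")
      }
      Y <- A %*% t(M[, markers, drop = FALSE])
      if (!is.null(sigs$autofluorescence)) {
        af_int <- stats::rlnorm(nrow(Y), af_meanlog, af_sdlog)
        Y <- Y + outer(af_int, sigs$autofluorescence$profile)
      }
      if ((noise$a %||% 0) > 0 || (noise$b %||% 0) > 0) {
        Y <- Y + stats::rnorm(length(Y), 0, noise$a + noise$b * abs(Y))
      }
      colnames(Y) <- sprintf("det%02d", seq_len(ncol(Y)))
      vals <- cbind(Y, scatter)
      kinds <- c(rep("detector", ncol(Y)), rep("scatter", 3))
    } else {
      if ((noise$a %||% 0) > 0 || (noise$b %||% 0) > 0) {
        A <- A + stats::rnorm(length(A), 0, noise$a + noise$b * abs(A))
      }
      vals <- cbind(A, scatter)
      kinds <- c(ifelse(markers == viability, "viability", "marker"),
                 rep("scatter", 3))
    }
    event_matrix(vals, colnames(vals), kinds, sample_id = sample_id,
                 batch_id = batch_id, truth_labels = truth)
  })
}

# ---- batches ----------------------------------------------------------------

#' Per-batch technical-shift specification
#'
#' Emulates the run-to-run variation of acquisitions separated by weeks:
#' each batch gets an independent per-channel multiplicative gain
#' (log-normal) and additive offset (Gaussian, raw intensity units) applied
#' to its fluorescence channels.
#'
#' @param gain_log_sd SD of the per-channel log gain (0 = no gain shifts).
#' @param offset_sd SD of the per-channel additive offset.
#' @return an object of class `batch_effect_spec`.
#' @export
batch_effect_spec <- function(gain_log_sd = 0.5, offset_sd = 300) {
  if (gain_log_sd < 0 || offset_sd < 0) {
    sf_stop("batch effect magnitudes must be non-negative", "sf_bad_input")
  }
  structure(list(gain_log_sd = gain_log_sd, offset_sd = offset_sd),
            class = "batch_effect_spec")
}

#' Simulate a multi-batch experiment
#'
#' All batches share the same population templates but receive independent
#' per-channel gain/offset shifts; optionally one batch carries an extra
#' batch-unique population (the donor-unique-cluster scenario, e.g. a
#' lymphoma clone present in a single donor).
#'
#' @param templates shared list of [population_template()].
#' @param n_events events per batch.
#' @param n_batches number of batches (>= 2).
#' @param batch_effects a [batch_effect_spec()].
#' @param unique_population optional [population_template()] injected into
#'   batch `unique_batch` at generation share `unique_frequency`.
#' @param unique_batch,unique_frequency see above.
#' @param seed integer seed driving all per-batch randomness.
#' @param ... passed to [simulate_sample()] (e.g. `space`, `artifacts`).
#' @return list of [event_matrix()] objects with batch ids "batch1"...
#' @export
simulate_batches <- function(templates, n_events, n_batches = 3,
                             batch_effects = batch_effect_spec(),
                             unique_population = NULL, unique_batch = 1,
                             unique_frequency = 0.3, seed = 1, ...) {
  if (n_batches < 2) sf_stop("need at least two batches", "sf_bad_input")
  lapply(seq_len(n_batches), function(b) {
    tpl <- templates
    if (!is.null(unique_population) && b == unique_batch) {
      shrink <- 1 - unique_frequency
      tpl <- lapply(tpl, function(t) { t$frequency <- t$frequency * shrink; t })
      up <- unique_population
      up$frequency <- unique_frequency
      tpl <- c(tpl, list(up))
    }
    m <- simulate_sample(tpl, n_events, seed = seed + 1000L * b,
                         sample_id = paste0("batch", b),
                         batch_id = paste0("batch", b), ...)
    with_seed(seed + 1000L * b + 500L, {
      fl <- m$channel_kinds %in% c("marker", "detector", "viability")
      gains <- exp(stats::rnorm(sum(fl), 0, batch_effects$gain_log_sd))
      offsets <- stats::rnorm(sum(fl), 0, batch_effects$offset_sd)
      m$values[, fl] <- pmax(sweep(sweep(m$values[, fl, drop = FALSE], 2, gains, `*`),
                                   2, offsets, `+`), 0)
    })
    m
  })
}
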