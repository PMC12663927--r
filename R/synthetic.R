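#' Configuration for the synthetic dataset generator
#'
#' Bundles the parameters of the generative model used to test the
#' analysis pipeline: sequences evolve site-independently over the 20
#' amino acids down a random coalescent tree, a latent ln-rate evolves
#' as Brownian motion along the same tree (so similar sequences have
#' similar rates), optional causal positions add a fixed ln-rate effect
#' when a trigger residue is present, and noisy observations are
#' generated under the pipeline's measurement model: a multiplicative
#' coupled-assay underestimation `beta`, log-normal batch effects, a
#' shared control variant in every batch, and literature-style direct
#' measurements at non-reference temperatures governed by a true Q10.
#'
#' @param n_leaves Number of leaf sequences.
#' @param L Alignment length (sites; no indels are simulated).
#' @param mu Substitutions per site per unit branch length.
#' @param sigma2 Brownian-motion variance of the latent ln-rate per unit
#'   branch length.
#' @param y0 Root ln-rate; the default `log(7)` centres true rates on
#'   the scale typical of measured carboxylation rates (1/s at 30 C).
#' @param n_causal Number of planted causal positions.
#' @param delta ln-rate effect added when a causal position carries its
#'   trigger residue.
#' @param form_labels Rubisco form labels assigned to the clades
#'   obtained by cutting the tree into `length(form_labels)` groups.
#' @param beta Multiplicative factor by which the coupled assay
#'   underestimates true rates.
#' @param sigma_obs Log-scale SD of observation noise.
#' @param sigma_batch Log-scale SD of multiplicative batch effects.
#' @param batch_size Measurements per batch.
#' @param control_rate True rate (1/s) of the control variant measured
#'   in every batch.
#' @param characterized_frac Fraction of leaves flagged characterized.
#' @param literature_frac Fraction of characterized leaves observed
#'   literature-style (direct assay, off-reference temperature) instead
#'   of through the coupled pipeline.
#' @param temp_range Range (degrees C) literature assay temperatures are
#'   drawn from uniformly.
#' @param q10 True Q10 governing the temperature dependence of rates.
#' @param tree_model Tree shape passed to [simulate_tree()].
#' @param seed Master seed; all randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_leaves = 150, L = 300, mu = 0.15, sigma2 = 0.2,
                       y0 = log(7), n_causal = 0, delta = 1,
                       form_labels = c("II", "II/III"), beta = 2.1,
                       sigma_obs = 0.2, sigma_batch = 0.15,
                       batch_size = 16, control_rate = 7,
                       characterized_frac = 0.5, literature_frac = 0.3,
                       temp_range = c(20, 40), q10 = 2.2,
                       tree_model = "coalescent", seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_leaves >= 2, L >= 1, mu >= 0, sigma2 >= 0, beta > 0,
            sigma_obs >= 0, sigma_batch >= 0, n_causal <= L,
            characterized_frac > 0, characterized_frac <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# evaluate `expr` under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a random coalescent tree
#'
#' A standard-coalescent binary tree with positive branch lengths,
#' serializable as newick via [ape::write.tree()]. Deterministic given
#' the seed.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param seed Seed.
#' @param model `"coalescent"` (standard coalescent; terminal branches
#'   shrink near the present, so many leaves have a near-identical
#'   sibling) or `"yule"` (pure-birth, rescaled to the same expected
#'   depth; terminal branches stay long, spreading the leaves --
#'   resembling a set of screened cluster representatives).
#' @return A `phylo` object with tips `t1 ... tn`.
#' @export
simulate_tree <- function(n_leaves, seed = 1,
                          model = c("coalescent", "yule")) {
  model <- match.arg(model)
  stopifnot(n_leaves >= 2)
  with_seed(seed, {
    if (model == "coalescent") {
      ape::rcoal(n_leaves)
    } else {
      tr <- ape::rphylo(n_leaves, birth = 1, death = 0)
      # rescale to depth 2, the expected depth of a large coalescent
      # tree, so mu and sigma2 mean the same thing under both models
      tr$edge.length <- tr$edge.length * 2 /
        max(ape::node.depth.edgelength(tr))
      tr
    }
  })
}

# evolve sequences down the tree: uniform 20-state jump model, no indels
simulate_sequences <- function(tree, L, mu, seed) {
  n_tip <- length(tree$tip.label)
  with_seed(seed, {
    seqs <- vector("list", max(tree$edge))
    root <- n_tip + 1L
    seqs[[root]] <- sample(AA_STATES, L, replace = TRUE)
    # cladewise order visits each parent edge before its children
    tr <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      t_len <- tr$edge.length[e]
      p_diff <- (19 / 20) * (1 - exp(-(20 / 19) * mu * t_len))
      s <- seqs[[parent]]
      hit <- runif(L) < p_diff
      if (any(hit)) {
        # jump to a uniformly drawn different state
        s[hit] <- vapply(s[hit], function(a)
          sample(setdiff(AA_STATES, a), 1), character(1))
      }
      seqs[[child]] <- s
    }
    out <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""),
                  character(1))
    setNames(out, tree$tip.label)
  })
}

# Brownian motion of the latent ln-rate along the tree
simulate_bm <- function(tree, y0, sigma2, seed) {
  n_tip <- length(tree$tip.label)
  with_seed(seed, {
    val <- numeric(max(tree$edge))
    val[n_tip + 1L] <- y0
    tr <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      val[child] <- val[parent] + rnorm(1, 0, sqrt(sigma2 * tr$edge.length[e]))
    }
    setNames(val[seq_len(n_tip)], tree$tip.label)
  })
}

#' Generate a synthetic rubisco-style dataset
#'
#' Draws a tree, leaf sequences, latent true ln-rates and noisy assay
#' observations under the model described in [sim_config()]. Causal
#' positions (if requested) are chosen among polymorphic sites whose
#' second-most-common residue has frequency in `[0.2, 0.8]`; that
#' residue is the trigger. Rubisco forms are assigned to clades by
#' cutting the (ultrametric) tree into `length(form_labels)` groups.
#'
#' Observations: characterized leaves are split into pipeline
#' measurements (coupled assay at 30 C, batched, biased low by `beta`,
#' batch-scaled) and literature measurements (direct assay at a drawn
#' temperature, with the true Q10 applied); all carry multiplicative
#' log-normal noise `sigma_obs`. The control variant is measured in
#' every pipeline batch.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `synthetic_dataset` with elements `tree`,
#'   `alignment` (alignment tibble with `true_ln_rate`), `records` (a
#'   rate table), and `truth` (all injected parameters, the causal
#'   table and batch effects).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  tree <- simulate_tree(cfg$n_leaves, seed = cfg$seed,
                        model = cfg$tree_model)
  seqs <- simulate_sequences(tree, cfg$L, cfg$mu, seed = cfg$seed + 1e3)
  y <- simulate_bm(tree, cfg$y0, cfg$sigma2, seed = cfg$seed + 2e3)

  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                  nrow = length(seqs), byrow = TRUE)
  causal <- tibble(position = integer(), residue = character(),
                   delta = numeric())
  if (cfg$n_causal > 0) {
    minor <- apply(chars, 2, function(col) {
      tab <- sort(table(col), decreasing = TRUE)
      if (length(tab) < 2) return(c(freq = 0))
      c(freq = unname(tab[2]) / length(col))
    })
    eligible <- which(minor >= 0.2 & minor <= 0.8)
    # identifiability condition: the trigger's carrier set must differ
    # from every other site's residue indicator (or its complement) by
    # at least 3 leaves -- a signal whose carriers coincide with a
    # background partition cannot be attributed to its position by any
    # method, and sequences evolved on a shared tree produce such
    # confounded partitions through linkage
    trigger_of <- function(j) names(sort(table(chars[, j]),
                                         decreasing = TRUE))[2]
    n_lv <- nrow(chars)
    ind <- NULL
    ind_pos <- integer(0)
    for (j in seq_len(ncol(chars))) {
      sts <- unique(chars[, j])
      ind <- cbind(ind, vapply(sts, function(a) chars[, j] == a,
                               logical(n_lv)))
      ind_pos <- c(ind_pos, rep(j, length(sts)))
    }
    eligible <- eligible[vapply(eligible, function(j) {
      v <- chars[, j] == trigger_of(j)
      other <- ind[, ind_pos != j, drop = FALSE]
      d <- colSums(other != v)
      all(pmin(d, n_lv - d) >= 3)
    }, logical(1))]
    if (length(eligible) < cfg$n_causal) {
      abort("not enough polymorphic sites for the requested causal positions")
    }
    picked <- with_seed(cfg$seed + 3e3,
                        sort(sample(eligible, cfg$n_causal)))
    trigger <- vapply(picked, trigger_of, character(1))
    causal <- tibble(position = picked, residue = trigger, delta = cfg$delta)
    for (k in seq_len(nrow(causal))) {
      hit <- chars[, causal$position[k]] == causal$residue[k]
      y[hit] <- y[hit] + causal$delta[k]
    }
  }

  form <- rep(cfg$form_labels[1], cfg$n_leaves)
  if (length(cfg$form_labels) > 1) {
    grp <- stats::cutree(ape::as.hclust.phylo(tree),
                         k = length(cfg$form_labels))
    form <- cfg$form_labels[grp[tree$tip.label]]
  }

  characterized <- with_seed(cfg$seed + 4e3, {
    idx <- sample.int(cfg$n_leaves, round(cfg$characterized_frac * cfg$n_leaves))
    seq_len(cfg$n_leaves) %in% idx
  })

  aln <- as_alignment(tibble(
    id = tree$tip.label,
    seq = unname(seqs[tree$tip.label]),
    form = form,
    characterized = characterized,
    complete = TRUE,
    true_ln_rate = unname(y[tree$tip.label])
  ))

  obs <- with_seed(cfg$seed + 5e3, {
    char_ids <- aln$id[aln$characterized]
    n_char <- length(char_ids)
    lit <- sample(c(TRUE, FALSE), n_char, replace = TRUE,
                  prob = c(cfg$literature_frac, 1 - cfg$literature_frac))
    pipe_ids <- char_ids[!lit]
    lit_ids <- char_ids[lit]
    true_rate <- exp(aln$true_ln_rate[match(char_ids, aln$id)])
    names(true_rate) <- char_ids

    n_batch <- max(1L, ceiling(length(pipe_ids) / cfg$batch_size))
    batch_of <- rep(seq_len(n_batch), each = cfg$batch_size,
                    length.out = length(pipe_ids))
    batch_effect <- exp(rnorm(n_batch, 0, cfg$sigma_batch))
    pipe <- tibble(
      variant_id = pipe_ids,
      kcat_c = unname(true_rate[pipe_ids]) / cfg$beta *
        batch_effect[batch_of] *
        exp(rnorm(length(pipe_ids), 0, cfg$sigma_obs)),
      temp_c = 30,
      assay = "coupled",
      batch_id = paste0("b", batch_of),
      source = "pipeline"
    )
    ctrl <- tibble(
      variant_id = "control",
      kcat_c = cfg$control_rate / cfg$beta * batch_effect *
        exp(rnorm(n_batch, 0, cfg$sigma_obs)),
      temp_c = 30,
      assay = "coupled",
      batch_id = paste0("b", seq_len(n_batch)),
      source = "pipeline"
    )
    lit_temp <- runif(length(lit_ids), cfg$temp_range[1], cfg$temp_range[2])
    lit_tbl <- tibble(
      variant_id = lit_ids,
      kcat_c = unname(true_rate[lit_ids]) * cfg$q10^((lit_temp - 30) / 10) *
        exp(rnorm(length(lit_ids), 0, cfg$sigma_obs)),
      temp_c = lit_temp,
      assay = "direct",
      batch_id = NA_character_,
      source = "literature"
    )
    list(records = as_rate_records(dplyr::bind_rows(pipe, ctrl, lit_tbl)),
         batch_effect = batch_effect)
  })

  structure(list(
    tree = tree,
    alignment = aln,
    records = obs$records,
    truth = list(cfg = cfg, causal = causal,
                 batch_effect = obs$batch_effect,
                 true_ln_rate = setNames(aln$true_ln_rate, aln$id))
  ), class = "synthetic_dataset")
}

#' Simulate paired coupled/direct rate measurements
#'
#' Draws `n_pairs` variants with log-normal true rates and observes each
#' through both assay types: the coupled observation is biased low by
#' `beta`, and both observations carry independent log-normal noise.
#' Used to study recovery of the assay-calibration factor.
#'
#' @param n_pairs Number of variants measured by both assays.
#' @param beta True multiplicative coupled-assay bias.
#' @param sigma_obs Log-scale SD of observation noise per measurement.
#' @param sigma_rate Log-scale SD of true rates around `log(7)`.
#' @param seed Seed.
#' @return A tibble with columns `k_coupled`, `k_direct`, `k_true`.
#' @export
simulate_rate_pairs <- function(n_pairs = 11, beta = 2.1, sigma_obs = 0.2,
                                sigma_rate = 0.8, seed = 1) {
  with_seed(seed, {
    k <- exp(rnorm(n_pairs, log(7), sigma_rate))
    tibble(
      k_coupled = k / beta * exp(rnorm(n_pairs, 0, sigma_obs)),
      k_direct = k * exp(rnorm(n_pairs, 0, sigma_obs)),
      k_true = k
    )
  })
}

#' Parameter-recovery experiment on synthetic data
#'
#' Runs the analysis chain on one synthetic dataset and compares
#' estimates with the injected truth: harmonizes the observed records
#' (Q10 correction of literature rates, control normalization of
#' pipeline batches), fits the assay-correction factor on simulated
#' coupled/direct pairs and checks whether its confidence interval
#' covers the true `beta`, benchmarks the requested model by
#' identity-thresholded leave-one-out cross-validation, and (when causal
#' positions were planted) reports the best rank any of them attains in
#' the position-association score.
#'
#' @param cfg A [sim_config()].
#' @param thresholds Identity thresholds for the cross-validation.
#' @param n_pairs Coupled/direct pairs used for the calibration fit.
#' @param model Prediction model to benchmark.
#' @param association Also run the position-association analysis
#'   (requires `cfg$n_causal > 0` to report a rank).
#' @param n_iterations Association iterations (when `association`).
#' @return A list with elements `correction` (the fit), `beta_true`,
#'   `ci_covers_beta`, `cv` (a `cv_result`), `harmonized` (records),
#'   and optionally `association` and `causal_best_rank`.
#' @export
recovery_experiment <- function(cfg = sim_config(), thresholds = c(0.5, 0.8, 0.9),
                                n_pairs = 11, model = "svr",
                                association = FALSE, n_iterations = 30) {
  ds <- simulate_dataset(cfg)
  rec <- ds$records

  pipe <- rec[rec$source == "pipeline", ]
  lit <- q10_correct(rec[rec$source == "literature", ], q10 = cfg$q10)
  pipe <- normalize_to_control(pipe, control_id = "control")

  pairs <- simulate_rate_pairs(n_pairs = n_pairs, beta = cfg$beta,
                               sigma_obs = cfg$sigma_obs,
                               seed = cfg$seed + 6e3)
  fit <- fit_assay_correction(pairs[, c("k_coupled", "k_direct")])
  pipe <- apply_correction(pipe, fit)

  harmonized <- dplyr::bind_rows(
    pipe[pipe$variant_id != "control", ], lit
  )

  cv_data <- ds$alignment[ds$alignment$characterized, ]
  cv_data <- with_seed(cfg$seed + 7e3, {
    cv_data$kcat_c <- exp(cv_data$true_ln_rate +
                            rnorm(nrow(cv_data), 0, cfg$sigma_obs))
    cv_data
  })
  cv <- loo_crossval(cv_data, model = model, thresholds = thresholds)

  out <- list(
    correction = fit,
    beta_true = cfg$beta,
    ci_covers_beta = fit$ci_low <= cfg$beta && cfg$beta <= fit$ci_high,
    cv = cv,
    harmonized = harmonized
  )
  if (association) {
    assoc <- fit_position_association(cv_data, n_iterations = n_iterations,
                                      seed = cfg$seed + 8e3)
    out$association <- assoc
    if (nrow(ds$truth$causal) > 0) {
      out$causal_best_rank <-
        min(assoc$rank[assoc$column %in% ds$truth$causal$position])
    }
  }
  out
}
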