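test_that("simulated trees are deterministic with the right leaf count", {
  t1 <- simulate_tree(10, seed = 4)
  t2 <- simulate_tree(10, seed = 4)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  for (n in c(2, 10, 100)) {
    expect_equal(length(simulate_tree(n, seed = 1)$tip.label), n)
  }
  cherry <- simulate_tree(2, seed = 1)
  expect_equal(cherry$Nnode, 1)
  expect_true(all(cherry$edge.length > 0))
})

test_that("degenerate generator limits behave as closed forms dictate", {
  # mu = 0: all sequences identical
  ds <- simulate_dataset(sim_config(n_leaves = 12, L = 40, mu = 0, seed = 2))
  expect_equal(length(unique(ds$alignment$seq)), 1)

  # sigma2 = 0 and no causal effects: every true rate is exp(y0)
  ds0 <- simulate_dataset(sim_config(n_leaves = 12, L = 40, sigma2 = 0,
                                     n_causal = 0, y0 = log(7), seed = 3))
  expect_equal(ds0$alignment$true_ln_rate, rep(log(7), 12))

  # noise-free, bias-free observation at 30 C reproduces truth exactly
  dsn <- simulate_dataset(sim_config(n_leaves = 16, L = 30, sigma_obs = 0,
                                     beta = 1, sigma_batch = 0,
                                     temp_range = c(30, 30), seed = 4))
  rec <- dsn$records
  rec <- rec[rec$variant_id != "control", ]
  truth <- exp(dsn$truth$true_ln_rate[rec$variant_id])
  expect_equal(rec$kcat_c, unname(truth))
})

test_that("the generator is deterministic and observations derive from truth", {
  cfg <- sim_config(n_leaves = 15, L = 25, seed = 11)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$alignment, d2$alignment)
  expect_identical(d1$records, d2$records)

  # pipeline observations: true/beta * batch_effect * noise, so after
  # dividing out the known truth and batch effect the residual noise is
  # log-normal with the configured sd (loose sanity bound)
  pipe <- d1$records[d1$records$source == "pipeline" &
                       d1$records$variant_id != "control", ]
  be <- d1$truth$batch_effect[as.integer(sub("b", "", pipe$batch_id))]
  resid <- log(pipe$kcat_c) -
    (d1$truth$true_ln_rate[pipe$variant_id] - log(cfg$beta) + log(be))
  expect_lt(max(abs(resid)), 4 * cfg$sigma_obs)
})

test_that("closer sequences have closer rates (phylogenetic signal)", {
  ok <- 0L
  n_rep <- 100
  for (seed in seq_len(n_rep)) {
    ds <- simulate_dataset(sim_config(n_leaves = 25, L = 120, seed = seed))
    idm <- identity_matrix(ds$alignment)
    y <- ds$alignment$true_ln_rate
    dy <- abs(outer(y, y, "-"))
    ut <- upper.tri(idm)
    if (cor(idm[ut], -dy[ut]) > 0) ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.95)
})

test_that("per-form true rates look log-normal", {
  ds <- simulate_dataset(sim_config(n_leaves = 120, L = 60, seed = 21))
  for (f in unique(ds$alignment$form)) {
    y <- ds$alignment$true_ln_rate[ds$alignment$form == f]
    if (length(y) >= 10 && length(y) <= 5000 && sd(y) > 0) {
      expect_gt(stats::shapiro.test(y)$p.value, 0.01)
    }
  }
})

test_that("cherry pairs are more alike than random pairs on average", {
  id_cherry <- dy_cherry <- id_rand <- dy_rand <- numeric(0)
  for (seed in 1:20) {
    ds <- simulate_dataset(sim_config(n_leaves = 30, L = 80, seed = seed))
    tr <- ds$tree
    idm <- identity_matrix(ds$alignment)
    y <- setNames(ds$alignment$true_ln_rate, ds$alignment$id)
    # cherries: internal nodes whose two children are both tips
    n_tip <- length(tr$tip.label)
    kids <- split(tr$edge[, 2], tr$edge[, 1])
    for (node in names(kids)) {
      pair <- kids[[node]]
      if (length(pair) == 2 && all(pair <= n_tip)) {
        a <- tr$tip.label[pair[1]]; b <- tr$tip.label[pair[2]]
        id_cherry <- c(id_cherry, idm[a, b])
        dy_cherry <- c(dy_cherry, abs(y[a] - y[b]))
      }
    }
    set.seed(seed)
    rnd <- replicate(20, sample(tr$tip.label, 2))
    id_rand <- c(id_rand, idm[cbind(rnd[1, ], rnd[2, ])])
    dy_rand <- c(dy_rand, abs(y[rnd[1, ]] - y[rnd[2, ]]))
  }
  expect_gt(mean(id_cherry), mean(id_rand))
  expect_lt(mean(dy_cherry), mean(dy_rand))
})

test_that("simulated assay pairs recover a trivial calibration exactly", {
  pairs <- simulate_rate_pairs(n_pairs = 8, beta = 1, sigma_obs = 0, seed = 3)
  fit <- fit_assay_correction(pairs)
  expect_equal(fit$factor, 1)
  expect_identical(pairs, simulate_rate_pairs(n_pairs = 8, beta = 1,
                                              sigma_obs = 0, seed = 3))
})

test_that("the recovery experiment returns coherent estimates", {
  cfg <- sim_config(n_leaves = 40, L = 80, seed = 31)
  out <- recovery_experiment(cfg, thresholds = c(0.5, 0.8), model = "nn")
  expect_s3_class(out$cv, "cv_result")
  expect_equal(out$beta_true, 2.1)
  expect_true(is.logical(out$ci_covers_beta))
  expect_gt(out$correction$factor, 1)
  # harmonized output carries no control rows and single source labels
  expect_false("control" %in% out$harmonized$variant_id)
})
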