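# permutation-definition Shapley oracle: average the marginal
# contribution of each feature over all orderings, with the same
# cover-weighted conditional expectation as value function
shapley_oracle <- function(tree, row) {
  feats <- rubiscope:::tree_features(tree)
  u <- length(feats)
  if (u == 0) return(list(phi = numeric(0), base = tree$value))
  val <- function(s) rubiscope:::descend_tree(tree, row, used = s)
  perms <- gtools_permutations(u)
  phi <- setNames(numeric(u), feats)
  for (p in seq_len(nrow(perms))) {
    s <- integer(0)
    v_prev <- val(s)
    for (k in perms[p, ]) {
      s <- c(s, feats[k])
      v_now <- val(s)
      phi[as.character(feats[k])] <- phi[as.character(feats[k])] +
        (v_now - v_prev)
      v_prev <- v_now
    }
  }
  list(phi = phi / nrow(perms), base = val(integer(0)))
}

# all permutations of 1..n (tiny n), without external packages
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1
  for (k in seq_len(n)) {
    for (j in seq_len(nrow(sub))) {
      rest <- setdiff(seq_len(n), k)
      out[r, ] <- c(k, rest[sub[j, ]])
      r <- r + 1
    }
  }
  out
}

random_tree_data <- function(n, p, seed) {
  set.seed(seed)
  x <- matrix(rbinom(n * p, 1, 0.5), nrow = n)
  y <- rnorm(n) + 1.5 * x[, 1] - x[, 2] * x[, 3]
  list(x = x, y = y)
}

test_that("tree splits maximize variance reduction (brute-force check)", {
  d <- random_tree_data(40, 6, seed = 61)
  tree <- fit_regression_tree(d$x, d$y, max_depth = 1)
  # exhaustive gain scan at the root
  gains <- vapply(seq_len(ncol(d$x)), function(j) {
    n1 <- sum(d$x[, j]); n0 <- length(d$y) - n1
    if (n1 == 0 || n0 == 0) return(-Inf)
    m1 <- mean(d$y[d$x[, j] == 1]); m0 <- mean(d$y[d$x[, j] == 0])
    n1 * n0 / length(d$y) * (m1 - m0)^2
  }, numeric(1))
  expect_equal(tree$feature, which.max(gains))
})

test_that("tree predictions are leaf means of the training rows", {
  d <- random_tree_data(60, 8, seed = 62)
  tree <- fit_regression_tree(d$x, d$y, max_depth = 3)
  pred <- predict_tree(tree, d$x)
  # rows mapped to the same leaf share a prediction equal to their mean
  leaves <- split(seq_along(d$y), round(pred, 12))
  for (rows in leaves) {
    expect_equal(mean(d$y[rows]), pred[rows[1]])
  }
})

test_that("Shapley attributions are locally accurate to machine precision", {
  for (seed in 61:64) {
    d <- random_tree_data(50, 7, seed = seed)
    tree <- fit_regression_tree(d$x, d$y, max_depth = 3)
    pred <- predict_tree(tree, d$x)
    for (i in sample(50, 10)) {
      sh <- tree_shapley(tree, d$x[i, ])
      expect_equal(sh$base + sum(sh$phi), pred[i], tolerance = 1e-12)
    }
  }
})

test_that("Shapley values match the permutation-definition oracle", {
  d <- random_tree_data(40, 5, seed = 65)
  tree <- fit_regression_tree(d$x, d$y, max_depth = 3)
  for (i in 1:8) {
    sh <- tree_shapley(tree, d$x[i, ])
    orc <- shapley_oracle(tree, d$x[i, ])
    expect_equal(sh$base, orc$base)
    expect_equal(unname(sh$phi), unname(orc$phi[names(sh$phi)]))
  }
})

test_that("duplicated identical features share attribution symmetrically", {
  set.seed(66)
  x1 <- rbinom(40, 1, 0.5)
  x <- cbind(x1, x1, rbinom(40, 1, 0.5))
  y <- 2 * x1 + rnorm(40, 0, 0.1)
  tree <- fit_regression_tree(x, y, max_depth = 2)
  # a greedy tree uses only one of the identical copies; attributions
  # must be invariant to which copy it is: refit with the copies swapped
  # and compare the (order-free) attribution values for the same row
  tree_sw <- fit_regression_tree(x[, c(2, 1, 3)], y, max_depth = 2)
  sh <- tree_shapley(tree, x[5, ])
  sh_sw <- tree_shapley(tree_sw, x[5, c(2, 1, 3)])
  expect_equal(unname(sort(sh$phi)), unname(sort(sh_sw$phi)))
})

test_that("constant targets yield zero attributions everywhere", {
  aln <- random_alignment(25, 30, seed = 67)
  aln$kcat_c <- 5
  assoc <- fit_position_association(aln, n_iterations = 5, seed = 1)
  expect_true(all(assoc$score == 0))
})

test_that("a planted causal position ranks first", {
  hits <- 0L
  for (seed in 1:5) {
    # one position carries the signal; everything else is noise (no
    # Brownian rate drift, fast-evolving background sequences)
    ds <- simulate_dataset(sim_config(n_leaves = 50, L = 80, mu = 1.5,
                                      n_causal = 1, delta = 1, sigma2 = 0,
                                      characterized_frac = 1, seed = seed))
    aln <- ds$alignment
    set.seed(seed)
    aln$kcat_c <- exp(aln$true_ln_rate + rnorm(nrow(aln), 0, 0.1))
    assoc <- fit_position_association(aln, n_iterations = 20, seed = seed)
    planted <- ds$truth$causal$position
    if (assoc$rank[match(planted, assoc$column)] == 1) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("association scores are deterministic under a fixed seed", {
  ds <- simulate_dataset(sim_config(n_leaves = 30, L = 60, mu = 1.5,
                                    n_causal = 1, sigma2 = 0,
                                    characterized_frac = 1, seed = 9))
  aln <- ds$alignment
  aln$kcat_c <- exp(aln$true_ln_rate)
  a1 <- fit_position_association(aln, n_iterations = 8, seed = 5)
  a2 <- fit_position_association(aln, n_iterations = 8, seed = 5)
  expect_identical(a1, a2)
})

test_that("alignment columns map to reference residue numbers", {
  aln <- as_alignment(tibble::tibble(id = c("ref", "o"),
                                     seq = c("A-CD", "AAAD")))
  map <- map_alignment_to_reference(aln, "ref")
  expect_equal(map$column, c(1L, 3L, 4L))
  expect_equal(map$ref_residue, 1:3)
  expect_true(all(diff(map$column) > 0))

  gapless <- as_alignment(tibble::tibble(id = "r", seq = "ACDEF"))
  m2 <- map_alignment_to_reference(gapless, "r")
  expect_equal(m2$column, 1:5)
  expect_equal(m2$ref_residue, 1:5)
  expect_error(map_alignment_to_reference(aln, "nope"), "not in alignment")
})

test_that("Kruskal-Wallis matches the hand-computed rank statistic", {
  aln <- as_alignment(tibble::tibble(
    id = sprintf("v%d", 1:6),
    seq = c("AY", "AY", "AY", "AF", "AF", "AF")
  ))
  aln$kcat_c <- c(1, 2, 3, 10, 11, 12)
  cmp <- residue_rate_comparison(aln, position = 2, ref_id = "v1")
  # H = 12/(N(N+1)) * sum(R_g^2/n_g) - 3(N+1) = 3.857142... for these ranks
  expect_equal(cmp$kruskal$statistic, 12 / 42 * (36 / 3 + 225 / 3) - 21,
               tolerance = 1e-10)
  expect_equal(nrow(cmp$dunn), 1)
  # with two groups the Dunn z-statistic squares to H (no ties)
  expect_equal(cmp$dunn$z^2, cmp$kruskal$statistic, tolerance = 1e-10)
  expect_true(all(cmp$dunn$p.adjusted >= cmp$dunn$p.value))
})

test_that("degenerate all-tied rates give H = 0 without blow-up", {
  aln <- as_alignment(tibble::tibble(
    id = sprintf("v%d", 1:6),
    seq = rep(c("AY", "AF"), 3)
  ))
  aln$kcat_c <- rep(5, 6)
  cmp <- residue_rate_comparison(aln, position = 2, ref_id = "v1")
  expect_equal(cmp$kruskal$statistic, 0)
  expect_equal(cmp$dunn$z, 0)
})

test_that("the Dunn/KW test holds its nominal size under the null", {
  set.seed(99)
  rejections <- 0L
  n_rep <- 1000
  for (r in seq_len(n_rep)) {
    x <- rnorm(16)
    g <- rep(c("Y", "F"), each = 8)
    p <- kruskal.test(x, factor(g))$p.value
    if (p < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / n_rep, 0.03)
  expect_lte(rejections / n_rep, 0.07)
})

test_that("residue grouping collapses classes as requested", {
  aln <- as_alignment(tibble::tibble(
    id = sprintf("v%d", 1:8),
    seq = c("AI", "AV", "AH", "AF", "AF", "AY", "AY", "AX")
  ))
  aln$kcat_c <- c(1, 2, 3, 4, 5, 20, 30, 100)
  cmp <- residue_rate_comparison(
    aln, position = 2, ref_id = "v1",
    groups = list("I/V/H" = c("I", "V", "H"), "F" = "F", "Y" = "Y"))
  expect_setequal(cmp$groups$group, c("I/V/H", "F", "Y"))
  expect_equal(sum(cmp$groups$n), 7) # the X row is dropped
  expect_equal(nrow(cmp$dunn), 3)
})
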