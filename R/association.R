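#' Depth-limited regression tree on binary features
#'
#' A small deterministic CART-style regression tree used for position
#' association. Splits maximize variance reduction
#' (`n_left * n_right / n * (mean_left - mean_right)^2`) over binary 0/1
#' features; ties are broken by the lowest feature index, and nodes with
#' no positive-gain split become leaves. `predict_tree()` descends each
#' row; `tree_shapley()` computes exact Shapley attributions (below).
#'
#' @param x Binary feature matrix (rows = samples).
#' @param y Numeric targets.
#' @param max_depth Maximum tree depth (root = depth 0).
#' @return A nested list of nodes; leaves carry `value` (mean target)
#'   and `n` (cover), internal nodes also `feature`, `left` (feature
#'   value 0) and `right` (feature value 1).
#' @export
fit_regression_tree <- function(x, y, max_depth = 3) {
  x <- as.matrix(x)
  grow <- function(rows, depth) {
    node <- list(value = mean(y[rows]), n = length(rows), leaf = TRUE)
    if (depth >= max_depth || length(rows) < 2) return(node)
    xs <- x[rows, , drop = FALSE]
    n1 <- colSums(xs)
    n0 <- length(rows) - n1
    ok <- n1 > 0 & n0 > 0
    if (!any(ok)) return(node)
    s1 <- drop(crossprod(xs, y[rows]))
    m1 <- s1 / n1
    m0 <- (sum(y[rows]) - s1) / n0
    gain <- ifelse(ok, n1 * n0 / length(rows) * (m1 - m0)^2, -Inf)
    j <- which.max(gain)
    if (gain[j] <= 1e-12) return(node)
    node$leaf <- FALSE
    node$feature <- j
    node$left <- grow(rows[xs[, j] == 0], depth + 1)
    node$right <- grow(rows[xs[, j] == 1], depth + 1)
    node
  }
  structure(grow(seq_along(y), 0), class = "rubi_tree")
}

#' @rdname fit_regression_tree
#' @param tree A fitted `rubi_tree`.
#' @param newdata Feature matrix of rows to predict.
#' @export
predict_tree <- function(tree, newdata) {
  newdata <- as.matrix(newdata)
  apply(newdata, 1, function(row) descend_tree(tree, row, used = NULL))
}

# expected tree value with the features in `used` fixed to `row`'s
# values and all other features marginalized by training cover weights;
# used = NULL means all features are fixed (plain prediction)
descend_tree <- function(node, row, used) {
  if (node$leaf) return(node$value)
  if (is.null(used) || node$feature %in% used) {
    child <- if (row[node$feature] == 1) node$right else node$left
    return(descend_tree(child, row, used))
  }
  wl <- node$left$n / node$n
  wl * descend_tree(node$left, row, used) +
    (1 - wl) * descend_tree(node$right, row, used)
}

tree_features <- function(node) {
  if (node$leaf) return(integer(0))
  sort(unique(c(node$feature, tree_features(node$left),
                tree_features(node$right))))
}

#' Exact Shapley attributions for a shallow tree
#'
#' Computes, for one row, the exact Shapley value of every feature used
#' by the tree, under the coalitional value function
#' `v(S) = E[tree | features in S fixed to the row's values]`, with
#' out-of-coalition features marginalized along the tree by training
#' cover weights. Since a depth-d tree uses few distinct features, the
#' Shapley sum is enumerated exactly over all feature subsets. The
#' attributions satisfy local accuracy: `base + sum(phi)` equals the
#' tree's prediction for the row, to machine precision.
#'
#' @param tree A fitted `rubi_tree`.
#' @param row A single feature row (numeric vector).
#' @return A list with `phi` (named numeric vector indexed by feature
#'   column) and `base` (the marginal expectation `v(empty set)`).
#' @export
tree_shapley <- function(tree, row) {
  feats <- tree_features(tree)
  u <- length(feats)
  if (u == 0) {
    return(list(phi = numeric(0), base = tree$value))
  }
  # value of every coalition, indexed by bitmask over `feats`
  v <- numeric(2^u)
  for (mask in 0:(2^u - 1)) {
    s <- feats[bitwAnd(mask, bitwShiftL(1, seq_len(u) - 1)) != 0]
    v[mask + 1] <- descend_tree(tree, row, used = s)
  }
  fact <- factorial(0:u)
  phi <- numeric(u)
  for (k in seq_len(u)) {
    bit <- bitwShiftL(1, k - 1)
    for (mask in 0:(2^u - 1)) {
      if (bitwAnd(mask, bit) != 0) next
      ssize <- sum(bitwAnd(mask, bitwShiftL(1, seq_len(u) - 1)) != 0)
      w <- fact[ssize + 1] * fact[u - ssize] / fact[u + 1]
      phi[k] <- phi[k] + w * (v[bitwOr(mask, bit) + 1] - v[mask + 1])
    }
  }
  list(phi = setNames(phi, feats), base = v[1])
}

#' Resampled tree-Shapley association of alignment positions with rate
#'
#' Quantifies how strongly each alignment position is associated with
#' the (log) carboxylation rate. The data are repeatedly split into 75%
#' training and 25% held-out rows; each iteration fits a depth-limited
#' regression tree on the one-hot features of the training rows and
#' computes exact Shapley attributions for every held-out row. Per
#' feature, the mean absolute attribution over held-out rows is taken;
#' per position, the attributions of its residue-state features are
#' summed (states are mutually exclusive); the final score is the mean
#' over iterations, in ln-rate units. Positions that never support a
#' split score 0.
#'
#' Iteration i draws its split from seed `seed + i`, so a fixed seed
#' yields a bit-identical result; the caller's RNG state is preserved.
#'
#' @param data An alignment tibble with a `kcat_c` column. Restrict to
#'   the forms of interest (e.g. II and II/III) before calling.
#' @param n_iterations Number of random splits.
#' @param train_fraction Fraction of rows used for training each split.
#' @param max_depth Maximum tree depth.
#' @param seed Master seed.
#' @param ref_id Optional id of a reference sequence (e.g. the
#'   *R. rubrum* variant); positions are then also reported in that
#'   sequence's ungapped residue numbering.
#' @return A tibble of class `position_association` with columns
#'   `column`, `original_column`, `ref_residue` (NA off-reference),
#'   `score` and `rank`, sorted by rank.
#' @export
fit_position_association <- function(data, n_iterations = 100,
                                     train_fraction = 0.75, max_depth = 3,
                                     seed = 1, ref_id = NULL) {
  data <- as_alignment(data, column_map = column_map(data))
  if (!("kcat_c" %in% names(data))) abort("`data` needs a `kcat_c` column")
  stopifnot(train_fraction > 0, train_fraction < 1, max_depth >= 1)
  n <- nrow(data)
  if (n < 20) abort("need at least 20 sequences for a resampled association")
  y <- log(data$kcat_c)
  enc <- one_hot_encode(data)
  fi <- attr(enc, "feature_index")
  # constant columns can never split; dropping them speeds the search
  keep <- which(matrixStats_colVars(enc) > 0)
  xs <- enc[, keep, drop = FALSE]
  scores <- matrix(0, nrow = n_iterations, ncol = length(keep))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  n_train <- round(train_fraction * n)
  for (it in seq_len(n_iterations)) {
    set.seed(seed + it)
    train <- sample.int(n, n_train)
    test <- setdiff(seq_len(n), train)
    tree <- fit_regression_tree(xs[train, , drop = FALSE], y[train],
                                max_depth = max_depth)
    abs_sum <- numeric(length(keep))
    for (i in test) {
      sh <- tree_shapley(tree, xs[i, ])
      if (length(sh$phi) > 0) {
        idx <- as.integer(names(sh$phi))
        abs_sum[idx] <- abs_sum[idx] + abs(sh$phi)
      }
    }
    scores[it, ] <- abs_sum / length(test)
  }
  feat_score <- colMeans(scores)
  pos_score <- tapply(feat_score, fi$position[keep], sum)
  width <- alignment_width(data)
  score <- numeric(width)
  score[as.integer(names(pos_score))] <- pos_score
  ref_residue <- rep(NA_integer_, width)
  if (!is.null(ref_id)) {
    map <- map_alignment_to_reference(data, ref_id)
    ref_residue[map$column] <- map$ref_residue
  }
  out <- tibble(
    column = seq_len(width),
    original_column = column_map(data),
    ref_residue = ref_residue,
    score = score
  )
  out$rank <- rank(-out$score, ties.method = "min")
  out <- dplyr::arrange(out, .data$rank)
  class(out) <- c("position_association", class(out))
  out
}

# column variances without depending on matrixStats
matrixStats_colVars <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  (colSums(x^2) - n * colMeans(x)^2) / (n - 1)
}

#' Map alignment columns to a reference sequence's residue numbers
#'
#' Columns where the reference sequence carries a residue are numbered
#' 1, 2, ... along its ungapped sequence; columns where the reference
#' has a gap are unmapped. The map is strictly increasing.
#'
#' @param aln An alignment tibble containing `ref_id`.
#' @param ref_id Id of the reference sequence.
#' @return A tibble with columns `column` (alignment column) and
#'   `ref_residue` (1-based ungapped residue number).
#' @export
map_alignment_to_reference <- function(aln, ref_id) {
  i <- match(ref_id, aln$id)
  if (is.na(i)) abort(paste0("reference id '", ref_id, "' not in alignment"))
  chars <- strsplit(aln$seq[i], "", fixed = TRUE)[[1]]
  has_res <- chars != GAP_CHAR
  tibble(column = which(has_res), ref_residue = seq_len(sum(has_res)))
}

#' Compare rates between residue groups at one position
#'
#' Groups the characterized variants by the amino acid they carry at a
#' reference-numbered position and tests whether carboxylation rates
#' differ between residue groups: a tie-corrected Kruskal-Wallis omnibus
#' test followed by pairwise Dunn z-tests with multiplicity adjustment.
#'
#' @param data An alignment tibble with a `kcat_c` column.
#' @param position Residue number in the reference sequence's numbering.
#' @param ref_id Id of the reference sequence.
#' @param groups Optional named list collapsing residues into groups,
#'   e.g. `list("I/V/H" = c("I", "V", "H"), F = "F", Y = "Y")`; residues
#'   not listed are dropped. Default: one group per observed residue
#'   (gaps and `X` dropped).
#' @param p_adjust Adjustment method for the Dunn p-values
#'   (see [stats::p.adjust()]); default Bonferroni.
#' @return An object of class `residue_rate_comparison`: a list with
#'   `groups` (per-group n and median rate), `kruskal` (H statistic, df,
#'   p-value) and `dunn` (pairwise z and adjusted p). Supports [tidy()]
#'   and [glance()].
#' @export
residue_rate_comparison <- function(data, position, ref_id, groups = NULL,
                                    p_adjust = "bonferroni") {
  data <- as_alignment(data, column_map = column_map(data))
  if (!("kcat_c" %in% names(data))) abort("`data` needs a `kcat_c` column")
  map <- map_alignment_to_reference(data, ref_id)
  col <- map$column[match(position, map$ref_residue)]
  if (is.na(col)) abort(paste0("position ", position, " not present in reference"))
  residue <- substr(data$seq, col, col)
  if (is.null(groups)) {
    keep <- !(residue %in% c(GAP_CHAR, AMBIG_CHAR))
    grp <- residue
  } else {
    lut <- setNames(rep(names(groups), lengths(groups)),
                    unlist(groups, use.names = FALSE))
    grp <- unname(lut[residue])
    keep <- !is.na(grp)
  }
  grp <- grp[keep]
  rates <- data$kcat_c[keep]
  if (length(unique(grp)) < 2) abort("need at least 2 non-empty residue groups")
  if (length(unique(rates)) == 1) {
    # every observation shares one value: H is 0 by convention (the
    # tie-corrected statistic is 0/0 otherwise)
    kw <- list(statistic = 0, parameter = length(unique(grp)) - 1,
               p.value = 1)
  } else {
    kw <- kruskal.test(rates, factor(grp))
  }
  group_tbl <- dplyr::group_by(tibble(group = grp, kcat_c = rates), .data$group) |>
    dplyr::summarise(n = dplyr::n(), median = median(.data$kcat_c),
                     .groups = "drop")
  out <- list(
    position = position,
    column = col,
    groups = group_tbl,
    kruskal = list(statistic = unname(kw$statistic),
                   df = unname(kw$parameter), p.value = kw$p.value),
    dunn = dunn_test(rates, grp, p_adjust = p_adjust)
  )
  class(out) <- "residue_rate_comparison"
  out
}

# pairwise Dunn z-tests on the joint ranks, with tie correction
dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  g <- sort(unique(groups))
  rbar <- tapply(r, groups, mean)[g]
  ng <- tapply(r, groups, length)[g]
  combos <- utils::combn(g, 2)
  z <- apply(combos, 2, function(p) {
    if (s2 <= 0) return(0) # all observations tied
    (rbar[p[1]] - rbar[p[2]]) /
      sqrt(s2 * (1 / ng[p[1]] + 1 / ng[p[2]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  tibble(
    group1 = combos[1, ], group2 = combos[2, ],
    z = unname(z), p.value = unname(p),
    p.adjusted = pmin(p.adjust(p, method = p_adjust), 1)
  )
}

#' @export
print.residue_rate_comparison <- function(x, ...) {
  cat(sprintf("Rates by residue at reference position %d (alignment column %d)\n",
              x$position, x$column))
  print(x$groups)
  cat(sprintf("Kruskal-Wallis H = %.3f, df = %d, p = %.3g\n",
              x$kruskal$statistic, x$kruskal$df, x$kruskal$p.value))
  print(x$dunn)
  invisible(x)
}
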