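#' Greedy centroid clustering at an identity threshold
#'
#' Re-implements greedy centroid clustering of aligned sequences: scanning
#' the sequences in a fixed order, each sequence joins the first existing
#' centroid it matches at `threshold` identity or better, otherwise it
#' founds a new cluster. The resulting partition satisfies two
#' invariants: every member has identity >= `threshold` to its centroid,
#' and every pair of centroids has identity < `threshold`.
#'
#' The scan order is part of the algorithm. The default (`"length"`)
#' visits sequences by decreasing ungapped length, ties broken by id, the
#' usual convention of greedy clustering tools; `"input"` preserves the
#' row order of `aln` so tests can fix it.
#'
#' @param aln An alignment tibble (see [as_alignment()]).
#' @param threshold Identity threshold in (0, 1]. Values above 1 are
#'   clamped to 1; at threshold 0 every sequence joins the first centroid.
#' @param order `"length"` (default) or `"input"`.
#' @return A tibble with columns `id`, `centroid_id`, `is_centroid` and
#'   attribute `threshold`.
#' @export
greedy_cluster <- function(aln, threshold, order = c("length", "input")) {
  order <- match.arg(order)
  aln <- as_alignment(aln, column_map = column_map(aln))
  threshold <- min(max(threshold, 0), 1)
  n <- nrow(aln)
  if (n == 0) {
    out <- tibble(id = character(), centroid_id = character(),
                  is_centroid = logical())
    attr(out, "threshold") <- threshold
    return(out)
  }
  ord <- if (order == "length") {
    order(-ungapped_length(aln$seq), aln$id)
  } else {
    seq_len(n)
  }
  idm <- identity_matrix(aln)
  centroids <- integer(0)
  assigned <- integer(n) # index (into aln) of the centroid of each row
  for (i in ord) {
    hit <- 0L
    for (cj in centroids) {
      if (idm[i, cj] >= threshold) { hit <- cj; break }
    }
    if (hit == 0L) {
      centroids <- c(centroids, i)
      assigned[i] <- i
    } else {
      assigned[i] <- hit
    }
  }
  out <- tibble(
    id = aln$id,
    centroid_id = aln$id[assigned],
    is_centroid = assigned == seq_len(n)
  )
  attr(out, "threshold") <- threshold
  out
}

#' Diversity coverage of representatives by characterized variants
#'
#' For each identity threshold X, the coverage is the fraction of
#' representative sequences that share at least X identity with at least
#' one kinetically characterized variant. Representatives are typically
#' the centroids of a 90% identity clustering of the full sequence set,
#' which de-biases the metric against over-sampled groups. The curve is
#' monotone non-increasing in X.
#'
#' @param representatives,characterized Alignment tibbles in the same
#'   column coordinate system.
#' @param thresholds Identity thresholds X; defaults to 0.50 to 1.00 in
#'   steps of 0.05.
#' @return A tibble of class `coverage_curve` with columns `threshold`
#'   and `coverage`, and attributes `n_representatives`,
#'   `n_characterized`.
#' @export
diversity_coverage <- function(representatives, characterized,
                               thresholds = seq(0.5, 1, by = 0.05)) {
  if (nrow(representatives) == 0) abort("no representative sequences")
  if (nrow(characterized) == 0) {
    cov <- ifelse(thresholds > 0, 0, 1)
    best <- rep(0, nrow(representatives))
  } else {
    idm <- identity_matrix(representatives, characterized)
    best <- apply(idm, 1, max)
    cov <- vapply(thresholds, function(x) mean(best >= x), numeric(1))
  }
  out <- tibble(threshold = thresholds, coverage = cov)
  attr(out, "n_representatives") <- nrow(representatives)
  attr(out, "n_characterized") <- nrow(characterized)
  attr(out, "best_identity") <- best
  class(out) <- c("coverage_curve", class(out))
  out
}
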