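#' One-hot encode an alignment
#'
#' Expands each alignment column into a block of 21 indicator features
#' (20 amino acids plus the gap), in position-major order with a fixed
#' state order. Each row then sums to the alignment length, with exactly
#' one 1 per position block — except at ambiguous (`X`) sites, which
#' encode as an all-zero block so they contribute no similarity; rows
#' containing ambiguities are flagged in the `ambiguous_rows` attribute.
#'
#' @param aln An alignment tibble (typically trimmed with
#'   [trim_gap_columns()]).
#' @return A numeric 0/1 matrix with `n_seq` rows and `21 * width`
#'   columns; attribute `feature_index` is a tibble mapping each column
#'   to its `(position, state)` pair.
#' @export
one_hot_encode <- function(aln) {
  m <- seq_matrix(aln)
  L <- ncol(m)
  states <- c(AA_STATES, GAP_CHAR)
  ns <- length(states)
  out <- matrix(0, nrow = nrow(m), ncol = ns * L)
  for (k in seq_along(states)) {
    out[, (seq_len(L) - 1L) * ns + k] <- (m == states[k]) * 1
  }
  rownames(out) <- aln$id
  feature_index <- tibble(
    column = seq_len(ns * L),
    position = rep(seq_len(L), each = ns),
    state = rep(states, L)
  )
  attr(out, "feature_index") <- feature_index
  attr(out, "ambiguous_rows") <- unname(which(rowSums(out) < L))
  out
}

#' @rdname one_hot_encode
#' @param x An encoded matrix from `one_hot_encode()`.
#' @return `decode_one_hot()` returns the character vector of aligned
#'   sequences (ambiguous sites restored as `X`).
#' @export
decode_one_hot <- function(x) {
  fi <- attr(x, "feature_index")
  if (is.null(fi)) abort("not a one-hot encoded matrix")
  states <- unique(fi$state)
  ns <- length(states)
  L <- nrow(fi) / ns
  vapply(seq_len(nrow(x)), function(i) {
    row <- x[i, ]
    chars <- vapply(seq_len(L), function(p) {
      block <- row[(p - 1L) * ns + seq_len(ns)]
      hit <- which(block == 1)
      if (length(hit) == 1) states[hit] else AMBIG_CHAR
    }, character(1))
    paste(chars, collapse = "")
  }, character(1))
}
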