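# Small deterministic fixtures used across the test files.

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# random gap-free alignment of n sequences of length L
random_alignment <- function(n, L, seed = 1, gap_prob = 0) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    chars <- sample(aa20, L, replace = TRUE)
    if (gap_prob > 0) {
      chars[runif(L) < gap_prob] <- "-"
    }
    paste(chars, collapse = "")
  }, character(1))
  as_alignment(tibble::tibble(id = sprintf("s%02d", seq_len(n)), seq = seqs))
}

# alignment where sequences are mutated copies of one ancestor, so that
# pairwise identities are high and graded
mutant_family <- function(n, L, n_mut, seed = 1) {
  set.seed(seed)
  root <- sample(aa20, L, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- root
    pos <- sample(L, min(n_mut * i, L))
    s[pos] <- vapply(s[pos], function(a) sample(setdiff(aa20, a), 1), "")
    paste(s, collapse = "")
  }, character(1))
  as_alignment(tibble::tibble(id = sprintf("m%02d", seq_len(n)), seq = seqs))
}

# seeded observation-noise draws that leave the ambient RNG state alone
with_seed_rnorm <- function(seed, n, sd) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed + 5e4)
  rnorm(n, 0, sd)
}

# independent brute-force identity (position-by-position loop), mirroring
# the documented gap/ambiguity convention but written without reusing the
# package's vectorized code path
slow_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  matches <- 0L
  compared <- 0L
  for (k in seq_along(va)) {
    if (va[k] == "-" && vb[k] == "-") next
    compared <- compared + 1L
    if (va[k] == vb[k] && va[k] != "-" && va[k] != "X") matches <- matches + 1L
  }
  matches / compared
}
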