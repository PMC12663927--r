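#' Build an aligned sequence table
#'
#' The central container of the package is an ordinary tibble with one row
#' per sequence and columns `id`, `seq`, `form`, `characterized` and
#' `complete`. `as_alignment()` validates a data frame into that shape:
#' ids must be unique, all sequences must have equal (aligned) length, and
#' missing metadata columns are filled with defaults (`form = "unknown"`,
#' `characterized = FALSE`, `complete = TRUE`).
#'
#' An integer attribute `column_map` maps current alignment columns to the
#' column indices of the original (untrimmed) alignment; it is maintained
#' by [trim_gap_columns()] and defaults to the identity map.
#'
#' @param x A data frame with at least columns `id` and `seq`.
#' @param column_map Optional integer vector of original column indices,
#'   one per alignment column, strictly increasing.
#' @return A tibble of class `rubi_aln`.
#' @export
as_alignment <- function(x, column_map = NULL) {
  x <- as_tibble(x)
  if (!all(c("id", "seq") %in% names(x))) {
    abort("an alignment needs `id` and `seq` columns")
  }
  if (anyDuplicated(x$id)) {
    dup <- unique(x$id[duplicated(x$id)])
    abort(paste0("duplicate sequence id(s): ", paste(dup, collapse = ", ")))
  }
  lens <- nchar(x$seq)
  if (nrow(x) > 0 && length(unique(lens)) > 1) {
    bad <- which(lens != lens[1])[1]
    abort(paste0(
      "ragged alignment: record ", bad, " ('", x$id[bad], "') has length ",
      lens[bad], ", expected ", lens[1]
    ))
  }
  if (!("form" %in% names(x))) x$form <- "unknown"
  if (!("characterized" %in% names(x))) x$characterized <- FALSE
  if (!("complete" %in% names(x))) x$complete <- TRUE
  x$form <- as.character(x$form)
  x$characterized <- as.logical(x$characterized)
  x$complete <- as.logical(x$complete)
  # rows without metadata (e.g. unmatched in a join) fall back to defaults
  x$form[is.na(x$form)] <- "unknown"
  x$characterized[is.na(x$characterized)] <- FALSE
  x$complete[is.na(x$complete)] <- TRUE
  width <- if (nrow(x) > 0) lens[1] else 0L
  if (is.null(column_map)) column_map <- seq_len(width)
  column_map <- as.integer(column_map)
  if (length(column_map) != width || (width > 1 && any(diff(column_map) <= 0))) {
    abort("`column_map` must be strictly increasing with one entry per column")
  }
  x <- x[, union(c("id", "seq", "form", "characterized", "complete"),
                 names(x))]
  attr(x, "column_map") <- column_map
  class(x) <- c("rubi_aln", class(x))
  x
}

#' @rdname as_alignment
#' @export
alignment_width <- function(x) {
  if (nrow(x) == 0) 0L else nchar(x$seq[[1]])
}

#' @rdname as_alignment
#' @export
column_map <- function(x) {
  attr(x, "column_map") %||% seq_len(alignment_width(x))
}

# character matrix (n x L) view of the alignment rows
seq_matrix <- function(aln) {
  if (nrow(aln) == 0) {
    return(matrix(character(), nrow = 0, ncol = 0))
  }
  m <- matrix(unlist(strsplit(aln$seq, "", fixed = TRUE), use.names = FALSE),
              nrow = nrow(aln), byrow = TRUE)
  rownames(m) <- aln$id
  m
}

collapse_rows <- function(m) unname(apply(m, 1, paste, collapse = ""))

#' Read an aligned FASTA file with optional per-sequence metadata
#'
#' Reads a FASTA alignment (gap character `-`) and joins per-sequence
#' metadata by `id`. Metadata may be a data frame or a path to a TSV file
#' with columns `id`, `form`, `characterized`, `complete`. Metadata ids
#' with no matching sequence are reported with a warning.
#'
#' @param path Path to an aligned FASTA file.
#' @param metadata Optional data frame or TSV path with per-sequence
#'   metadata.
#' @return A [as_alignment()] tibble.
#' @export
read_alignment <- function(path, metadata = NULL) {
  recs <- read_fasta(path)
  aln <- tibble(id = names(recs), seq = unname(recs))
  if (!is.null(metadata)) {
    if (is.character(metadata) && length(metadata) == 1) {
      metadata <- read.delim(metadata, sep = "\t", stringsAsFactors = FALSE)
    }
    metadata <- as_tibble(metadata)
    unmatched <- setdiff(metadata$id, aln$id)
    if (length(unmatched) > 0) {
      warn(paste0("metadata ids with no sequence: ",
                  paste(unmatched, collapse = ", ")))
    }
    aln <- dplyr::left_join(aln, metadata, by = "id")
  }
  as_alignment(aln)
}

#' @rdname read_alignment
#' @param aln An alignment tibble.
#' @param wrap Line width for sequence wrapping.
#' @export
write_alignment <- function(aln, path, wrap = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", aln$id[i]), con)
    s <- aln$seq[i]
    starts <- seq(1, max(nchar(s), 1), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1, nchar(s))), con)
  }
  invisible(path)
}

# minimal FASTA reader; uses Biostrings when available, plain text otherwise
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    if (!any(hdr)) abort("not a FASTA file: no '>' headers found")
    idx <- cumsum(hdr)
    ids <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
    seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, "", collapse = "")
    out <- setNames(unname(seqs), ids)
  }
  if (anyDuplicated(names(out))) {
    abort(paste0("duplicate FASTA id(s): ",
                 paste(unique(names(out)[duplicated(names(out))]),
                       collapse = ", ")))
  }
  out
}

#' Filter sequences by ungapped length
#'
#' Keeps sequences whose ungapped length is within `[min_len, max_len]`
#' (bounds inclusive). The default window of 300 to 700 residues retains
#' plausible rubisco large-subunit sequences and drops fragments and
#' fusions. Rejected sequences are reported in the `rejections` attribute
#' (a tibble with columns `id`, `length`, `reason`).
#'
#' @param seqs A data frame with columns `id` and `seq` (aligned or not;
#'   gaps are ignored when counting length).
#' @param min_len,max_len Inclusive bounds on ungapped length, in residues.
#' @return The kept subset, with attribute `rejections`.
#' @export
length_filter <- function(seqs, min_len = 300, max_len = 700) {
  seqs <- as_tibble(seqs)
  len <- ungapped_length(seqs$seq)
  keep <- len >= min_len & len <= max_len
  rejections <- tibble(
    id = seqs$id[!keep],
    length = len[!keep],
    reason = ifelse(len[!keep] < min_len, "too_short", "too_long")
  )
  out <- seqs[keep, , drop = FALSE]
  attr(out, "rejections") <- rejections
  out
}

ungapped_length <- function(seq) {
  nchar(gsub("-", "", seq, fixed = TRUE))
}

#' Remove gap-dominated alignment columns
#'
#' Drops every column whose gap fraction strictly exceeds `max_gap_frac`
#' (default 0.95, i.e. a column present in at least 5% of sequences is
#' kept). The surviving columns' original indices are recorded in the
#' `column_map` attribute so positions can be traced back to the untrimmed
#' alignment. Trimming is idempotent at a fixed threshold.
#'
#' @param aln An alignment tibble.
#' @param max_gap_frac Columns with gap fraction strictly greater than
#'   this are removed; in (0, 1].
#' @return The trimmed alignment.
#' @export
trim_gap_columns <- function(aln, max_gap_frac = 0.95) {
  aln <- as_alignment(aln, column_map = column_map(aln))
  stopifnot(max_gap_frac > 0, max_gap_frac <= 1)
  m <- seq_matrix(aln)
  if (ncol(m) == 0) return(aln)
  gap_frac <- colMeans(m == GAP_CHAR)
  keep <- gap_frac <= max_gap_frac
  if (!any(keep)) abort("all alignment columns exceed the gap threshold")
  out <- aln
  out$seq <- collapse_rows(m[, keep, drop = FALSE])
  as_alignment(out, column_map = column_map(aln)[keep])
}

#' Pairwise sequence identity on aligned rows
#'
#' Identity is the fraction of matching columns among compared columns of
#' two equal-length aligned sequences. Columns where both sequences carry
#' a gap are excluded from the comparison; a gap opposite a residue counts
#' as a mismatch; the ambiguity code `X` matches nothing (including
#' another `X`). With this convention `pairwise_identity(a, a) == 1` for
#' any gapped sequence without ambiguities.
#'
#' @param a,b Aligned sequences (equal-length strings).
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("aligned sequences must have equal length")
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  both_gap <- va == GAP_CHAR & vb == GAP_CHAR
  compared <- sum(!both_gap)
  if (compared == 0) abort("identity undefined: no compared columns")
  matches <- sum(!both_gap & va == vb & va != GAP_CHAR & va != AMBIG_CHAR)
  matches / compared
}

#' All-pairs identity matrix
#'
#' Computes the [pairwise_identity()] matrix between the rows of `aln`
#' (or between `aln` and `aln2`) using indicator-matrix cross-products, so
#' it scales to hundreds of sequences.
#'
#' @param aln,aln2 Alignment tibbles in the same column coordinate system;
#'   `aln2 = NULL` computes the symmetric self-identity matrix.
#' @return A numeric matrix of identities, rows named by `aln$id` and
#'   columns by `aln2$id` (or `aln$id`).
#' @export
identity_matrix <- function(aln, aln2 = NULL) {
  m1 <- seq_matrix(aln)
  m2 <- if (is.null(aln2)) m1 else seq_matrix(aln2)
  if (ncol(m1) != ncol(m2)) {
    abort("alignments must share the same number of columns")
  }
  L <- ncol(m1)
  states <- AA_STATES
  ind <- function(m) {
    # n x (20 L) residue indicators; gaps and X contribute nothing
    out <- matrix(0, nrow = nrow(m), ncol = length(states) * L)
    for (k in seq_along(states)) {
      hit <- m == states[k]
      out[, (seq_len(L) - 1L) * length(states) + k] <- hit
    }
    out
  }
  a1 <- ind(m1); a2 <- ind(m2)
  g1 <- (m1 == GAP_CHAR) * 1; g2 <- (m2 == GAP_CHAR) * 1
  matches <- tcrossprod(a1, a2)
  both_gap <- tcrossprod(g1, g2)
  compared <- L - both_gap
  if (any(compared == 0)) abort("identity undefined: a pair shares no compared columns")
  out <- matches / compared
  rownames(out) <- rownames(m1)
  colnames(out) <- rownames(m2)
  out
}
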