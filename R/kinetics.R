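#' Validate a table of kinetic rate measurements
#'
#' A rate table has one row per measurement with columns `variant_id`,
#' `kcat_c` (carboxylation turnover, 1/s, positive), `temp_c` (assay
#' temperature, degrees C), `assay` (`"coupled"` or `"direct"`),
#' `batch_id` (optional batch label) and `source` (`"pipeline"` or
#' `"literature"`). Three logical flag columns track which harmonization
#' steps have been applied: `q10_corrected`, `control_normalized`,
#' `assay_corrected`.
#'
#' @param x A data frame of measurements.
#' @return A validated tibble.
#' @export
as_rate_records <- function(x) {
  x <- as_tibble(x)
  if (!all(c("variant_id", "kcat_c") %in% names(x))) {
    abort("rate records need `variant_id` and `kcat_c` columns")
  }
  if (any(!is.finite(x$kcat_c)) || any(x$kcat_c <= 0)) {
    abort("all `kcat_c` values must be finite and positive")
  }
  if (!("temp_c" %in% names(x))) x$temp_c <- 30
  if (any(x$temp_c < 0 | x$temp_c > 100)) {
    abort("`temp_c` outside the plausible 0-100 degrees C range")
  }
  if (!("assay" %in% names(x))) x$assay <- "coupled"
  if (!("batch_id" %in% names(x))) x$batch_id <- NA_character_
  if (!("source" %in% names(x))) x$source <- "pipeline"
  for (flag in c("q10_corrected", "control_normalized", "assay_corrected")) {
    if (is.null(x[[flag]])) x[[flag]] <- FALSE
  }
  x
}

#' Temperature-correct rates with a Q10 rule
#'
#' Rescales each measurement to a common reference temperature assuming
#' the rate changes by a factor `q10` per 10 degrees C:
#' `kcat' = kcat * q10^((t_target - temp_c) / 10)`. The default Q10 of
#' 2.2 is the standard value used to bring literature rubisco rates to
#' 30 degrees C. Correcting an already-corrected table is an error unless
#' `force = TRUE`.
#'
#' @param records A rate table (see [as_rate_records()]).
#' @param t_target Target temperature, degrees C.
#' @param q10 Fold change per 10 degrees C, > 0.
#' @param force Allow re-correction of already corrected records.
#' @return The corrected rate table (`temp_c` set to `t_target`).
#' @export
q10_correct <- function(records, t_target = 30, q10 = 2.2, force = FALSE) {
  records <- as_rate_records(records)
  stopifnot(q10 > 0)
  if (any(records$q10_corrected) && !force) {
    abort("records already temperature-corrected; use `force = TRUE` to redo")
  }
  records$kcat_c <- records$kcat_c * q10^((t_target - records$temp_c) / 10)
  records$temp_c <- t_target
  records$q10_corrected <- TRUE
  records
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Normalize batches to a control variant
#'
#' Every measurement batch of the experimental pipeline includes the same
#' control rubisco; scaling each batch so the control hits a common
#' reference value removes batch-to-batch variability. Each record in
#' batch b is multiplied by `control_reference / g_b`, where `g_b` is the
#' geometric mean of the batch's control measurements (rates are treated
#' as log-normal). Batches without a control measurement are left
#' unnormalized and reported in the `unnormalized_batches` attribute.
#'
#' @param records A rate table.
#' @param control_id Variant id of the control.
#' @param control_reference Reference rate for the control (1/s). The
#'   default `NULL` uses the grand geometric mean of all control
#'   measurements, which removes batch effects without changing the
#'   overall scale.
#' @return The normalized rate table.
#' @export
normalize_to_control <- function(records, control_id,
                                 control_reference = NULL) {
  records <- as_rate_records(records)
  if (any(records$control_normalized)) {
    abort("records already control-normalized")
  }
  ctrl <- records[records$variant_id == control_id, ]
  if (nrow(ctrl) == 0) abort(paste0("no measurements of control '", control_id, "'"))
  if (is.null(control_reference)) {
    control_reference <- geometric_mean(ctrl$kcat_c)
  }
  batch_means <- tapply(ctrl$kcat_c, ctrl$batch_id, geometric_mean)
  missing <- setdiff(unique(records$batch_id), names(batch_means))
  if (length(missing) > 0) {
    warn(paste0("batch(es) without control measurement left unnormalized: ",
                paste(missing, collapse = ", ")))
  }
  scale <- control_reference / batch_means[as.character(records$batch_id)]
  scale[is.na(scale)] <- 1
  records$kcat_c <- as.numeric(records$kcat_c * unname(scale))
  records$control_normalized <- !(records$batch_id %in% missing)
  attr(records, "unnormalized_batches") <- missing
  attr(records, "control_reference") <- control_reference
  records
}

#' Calibrate coupled against direct assay rates
#'
#' Coupled spectrophotometric assays systematically underestimate
#' carboxylation rates relative to direct assays. Given variants measured
#' by both, the calibration is a log-log fit with slope fixed to 1, which
#' reduces to the mean log-ratio: `b = mean(ln k_direct - ln k_coupled)`
#' and a multiplicative correction `factor = exp(b)`. The confidence
#' interval is a t-interval on the log-ratios,
#' `exp(b +- t_{n-1} s / sqrt(n))`.
#'
#' @param pairs A data frame with columns `k_coupled` and `k_direct`
#'   (both positive), one row per variant measured by both assays.
#' @param conf_level Confidence level for the interval.
#' @return An object of class `correction_fit` with elements
#'   `log_offset`, `factor`, `ci_low`, `ci_high`, `n_pairs`,
#'   `conf_level`. Supports [tidy()] and [glance()].
#' @export
fit_assay_correction <- function(pairs, conf_level = 0.95) {
  pairs <- as_tibble(pairs)
  stopifnot(all(c("k_coupled", "k_direct") %in% names(pairs)))
  if (nrow(pairs) < 2) abort("need at least 2 coupled/direct pairs")
  if (any(pairs$k_coupled <= 0) || any(pairs$k_direct <= 0)) {
    abort("all rates must be positive")
  }
  lr <- log(pairs$k_direct) - log(pairs$k_coupled)
  n <- length(lr)
  b <- mean(lr)
  s <- sd(lr)
  half <- qt(1 - (1 - conf_level) / 2, df = n - 1) * s / sqrt(n)
  out <- list(
    log_offset = b,
    factor = exp(b),
    ci_low = exp(b - half),
    ci_high = exp(b + half),
    n_pairs = n,
    conf_level = conf_level,
    log_ratios = lr
  )
  class(out) <- "correction_fit"
  out
}

#' @export
print.correction_fit <- function(x, ...) {
  cat(sprintf(
    "Assay correction factor: %.3g (%d%% CI %.3g to %.3g), n = %d pairs\n",
    x$factor, round(100 * x$conf_level), x$ci_low, x$ci_high, x$n_pairs
  ))
  invisible(x)
}

#' Apply an assay correction factor to coupled-assay rates
#'
#' Multiplies every rate by the fitted coupled-to-direct factor. Records
#' already assay-corrected raise an error (double application would
#' silently square the factor).
#'
#' @param records A rate table of coupled-assay measurements.
#' @param fit A `correction_fit`, or a bare numeric factor.
#' @return The corrected rate table.
#' @export
apply_correction <- function(records, fit) {
  records <- as_rate_records(records)
  factor <- if (inherits(fit, "correction_fit")) fit$factor else as.numeric(fit)
  stopifnot(factor > 0)
  if (any(records$assay_corrected)) {
    abort("records already assay-corrected")
  }
  records$kcat_c <- records$kcat_c * factor
  records$assay_corrected <- TRUE
  records$assay <- "direct"
  records
}

#' Summarize rates overall or per rubisco form
#'
#' Computes n, median and the 0.25/0.75 quantiles of `kcat_c` per group,
#' using linear-interpolation quantiles. All records should first be
#' harmonized to a common temperature.
#'
#' @param records A rate table; needs a `form` column when `by = "form"`.
#' @param by `"all"` for a single summary or `"form"` for per-form rows.
#' @return A tibble with columns `group`, `n`, `median`, `q25`, `q75`.
#' @export
summarize_rates <- function(records, by = c("all", "form")) {
  by <- match.arg(by)
  records <- as_rate_records(records)
  if (length(unique(records$temp_c)) > 1) {
    warn("records span several temperatures; harmonize with q10_correct() first")
  }
  groups <- if (by == "all") rep("all", nrow(records)) else {
    if (!("form" %in% names(records))) abort("`by = \"form\"` needs a `form` column")
    records$form
  }
  dplyr::group_by(tibble(group = groups, kcat_c = records$kcat_c), .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$kcat_c),
      q25 = quantile(.data$kcat_c, 0.25, names = FALSE),
      q75 = quantile(.data$kcat_c, 0.75, names = FALSE),
      .groups = "drop"
    )
}

#' Pairwise rate ratios as a function of sequence identity
#'
#' For every unordered pair of measured variants, computes the pairwise
#' identity from the alignment and the rate ratio `max(ki, kj) /
#' min(ki, kj)` (always >= 1), then bins pairs by identity and reports
#' the per-bin median ratio. A flat landscape — similar sequences having
#' similar rates — shows up as median ratios near 1 in high-identity
#' bins. Variants with several measurements are collapsed to their
#' geometric mean rate first. Variants missing from the alignment are
#' excluded and reported in the `excluded` attribute.
#'
#' @param records A rate table (common temperature).
#' @param aln An alignment tibble containing the measured variants.
#' @param bins Identity bin edges (default 0 to 1 by 0.1); pairs are
#'   assigned by `bin_low <= identity < bin_high`, with identity 1 in the
#'   top bin.
#' @return A tibble of class `ratio_by_identity` with columns `bin_low`,
#'   `bin_high`, `n_pairs`, `median_ratio`; the pair-level table is in
#'   the `pairs` attribute.
#' @export
rate_ratio_vs_identity <- function(records, aln, bins = seq(0, 1, by = 0.1)) {
  records <- as_rate_records(records)
  per_variant <- dplyr::group_by(records, .data$variant_id) |>
    dplyr::summarise(kcat_c = geometric_mean(.data$kcat_c), .groups = "drop")
  excluded <- setdiff(per_variant$variant_id, aln$id)
  if (length(excluded) > 0) {
    warn(paste0("variant(s) missing from alignment excluded: ",
                paste(excluded, collapse = ", ")))
    per_variant <- per_variant[!per_variant$variant_id %in% excluded, ]
  }
  if (nrow(per_variant) < 2) abort("need at least two variants in the alignment")
  sub <- aln[match(per_variant$variant_id, aln$id), ]
  idm <- identity_matrix(as_alignment(sub))
  ut <- which(upper.tri(idm), arr.ind = TRUE)
  k <- per_variant$kcat_c
  pair_tbl <- tibble(
    id_a = per_variant$variant_id[ut[, 1]],
    id_b = per_variant$variant_id[ut[, 2]],
    identity = idm[ut],
    ratio = pmax(k[ut[, 1]], k[ut[, 2]]) / pmin(k[ut[, 1]], k[ut[, 2]])
  )
  idx <- findInterval(pair_tbl$identity, bins, rightmost.closed = TRUE,
                      all.inside = TRUE)
  out <- tibble(
    bin_low = bins[-length(bins)],
    bin_high = bins[-1]
  )
  out$n_pairs <- vapply(seq_len(nrow(out)), function(i) sum(idx == i), integer(1))
  out$median_ratio <- vapply(seq_len(nrow(out)), function(i) {
    if (any(idx == i)) median(pair_tbl$ratio[idx == i]) else NA_real_
  }, numeric(1))
  attr(out, "pairs") <- pair_tbl
  class(out) <- c("ratio_by_identity", class(out))
  out
}
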