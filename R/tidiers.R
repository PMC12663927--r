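#' Tidiers for fitted objects
#'
#' broom-style methods: `tidy()` returns one row per estimated quantity,
#' `glance()` a one-row model summary.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name rubiscope-tidiers
NULL

#' @rdname rubiscope-tidiers
#' @method tidy correction_fit
#' @export
tidy.correction_fit <- function(x, ...) {
  tibble(
    term = "assay_correction_factor",
    estimate = x$factor,
    conf.low = x$ci_low,
    conf.high = x$ci_high
  )
}

#' @rdname rubiscope-tidiers
#' @method glance correction_fit
#' @export
glance.correction_fit <- function(x, ...) {
  tibble(
    factor = x$factor,
    log_offset = x$log_offset,
    conf.low = x$ci_low,
    conf.high = x$ci_high,
    conf.level = x$conf_level,
    n_pairs = x$n_pairs
  )
}

#' @rdname rubiscope-tidiers
#' @method tidy residue_rate_comparison
#' @export
tidy.residue_rate_comparison <- function(x, ...) {
  x$dunn
}

#' @rdname rubiscope-tidiers
#' @method glance residue_rate_comparison
#' @export
glance.residue_rate_comparison <- function(x, ...) {
  tibble(
    statistic = x$kruskal$statistic,
    df = x$kruskal$df,
    p.value = x$kruskal$p.value,
    n_groups = nrow(x$groups),
    n = sum(x$groups$n)
  )
}
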