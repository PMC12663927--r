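#' Pipeline configuration
#'
#' Collects the constants of the end-to-end analysis in one list so a
#' run is fully described by (inputs, config, seed). Defaults follow the
#' conventions used throughout the package: Q10 of 2.2 to 30 C, gap
#' trimming at 95%, a 300-700 residue length window, representatives
#' from 90% identity clustering, and SVR as the headline predictor.
#' Configs round-trip through JSON ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param q10,t_target Temperature correction parameters.
#' @param gap_trim Maximum tolerated column gap fraction.
#' @param min_len,max_len Ungapped length window (residues).
#' @param cluster_threshold Identity threshold for representative
#'   selection.
#' @param coverage_thresholds Identity grid for the coverage curve.
#' @param control_id,control_reference Control variant and its reference
#'   rate for batch normalization (`NULL` reference = grand geometric
#'   mean of the control's measurements).
#' @param correction_factor Optional fixed coupled-to-direct factor; if
#'   `NULL` it is fitted from the supplied pairs.
#' @param model,lambda,cv_thresholds Prediction model settings.
#' @param association_forms Forms entering the position-association
#'   analysis.
#' @param n_iterations,train_fraction,max_depth Association settings.
#' @param ref_id Reference sequence for residue numbering (optional).
#' @param seed Master seed; stages derive scoped seeds from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(q10 = 2.2, t_target = 30, gap_trim = 0.95,
                            min_len = 300, max_len = 700,
                            cluster_threshold = 0.9,
                            coverage_thresholds = seq(0.5, 1, by = 0.05),
                            control_id = "control",
                            control_reference = NULL,
                            correction_factor = NULL,
                            model = "svr", lambda = 14,
                            cv_thresholds = seq(0.5, 0.9, by = 0.1),
                            association_forms = c("II", "II/III"),
                            n_iterations = 100, train_fraction = 0.75,
                            max_depth = 3, ref_id = NULL, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(q10 > 0, gap_trim > 0, gap_trim <= 1, min_len <= max_len,
            cluster_threshold > 0, cluster_threshold <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path File path for the JSON serialization.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Run the full analysis chain
#'
#' Executes the stages in their canonical order on in-memory inputs:
#' length filtering, gap-column trimming, representative clustering,
#' diversity coverage, rate harmonization (Q10 correction of literature
#' records with per-variant medians, control normalization and assay
#' correction of pipeline records), rate summaries, the rate-ratio
#' versus identity landscape, the identity-thresholded cross-validation
#' benchmark, per-form prediction of uncharacterized variants, and the
#' position-association analysis. A stage failure aborts with the stage
#' name. When `out_dir` is given, every table is written as TSV/JSON
#' together with a manifest carrying the config hash and seed, so two
#' runs with the same inputs, config and seed produce byte-identical
#' outputs.
#'
#' @param alignment An alignment tibble (with metadata columns).
#' @param records A rate table of observed measurements.
#' @param pairs Optional coupled/direct pairs for the calibration fit.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A list of stage outputs (class `pipeline_result`).
#' @export
run_full <- function(alignment, records, pairs = NULL,
                     config = pipeline_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  res <- list(config = config)

  aln <- stage("length_filter",
               as_alignment(length_filter(alignment, config$min_len,
                                          config$max_len)))
  aln <- stage("trim", trim_gap_columns(aln, config$gap_trim))
  res$alignment <- aln

  res$clusters <- stage("cluster",
                        greedy_cluster(aln, config$cluster_threshold))
  reps <- aln[aln$id %in% res$clusters$centroid_id, ]
  chars <- aln[aln$characterized, ]
  res$coverage <- stage("coverage",
                        diversity_coverage(reps, chars,
                                           config$coverage_thresholds))

  res$harmonized <- stage("harmonize", {
    lit <- records[records$source == "literature", ]
    pipe <- records[records$source == "pipeline", ]
    parts <- list()
    if (nrow(lit) > 0) {
      lit <- q10_correct(lit, t_target = config$t_target, q10 = config$q10)
      # several published values per variant collapse to their median
      lit <- dplyr::group_by(lit, .data$variant_id) |>
        dplyr::summarise(kcat_c = median(.data$kcat_c),
                         temp_c = config$t_target, assay = "direct",
                         batch_id = NA_character_, source = "literature",
                         .groups = "drop") |>
        as_rate_records()
      lit$q10_corrected <- TRUE
      parts$lit <- lit
    }
    if (nrow(pipe) > 0) {
      pipe <- normalize_to_control(pipe, config$control_id,
                                   config$control_reference)
      fit <- if (!is.null(config$correction_factor)) {
        config$correction_factor
      } else if (!is.null(pairs)) {
        fit_assay_correction(pairs)
      } else {
        abort("no correction factor and no pairs to fit one from")
      }
      if (inherits(fit, "correction_fit")) res$correction <- fit
      pipe <- apply_correction(pipe, fit)
      parts$pipe <- pipe[pipe$variant_id != config$control_id, ]
    }
    dplyr::bind_rows(parts)
  })

  res$summary_all <- stage("summarize", summarize_rates(res$harmonized, "all"))
  meas <- res$harmonized
  meas$form <- aln$form[match(meas$variant_id, aln$id)]
  meas_in_aln <- meas[!is.na(meas$form), ]
  if (nrow(meas_in_aln) > 0) {
    res$summary_form <- stage("summarize",
                              summarize_rates(meas_in_aln, "form"))
  }

  res$ratio <- stage("ratio_vs_identity", {
    suppressWarnings(rate_ratio_vs_identity(res$harmonized, aln))
  })

  cv_data <- chars
  cv_data$kcat_c <- res$harmonized$kcat_c[match(cv_data$id,
                                                res$harmonized$variant_id)]
  cv_data <- cv_data[!is.na(cv_data$kcat_c), ]
  if (nrow(cv_data) >= 3) {
    res$cv <- stage("crossval",
                    loo_crossval(cv_data, model = config$model,
                                 thresholds = config$cv_thresholds,
                                 lambda = config$lambda))
    unchar <- aln[!aln$characterized, ]
    if (nrow(unchar) > 0) {
      res$predictions <- stage("predict",
                               predict_all(cv_data, unchar,
                                           model = config$model,
                                           lambda = config$lambda))
    }
    assoc_data <- cv_data[cv_data$form %in% config$association_forms, ]
    if (nrow(assoc_data) >= 20) {
      res$association <- stage("associate",
        fit_position_association(assoc_data,
                                 n_iterations = config$n_iterations,
                                 train_fraction = config$train_fraction,
                                 max_depth = config$max_depth,
                                 seed = config$seed,
                                 ref_id = config$ref_id))
    }
  }

  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

config_hash <- function(config) rlang::hash(unclass(config))

write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(res$config)
  put <- function(x, name) {
    if (is.null(x)) return(invisible(NULL))
    path <- file.path(out_dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    writeLines(paste0("# config_hash=", hash, " seed=", res$config$seed), con)
    write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
  }
  put(res$alignment[, c("id", "form", "characterized", "complete")],
      "alignment_meta")
  put(res$clusters, "clusters")
  put(res$coverage, "coverage")
  put(res$harmonized, "harmonized_rates")
  put(res$summary_all, "summary_all")
  put(res$summary_form, "summary_form")
  put(res$ratio, "ratio_by_identity")
  put(res$cv, "crossval")
  put(res$predictions, "predictions")
  put(res$association, "association")
  if (!is.null(res$correction)) {
    jsonlite::write_json(
      c(list(config_hash = hash), tidy(res$correction)),
      file.path(out_dir, "correction.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(config_hash = hash, seed = res$config$seed,
         config = unclass(res$config)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(out_dir)
}
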