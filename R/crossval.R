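#' Identity-thresholded leave-one-out cross-validation
#'
#' Benchmarks sequence-based rate predictors under increasingly stringent
#' training-set restrictions. For each held-out variant and each identity
#' threshold X, the training set is restricted to the other characterized
#' variants sharing at least X identity with it (optionally also the same
#' rubisco form). Held-out variants with an empty training set at a
#' threshold are skipped there and counted out of `n_evaluable`.
#' Prediction error is the root-mean-square error in natural-log space
#' (`rmse_ln`), also reported as the fold-change error
#' `fold_error = exp(rmse_ln)` (1 = perfect, 2 = typically off by
#' twofold).
#'
#' All four models are deterministic, so a fixed input yields a
#' bit-identical result.
#'
#' @param data An alignment tibble with a `kcat_c` column of harmonized
#'   rates (1/s at a common temperature).
#' @param model Character vector from `"nn"`, `"mean"`,
#'   `"weighted_mean"`, `"svr"`; one result row per model x threshold.
#' @param thresholds Identity thresholds X.
#' @param lambda Decay for the weighted-mean model.
#' @param per_form Restrict training sets to the held-out variant's form.
#' @return A tibble of class `cv_result` with columns `model`,
#'   `threshold`, `n_evaluable`, `rmse_ln`, `fold_error`.
#' @export
loo_crossval <- function(data, model = c("svr", "nn", "mean", "weighted_mean"),
                         thresholds = seq(0.5, 0.95, by = 0.05),
                         lambda = 14, per_form = FALSE) {
  model <- match.arg(model, several.ok = TRUE)
  data <- as_alignment(data, column_map = column_map(data))
  if (!("kcat_c" %in% names(data))) abort("`data` needs a `kcat_c` column")
  n <- nrow(data)
  if (n < 3) abort("need at least 3 characterized sequences")
  y <- log(data$kcat_c)
  idm <- identity_matrix(data)
  enc <- if ("svr" %in% model) one_hot_encode(data) else NULL
  grid <- tidyr::expand_grid(model = model, threshold = thresholds)
  res <- purrr::pmap_dfr(grid, function(model, threshold) {
    err <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      train <- which(idm[i, ] >= threshold)
      train <- setdiff(train, i)
      if (per_form) train <- train[data$form[train] == data$form[i]]
      if (length(train) == 0) next
      pred <- predict_one(model, train, i, y, idm, enc, lambda)
      err[i] <- pred - y[i]
    }
    evaluable <- !is.na(err)
    rmse <- if (any(evaluable)) sqrt(mean(err[evaluable]^2)) else NA_real_
    tibble(model = model, threshold = threshold,
           n_evaluable = sum(evaluable), rmse_ln = rmse,
           fold_error = exp(rmse))
  })
  if (all(res$n_evaluable == 0)) {
    abort("no evaluable held-out variants at any threshold")
  }
  class(res) <- c("cv_result", class(res))
  res
}

predict_one <- function(model, train, i, y, idm, enc, lambda) {
  s <- idm[i, train]
  switch(model,
    nn = predict_nn(s, y[train]),
    mean = predict_mean(s, y[train]),
    weighted_mean = predict_weighted_mean(s, y[train], lambda),
    svr = {
      if (length(train) < 2) {
        # a one-sequence training set admits no kernel fit; fall back to
        # its value (equivalently the training mean)
        y[train]
      } else {
        fit <- fit_svr(enc[train, , drop = FALSE], y[train])
        predict(fit, enc[i, , drop = FALSE])
      }
    }
  )
}

#' Predict rates of uncharacterized variants, per rubisco form
#'
#' Trains one model per rubisco form on all characterized variants of
#' that form and predicts every uncharacterized variant from its own
#' form's model, back-transforming to 1/s. Each prediction carries a
#' per-form fold-change error estimate obtained by within-form
#' leave-one-out cross-validation of the same model. Forms with fewer
#' than `min_train` characterized variants (and variants of unknown
#' form) are refused rather than extrapolated, and listed in the
#' `unpredicted` attribute.
#'
#' @param characterized An alignment tibble with a `kcat_c` column.
#' @param uncharacterized An alignment tibble in the same column
#'   coordinates, with a `form` column.
#' @param model One of `"svr"`, `"nn"`, `"mean"`, `"weighted_mean"`.
#' @param min_train Minimum characterized variants a form needs.
#' @param lambda Decay for the weighted-mean model.
#' @return A tibble with columns `variant_id`, `form`,
#'   `predicted_kcat_c`, `fold_error`, `model`; attribute `unpredicted`
#'   lists refused variants with reasons.
#' @export
predict_all <- function(characterized, uncharacterized, model = "svr",
                        min_train = 3, lambda = 14) {
  model <- match.arg(model, c("svr", "nn", "mean", "weighted_mean"))
  characterized <- as_alignment(characterized,
                                column_map = column_map(characterized))
  uncharacterized <- as_alignment(uncharacterized,
                                  column_map = column_map(uncharacterized))
  if (!("kcat_c" %in% names(characterized))) {
    abort("`characterized` needs a `kcat_c` column")
  }
  y_all <- log(characterized$kcat_c)
  forms <- unique(uncharacterized$form)
  out <- list()
  unpred <- list()
  for (f in forms) {
    q_idx <- which(uncharacterized$form == f)
    t_idx <- which(characterized$form == f)
    if (f == "unknown" || length(t_idx) < min_train) {
      reason <- if (f == "unknown") "unknown form" else
        sprintf("form has %d < %d characterized variants", length(t_idx), min_train)
      unpred[[f]] <- tibble(variant_id = uncharacterized$id[q_idx],
                            form = f, reason = reason)
      next
    }
    train <- characterized[t_idx, ]
    y <- y_all[t_idx]
    queries <- uncharacterized[q_idx, ]
    preds <- if (model == "svr") {
      enc_t <- one_hot_encode(train)
      enc_q <- one_hot_encode(queries)
      if (length(t_idx) >= 2) {
        fit <- fit_svr(enc_t, y)
        predict(fit, enc_q)
      } else rep(y, length(q_idx))
    } else {
      idm <- identity_matrix(queries, train)
      vapply(seq_len(nrow(queries)), function(i) {
        switch(model,
          nn = predict_nn(idm[i, ], y),
          mean = predict_mean(idm[i, ], y),
          weighted_mean = predict_weighted_mean(idm[i, ], y, lambda)
        )
      }, numeric(1))
    }
    cv <- loo_crossval(train, model = model, thresholds = 0, lambda = lambda)
    out[[f]] <- tibble(
      variant_id = queries$id, form = f,
      predicted_kcat_c = exp(preds),
      fold_error = cv$fold_error[[1]],
      model = model
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "unpredicted") <- dplyr::bind_rows(unpred)
  res
}
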