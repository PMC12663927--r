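test_that("Q10 correction follows the closed form and round-trips", {
  r <- as_rate_records(tibble::tibble(
    variant_id = c("a", "b", "c"),
    kcat_c = c(3, 10, 5),
    temp_c = c(30, 20, 25)
  ))
  out <- q10_correct(r)
  expect_equal(out$kcat_c, c(3, 22, 5 * 2.2^0.5))
  expect_true(all(out$temp_c == 30))
  expect_error(q10_correct(out), "already")

  # correcting to T and back recovers the input
  back <- q10_correct(out, t_target = 25, force = TRUE)
  back <- q10_correct(back, t_target = 30, force = TRUE)
  expect_equal(back$kcat_c, out$kcat_c)

  round_trip <- q10_correct(q10_correct(r, t_target = 55),
                            t_target = 30, force = TRUE)
  expect_equal(round_trip$kcat_c[1], 3)
})

test_that("control normalization scales batches by the control geomean", {
  rec <- tibble::tibble(
    variant_id = c("v1", "ctrl", "v2", "ctrl"),
    kcat_c = c(4, 8, 6, 12.5),
    batch_id = c("b1", "b1", "b2", "b2")
  )
  out <- normalize_to_control(rec, "ctrl", control_reference = 10)
  # scale factors 10/8 = 1.25 and 10/12.5 = 0.8, controls scaled too
  expect_equal(out$kcat_c, c(5, 10, 4.8, 10))

  # identity when controls already sit at the reference
  same <- tibble::tibble(variant_id = c("v", "ctrl"), kcat_c = c(3, 10),
                         batch_id = "b1")
  expect_equal(normalize_to_control(same, "ctrl", 10)$kcat_c, c(3, 10))

  # control at twice the reference halves the whole batch
  twice <- tibble::tibble(variant_id = c("v", "ctrl"), kcat_c = c(6, 20),
                          batch_id = "b1")
  expect_equal(normalize_to_control(twice, "ctrl", 10)$kcat_c, c(3, 10))
})

test_that("after normalization every batch's control geomean is the reference", {
  set.seed(77)
  rec <- tibble::tibble(
    variant_id = c(rep("ctrl", 6), sprintf("v%d", 1:9)),
    kcat_c = exp(rnorm(15, log(7), 0.5)),
    batch_id = rep(c("b1", "b2", "b3"), 5)
  )
  out <- normalize_to_control(rec, "ctrl", control_reference = 7)
  ctrl <- out[out$variant_id == "ctrl", ]
  gm <- tapply(ctrl$kcat_c, ctrl$batch_id, function(x) exp(mean(log(x))))
  expect_equal(as.numeric(gm), rep(7, 3))
})

test_that("batches missing the control are flagged and left unscaled", {
  rec <- tibble::tibble(
    variant_id = c("v1", "ctrl", "v2"),
    kcat_c = c(4, 20, 6),
    batch_id = c("b1", "b1", "b2")
  )
  expect_warning(out <- normalize_to_control(rec, "ctrl", 10), "b2")
  expect_equal(out$kcat_c[3], 6)
  expect_false(out$control_normalized[3])
  expect_equal(attr(out, "unnormalized_batches"), "b2")
})

test_that("assay calibration reduces to the geometric-mean ratio", {
  equal_pairs <- tibble::tibble(k_coupled = c(2, 5, 9), k_direct = c(2, 5, 9))
  fit <- fit_assay_correction(equal_pairs)
  expect_equal(fit$factor, 1)
  expect_equal(c(fit$ci_low, fit$ci_high), c(1, 1))

  fit2 <- fit_assay_correction(tibble::tibble(k_coupled = c(1, 2),
                                              k_direct = c(2, 4)))
  expect_equal(fit2$factor, 2)

  expect_error(fit_assay_correction(tibble::tibble(k_coupled = 1, k_direct = 2)),
               "at least 2")
  expect_error(fit_assay_correction(tibble::tibble(k_coupled = c(1, -1),
                                                   k_direct = c(2, 2))),
               "positive")
})

test_that("calibration is scale-invariant and equivariant in k_direct", {
  pairs <- simulate_rate_pairs(n_pairs = 11, beta = 2.1, seed = 5)
  f0 <- fit_assay_correction(pairs)
  scaled <- dplyr::mutate(pairs, k_coupled = k_coupled * 13.7,
                          k_direct = k_direct * 13.7)
  expect_equal(fit_assay_correction(scaled)$factor, f0$factor)
  boosted <- dplyr::mutate(pairs, k_direct = k_direct * 3)
  expect_equal(fit_assay_correction(boosted)$factor, 3 * f0$factor)
})

test_that("applying the correction multiplies once and only once", {
  rec <- tibble::tibble(variant_id = letters[1:3], kcat_c = c(10, 1, 4))
  out <- apply_correction(rec, 2.1)
  expect_equal(out$kcat_c, c(21, 2.1, 8.4))
  expect_equal(out$variant_id, rec$variant_id)
  expect_error(apply_correction(out, 2.1), "already")
  expect_equal(apply_correction(rec, 1)$kcat_c, rec$kcat_c)
})

test_that("rate summaries use linear-interpolation quantiles", {
  r <- tibble::tibble(variant_id = as.character(1:3), kcat_c = c(1, 2, 3))
  s <- summarize_rates(r)
  expect_equal(s$median, 2)
  expect_equal(summarize_rates(tibble::tibble(variant_id = c("a", "b"),
                                              kcat_c = c(4, 6)))$median, 5)

  set.seed(12)
  x <- exp(rnorm(100, log(7), 0.6))
  s <- summarize_rates(tibble::tibble(variant_id = as.character(1:100),
                                      kcat_c = x))
  # sort-based oracle for the interpolated quantiles
  xs <- sort(x)
  q_oracle <- function(p) {
    h <- (length(xs) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
  }
  expect_equal(s$median, q_oracle(0.5))
  expect_equal(s$q25, q_oracle(0.25))
  expect_equal(s$q75, q_oracle(0.75))
  expect_true(s$q25 <= s$median && s$median <= s$q75)
})

test_that("per-form summaries require and use the form column", {
  r <- tibble::tibble(variant_id = letters[1:4], kcat_c = c(1, 3, 10, 30),
                      form = c("II", "II", "III", "III"))
  s <- summarize_rates(r, by = "form")
  expect_equal(s$median[s$group == "II"], 2)
  expect_equal(s$median[s$group == "III"], 20)
  expect_error(summarize_rates(dplyr::select(r, -form), by = "form"), "form")
})

test_that("rate ratios vs identity match exhaustive pair enumeration", {
  aln <- as_alignment(tibble::tibble(
    id = c("a", "b", "c"),
    seq = c(paste(rep("A", 10), collapse = ""),
            paste(c(rep("A", 9), "C"), collapse = ""),   # 0.9 to a
            paste(c(rep("C", 5), rep("A", 5)), collapse = "")) # 0.5 to a
  ))
  rec <- tibble::tibble(variant_id = c("a", "b", "c"), kcat_c = c(2, 4, 8))
  rr <- rate_ratio_vs_identity(rec, aln, bins = c(0, 0.7, 1))
  pairs <- attr(rr, "pairs")
  expect_equal(nrow(pairs), 3) # n(n-1)/2
  expect_true(all(pairs$ratio >= 1))
  # low-identity bin holds (a,c) ratio 4 and (b,c) ratio 2; high bin (a,b)
  expect_equal(rr$median_ratio, c(3, 2))
  expect_equal(rr$n_pairs, c(2, 1))

  # equal rates give all-1 ratios everywhere
  rec1 <- dplyr::mutate(rec, kcat_c = 5)
  rr1 <- rate_ratio_vs_identity(rec1, aln, bins = c(0, 0.7, 1))
  expect_true(all(rr1$median_ratio[rr1$n_pairs > 0] == 1))
})

test_that("variants absent from the alignment are excluded with a report", {
  aln <- random_alignment(3, 10, seed = 3)
  rec <- tibble::tibble(variant_id = c("s01", "s02", "zzz"),
                        kcat_c = c(1, 2, 3))
  expect_warning(rr <- rate_ratio_vs_identity(rec, aln), "zzz")
  expect_equal(nrow(attr(rr, "pairs")), 1)
})
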