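test_that("the synthetic cohort is reproducible and respects its truncations", {
  c1 <- synthesize_cohort(20, seed = 17)
  c2 <- synthesize_cohort(20, seed = 17)
  expect_identical(c1, c2)
  c3 <- synthesize_cohort(20, seed = 18)
  expect_false(identical(c1$subjects, c3$subjects))
  expect_true(all(c1$truth$weight_kg > 40))
  expect_true(all(c1$truth$k_true > 0))
  expect_equal(c1$truth$dose_mg, 0.25 * c1$truth$weight_kg)
  expect_equal(nrow(c1$subjects), 20)
  expect_true(all(c1$subjects$n_samples == 7))
  # the generator must not disturb the session RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(synthesize_cohort(3, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("subject CSV files round-trip losslessly", {
  coh <- synthesize_cohort(4, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_subjects(coh$subjects, path)
  back <- read_subjects(path)
  expect_equal(back$subject_id, coh$subjects$subject_id)
  expect_equal(back$weight_kg, coh$subjects$weight_kg, tolerance = 1e-12)
  for (i in seq_len(4))
    expect_equal(back$samples[[i]], coh$subjects$samples[[i]],
                 tolerance = 1e-12)
})

test_that("invalid subjects are skipped with named warnings", {
  coh <- synthesize_cohort(2, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_subjects(coh$subjects, path)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  raw$conc_mg_per_L[3] <- 0                        # poison subject 1
  extra <- raw[raw$subject_id == "S002", ][1:2, ]  # 2-sample subject
  extra$subject_id <- "S999"
  readr::write_csv(rbind(raw, extra), path)

  expect_warning(expect_warning(subs <- read_subjects(path),
                                "S001"), "S999")
  expect_equal(subs$subject_id, "S002")

  # a file with no usable subject is an error
  readr::write_csv(raw[raw$subject_id == "S001", ][1, ], path)
  expect_warning(expect_error(read_subjects(path), class = "icgpv_bad_csv"))
  # missing columns are an error
  readr::write_csv(raw[, -5], path)
  expect_error(suppressWarnings(read_subjects(path)),
               class = "icgpv_bad_csv")
})

test_that("cohort estimates obey the exact extrapolation identity", {
  coh <- synthesize_cohort(12, seed = 8, sigma = 0.05)
  res <- compute_cohort_pv(coh$subjects, t_a_list = c(0, 1))
  est <- tidy(res)
  wide <- tidyr::pivot_wider(est[, c("subject_id", "t_a", "pv")],
                             names_from = "t_a", values_from = "pv",
                             names_prefix = "pv_")
  joined <- dplyr::left_join(wide, res$fits, by = "subject_id")
  # PV(t_a = 1) = PV(0) * exp(k) exactly, so the proposed estimate always
  # exceeds the traditional one when the dye decays
  expect_equal(joined$pv_1, joined$pv_0 * exp(joined$decay_rate),
               tolerance = 1e-12)
  expect_true(all(joined$pv_1 > joined$pv_0))
})

test_that("cohort summaries match a direct two-pass computation", {
  coh <- synthesize_cohort(10, seed = 21)
  res <- compute_cohort_pv(coh$subjects, t_a_list = c(0, 1))
  est <- tidy(res)
  for (ta in c(0, 1)) {
    x <- est$pv[est$t_a == ta]
    m <- sum(x) / length(x)
    s <- sqrt(sum((x - m)^2) / (length(x) - 1))  # n - 1 convention
    row <- res$summary[res$summary$t_a == ta, ]
    expect_equal(row$pv_l_mean, m, tolerance = 1e-12)
    expect_equal(row$pv_l_sd, s, tolerance = 1e-12)
    expect_equal(row$n, length(x))
  }
})

test_that("noise-free cohorts are recovered exactly at the mixing time", {
  coh <- synthesize_cohort(8, seed = 4, sigma = 0)
  res <- compute_cohort_pv(coh$subjects, t_a_list = 1)  # t_mix = 1
  est <- dplyr::left_join(tidy(res), coh$truth, by = "subject_id")
  expect_equal(est$pv, est$pv_l_true, tolerance = 1e-10)
  # and the fitted decay rates are the generating ones
  fits <- dplyr::left_join(res$fits, coh$truth, by = "subject_id")
  expect_equal(fits$decay_rate, fits$k_true, tolerance = 1e-10)
})

test_that("recovery bias shrinks with the assay noise level", {
  bias <- vapply(c(0, 0.02, 0.05), function(sig) {
    coh <- synthesize_cohort(60, seed = 31, sigma = sig)
    est <- dplyr::left_join(tidy(compute_cohort_pv(coh$subjects, 1)),
                            coh$truth, by = "subject_id")
    abs(mean(est$pv / est$pv_l_true - 1))
  }, numeric(1))
  expect_equal(bias[1], 0, tolerance = 1e-10)
  expect_lt(bias[2], 0.02)
  expect_lt(bias[3], 0.03)
})

test_that("log-linear fits on noisy cohorts look like clinical fits", {
  coh <- synthesize_cohort(36, seed = 12, sigma = 0.05)
  res <- compute_cohort_pv(coh$subjects)
  expect_true(all(res$fits$r_squared > 0.85))
  expect_true(all(res$fits$r_squared <= 1))
  # decay rates populate the clinically observed range
  expect_equal(mean(res$fits$decay_rate), 0.25, tolerance = 0.2)
})

test_that("cohort computation validates its inputs", {
  coh <- synthesize_cohort(3, seed = 2)
  expect_error(compute_cohort_pv(coh$subjects, t_a_list = numeric(0)),
               class = "icgpv_bad_ta")
  expect_error(synthesize_cohort(0, seed = 1), class = "icgpv_bad_target")
  expect_error(synthesize_cohort(5, seed = 1, sigma = -1),
               class = "icgpv_bad_target")
})
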